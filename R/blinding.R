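#' Per-arm table of end-of-trial allocation guesses
#'
#' Holds the counts of participants in one trial arm who guessed they
#' received the real intervention, the placebo, or answered "don't know".
#'
#' @param arm `"real"` or `"placebo"`: the arm's true allocation.
#' @param n_guess_real,n_guess_placebo,n_dont_know non-negative integer
#'   counts; their sum (the number of respondents) must be positive.
#' @return an object of class `guess_table`.
#' @examples
#' guess_table("real", 60, 25, 15)
#' @export
guess_table <- function(arm, n_guess_real, n_guess_placebo, n_dont_know = 0) {
  .check(is.character(arm) && length(arm) == 1L && arm %in% c("real", "placebo"),
         "arm must be \"real\" or \"placebo\"")
  for (nm in c("n_guess_real", "n_guess_placebo", "n_dont_know")) {
    .check(.is_count(get(nm)), "%s must be a non-negative integer count", nm)
  }
  total <- n_guess_real + n_guess_placebo + n_dont_know
  .check(total > 0, "guess table has no respondents (total = 0)")
  structure(list(arm = arm,
                 n_guess_real = as.integer(n_guess_real),
                 n_guess_placebo = as.integer(n_guess_placebo),
                 n_dont_know = as.integer(n_dont_know),
                 total = as.integer(total)),
            class = "guess_table")
}

#' @export
print.guess_table <- function(x, ...) {
  cat(sprintf("<guess_table> %s arm: real %d / placebo %d / don't know %d (n = %d)\n",
              x$arm, x$n_guess_real, x$n_guess_placebo, x$n_dont_know, x$total))
  invisible(x)
}

#' Bang's blinding index for one arm
#'
#' The chance-corrected proportion of participants potentially unblinded
#' beyond chance: the difference between the proportions guessing their own
#' arm and guessing the other arm, with "don't know" answers kept in the
#' denominator. Ranges over \[-1, 1\]: 1 means everyone guessed correctly, 0
#' random guessing, -1 everyone guessed the opposite arm (in a placebo arm,
#' everyone believed they got the real treatment).
#'
#' @param gt a [guess_table()].
#' @return the index, a number in \[-1, 1\].
#' @examples
#' bang_bi(guess_table("real", 60, 25, 15))   # 0.35
#' bang_bi(guess_table("placebo", 30, 0, 0))  # -1
#' @export
bang_bi <- function(gt) {
  .check(inherits(gt, "guess_table"), "gt must be a guess_table")
  correct <- if (gt$arm == "real") gt$n_guess_real else gt$n_guess_placebo
  incorrect <- if (gt$arm == "real") gt$n_guess_placebo else gt$n_guess_real
  (correct - incorrect) / gt$total
}

#' Standard error and Wald confidence interval for Bang's index
#'
#' The index is a difference of two multinomial proportions, so
#' `var = (p1 (1 - p1) + p2 (1 - p2) + 2 p1 p2) / n` with `p1` the
#' proportion guessing the arm's own intervention and `p2` the proportion
#' guessing the other one. The interval is the symmetric Wald interval
#' `bi +/- z se`; it is not truncated to \[-1, 1\] unless requested.
#'
#' @param gt a [guess_table()].
#' @param level confidence level in (0, 1); default 0.95.
#' @param truncate logical; clip the interval to \[-1, 1\] (default `FALSE`,
#'   matching usual reporting).
#' @return list with `se`, `ci_low`, `ci_high`.
#' @examples
#' bi_confidence_interval(guess_table("real", 60, 25, 15))
#' @export
bi_confidence_interval <- function(gt, level = 0.95, truncate = FALSE) {
  .check(inherits(gt, "guess_table"), "gt must be a guess_table")
  .check(is.numeric(level) && length(level) == 1L && level > 0 && level < 1,
         "level must be in (0, 1)")
  p1 <- (if (gt$arm == "real") gt$n_guess_real else gt$n_guess_placebo) / gt$total
  p2 <- (if (gt$arm == "real") gt$n_guess_placebo else gt$n_guess_real) / gt$total
  v <- (p1 * (1 - p1) + p2 * (1 - p2) + 2 * p1 * p2) / gt$total
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  bi <- bang_bi(gt)
  lo <- bi - z * se
  hi <- bi + z * se
  if (truncate) {
    lo <- max(-1, lo)
    hi <- min(1, hi)
  }
  list(se = se, ci_low = lo, ci_high = hi)
}

#' Classify a blinding-index value into a guess status
#'
#' Thresholds: random guess for -0.2 < BI < 0.2; "unblinded" (more correct
#' guesses than chance, not literally broken blinding) for BI >= 0.2;
#' opposite guess for BI <= -0.2. The boundaries belong to the non-random
#' statuses.
#'
#' @param bi a blinding index in \[-1, 1\].
#' @return `"random_guess"`, `"unblinded"` or `"opposite_guess"`.
#' @examples
#' classify_bi(0.42)
#' classify_bi(-0.21)
#' classify_bi(0.2)   # boundary: unblinded
#' @export
classify_bi <- function(bi) {
  .check(is.numeric(bi) && length(bi) == 1L && is.finite(bi),
         "bi must be a single finite number")
  .check(bi >= -1 && bi <= 1, "bi = %g is outside [-1, 1]", bi)
  if (bi >= 0.2) "unblinded"
  else if (bi <= -0.2) "opposite_guess"
  else "random_guess"
}

#' Assess blinding for one arm
#'
#' Convenience wrapper bundling [bang_bi()], [bi_confidence_interval()] and
#' [classify_bi()].
#'
#' @inheritParams bi_confidence_interval
#' @return list of class `blinding_assessment`: `bi`, `se`, `ci_low`,
#'   `ci_high`, `status`.
#' @export
assess_blinding <- function(gt, level = 0.95, truncate = FALSE) {
  bi <- bang_bi(gt)
  ci <- bi_confidence_interval(gt, level = level, truncate = truncate)
  structure(c(list(bi = bi), ci, list(status = classify_bi(bi))),
            class = "blinding_assessment")
}

# the 3x3 (experimental status, control status) -> scenario grid
.scenario_map <- data.frame(
  id = paste0("S", 1:9),
  exp_status = c("random_guess", "random_guess", "random_guess",
                 "unblinded", "unblinded", "unblinded",
                 "opposite_guess", "opposite_guess", "opposite_guess"),
  ctrl_status = c("random_guess", "opposite_guess", "unblinded",
                  "unblinded", "opposite_guess", "random_guess",
                  "opposite_guess", "random_guess", "unblinded"),
  interpretation = c(
    "possibly most ideal from a scientific/statistical perspective",
    "rare",
    "possibly little treatment effect and no effect in control group",
    "possibly problematic",
    "ideal; wishful thinking, any treatment perceived as real",
    "possibly problematic; control arm does not know what to expect",
    "rare",
    "rare",
    "no treatment effect at all, or low expectations"),
  stringsAsFactors = FALSE
)

#' The nine blinding scenarios
#'
#' Each study is classified by the pair of guess statuses of its
#' experimental (real) and control (placebo) arms, giving nine scenarios
#' S1-S9, each with a stock interpretation (S1 and S5 are regarded as the
#' ideal blinding situations; S4 and S6 as possibly problematic).
#'
#' @param exp_status,ctrl_status guess statuses (`"random_guess"`,
#'   `"unblinded"`, `"opposite_guess"`) of the experimental and control arm.
#' @return list with `id` (`"S1"`..`"S9"`), `exp_status`, `ctrl_status`,
#'   `interpretation`.
#' @examples
#' assign_scenario("unblinded", "opposite_guess")$id  # "S5"
#' @export
assign_scenario <- function(exp_status, ctrl_status) {
  valid <- c("random_guess", "unblinded", "opposite_guess")
  .check(exp_status %in% valid, "invalid exp_status: %s", exp_status)
  .check(ctrl_status %in% valid, "invalid ctrl_status: %s", ctrl_status)
  i <- which(.scenario_map$exp_status == exp_status &
               .scenario_map$ctrl_status == ctrl_status)
  as.list(.scenario_map[i, ])
}

#' @rdname assign_scenario
#' @return `scenario_definitions()` returns the full 9-row scenario grid as
#'   a data frame.
#' @export
scenario_definitions <- function() .scenario_map

#' Mann-Whitney U test (two-sided)
#'
#' Exact test by enumeration of all group assignments when both groups have
#' at most 8 observations (ties handled by mid-ranks within the
#' enumeration); otherwise the normal approximation with tie correction and
#' no continuity correction. The reported statistic is U for the first
#' group: the number of (a, b) pairs with a > b, counting ties as 1/2.
#'
#' @param a,b numeric vectors.
#' @return list with `statistic` (U for `a`), `p` (two-sided), and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(a, b) {
  .check(is.numeric(a) && is.numeric(b) && length(a) > 0 && length(b) > 0,
         "both groups must be non-empty numeric vectors")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx1) sum(r[idx1]) - n1 * (n1 + 1) / 2
  u <- u_of(seq_len(n1))
  if (n1 <= 8 && n2 <= 8) {
    combos <- utils::combn(n1 + n2, n1)
    us <- apply(combos, 2, u_of)
    p <- min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
    method <- "exact"
  } else {
    n <- n1 + n2
    t_sizes <- table(pooled)
    tie_term <- sum(t_sizes^3 - t_sizes) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (u - n1 * n2 / 2) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = u, p = p, method = method)
}

#' Compare blinding indices between two groups of arms
#'
#' Used to compare BI distributions between disclosure categories (e.g.
#' placebo-arm BIs under full vs no disclosure). Each group is first checked
#' for normality with the Shapiro-Wilk test; if both pass at `alpha` the
#' two-sided independent t-test is used, otherwise the two-sided
#' Mann-Whitney U test. A constant group (Shapiro-Wilk undefined) is treated
#' as non-normal.
#'
#' @param group_a,group_b numeric vectors of per-arm blinding indices, each
#'   of length >= 3.
#' @param alpha significance level gating the normality check (default
#'   0.05).
#' @param force `"auto"` (default), `"t"` or `"mann_whitney"` to override
#'   the distribution-based choice.
#' @param welch logical; use the Welch (unequal variance) t-test instead of
#'   the equal-variance Student form (default `FALSE`).
#' @return list with `test` (`"t"` or `"mann_whitney"`), `statistic`, `p`,
#'   and the two Shapiro-Wilk p-values (`shapiro_p_a`, `shapiro_p_b`; `NA`
#'   when forced).
#' @export
compare_bi_groups <- function(group_a, group_b, alpha = 0.05,
                              force = c("auto", "t", "mann_whitney"),
                              welch = FALSE) {
  force <- match.arg(force)
  .check(length(group_a) >= 3 && length(group_b) >= 3,
         "each group needs at least 3 values (normality test undefined below n = 3)")
  .check(is.numeric(alpha) && alpha > 0 && alpha < 1, "alpha must be in (0, 1)")

  sw_p <- function(x) {
    if (length(unique(x)) == 1L) return(0)  # constant: clearly non-normal
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  }
  p_a <- p_b <- NA_real_
  if (force == "auto") {
    p_a <- sw_p(group_a); p_b <- sw_p(group_b)
    test <- if (p_a > alpha && p_b > alpha) "t" else "mann_whitney"
  } else {
    test <- if (force == "t") "t" else "mann_whitney"
  }
  if (test == "t") {
    tt <- stats::t.test(group_a, group_b, var.equal = !welch)
    res <- list(test = "t", statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    mw <- mann_whitney_u(group_a, group_b)
    res <- list(test = "mann_whitney", statistic = mw$statistic, p = mw$p)
  }
  c(res, list(shapiro_p_a = p_a, shapiro_p_b = p_b))
}

#' Per-arm blinding assessment of a guesses table
#'
#' Vectorized front end: takes the guesses CSV schema (one row per arm) and
#' returns BI, SE, CI and status per row, plus the per-study scenario when
#' both arms of a study are present.
#'
#' @param guesses data frame with columns `study_id`, `arm`
#'   (`"real"|"placebo"`), `n_guess_real`, `n_guess_placebo`, `n_dont_know`,
#'   and optionally `category`, `region`.
#' @inheritParams bi_confidence_interval
#' @return list with `arms` (the input plus `bi`, `se`, `ci_low`, `ci_high`,
#'   `status`) and `scenarios` (one row per study with both arms: `study_id`,
#'   `scenario`, `exp_status`, `ctrl_status`, plus `category`/`region` when
#'   available).
#' @export
assess_corpus_blinding <- function(guesses, level = 0.95, truncate = FALSE) {
  need <- c("study_id", "arm", "n_guess_real", "n_guess_placebo", "n_dont_know")
  .check(all(need %in% names(guesses)),
         "guesses needs columns: %s", paste(need, collapse = ", "))
  n <- nrow(guesses)
  arms <- guesses
  arms$bi <- arms$se <- arms$ci_low <- arms$ci_high <- NA_real_
  arms$status <- NA_character_
  for (i in seq_len(n)) {
    gt <- guess_table(guesses$arm[i], guesses$n_guess_real[i],
                      guesses$n_guess_placebo[i], guesses$n_dont_know[i])
    ba <- assess_blinding(gt, level = level, truncate = truncate)
    arms$bi[i] <- ba$bi; arms$se[i] <- ba$se
    arms$ci_low[i] <- ba$ci_low; arms$ci_high[i] <- ba$ci_high
    arms$status[i] <- ba$status
  }
  scen <- NULL
  for (sid in unique(arms$study_id)) {
    sub <- arms[arms$study_id == sid, ]
    if (all(c("real", "placebo") %in% sub$arm)) {
      es <- sub$status[sub$arm == "real"][1]
      cs <- sub$status[sub$arm == "placebo"][1]
      sc <- assign_scenario(es, cs)
      row <- data.frame(study_id = sid, scenario = sc$id,
                        exp_status = es, ctrl_status = cs,
                        stringsAsFactors = FALSE)
      for (extra in intersect(c("category", "region"), names(sub))) {
        row[[extra]] <- sub[[extra]][1]
      }
      scen <- rbind(scen, row)
    }
  }
  list(arms = arms, scenarios = scen)
}

#' Scenario frequency grid by disclosure group
#'
#' Tabulates per-study blinding scenarios (S1-S9) within each disclosure
#' group, as counts and half-up one-decimal percentages, in the layout of a
#' scenario-frequency table.
#'
#' @param scenarios data frame from [assess_corpus_blinding()] (`$scenarios`)
#'   with columns `scenario` and a grouping column.
#' @param group name of the grouping column (default `"category"`).
#' @return data frame with one row per scenario (S1-S9): `scenario`,
#'   `exp_status`, `ctrl_status`, `interpretation`, then `n_<g>` and
#'   `pct_<g>` per group level.
#' @export
scenario_grid <- function(scenarios, group = "category") {
  .check(is.data.frame(scenarios) && "scenario" %in% names(scenarios),
         "scenarios must have a 'scenario' column")
  .check(group %in% names(scenarios), "grouping column '%s' not found", group)
  out <- .scenario_map
  names(out)[names(out) == "id"] <- "scenario"
  for (g in unique(scenarios[[group]])) {
    sub <- scenarios[scenarios[[group]] == g, ]
    cnt <- as.integer(table(factor(sub$scenario, levels = out$scenario)))
    out[[paste0("n_", g)]] <- cnt
    out[[paste0("pct_", g)]] <- round_half_up(100 * cnt / nrow(sub), 1)
  }
  out
}
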