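#' Guess-model probabilities and expected blinding index
#'
#' The generator's three-parameter guess model: each participant
#' independently (i) perceives their true assignment with probability
#' `p_perceive` and guesses it correctly, (ii) answers "don't know" with
#' probability `p_dontknow`, or (iii) otherwise guesses "real" with
#' probability `w_wishful` (wishful thinking) and "placebo" with
#' `1 - w_wishful`. With `r = 1 - p_perceive - p_dontknow` the expected
#' Bang index is `p_perceive + r (2 w_wishful - 1)` in the real arm and
#' `p_perceive + r (1 - 2 w_wishful)` in the placebo arm, so the model can
#' realize every combination of the nine blinding scenarios.
#'
#' @param arm `"real"` or `"placebo"`.
#' @param params list with `p_perceive`, `w_wishful`, `p_dontknow`, each a
#'   probability with `p_perceive + p_dontknow <= 1`.
#' @return `guess_probs()`: named numeric vector `c(real, placebo,
#'   dont_know)` of guess probabilities; `expected_bi()`: the expected Bang
#'   index for the arm.
#' @export
guess_probs <- function(arm, params) {
  .validate_guess_params(params)
  p <- params$p_perceive; d <- params$p_dontknow; w <- params$w_wishful
  r <- 1 - p - d
  if (arm == "real") {
    c(real = p + r * w, placebo = r * (1 - w), dont_know = d)
  } else if (arm == "placebo") {
    c(real = r * w, placebo = p + r * (1 - w), dont_know = d)
  } else stop("arm must be \"real\" or \"placebo\"", call. = FALSE)
}

#' @rdname guess_probs
#' @export
expected_bi <- function(arm, params) {
  pr <- guess_probs(arm, params)
  if (arm == "real") unname(pr["real"] - pr["placebo"])
  else unname(pr["placebo"] - pr["real"])
}

.validate_guess_params <- function(params) {
  .check(all(c("p_perceive", "w_wishful", "p_dontknow") %in% names(params)),
         "guess params need p_perceive, w_wishful, p_dontknow")
  for (nm in c("p_perceive", "w_wishful", "p_dontknow")) {
    .check(.is_prob(params[[nm]]), "%s must be a probability in [0, 1]", nm)
  }
  .check(params$p_perceive + params$p_dontknow <= 1,
         "infeasible guess model: p_perceive + p_dontknow > 1")
  invisible(TRUE)
}

#' Solve guess-model parameters for target mean blinding indices
#'
#' Inverts the closed-form expected-BI expressions of [guess_probs()]: given
#' target mean BIs for the real and placebo arm of one disclosure category
#' and a fixed don't-know rate, returns the `(p_perceive, w_wishful,
#' p_dontknow)` triple whose expectations match exactly. Used once to set
#' the package defaults from published category means; no stochastic search
#' is involved.
#'
#' @param bi_real,bi_placebo target expected Bang indices.
#' @param p_dontknow fixed don't-know probability.
#' @return a guess-parameter list accepted by [guess_probs()].
#' @examples
#' p <- solve_guess_params(0.42, -0.16, 0.12)
#' expected_bi("real", p)     # 0.42
#' expected_bi("placebo", p)  # -0.16
#' @export
solve_guess_params <- function(bi_real, bi_placebo, p_dontknow = 0.12) {
  p <- (bi_real + bi_placebo) / 2
  .check(p >= 0 && p <= 1, "targets imply p_perceive = %g outside [0, 1]", p)
  r <- 1 - p - p_dontknow
  .check(r > 0, "infeasible: p_perceive + p_dontknow >= 1")
  delta <- (bi_real - bi_placebo) / 2  # = r (2 w - 1)
  w <- (delta / r + 1) / 2
  .check(w >= 0 && w <= 1, "targets imply w_wishful = %g outside [0, 1]", w)
  params <- list(p_perceive = p, w_wishful = w, p_dontknow = p_dontknow)
  .validate_guess_params(params)
  params
}

#' Simulation configuration for a synthetic PIL/trial corpus
#'
#' Defaults encode the corpus the analysis was designed around: 70 placebo
#' groups (40 FD / 25 DD / 5 MI) described in 65 PILs; guess data for 17 FD
#' and 11 DD-or-MI groups (10 DD + 1 MI); continuous outcome data for 14 FD
#' and 10 DD comparisons (none from MI); per-arm sample sizes uniform on
#' 16..88 so per-study SMD standard errors span roughly 0.15-0.35; true
#' subgroup effects -0.12 (FD) and -0.43 (DD) with between-study SD
#' `tau = 0.1`; and per-category guess models solved analytically (see
#' [solve_guess_params()]) so expected Bang indices are 0.42/-0.16 (FD) and
#' 0.41/-0.21 (DD, shared by MI).
#'
#' @param k_fd,k_dd,k_mi placebo-group counts per disclosure category.
#' @param n_twin_pils how many PILs describe two placebo groups (so the
#'   number of PILs is `k_fd + k_dd + k_mi - n_twin_pils`).
#' @param n_bi_fd,n_bi_dd,n_bi_mi how many groups per category carry
#'   end-of-trial guess data.
#' @param n_meta_fd,n_meta_dd how many groups per category carry outcome
#'   data (MI never does).
#' @param n_per_arm_range integer range (min, max) for per-arm sample sizes.
#' @param true_smd_fd,true_smd_dd true subgroup standardized mean
#'   differences (negative favors the real intervention).
#' @param tau between-study SD of the true per-study effect.
#' @param guess_params named list `fd`, `dd`, `mi` of guess-model parameter
#'   lists.
#' @param p_asia per-category probability that a group's trial is from Asia.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(k_fd = 40, k_dd = 25, k_mi = 5,
                       n_twin_pils = 5,
                       n_bi_fd = 17, n_bi_dd = 10, n_bi_mi = 1,
                       n_meta_fd = 14, n_meta_dd = 10,
                       n_per_arm_range = c(16, 88),
                       true_smd_fd = -0.12, true_smd_dd = -0.43,
                       tau = 0.1,
                       guess_params = list(
                         fd = solve_guess_params(0.42, -0.16, 0.12),
                         dd = solve_guess_params(0.41, -0.21, 0.12),
                         mi = solve_guess_params(0.41, -0.21, 0.12)),
                       p_asia = c(fd = 0.30, dd = 0.65, mi = 0.65)) {
  for (nm in c("k_fd", "k_dd", "k_mi")) .check(.is_count(get(nm)), "%s must be a count", nm)
  .check(n_bi_fd <= k_fd && n_bi_dd <= k_dd && n_bi_mi <= k_mi,
         "guess-data counts cannot exceed category sizes")
  .check(n_meta_fd <= k_fd && n_meta_dd <= k_dd,
         "outcome-data counts cannot exceed category sizes")
  .check(n_twin_pils <= k_fd + k_dd + k_mi - 1,
         "n_twin_pils too large for the corpus")
  .check(length(n_per_arm_range) == 2L && n_per_arm_range[1] >= 2 &&
           n_per_arm_range[2] >= n_per_arm_range[1],
         "n_per_arm_range must be an increasing pair >= 2")
  lapply(guess_params, .validate_guess_params)
  structure(list(k_fd = k_fd, k_dd = k_dd, k_mi = k_mi,
                 n_twin_pils = n_twin_pils,
                 n_bi_fd = n_bi_fd, n_bi_dd = n_bi_dd, n_bi_mi = n_bi_mi,
                 n_meta_fd = n_meta_fd, n_meta_dd = n_meta_dd,
                 n_per_arm_range = as.integer(n_per_arm_range),
                 true_smd = c(fd = true_smd_fd, dd = true_smd_dd, mi = NA_real_),
                 tau = tau, guess_params = guess_params, p_asia = p_asia),
            class = "sim_config")
}

# deterministic per-study substream seed below 2^31 - 1
.stream_seed <- function(seed, i) {
  as.integer((abs(seed) %% 2147483647) * 1009 + i * 7919) %% 2147483647L
}

# snippet templates; %s is filled with a lexicon token of the right tier
.fd_templates <- c(
  "You will be randomly assigned to receive real acupuncture or %s acupuncture.",
  "Half of the participants will receive a %s treatment instead of real acupuncture.",
  "The comparison group will be treated with %s needles.")
.fd_escalated_templates <- c(
  "You will be allocated to the control group, which will receive needling at non-acupoint locations.",
  "Participants in group two will receive a needle that does not penetrate the skin.",
  "The control group will be needled away from true points.")
.dd_templates <- c(
  "You will be assigned to group one or group two.",
  "You may be allocated to the control group of this study.",
  "Some participants will receive a different style of acupuncture.",
  "You may be assigned to a non-traditional acupuncture group.",
  "One group will receive a treatment that is not typical acupuncture.",
  "You will receive one of two test treatments.")
.mi_templates <- c(
  "",
  "This study examines acupuncture for chronic pain over eight weeks.",
  "You will receive acupuncture treatment once a week for the duration of the study.",
  "The study involves weekly acupuncture sessions and questionnaires about your symptoms.")

.snippet_text <- function(category, escalate, rules) {
  if (category == "FD") {
    if (escalate) sample(.fd_escalated_templates, 1)
    else sprintf(sample(.fd_templates, 1), sample(rules$fd, 1))
  } else if (category == "DD") {
    sample(.dd_templates, 1)
  } else {
    sample(.mi_templates, 1)
  }
}

#' Draw one arm's guess counts
#'
#' Multinomial draw of (guess real, guess placebo, don't know) counts for
#' `n` respondents under the three-parameter guess model.
#'
#' @param n number of respondents.
#' @param arm `"real"` or `"placebo"`.
#' @param params guess-model parameters (see [guess_probs()]).
#' @return integer vector `c(n_guess_real, n_guess_placebo, n_dont_know)`
#'   summing to `n`. Uses the current RNG state.
#' @export
simulate_guess_counts <- function(n, arm, params) {
  .check(.is_count(n) && n >= 1, "n must be a positive count")
  pr <- guess_probs(arm, params)
  drop(stats::rmultinom(1, n, pr))
}

#' Generate a synthetic PIL / guess-table / outcome corpus
#'
#' Produces the three inputs of the analysis pipeline with known truth:
#' PIL snippets whose text is built from the disclosure lexicon (so the
#' rule-based coder recovers the intended category), per-arm guess tables
#' drawn from the category's guess model, and continuous outcome summaries
#' whose true standardized mean difference is the category effect plus a
#' normal between-study deviation (`tau`). Outcomes are simulated at the
#' summary level: observed arm means carry sampling error `sd/sqrt(n)` and
#' observed SDs are chi-square draws, with true placebo mean 0 and SD 1.
#'
#' Each placebo group has its own RNG substream derived from `seed`, so a
#' corpus is reproducible and individual groups are stable when category
#' counts change.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @param rules disclosure lexicon used for snippet templates.
#' @return list of class `sim_corpus` with data frames `pils` (`pil_id`,
#'   `placebo_group_id`, `text`, `region`), `guesses` (guess-table schema,
#'   two rows per group with blinding data), `outcomes` (continuous-summary
#'   schema incl. `shared_arm_k = 1`), and `truth` (`study_id`, `category`,
#'   `region`, `true_smd`, `has_bi`, `has_outcome`).
#' @export
generate_corpus <- function(config = sim_config(), seed = 1,
                            rules = disclosure_rules()) {
  .check(inherits(config, "sim_config"), "config must be a sim_config")
  k_tot <- config$k_fd + config$k_dd + config$k_mi
  categories <- rep(c("FD", "DD", "MI"), c(config$k_fd, config$k_dd, config$k_mi))
  idx_in_cat <- stats::ave(seq_len(k_tot), categories, FUN = seq_along)
  n_bi <- c(FD = config$n_bi_fd, DD = config$n_bi_dd, MI = config$n_bi_mi)
  n_meta <- c(FD = config$n_meta_fd, DD = config$n_meta_dd, MI = 0)
  n_pils <- k_tot - config$n_twin_pils

  pils <- guesses <- outcomes <- truth <- NULL
  for (i in seq_len(k_tot)) {
    cat_i <- categories[i]
    key <- tolower(cat_i)
    old <- .Random.seed_save()
    set.seed(.stream_seed(seed, i))

    region <- if (stats::runif(1) < config$p_asia[[key]]) "Asia" else "non-Asia"
    escalate <- cat_i == "FD" && stats::runif(1) < 0.25
    text <- .snippet_text(cat_i, escalate, rules)
    pil_idx <- if (i <= n_pils) i else i - config$n_twin_pils
    gid <- sprintf("G%03d", i)
    pils <- rbind(pils, data.frame(
      pil_id = sprintf("P%03d", pil_idx), placebo_group_id = gid,
      text = text, region = region, stringsAsFactors = FALSE))

    has_bi <- idx_in_cat[i] <= n_bi[[cat_i]]
    if (has_bi) {
      gp <- config$guess_params[[key]]
      for (arm in c("real", "placebo")) {
        n_arm <- sample(config$n_per_arm_range[1]:config$n_per_arm_range[2], 1)
        cnt <- simulate_guess_counts(n_arm, arm, gp)
        guesses <- rbind(guesses, data.frame(
          study_id = gid, arm = arm,
          n_guess_real = cnt[1], n_guess_placebo = cnt[2], n_dont_know = cnt[3],
          category = cat_i, region = region, stringsAsFactors = FALSE))
      }
    }

    has_outcome <- idx_in_cat[i] <= n_meta[[cat_i]]
    theta <- NA_real_
    if (has_outcome) {
      theta <- config$true_smd[[key]] + stats::rnorm(1, 0, config$tau)
      n_r <- sample(config$n_per_arm_range[1]:config$n_per_arm_range[2], 1)
      n_p <- sample(config$n_per_arm_range[1]:config$n_per_arm_range[2], 1)
      outcomes <- rbind(outcomes, data.frame(
        study_id = gid, category = cat_i, region = region,
        outcome_type = "continuous",
        mean_real = stats::rnorm(1, theta, 1 / sqrt(n_r)),
        sd_real = sqrt(stats::rchisq(1, n_r - 1) / (n_r - 1)),
        n_real = n_r,
        mean_placebo = stats::rnorm(1, 0, 1 / sqrt(n_p)),
        sd_placebo = sqrt(stats::rchisq(1, n_p - 1) / (n_p - 1)),
        n_placebo = n_p,
        shared_arm_k = 1L, stringsAsFactors = FALSE))
    }

    truth <- rbind(truth, data.frame(
      study_id = gid, category = cat_i, region = region, true_smd = theta,
      has_bi = has_bi, has_outcome = has_outcome, stringsAsFactors = FALSE))
    .Random.seed_restore(old)
  }
  structure(list(pils = pils, guesses = guesses, outcomes = outcomes,
                 truth = truth),
            class = "sim_corpus")
}

# save/restore the global RNG state so corpus generation does not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a synthetic corpus to disk
#'
#' Writes `pils.jsonl` (one JSON object per placebo group), `guesses.csv`
#' and `outcomes.csv` in the schemas read by the pipeline, plus
#' `truth.csv`.
#'
#' @param corpus a `sim_corpus` from [generate_corpus()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_corpus <- function(corpus, dir) {
  .check(inherits(corpus, "sim_corpus"), "corpus must be a sim_corpus")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pils = file.path(dir, "pils.jsonl"),
             guesses = file.path(dir, "guesses.csv"),
             outcomes = file.path(dir, "outcomes.csv"),
             truth = file.path(dir, "truth.csv"))
  con <- file(paths["pils"], "w")
  for (i in seq_len(nrow(corpus$pils))) {
    writeLines(jsonlite::toJSON(as.list(corpus$pils[i, ]), auto_unbox = TRUE), con)
  }
  close(con)
  utils::write.csv(corpus$guesses, paths["guesses"], row.names = FALSE, quote = FALSE)
  utils::write.csv(corpus$outcomes, paths["outcomes"], row.names = FALSE, quote = FALSE)
  utils::write.csv(corpus$truth, paths["truth"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Parameter-recovery study over replicated synthetic corpora
#'
#' Runs the full pipeline (disclosure coding, blinding indices, effect
#' sizes, subgroup meta-analysis) on `n_reps` independently seeded corpora
#' and summarizes how well the known truth is recovered.
#'
#' @param config a [sim_config()].
#' @param n_reps number of replicate corpora.
#' @param seed master seed; replicate `r` uses `seed + r`.
#' @param rules disclosure lexicon.
#' @return list with `n_reps`; `coding_agreement` (proportion of placebo
#'   groups whose coded category equals the generating category, pooled over
#'   replicates); `mean_bi` (mean per-arm Bang index by category and arm);
#'   per-subgroup `mean_est`, `bias`, `coverage` (CI covering the true
#'   subgroup effect) for FD and DD; and `subgroup_rejection_rate`
#'   (proportion of replicates with subgroup-difference p < 0.05).
#' @export
recover_parameters <- function(config = sim_config(), n_reps = 100, seed = 1,
                               rules = disclosure_rules()) {
  .check(.is_count(n_reps) && n_reps >= 1, "n_reps must be a positive count")
  est <- matrix(NA_real_, n_reps, 2, dimnames = list(NULL, c("FD", "DD")))
  cover <- matrix(NA, n_reps, 2, dimnames = list(NULL, c("FD", "DD")))
  reject <- logical(n_reps)
  agree_num <- agree_den <- 0
  bi_sum <- bi_n <- matrix(0, 3, 2, dimnames = list(c("FD", "DD", "MI"),
                                                    c("real", "placebo")))
  truths <- c(FD = config$true_smd[["fd"]], DD = config$true_smd[["dd"]])
  for (r in seq_len(n_reps)) {
    corpus <- generate_corpus(config, seed = seed + r, rules = rules)
    coded <- code_corpus(corpus$pils, rules)
    agree_num <- agree_num + sum(coded$category == corpus$truth$category)
    agree_den <- agree_den + nrow(coded)

    if (!is.null(corpus$guesses)) {
      ba <- assess_corpus_blinding(corpus$guesses)
      for (i in seq_len(nrow(ba$arms))) {
        a <- ba$arms[i, ]
        bi_sum[a$category, a$arm] <- bi_sum[a$category, a$arm] + a$bi
        bi_n[a$category, a$arm] <- bi_n[a$category, a$arm] + 1
      }
    }

    if (!is.null(corpus$outcomes)) {
      effects <- compute_effects(corpus$outcomes)
      pooled <- pool_by_subgroup(effects, group = "category")
      for (g in c("FD", "DD")) {
        res <- pooled$subgroups[[g]]
        if (is.null(res)) next
        est[r, g] <- res$pooled
        cover[r, g] <- res$ci_low <= truths[[g]] && truths[[g]] <= res$ci_high
      }
      reject[r] <- !is.null(pooled$comparison) && pooled$comparison$p_between < 0.05
    }
  }
  mean_est <- colMeans(est)
  list(n_reps = n_reps,
       coding_agreement = agree_num / agree_den,
       mean_bi = ifelse(bi_n > 0, bi_sum / bi_n, NA),
       mean_est = mean_est,
       bias = mean_est - truths,
       coverage = colMeans(cover),
       subgroup_rejection_rate = mean(reject))
}
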