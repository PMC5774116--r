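#' DerSimonian-Laird random-effects pooling (generic inverse variance)
#'
#' Pools per-study effects with the method-of-moments between-study variance:
#' fixed weights `w_i = 1/var_i` give the fixed-effect mean and Cochran's
#' `Q = sum w_i (theta_i - theta_FE)^2`; then
#' `tau2 = max(0, (Q - df) / C)` with `C = sum(w) - sum(w^2)/sum(w)`;
#' random-effects weights `w*_i = 1/(var_i + tau2)` give the pooled estimate,
#' `se = 1/sqrt(sum w*)`, a normal-quantile CI and two-sided z-test.
#' `I2 = max(0, (Q - df)/Q) * 100`. No Knapp-Hartung adjustment.
#'
#' @param smd numeric vector of per-study effects (any inverse-variance
#'   scale; here standardized mean differences, negative favoring the real
#'   intervention).
#' @param var_smd numeric vector of their variances, all > 0.
#' @param level confidence level (default 0.95).
#' @param labels optional study labels for the weights.
#' @return list of class `meta_result`: `k`, `pooled`, `se`, `ci_low`,
#'   `ci_high`, `z`, `p`, `Q`, `df_q`, `tau2`, `i2` (percent), `weights`
#'   (normalized random-effects weights summing to 1).
#' @examples
#' pool_random_effects(c(0, 1), c(0.04, 0.04))  # Q = 12.5, tau2 = 0.46
#' @export
pool_random_effects <- function(smd, var_smd, level = 0.95, labels = NULL) {
  .check(length(smd) >= 1L, "no effects to pool")
  .check(length(var_smd) == length(smd), "smd and var_smd lengths differ")
  .check(all(is.finite(smd)) && all(is.finite(var_smd)) && all(var_smd > 0),
         "all variances must be finite and > 0")
  .check(is.numeric(level) && level > 0 && level < 1, "level must be in (0, 1)")
  k <- length(smd)
  w <- 1 / var_smd
  theta_fe <- sum(w * smd) / sum(w)
  q <- sum(w * (smd - theta_fe)^2)
  df_q <- k - 1L
  tau2 <- if (k == 1L) 0 else {
    c_dl <- sum(w) - sum(w^2) / sum(w)
    max(0, (q - df_q) / c_dl)
  }
  ws <- 1 / (var_smd + tau2)
  pooled <- sum(ws * smd) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  z <- pooled / se
  zq <- stats::qnorm(1 - (1 - level) / 2)
  i2 <- if (q > 0) max(0, (q - df_q) / q) * 100 else 0
  structure(list(k = k, pooled = pooled, se = se,
                 ci_low = pooled - zq * se, ci_high = pooled + zq * se,
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 Q = q, df_q = df_q, tau2 = tau2, i2 = i2,
                 weights = stats::setNames(ws / sum(ws), labels)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> k = %d: pooled %.4f [%.4f, %.4f], p = %.4g\n",
              x$k, x$pooled, x$ci_low, x$ci_high, x$p))
  cat(sprintf("  Q = %.4f (df %d), tau2 = %.4f, I2 = %.1f%%\n",
              x$Q, x$df_q, x$tau2, x$i2))
  invisible(x)
}

#' Test for subgroup differences (subtotals-as-studies)
#'
#' Compares random-effects subtotals between subgroups by treating each
#' subgroup's pooled estimate as a single observation weighted by the
#' reciprocal of its squared standard error: Cochran's
#' `Q_between = sum w_g (theta_g - theta_bar)^2` on `#subgroups - 1` degrees
#' of freedom, with `I2_between = max(0, (Q_between - df)/Q_between) * 100`.
#'
#' @param results named list of [pool_random_effects()] results (or any
#'   lists with elements `pooled` and `se`), one per subgroup; >= 2
#'   subgroups, all with `se > 0`.
#' @return list of class `subgroup_comparison`: `subgroup_results`,
#'   `q_between`, `df_between`, `p_between`, `i2_between`.
#' @export
subgroup_difference <- function(results) {
  .check(is.list(results) && length(results) >= 2L,
         "need at least 2 subgroups to compare")
  est <- vapply(results, function(r) r$pooled, numeric(1))
  se <- vapply(results, function(r) r$se, numeric(1))
  .check(all(is.finite(se)) && all(se > 0),
         "every subgroup must have a positive standard error")
  w <- 1 / se^2
  theta_bar <- sum(w * est) / sum(w)
  q <- sum(w * (est - theta_bar)^2)
  df <- length(results) - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  structure(list(subgroup_results = results,
                 q_between = q, df_between = df,
                 p_between = stats::pchisq(q, df, lower.tail = FALSE),
                 i2_between = i2),
            class = "subgroup_comparison")
}

#' @export
print.subgroup_comparison <- function(x, ...) {
  cat(sprintf("<subgroup_comparison> %d subgroups: Q = %.4f (df %d), p = %.4g, I2 = %.1f%%\n",
              length(x$subgroup_results), x$q_between, x$df_between,
              x$p_between, x$i2_between))
  invisible(x)
}

#' Pool effects within subgroups and test their difference
#'
#' Convenience wrapper over [pool_random_effects()] and
#' [subgroup_difference()] for an effects table. Subgroups with no usable
#' rows are dropped with a warning (e.g. a missing-information category that
#' contributed no outcome data).
#'
#' @param effects data frame from [compute_effects()] (columns `smd`,
#'   `var_smd`, a grouping column, optionally `study_id`).
#' @param group name of the grouping column (default `"category"`).
#' @param level confidence level.
#' @return list with `subgroups` (named list of `meta_result`s),
#'   `comparison` (`subgroup_comparison`, or `NULL` if < 2 subgroups
#'   remain), and `dropped` (character vector of dropped subgroup labels).
#' @export
pool_by_subgroup <- function(effects, group = "category", level = 0.95) {
  .check(is.data.frame(effects) && all(c("smd", "var_smd") %in% names(effects)),
         "effects needs columns smd and var_smd")
  .check(group %in% names(effects), "grouping column '%s' not found", group)
  labs <- unique(effects[[group]])
  subgroups <- list()
  dropped <- character(0)
  for (g in labs) {
    sub <- effects[effects[[group]] == g & is.finite(effects$smd) &
                     is.finite(effects$var_smd) & effects$var_smd > 0, ]
    if (nrow(sub) == 0L) {
      warning(sprintf("subgroup '%s' contributed no poolable effect data; dropped", g),
              call. = FALSE)
      dropped <- c(dropped, g)
      next
    }
    lbl <- if ("study_id" %in% names(sub)) sub$study_id else NULL
    subgroups[[g]] <- pool_random_effects(sub$smd, sub$var_smd,
                                          level = level, labels = lbl)
  }
  comparison <- if (length(subgroups) >= 2L) subgroup_difference(subgroups) else NULL
  list(subgroups = subgroups, comparison = comparison, dropped = dropped)
}

#' Plain-text forest table
#'
#' A forest-plot-shaped table without the graphics: one row per study with
#' its SMD, CI, and normalized random-effects weight (percent, one
#' decimal), followed by a subtotal row per subgroup.
#'
#' @param pooled result of [pool_by_subgroup()].
#' @param effects the effects data frame that was pooled.
#' @param group grouping column name used in the pooling.
#' @param level confidence level for the per-study CIs.
#' @return data frame with columns `subgroup`, `study_id`, `smd`, `ci_low`,
#'   `ci_high`, `weight_pct`, `row_type` (`"study"` or `"subtotal"`).
#' @export
forest_table <- function(pooled, effects, group = "category", level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- NULL
  for (g in names(pooled$subgroups)) {
    res <- pooled$subgroups[[g]]
    sub <- effects[effects[[group]] == g & is.finite(effects$smd) &
                     is.finite(effects$var_smd) & effects$var_smd > 0, ]
    rows <- data.frame(
      subgroup = g,
      study_id = if ("study_id" %in% names(sub)) sub$study_id else as.character(seq_len(nrow(sub))),
      smd = sub$smd,
      ci_low = sub$smd - zq * sub$se_smd,
      ci_high = sub$smd + zq * sub$se_smd,
      weight_pct = round_half_up(100 * unname(res$weights), 1),
      row_type = "study", stringsAsFactors = FALSE)
    subtotal <- data.frame(
      subgroup = g, study_id = sprintf("subtotal (%s)", g),
      smd = res$pooled, ci_low = res$ci_low, ci_high = res$ci_high,
      weight_pct = 100, row_type = "subtotal", stringsAsFactors = FALSE)
    out <- rbind(out, rows, subtotal)
  }
  out
}
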