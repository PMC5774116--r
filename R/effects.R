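#' Standardized mean difference from continuous summaries
#'
#' Hedges' g with the usual inverse-variance-ready variance: the raw
#' standardized difference `d = (mean_real - mean_placebo) / s_pooled` (df-
#' weighted pooled SD) is shrunk by the small-sample factor
#' `J = 1 - 3 / (4 (n1 + n2 - 2) - 1)`, and
#' `var(g) = (n1 + n2) / (n1 n2) + g^2 / (2 (n1 + n2))`. Under this
#' package's sign convention a negative SMD favors the real intervention,
#' so outcomes must be coded so that lower is better (or the caller negates
#' afterwards).
#'
#' @param mean_real,sd_real,n_real,mean_placebo,sd_placebo,n_placebo per-arm
#'   mean, SD (>= 0) and sample size (>= 2) of the chosen outcome.
#' @param hedges logical; apply the small-sample correction (default `TRUE`).
#'   `FALSE` gives uncorrected Cohen's d with the same variance formula.
#' @return list of class `study_effect`: `smd`, `var_smd`, `se_smd`,
#'   `source = "continuous"`.
#' @examples
#' smd_continuous(10, 4, 20, 12, 4, 20)  # g ~ -0.49
#' @export
smd_continuous <- function(mean_real, sd_real, n_real,
                           mean_placebo, sd_placebo, n_placebo,
                           hedges = TRUE) {
  .check(all(is.finite(c(mean_real, sd_real, n_real,
                         mean_placebo, sd_placebo, n_placebo))),
         "all summaries must be finite")
  .check(sd_real >= 0 && sd_placebo >= 0, "SDs must be non-negative")
  .check(n_real >= 2 && n_placebo >= 2, "each arm needs n >= 2")
  df <- n_real + n_placebo - 2
  s_pooled <- sqrt(((n_real - 1) * sd_real^2 + (n_placebo - 1) * sd_placebo^2) / df)
  .check(s_pooled > 0, "pooled SD is zero: degenerate outcome")
  d <- (mean_real - mean_placebo) / s_pooled
  j <- if (hedges) 1 - 3 / (4 * df - 1) else 1
  g <- j * d
  n <- n_real + n_placebo
  v <- n / (n_real * n_placebo) + g^2 / (2 * n)
  structure(list(smd = g, var_smd = v, se_smd = sqrt(v), source = "continuous"),
            class = "study_effect")
}

#' Standardized mean difference from dichotomous summaries
#'
#' Converts the odds ratio of a 2x2 events table to the SMD scale by the
#' logistic-distribution identity `SMD = (sqrt(3) / pi) ln OR`, with
#' `var(SMD) = (3 / pi^2) var(ln OR)` and `var(ln OR)` the sum of the
#' reciprocals of the four cells. When any cell is zero, 0.5 is added to all
#' four cells before computing.
#'
#' Under the negative-favors-real convention the event must be a harm
#' (`event_is_harm = TRUE`, the default): more events in the real arm then
#' yields a positive SMD. For a beneficial event set `event_is_harm = FALSE`
#' and the sign is flipped.
#'
#' @param events_real,total_real,events_placebo,total_placebo counts,
#'   `0 <= events <= total`, totals >= 1.
#' @param event_is_harm logical; see Details.
#' @return list of class `study_effect`: `smd`, `var_smd`, `se_smd`,
#'   `source = "dichotomous"`.
#' @examples
#' smd_from_dichotomous(10, 20, 5, 20)  # OR = 3, smd ~ 0.606
#' @export
smd_from_dichotomous <- function(events_real, total_real,
                                 events_placebo, total_placebo,
                                 event_is_harm = TRUE) {
  for (nm in c("events_real", "total_real", "events_placebo", "total_placebo")) {
    .check(.is_count(get(nm)), "%s must be a non-negative integer count", nm)
  }
  .check(total_real >= 1 && total_placebo >= 1, "totals must be >= 1")
  .check(events_real <= total_real && events_placebo <= total_placebo,
         "events cannot exceed totals")
  a <- events_real; b <- total_real - events_real
  c_ <- events_placebo; d <- total_placebo - events_placebo
  # an empty events or non-events column carries no odds-ratio information,
  # continuity correction or not
  .check(!((a == 0 && c_ == 0) || (b == 0 && d == 0)),
         "degenerate table: both arms all-events or all-non-events")
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  lor <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
  v_lor <- sum(1 / cells)
  smd <- sqrt(3) / pi * lor
  if (!event_is_harm) smd <- -smd
  v <- 3 / pi^2 * v_lor
  structure(list(smd = smd, var_smd = v, se_smd = sqrt(v), source = "dichotomous"),
            class = "study_effect")
}

#' Split a shared arm across comparisons
#'
#' In a multi-arm trial whose real-treatment arm is compared against k
#' placebo groups, the shared arm's participants are divided evenly across
#' the k comparisons to avoid double counting. When `n_shared` is not
#' divisible by `k`, the earlier comparisons receive the extra unit(s);
#' the split is deterministic and conserves the total.
#'
#' @param n_shared participant count of the shared arm.
#' @param k number of comparisons (>= 2).
#' @return integer vector of length `k` summing to `n_shared`, entries
#'   differing by at most 1.
#' @examples
#' split_shared_arm(51, 2)  # c(26, 25)
#' @export
split_shared_arm <- function(n_shared, k) {
  .check(.is_count(n_shared) && .is_count(k) && k >= 2,
         "n_shared must be a count and k an integer >= 2")
  .check(n_shared >= k, "cannot split %d participants across %d comparisons",
         n_shared, k)
  base <- n_shared %/% k
  rem <- n_shared %% k
  as.integer(base + (seq_len(k) <= rem))
}

#' Select the outcome to meta-analyse for one study
#'
#' Deterministic priority mirroring the outcome-selection strategy for
#' pooling primary outcomes: (a) a designated primary endpoint with
#' extractable data; failing that, (b) among candidates with clear data,
#' one on the condition's common scale (e.g. VAS for pain); failing that,
#' (c) any candidate with clear data. Within a rule the candidate whose
#' timepoint is closest to the last treatment session wins; remaining ties
#' go to input order.
#'
#' @param candidates data frame with columns `label`,
#'   `is_primary_endpoint`, `timepoint_offset_from_last_treatment`
#'   (signed; 0 = at last session), `is_common_scale`, `has_clear_data`.
#' @return the selected row (single-row data frame).
#' @export
select_outcome <- function(candidates) {
  need <- c("label", "is_primary_endpoint",
            "timepoint_offset_from_last_treatment",
            "is_common_scale", "has_clear_data")
  .check(is.data.frame(candidates) && nrow(candidates) > 0L,
         "candidates must be a non-empty data frame")
  .check(all(need %in% names(candidates)),
         "candidates needs columns: %s", paste(need, collapse = ", "))
  pick <- function(idx) {
    if (length(idx) == 0L) return(NULL)
    off <- abs(candidates$timepoint_offset_from_last_treatment[idx])
    idx <- idx[off == min(off)]
    candidates[idx[1], , drop = FALSE]
  }
  clear <- which(candidates$has_clear_data)
  sel <- pick(intersect(which(candidates$is_primary_endpoint), clear))
  if (is.null(sel)) sel <- pick(intersect(which(candidates$is_common_scale), clear))
  if (is.null(sel)) sel <- pick(clear)
  if (is.null(sel)) {
    stop("no candidate outcome with extractable data: study excluded from meta-analysis",
         call. = FALSE)
  }
  sel
}

#' Build study effects from an outcomes table
#'
#' Applies [smd_continuous()] or [smd_from_dichotomous()] row-wise to the
#' outcomes CSV schema and returns the effects table consumed by
#' [pool_random_effects()].
#'
#' @param outcomes data frame with columns `study_id`, `category`, `region`,
#'   `outcome_type` (`"continuous"|"dichotomous"`) and the matching summary
#'   columns (`mean_*`, `sd_*`, `n_*` or `events_*`, `total_*`); an optional
#'   `event_is_harm` logical column applies to dichotomous rows.
#' @param hedges logical, passed to [smd_continuous()].
#' @return data frame with `study_id`, `category`, `region`, `smd`,
#'   `var_smd`, `se_smd`, `source`.
#' @export
compute_effects <- function(outcomes, hedges = TRUE) {
  .check(is.data.frame(outcomes) && nrow(outcomes) > 0L,
         "outcomes must be a non-empty data frame")
  .check(all(c("study_id", "outcome_type") %in% names(outcomes)),
         "outcomes needs columns study_id, outcome_type")
  rows <- lapply(seq_len(nrow(outcomes)), function(i) {
    o <- outcomes[i, ]
    eff <- if (o$outcome_type == "continuous") {
      smd_continuous(o$mean_real, o$sd_real, o$n_real,
                     o$mean_placebo, o$sd_placebo, o$n_placebo,
                     hedges = hedges)
    } else if (o$outcome_type == "dichotomous") {
      harm <- if ("event_is_harm" %in% names(o)) isTRUE(o$event_is_harm) else TRUE
      smd_from_dichotomous(o$events_real, o$total_real,
                           o$events_placebo, o$total_placebo,
                           event_is_harm = harm)
    } else {
      stop(sprintf("row %d: unknown outcome_type '%s'", i, o$outcome_type),
           call. = FALSE)
    }
    data.frame(study_id = o$study_id,
               category = if ("category" %in% names(o)) o$category else NA_character_,
               region = if ("region" %in% names(o)) o$region else NA_character_,
               smd = eff$smd, var_smd = eff$var_smd, se_smd = eff$se_smd,
               source = eff$source, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
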