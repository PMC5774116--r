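test_that("smd_continuous computes Hedges' g with its variance", {
  expect_equal(smd_continuous(10, 3, 15, 10, 3, 15)$smd, 0)

  e <- smd_continuous(10, 4, 20, 12, 4, 20)
  j <- 1 - 3 / (4 * 38 - 1)
  expect_equal(e$smd, j * -0.5)
  expect_equal(e$smd, -0.4900662, tolerance = 1e-6)
  expect_equal(e$var_smd, 40 / 400 + e$smd^2 / 80)
  expect_equal(e$var_smd, 0.1030021, tolerance = 1e-6)
  expect_equal(e$se_smd, sqrt(e$var_smd))

  # swapping arms negates the effect, variance unchanged
  sw <- smd_continuous(12, 4, 20, 10, 4, 20)
  expect_equal(sw$smd, -e$smd)
  expect_equal(sw$var_smd, e$var_smd)

  expect_error(smd_continuous(1, 0, 10, 1, 0, 10), "pooled SD is zero")
  expect_error(smd_continuous(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("smd_continuous is affine-invariant and the Hedges factor shrinks d", {
  set.seed(5)
  for (i in 1:20) {
    m <- rnorm(2, 10, 3); s <- runif(2, 1, 4); n <- sample(5:50, 2)
    g <- smd_continuous(m[1], s[1], n[1], m[2], s[2], n[2])
    cc <- runif(1, 0.1, 10)
    g2 <- smd_continuous(cc * m[1], cc * s[1], n[1], cc * m[2], cc * s[2], n[2])
    expect_equal(g2$smd, g$smd, tolerance = 1e-12)

    d <- smd_continuous(m[1], s[1], n[1], m[2], s[2], n[2], hedges = FALSE)
    if (abs(d$smd) > 1e-8) expect_lt(abs(g$smd), abs(d$smd))
  }
  # correction vanishes as n grows
  g_small <- smd_continuous(10, 4, 5, 12, 4, 5)
  g_big <- smd_continuous(10, 4, 5000, 12, 4, 5000)
  d_big <- smd_continuous(10, 4, 5000, 12, 4, 5000, hedges = FALSE)
  expect_lt(abs(g_big$smd - d_big$smd), 1e-4)
  expect_gt(abs(g_small$smd - smd_continuous(10, 4, 5, 12, 4, 5, hedges = FALSE)$smd),
            abs(g_big$smd - d_big$smd))
})

test_that("smd_from_dichotomous applies the sqrt(3)/pi log-OR conversion", {
  expect_equal(smd_from_dichotomous(5, 10, 5, 10)$smd, 0)

  e <- smd_from_dichotomous(10, 20, 5, 20)
  expect_equal(e$smd, sqrt(3) / pi * log(3))
  expect_equal(e$smd, 0.6056967, tolerance = 1e-6)
  expect_equal(e$var_smd, 3 / pi^2 * (1 / 10 + 1 / 10 + 1 / 5 + 1 / 15))
  expect_equal(e$var_smd, 0.1418497, tolerance = 1e-6)

  # antisymmetry in the odds ratio; monotone increasing in OR
  flip <- smd_from_dichotomous(5, 20, 10, 20)
  expect_equal(flip$smd, -e$smd)
  set.seed(6)
  prev <- -Inf
  for (ev in 1:19) {
    cur <- smd_from_dichotomous(ev, 20, 10, 20)$smd
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("zero cells get the 0.5 correction; uninformative tables error", {
  e <- smd_from_dichotomous(0, 10, 3, 10)
  lor <- log((0.5 * 7.5) / (10.5 * 3.5))
  expect_equal(e$smd, sqrt(3) / pi * lor)
  expect_equal(e$var_smd, 3 / pi^2 * (1 / 0.5 + 1 / 10.5 + 1 / 3.5 + 1 / 7.5))

  expect_error(smd_from_dichotomous(0, 10, 0, 12), "degenerate")
  expect_error(smd_from_dichotomous(10, 10, 12, 12), "degenerate")
  expect_error(smd_from_dichotomous(11, 10, 3, 10), "exceed")

  # with a beneficial event the sign convention flips
  expect_equal(smd_from_dichotomous(10, 20, 5, 20, event_is_harm = FALSE)$smd,
               -smd_from_dichotomous(10, 20, 5, 20)$smd)
})

test_that("split_shared_arm divides evenly, earlier comparisons first", {
  expect_equal(split_shared_arm(50, 2), c(25L, 25L))
  expect_equal(split_shared_arm(30, 3), c(10L, 10L, 10L))
  expect_equal(split_shared_arm(51, 2), c(26L, 25L))
  expect_error(split_shared_arm(1, 2), "cannot split")

  set.seed(7)
  for (i in 1:30) {
    k <- sample(2:6, 1); n <- sample(k:120, 1)
    parts <- split_shared_arm(n, k)
    expect_equal(sum(parts), n)
    expect_lte(max(parts) - min(parts), 1L)
    expect_true(all(diff(parts) <= 0))  # extras go to earlier comparisons
  }
})

test_that("select_outcome follows the priority ladder with deterministic ties", {
  cand <- data.frame(
    label = c("VAS", "SF-36"),
    is_primary_endpoint = c(TRUE, FALSE),
    timepoint_offset_from_last_treatment = c(8, 0),
    is_common_scale = c(TRUE, FALSE),
    has_clear_data = c(TRUE, TRUE), stringsAsFactors = FALSE)
  expect_equal(select_outcome(cand)$label, "VAS")  # primary beats closer timepoint

  cand2 <- data.frame(
    label = c("global score", "VAS"),
    is_primary_endpoint = FALSE,
    timepoint_offset_from_last_treatment = c(0, 2),
    is_common_scale = c(FALSE, TRUE),
    has_clear_data = c(FALSE, TRUE), stringsAsFactors = FALSE)
  expect_equal(select_outcome(cand2)$label, "VAS")  # figure-only data loses

  cand3 <- data.frame(
    label = c("first", "second"),
    is_primary_endpoint = FALSE,
    timepoint_offset_from_last_treatment = c(2, -2),
    is_common_scale = FALSE,
    has_clear_data = TRUE, stringsAsFactors = FALSE)
  expect_equal(select_outcome(cand3)$label, "first")  # equal |offset|: input order

  cand4 <- data.frame(
    label = c("far", "near"),
    is_primary_endpoint = FALSE,
    timepoint_offset_from_last_treatment = c(10, -1),
    is_common_scale = FALSE,
    has_clear_data = TRUE, stringsAsFactors = FALSE)
  expect_equal(select_outcome(cand4)$label, "near")  # closest to last session

  cand5 <- cand2
  cand5$has_clear_data <- FALSE
  expect_error(select_outcome(cand5), "excluded from meta-analysis")
})

test_that("compute_effects dispatches on outcome type", {
  outcomes <- data.frame(
    study_id = c("A", "B"), category = c("FD", "DD"), region = "Asia",
    outcome_type = c("continuous", "dichotomous"),
    mean_real = c(10, NA), sd_real = c(4, NA), n_real = c(20, NA),
    mean_placebo = c(12, NA), sd_placebo = c(4, NA), n_placebo = c(20, NA),
    events_real = c(NA, 10), total_real = c(NA, 20),
    events_placebo = c(NA, 5), total_placebo = c(NA, 20),
    stringsAsFactors = FALSE)
  eff <- compute_effects(outcomes)
  expect_equal(eff$source, c("continuous", "dichotomous"))
  expect_equal(eff$smd[1], smd_continuous(10, 4, 20, 12, 4, 20)$smd)
  expect_equal(eff$smd[2], smd_from_dichotomous(10, 20, 5, 20)$smd)
  outcomes$outcome_type[1] <- "ordinal"
  expect_error(compute_effects(outcomes), "unknown outcome_type")
})
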