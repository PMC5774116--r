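test_that("bang_bi reproduces the analytic anchors", {
  expect_equal(bang_bi(guess_table("real", 50, 0, 0)), 1)
  expect_equal(bang_bi(guess_table("placebo", 30, 0, 0)), -1)
  expect_equal(bang_bi(guess_table("real", 40, 40, 20)), 0)
  expect_equal(bang_bi(guess_table("real", 60, 25, 15)), 0.35)
  expect_error(guess_table("real", 0, 0, 0), "no respondents")
  expect_error(guess_table("left", 1, 1, 0), "arm must be")
  expect_error(guess_table("real", -1, 2, 0), "non-negative")
})

test_that("bang_bi symmetry and don't-know shrinkage properties hold", {
  set.seed(1)
  for (i in 1:50) {
    cnt <- c(rpois(2, 20), rpois(1, 5))
    if (sum(cnt) == 0) cnt[1] <- 1
    bi <- bang_bi(guess_table("real", cnt[1], cnt[2], cnt[3]))
    expect_true(bi >= -1 && bi <= 1)
    # swapping the two guess counts negates the index
    expect_equal(bang_bi(guess_table("real", cnt[2], cnt[1], cnt[3])), -bi)
    # relabeling the arm with fixed counts negates it too
    expect_equal(bang_bi(guess_table("placebo", cnt[1], cnt[2], cnt[3])), -bi)
    # extra don't-know answers shrink |bi| strictly toward 0
    bi2 <- bang_bi(guess_table("real", cnt[1], cnt[2], cnt[3] + 5))
    if (bi != 0) expect_lt(abs(bi2), abs(bi)) else expect_equal(bi2, 0)
  }
})

test_that("bi_confidence_interval uses the multinomial-difference variance", {
  ci <- bi_confidence_interval(guess_table("real", 60, 25, 15))
  # hand arithmetic: var = (.6*.4 + .25*.75 + 2*.6*.25)/100
  expect_equal(ci$se, sqrt((0.6 * 0.4 + 0.25 * 0.75 + 2 * 0.6 * 0.25) / 100))
  expect_equal(ci$se, 0.08529361, tolerance = 1e-7)
  expect_equal(ci$ci_low, 0.1828276, tolerance = 1e-6)
  expect_equal(ci$ci_high, 0.5171724, tolerance = 1e-6)

  deg <- bi_confidence_interval(guess_table("real", 50, 0, 0))
  expect_equal(deg$se, 0)
  expect_equal(c(deg$ci_low, deg$ci_high), c(1, 1))

  gt <- guess_table("real", 30, 10, 10)
  ci95 <- bi_confidence_interval(gt, 0.95)
  ci99 <- bi_confidence_interval(gt, 0.99)
  expect_lt(ci99$ci_low, ci95$ci_low)
  expect_gt(ci99$ci_high, ci95$ci_high)
  expect_error(bi_confidence_interval(gt, 1.2), "level")

  tr <- bi_confidence_interval(guess_table("placebo", 29, 1, 0), truncate = TRUE)
  expect_gte(tr$ci_low, -1)
})

test_that("classify_bi applies the half-open thresholds with closed boundaries", {
  expect_equal(classify_bi(0.42), "unblinded")
  expect_equal(classify_bi(-0.16), "random_guess")
  expect_equal(classify_bi(-0.21), "opposite_guess")
  expect_equal(classify_bi(0.2), "unblinded")
  expect_equal(classify_bi(-0.2), "opposite_guess")
  expect_equal(classify_bi(0.1999), "random_guess")
  expect_error(classify_bi(1.2), "outside")
})

test_that("classification over an exhaustive grid of small tables matches the oracle", {
  for (total in 1:6) {
    for (nr in 0:total) {
      for (np in 0:(total - nr)) {
        for (arm in c("real", "placebo")) {
          gt <- guess_table(arm, nr, np, total - nr - np)
          bi <- bang_bi(gt)
          expect_equal(classify_bi(bi), status_oracle(bi))
        }
      }
    }
  }
})

test_that("the scenario mapping is the published 3x3 bijection", {
  expect_equal(assign_scenario("unblinded", "opposite_guess")$id, "S5")
  expect_equal(assign_scenario("random_guess", "random_guess")$id, "S1")
  expect_equal(assign_scenario("opposite_guess", "unblinded")$id, "S9")

  statuses <- c("random_guess", "unblinded", "opposite_guess")
  seen <- character(0)
  for (es in statuses) for (cs in statuses) {
    sc <- assign_scenario(es, cs)
    expect_false(sc$id %in% seen)
    seen <- c(seen, sc$id)
    # round-trip: id -> statuses -> id
    row <- scenario_definitions()[scenario_definitions()$id == sc$id, ]
    expect_equal(assign_scenario(row$exp_status, row$ctrl_status)$id, sc$id)
  }
  expect_setequal(seen, paste0("S", 1:9))
  expect_error(assign_scenario("shrug", "unblinded"), "invalid")
})

test_that("mann_whitney_u: exact enumeration matches theory and the stats oracle", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)   # 2/20 arrangements as extreme
  expect_equal(res$method, "exact")

  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
    ours <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("mann_whitney_u: tie-corrected normal approximation for larger groups", {
  set.seed(9)
  for (i in 1:10) {
    a <- sample(1:6, 15, replace = TRUE)  # heavy ties
    b <- sample(2:7, 12, replace = TRUE)
    ours <- mann_whitney_u(a, b)
    expect_equal(ours$method, "normal")
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("compare_bi_groups gates on Shapiro-Wilk and records the test used", {
  set.seed(21)
  # the auto choice must agree with gating on stats::shapiro.test directly
  for (i in 1:10) {
    a <- if (i %% 2) rnorm(12) else rexp(12)^3
    b <- rnorm(10)
    res <- compare_bi_groups(a, b)
    normal_both <- shapiro.test(a)$p.value > 0.05 && shapiro.test(b)$p.value > 0.05
    expect_equal(res$test, if (normal_both) "t" else "mann_whitney")
  }

  x <- c(0.1, 0.2, 0.3, 0.15)
  expect_gte(compare_bi_groups(x, x, force = "mann_whitney")$p, 0.05)
  expect_gte(compare_bi_groups(x, x, force = "t")$p, 0.05)

  a <- rnorm(10); b <- rnorm(10)
  forced <- compare_bi_groups(a, b, force = "t")
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(forced$statistic, unname(ref$statistic))
  expect_equal(forced$p, ref$p.value)
  welched <- compare_bi_groups(a, b, force = "t", welch = TRUE)
  expect_equal(welched$p, t.test(a, b)$p.value)

  expect_error(compare_bi_groups(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("forced t-test holds its type-I error under a normal null", {
  set.seed(31)
  rej <- replicate(1000, {
    compare_bi_groups(rnorm(15), rnorm(15), force = "t")$p < 0.05
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("assess_corpus_blinding assigns per-study scenarios and the grid sums", {
  corpus <- tiny_corpus()
  ba <- assess_corpus_blinding(corpus$guesses)
  expect_equal(nrow(ba$arms), nrow(corpus$guesses))
  expect_true(all(ba$arms$status %in%
                    c("random_guess", "unblinded", "opposite_guess")))
  expect_equal(sort(unique(ba$scenarios$study_id)),
               sort(unique(corpus$guesses$study_id)))
  grp <- ba$scenarios
  grp$category <- ifelse(grp$category == "FD", "FD", "DD/MI")
  grid <- scenario_grid(grp)
  expect_equal(sum(grid$`n_FD`) + sum(grid$`n_DD/MI`), nrow(ba$scenarios))
  expect_equal(grid$scenario, paste0("S", 1:9))
})
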