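test_that("guess model probabilities and expected index are consistent", {
  p <- list(p_perceive = 0.2, w_wishful = 0.7, p_dontknow = 0.1)
  for (arm in c("real", "placebo")) {
    pr <- guess_probs(arm, p)
    expect_equal(sum(pr), 1)
    expect_true(all(pr >= 0))
  }
  expect_equal(expected_bi("real", p), 0.2 + 0.7 * (2 * 0.7 - 1))
  expect_equal(expected_bi("placebo", p), 0.2 + 0.7 * (1 - 2 * 0.7))
  expect_error(guess_probs("real", list(p_perceive = 0.8, w_wishful = 0.5,
                                        p_dontknow = 0.3)), "infeasible")
})

test_that("solve_guess_params inverts the expected-index equations exactly", {
  for (tgt in list(c(0.42, -0.16), c(0.41, -0.21), c(0, 0), c(0.6, 0.1))) {
    p <- solve_guess_params(tgt[1], tgt[2], p_dontknow = 0.12)
    expect_equal(expected_bi("real", p), tgt[1], tolerance = 1e-12)
    expect_equal(expected_bi("placebo", p), tgt[2], tolerance = 1e-12)
  }
  expect_error(solve_guess_params(1, 0.99), "infeasible|outside")
})

test_that("degenerate guess models force the published anchor behaviors", {
  all_wishful <- list(p_perceive = 0, w_wishful = 1, p_dontknow = 0)
  set.seed(2)
  for (i in 1:10) {
    cnt <- simulate_guess_counts(30, "placebo", all_wishful)
    expect_equal(unname(cnt), c(30, 0, 0))  # everyone guesses "real"
    expect_equal(bang_bi(guess_table("placebo", cnt[1], cnt[2], cnt[3])), -1)
  }
  # symmetric guessing: mean BI near 0
  sym <- list(p_perceive = 0, w_wishful = 0.5, p_dontknow = 0)
  set.seed(3)
  bis <- replicate(1000, {
    cnt <- simulate_guess_counts(40, "real", sym)
    bang_bi(guess_table("real", cnt[1], cnt[2], cnt[3]))
  })
  expect_lt(abs(mean(bis)), 0.02)
})

test_that("expected placebo-arm index strictly decreases in wishful thinking", {
  ws <- seq(0.1, 0.9, by = 0.1)
  ebis <- vapply(ws, function(w)
    expected_bi("placebo", list(p_perceive = 0.1, w_wishful = w,
                                p_dontknow = 0.1)), numeric(1))
  expect_true(all(diff(ebis) < 0))
})

test_that("corpora are seed-reproducible and structurally valid", {
  cfg <- sim_config()
  c1 <- generate_corpus(cfg, seed = 11)
  c2 <- generate_corpus(cfg, seed = 11)
  c3 <- generate_corpus(cfg, seed = 12)
  expect_identical(c1, c2)
  expect_false(identical(c1$guesses, c3$guesses))

  expect_equal(nrow(c1$pils), 70)
  expect_equal(length(unique(c1$pils$pil_id)), 65)
  expect_equal(anyDuplicated(paste(c1$pils$pil_id, c1$pils$placebo_group_id)), 0)
  expect_equal(unname(table(c1$truth$category)[c("FD", "DD", "MI")]),
               c(40, 25, 5), ignore_attr = TRUE)

  # guess triples sum to the arm size and are non-negative
  g <- c1$guesses
  expect_true(all(g$n_guess_real >= 0 & g$n_guess_placebo >= 0 & g$n_dont_know >= 0))
  tot <- g$n_guess_real + g$n_guess_placebo + g$n_dont_know
  expect_true(all(tot >= sim_config()$n_per_arm_range[1]))
  expect_true(all(tot <= sim_config()$n_per_arm_range[2]))
  expect_equal(nrow(g), 2 * (17 + 10 + 1))
  expect_equal(nrow(c1$outcomes), 24)
  expect_true(all(c1$truth$category[c1$truth$has_outcome] %in% c("FD", "DD")))
})

test_that("per-study substreams keep shared studies stable when k changes", {
  big <- generate_corpus(sim_config(), seed = 4)
  small <- generate_corpus(sim_config(k_mi = 0, n_twin_pils = 0, n_bi_mi = 0),
                           seed = 4)
  shared <- small$guesses$study_id
  expect_equal(small$guesses,
               big$guesses[big$guesses$study_id %in% shared, ],
               ignore_attr = TRUE)
  expect_equal(small$outcomes, big$outcomes, ignore_attr = TRUE)
})

test_that("generate_corpus leaves the caller's RNG stream untouched", {
  set.seed(100); x1 <- runif(3)
  set.seed(100); invisible(generate_corpus(sim_config(), seed = 9)); x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("generated snippets are recovered by the coder and corpus round-trips to disk", {
  corpus <- tiny_corpus(seed = 21)
  coded <- code_corpus(corpus$pils)
  expect_equal(coded$category, corpus$truth$category)

  dir <- withr::local_tempdir()
  paths <- write_corpus(corpus, dir)
  expect_true(all(file.exists(paths)))
  pils <- read_pils_jsonl(paths[["pils"]])
  expect_equal(pils$placebo_group_id, corpus$pils$placebo_group_id)
  expect_equal(pils$text, corpus$pils$text)
  g <- read_guesses_csv(paths[["guesses"]])
  expect_equal(g$n_guess_real, corpus$guesses$n_guess_real)
  o <- read_outcomes_csv(paths[["outcomes"]])
  expect_equal(o$mean_real, corpus$outcomes$mean_real, tolerance = 1e-12)
})

test_that("recover_parameters reports bias, coverage and coding agreement", {
  rp <- recover_parameters(sim_config(), n_reps = 20, seed = 41)
  expect_equal(rp$coding_agreement, 1)
  expect_lt(max(abs(rp$bias)), 0.1)       # loose: 20 reps only
  expect_gt(min(rp$coverage), 0.7)
  expect_lt(abs(rp$mean_bi["FD", "placebo"] - (-0.16)), 0.1)
  expect_lt(abs(rp$mean_bi["DD", "real"] - 0.41), 0.1)
})
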