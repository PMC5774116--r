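# Independent straight-line re-implementation of DerSimonian-Laird pooling,
# written with explicit loops so it shares no code path with the package.
dl_oracle <- function(y, v, level = 0.95) {
  k <- length(y)
  sw <- 0; swy <- 0; sw2 <- 0
  for (i in seq_len(k)) {
    w <- 1 / v[i]
    sw <- sw + w; swy <- swy + w * y[i]; sw2 <- sw2 + w^2
  }
  fe <- swy / sw
  q <- 0
  for (i in seq_len(k)) q <- q + (y[i] - fe)^2 / v[i]
  tau2 <- 0
  if (k > 1) {
    c_dl <- sw - sw2 / sw
    tau2 <- (q - (k - 1)) / c_dl
    if (tau2 < 0) tau2 <- 0
  }
  sws <- 0; swsy <- 0
  for (i in seq_len(k)) {
    ws <- 1 / (v[i] + tau2)
    sws <- sws + ws; swsy <- swsy + ws * y[i]
  }
  pooled <- swsy / sws
  se <- sqrt(1 / sws)
  z <- qnorm(1 - (1 - level) / 2)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  list(pooled = pooled, se = se, ci_low = pooled - z * se,
       ci_high = pooled + z * se, Q = q, tau2 = tau2, i2 = i2)
}

# draw a random small meta-analysis
random_meta <- function(k = NULL) {
  if (is.null(k)) k <- sample(1:10, 1)
  v <- runif(k, 0.01, 0.2)
  y <- rnorm(k, sd = sqrt(v + 0.05))
  list(y = y, v = v, k = k)
}

# brute-force threshold oracle for guess statuses
status_oracle <- function(bi) {
  stopifnot(bi >= -1, bi <= 1)
  if (bi >= 0.2) return("unblinded")
  if (bi <= -0.2) return("opposite_guess")
  "random_guess"
}

# a tiny pipeline-ready corpus fixture built in code
tiny_corpus <- function(seed = 3) {
  generate_corpus(sim_config(), seed = seed)
}
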