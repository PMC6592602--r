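# Shared fixtures and independent oracles used across test files.

lc24 <- celegans_lc_table()
curves <- metal_curves(lc24)

# closed-form two-point construction, written independently of the package
oracle_two_point <- function(c1, y1, c2, y2) {
  beta <- log((y2 / (100 - y2)) / (y1 / (100 - y1))) / log(c2 / c1)
  ec50 <- c1 / (y1 / (100 - y1))^(1 / beta)
  c(ec50 = ec50, beta = beta)
}

# brute-force grid scan of the Concentration Addition balance:
# pick the y minimising |sum_i c_i / (ec50_i q^(1/beta_i)) - 1|
oracle_ca_grid <- function(conc, ec50, beta, step = 0.001) {
  ys <- seq(step, 100 - step, by = step)
  q <- ys / (100 - ys)
  total <- rep(-1, length(ys))
  for (i in seq_along(conc))
    total <- total + conc[i] / (ec50[i] * q^(1 / beta[i]))
  ys[which.min(abs(total))]
}

# per-interval trapezoid sum, written as the naive loop
oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  s
}

# exact one-sided signed-rank p-value by enumeration of all sign
# patterns (valid for distinct nonzero differences)
oracle_signed_rank_p_less <- function(d) {
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  n <- length(d)
  ranks <- rank(abs(d))
  v_obs <- sum(ranks[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_null <- as.matrix(signs) %*% ranks
  mean(v_null <= v_obs)
}

random_curve <- function() {
  loglogistic_curve(ec50 = 10^stats::runif(1, -1, 2),
                    beta = stats::runif(1, 0.3, 3))
}
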