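# Shared fixtures and independent oracles used across test files.

# Monte-Carlo estimate of the probability that a Gaussian endpoint lands in
# a disk; returns the estimate and its binomial standard error.
mc_disk_prob <- function(center, radius, aim, sd_x, sd_y, n = 1e6) {
  x <- rnorm(n, aim[1], sd_x)
  y <- rnorm(n, aim[2], sd_y)
  hit <- (x - center[1])^2 + (y - center[2])^2 <= radius^2
  p <- mean(hit)
  list(p = p, se = sqrt(max(p * (1 - p), 1e-12) / n))
}

# Monte-Carlo expected gain by scoring simulated endpoints against both
# disks (overlap hits score both terms).
mc_expected_gain <- function(aim, cfg, sd_x, sd_y, n = 1e6) {
  x <- rnorm(n, aim[1], sd_x)
  y <- rnorm(n, aim[2], sd_y)
  r <- cfg$gain_target *
    ((x - cfg$target_center_mm[1])^2 +
       (y - cfg$target_center_mm[2])^2 <= cfg$target_radius_mm^2) +
    cfg$gain_penalty *
    ((x - cfg$penalty_center_mm[1])^2 +
       (y - cfg$penalty_center_mm[2])^2 <= cfg$penalty_radius_mm^2)
  list(eg = mean(r), se = sd(r) / sqrt(n))
}

# Brute-force MEG: exhaustive coarse grid, then an exhaustive fine grid
# around the coarse optimum, both using the package's expected-gain
# evaluation. `fine` is the final grid spacing.
brute_force_meg <- function(cfg, noise, coarse = 0.1, fine = 0.01,
                            margin_sd = 2) {
  sd_max <- sqrt(max(noise$var_x_mm2, noise$var_y_mm2))
  half <- cfg$target_radius_mm + margin_sd * sd_max
  g1 <- as.matrix(expand.grid(
    seq(cfg$target_center_mm[1] - half, cfg$target_center_mm[1] + half,
        by = coarse),
    seq(cfg$target_center_mm[2] - half, cfg$target_center_mm[2] + half,
        by = coarse)
  ))
  e1 <- riskreach:::.eg_aims(g1, cfg, noise)
  b <- g1[which.max(e1), ]
  g2 <- as.matrix(expand.grid(
    seq(b[1] - 1.5 * coarse, b[1] + 1.5 * coarse, by = fine),
    seq(b[2] - 1.5 * coarse, b[2] + 1.5 * coarse, by = fine)
  ))
  e2 <- riskreach:::.eg_aims(g2, cfg, noise)
  as.numeric(g2[which.max(e2), ])
}

# Numeric double-quadrature oracle for the variance-structure evidence,
# working directly on the sigma scale with stats::integrate (independent of
# the package's incomplete-Gamma closed forms). Likelihoods are rescaled by
# their peak value before integration so that n ~ hundreds does not
# underflow a double.
oracle_variance_evidence <- function(res_a, res_b,
                                     comparison = "A_greater_vs_equal",
                                     bounds = c(0.1, 100)) {
  lo <- bounds[1]; hi <- bounds[2]
  z <- log(hi / lo)
  loglik <- function(s, res) sum(dnorm(res, 0, s, log = TRUE))
  # scaled log-integral of exp(loglik)/(s z) over [a, b]
  log_int <- function(res, a, b) {
    grid <- exp(seq(log(a), log(b), length.out = 400))
    m <- max(vapply(grid, loglik, numeric(1), res = res))
    v <- integrate(Vectorize(function(s) {
      exp(loglik(s, res) - m) / (s * z)
    }), a, b, rel.tol = 1e-10)$value
    m + log(v)
  }
  log_l_eq <- log_int(c(res_a, res_b), lo, hi)
  if (comparison == "unequal_vs_equal") {
    log_l_alt <- log_int(res_a, lo, hi) + log_int(res_b, lo, hi)
  } else {
    grid <- exp(seq(log(lo), log(hi), length.out = 400))
    log_outer <- function(sb) {
      if (sb >= hi) return(-Inf)
      loglik(sb, res_b) - log(sb * z) + log_int(res_a, sb, hi)
    }
    m <- max(vapply(grid, log_outer, numeric(1)))
    v <- integrate(Vectorize(function(sb) exp(log_outer(sb) - m)),
                   lo, hi, rel.tol = 1e-8)$value
    log_l_alt <- log(2) + m + log(v)
  }
  10 / log(10) * (log_l_alt - log_l_eq)
}

default_design <- function() experiment_design()
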