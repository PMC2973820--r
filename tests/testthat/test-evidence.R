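test_that("decibel/odds conversion is exact and handles huge odds", {
  expect_equal(db_odds_convert(0), 1)
  expect_equal(db_odds_convert(10), 10)
  expect_equal(db_odds_convert(29), 794.3282, tolerance = 1e-6)
  expect_equal(db_odds_convert(794.3282, "odds_to_db"), 29,
               tolerance = 1e-6)
  # round trip over a range of values
  for (db in c(-50, -3, 0, 12.7, 100)) {
    expect_equal(db_odds_convert(db_odds_convert(db), "odds_to_db"), db,
                 tolerance = 1e-9)
  }
  # odds beyond double precision as a scientific-notation string
  expect_equal(db_odds_convert("2.2e681", "odds_to_db"), 6813.42,
               tolerance = 0.01)
  expect_error(db_odds_convert(-2, "odds_to_db"), "positive")
  expect_error(db_odds_convert("junk", "odds_to_db"), "parse")
})

test_that("bounded Jeffreys marginal matches a quadrature oracle and its closed form", {
  # the package closed form (incomplete Gamma) vs direct sigma-scale
  # quadrature, over a range of n and sums of squares
  for (case in list(c(1, 1), c(2, 1.25), c(10, 50), c(240, 240 * 27))) {
    n <- case[1]; S <- case[2]
    lf <- function(s) -n / 2 * log(2 * pi * s^2) - S / (2 * s^2) - log(s)
    m <- max(lf(exp(seq(log(0.1), log(100), length.out = 500))))
    o <- m + log(integrate(function(s) exp(lf(s) - m), 0.1, 100,
                           rel.tol = 1e-10)$value)
    expect_equal(riskreach:::.log_jeffreys_integral(n, S, 0.1, 100), o,
                 tolerance = 1e-6)
  }
  # widening the bounds converges to the infinite-support Gamma expression
  n <- 12; S <- 30
  closed_inf <- -n / 2 * log(2 * pi) - log(2) + n / 2 * (log(2) - log(S)) +
    lgamma(n / 2)
  wide <- riskreach:::.log_jeffreys_integral(n, S, 1e-6, 1e6)
  expect_equal(wide, closed_inf, tolerance = 1e-9)
})

test_that("variance-structure evidence matches the double-quadrature oracle", {
  set.seed(701)
  cases <- list(
    list(a = 1.0, b = -0.5),
    list(a = rnorm(8, 0, 2), b = rnorm(8, 0, 2)),
    list(a = rnorm(20, 0, 3), b = rnorm(20, 0, 1))
  )
  for (cs in cases) {
    for (cmp in c("A_greater_vs_equal", "unequal_vs_equal")) {
      mine <- variance_structure_evidence(cs$a, cs$b, cmp)$evidence_db
      oracle <- oracle_variance_evidence(cs$a, cs$b, cmp)
      expect_equal(mine, oracle, tolerance = 1e-4)
    }
  }
  # single-observation case has near-zero evidence for unit-scale residuals
  expect_lt(abs(variance_structure_evidence(1.0, -0.5)$evidence_db), 3)
})

test_that("variance-structure evidence has the study's sign pattern at n = 240", {
  set.seed(702)
  # equal variances: negative evidence (favouring equality), as in the
  # vertical drift vs no-drift comparisons
  neg <- replicate(5, {
    variance_structure_evidence(rnorm(240, 0, 3),
                                rnorm(240, 0, 3))$evidence_db
  })
  expect_true(all(neg < 0))
  # 3x variance ratio: strongly positive, as in horizontal vs vertical
  # (drift) comparisons
  pos <- replicate(5, {
    variance_structure_evidence(rnorm(240, 0, sqrt(27)),
                                rnorm(240, 0, 3))$evidence_db
  })
  expect_true(all(pos > 20))
})

test_that("evidence is invariant to common rescaling with rescaled bounds", {
  set.seed(703)
  a <- rnorm(30, 0, 2)
  b <- rnorm(30, 0, 1.2)
  e1 <- variance_structure_evidence(a, b, prior_bounds = c(0.1, 100))
  e2 <- variance_structure_evidence(10 * a, 10 * b,
                                    prior_bounds = c(1, 1000))
  expect_equal(e1$evidence_db, e2$evidence_db, tolerance = 1e-5)
})

test_that("aimpoint-model evidence is zero for identical predictions and additive", {
  d <- default_design()
  cfgs <- default_configs()
  ds <- simulate_experiment(d, subject_spec("circular", rng_seed = 75),
                            sessions = "drift")
  zp <- zero_penalty_points(ds, "drift")
  noise <- fit_noise_models(zp)$full
  pa <- predict_model_aimpoints(zp, "M_a", cfgs)
  pc <- predict_model_aimpoints(zp, "M_c", cfgs)
  # identical predictions: exactly 0 dB
  expect_equal(aimpoint_model_evidence(ds, pa, pa, noise)$evidence_db, 0)
  # additivity over disjoint trial subsets
  pen <- ds[ds$block_kind == "penalty", ]
  split1 <- pen[seq_len(240), ]
  split2 <- pen[-seq_len(240), ]
  e_all <- aimpoint_model_evidence(pen, pa, pc, noise)$evidence_db
  e_sum <- aimpoint_model_evidence(split1, pa, pc, noise)$evidence_db +
    aimpoint_model_evidence(split2, pa, pc, noise)$evidence_db
  expect_equal(e_all, e_sum, tolerance = 1e-9)
  # direct log-density summation oracle
  ll <- function(pred) {
    sum(vapply(seq_len(nrow(pen)), function(k) {
      a <- pred$aimpoints[[pen$penalty_direction[k]]]
      dnorm(pen$x_mm[k], a[1], sqrt(noise$var_x_mm2), log = TRUE) +
        dnorm(pen$y_mm[k], a[2], sqrt(noise$var_y_mm2), log = TRUE)
    }, numeric(1)))
  }
  expect_equal(e_all, 10 / log(10) * (ll(pc) - ll(pa)), tolerance = 1e-9)
})

test_that("evidence trace starts at zero and has the right asymptotic signs", {
  set.seed(704)
  # anisotropic residuals: positive, roughly increasing evidence
  res <- cbind(rnorm(207, 0, sqrt(27)), rnorm(207, 0, 3))
  tr <- evidence_trace(res)
  expect_equal(tr$n_trials[1], 0)
  expect_equal(tr$evidence_db[1], 0)
  expect_equal(nrow(tr), 208)
  expect_gt(tr$evidence_db[nrow(tr)], 20)
  # matches the one-shot computation at the final n
  one <- variance_structure_evidence(res[, 1], res[, 2])$evidence_db
  expect_equal(tr$evidence_db[nrow(tr)], one, tolerance = 1e-9)
  # isotropic residuals: negative end-of-training evidence (typical case)
  res0 <- cbind(rnorm(207, 0, 3), rnorm(207, 0, 3))
  tr0 <- evidence_trace(res0, every = 207)
  expect_lt(tr0$evidence_db[nrow(tr0)], 5)
  # thinning evaluates fewer points but the same final value
  tr_thin <- evidence_trace(res, every = 50)
  expect_equal(tr_thin$evidence_db[nrow(tr_thin)],
               tr$evidence_db[nrow(tr)], tolerance = 1e-9)
})
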