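#' Convert between decibels of evidence and odds
#'
#' Evidence in decibels is `10 * log10` of a ratio of model probabilities,
#' so 10 dB corresponds to 10:1 odds.
#'
#' @param value Evidence in dB, or odds, depending on `direction`. Odds too
#'   large for a double (beyond ~1e308) can be given as a scientific-notation
#'   string, e.g. `"2.2e681"`.
#' @param direction `"db_to_odds"` or `"odds_to_db"`.
#' @return The converted value.
#' @examples
#' db_odds_convert(29, "db_to_odds")         # ~794:1
#' db_odds_convert("2.2e681", "odds_to_db")  # ~6813 dB
#' @export
db_odds_convert <- function(value, direction = c("db_to_odds",
                                                 "odds_to_db")) {
  direction <- match.arg(direction)
  if (direction == "db_to_odds") {
    stopifnot(is.numeric(value), all(is.finite(value)))
    10^(value / 10)
  } else {
    if (is.character(value)) {
      m <- regmatches(value,
                      regexec("^\\s*([0-9.]+)[eE]([+-]?[0-9]+)\\s*$", value))
      bad <- vapply(m, length, integer(1)) != 3
      if (any(bad)) stop("cannot parse odds: ", value[bad][1])
      mant <- as.numeric(vapply(m, `[`, "", 2))
      expo <- as.numeric(vapply(m, `[`, "", 3))
      if (any(mant <= 0)) stop("odds must be positive")
      return(10 * (log10(mant) + expo))
    }
    stopifnot(is.numeric(value), all(is.finite(value)))
    if (any(value <= 0)) stop("odds must be positive")
    10 * log10(value)
  }
}

#' Decibel evidence comparing the circular and anisotropic aimpoint models
#'
#' For every penalty trial the endpoint is scored under a bivariate Gaussian
#' centred on the model's predicted aimpoint for that trial's penalty
#' direction, with the plug-in covariance estimated from the subject's
#' zero-penalty data. The evidence is
#' `10 * log10( P(D | M_c) / P(D | M_a) )` under a uniform prior over the
#' two models: positive values favour the circular model.
#'
#' @param dataset An `endpoint_dataset` (only `block_kind == "penalty"` rows
#'   are used) or a data frame with `penalty_direction`, `x_mm`, `y_mm`.
#' @param predictions_a,predictions_c `planner_prediction`s from
#'   [predict_model_aimpoints()] for models `M_a` and `M_c`.
#' @param noise Plug-in [noise_model()] (the full fit to the same
#'   zero-penalty data).
#' @return An `evidence_result`: list with `evidence_db`, `loglik_c`,
#'   `loglik_a` and `n_trials`.
#' @export
aimpoint_model_evidence <- function(dataset, predictions_a, predictions_c,
                                    noise) {
  stopifnot(inherits(noise, "noise_model"))
  pen <- if ("block_kind" %in% names(dataset)) {
    dataset[dataset$block_kind == "penalty", ]
  } else {
    dataset
  }
  if (nrow(pen) == 0) stop("no penalty trials")
  ll <- function(predictions) {
    total <- 0
    for (d in unique(pen$penalty_direction)) {
      i <- pen$penalty_direction == d
      a <- predictions$aimpoints[[d]]
      if (is.null(a)) stop("no predicted aimpoint for direction ", d)
      total <- total +
        sum(stats::dnorm(pen$x_mm[i], a[1], sqrt(noise$var_x_mm2),
                         log = TRUE)) +
        sum(stats::dnorm(pen$y_mm[i], a[2], sqrt(noise$var_y_mm2),
                         log = TRUE))
    }
    total
  }
  ll_a <- ll(predictions_a)
  ll_c <- ll(predictions_c)
  structure(
    list(evidence_db = 10 / log(10) * (ll_c - ll_a),
         loglik_c = ll_c, loglik_a = ll_a, n_trials = nrow(pen)),
    class = "evidence_result"
  )
}

#' @export
print.evidence_result <- function(x, ...) {
  cat(sprintf("<evidence_result: %.2f dB over %d trials>\n",
              x$evidence_db, if (!is.null(x$n_trials)) x$n_trials else NA))
  invisible(x)
}

# log of I(n, S; lo, hi) = int_lo^hi (2 pi s^2)^(-n/2) exp(-S/(2 s^2)) ds/s,
# the marginal likelihood of n zero-mean Gaussian residuals with sum of
# squares S under an (unnormalised) 1/sigma prior truncated to [lo, hi].
# Substituting v = S / (2 s^2) gives an incomplete-Gamma expression,
# evaluated in the log domain.
.log_jeffreys_integral <- function(n, S, lo, hi) {
  stopifnot(n >= 1, lo > 0, hi > lo)
  if (S <= 0) {
    # all-zero residuals: L(s) = (2 pi s^2)^(-n/2), integrable in closed form
    return(-(n / 2) * log(2 * pi) + log((lo^(-n) - hi^(-n)) / n))
  }
  shape <- n / 2
  v_lo <- S / (2 * lo^2)   # larger
  v_hi <- S / (2 * hi^2)   # smaller
  lower_hi <- stats::pgamma(v_hi, shape, log.p = TRUE)
  if (lower_hi > log(0.5)) {
    lmass <- logspace_sub(
      stats::pgamma(v_hi, shape, lower.tail = FALSE, log.p = TRUE),
      stats::pgamma(v_lo, shape, lower.tail = FALSE, log.p = TRUE)
    )
  } else {
    lmass <- logspace_sub(stats::pgamma(v_lo, shape, log.p = TRUE), lower_hi)
  }
  -(n / 2) * log(2 * pi) - log(2) + (n / 2) * (log(2) - log(S)) +
    lgamma(shape) + lmass
}

# Vectorised over the lower bound; used by the outer quadrature below.
.log_jeffreys_integral_lo <- function(n, S, lo_vec, hi) {
  out <- rep(-Inf, length(lo_vec))
  ok <- lo_vec < hi
  if (!any(ok)) return(out)
  lo <- lo_vec[ok]
  if (S <= 0) {
    out[ok] <- -(n / 2) * log(2 * pi) + log((lo^(-n) - hi^(-n)) / n)
    return(out)
  }
  shape <- n / 2
  v_lo <- S / (2 * lo^2)
  v_hi <- S / (2 * hi^2)
  # mass = F(v_lo) - F(v_hi) with v_lo >= v_hi elementwise; take the
  # difference in whichever tail is smaller for numerical headroom
  k <- length(lo)
  up_hi <- rep_len(stats::pgamma(v_hi, shape, lower.tail = FALSE,
                                 log.p = TRUE), k)
  up_lo <- stats::pgamma(v_lo, shape, lower.tail = FALSE, log.p = TRUE)
  lw_hi <- rep_len(stats::pgamma(v_hi, shape, log.p = TRUE), k)
  lw_lo <- stats::pgamma(v_lo, shape, log.p = TRUE)
  use_upper <- lw_hi > log(0.5)
  lmass <- numeric(k)
  lmass[use_upper] <- logspace_sub(up_hi[use_upper], up_lo[use_upper])
  lmass[!use_upper] <- logspace_sub(lw_lo[!use_upper], lw_hi[!use_upper])
  out[ok] <- -(n / 2) * log(2 * pi) - log(2) + (n / 2) * (log(2) - log(S)) +
    lgamma(shape) + lmass
  out
}

# log of the order-constrained double integral
#   J = int_lo^hi (1/sB) L_B(sB) [ int_sB^hi (1/sA) L_A(sA) dsA ] dsB
# with L(s) the zero-mean Gaussian likelihood. The inner integral is
# closed-form (incomplete Gamma); the outer integral is done in u = log(sB)
# with Simpson's rule on an adaptively located window around the peak.
.log_constrained_integral <- function(n_A, S_A, n_B, S_B, lo, hi) {
  log_g <- function(u) {
    # in u = log(sB) the 1/sB prior factor cancels the Jacobian exactly
    inner <- .log_jeffreys_integral_lo(n_A, S_A, exp(u), hi)
    -(n_B / 2) * log(2 * pi) - n_B * u - S_B * exp(-2 * u) / 2 + inner
  }
  u_lo <- log(lo)
  u_hi <- log(hi)
  scout <- seq(u_lo, u_hi, length.out = 1001)
  lg <- log_g(scout)
  m <- max(lg)
  if (!is.finite(m)) return(-Inf)
  keep <- which(lg > m - 60)
  i0 <- max(1L, min(keep) - 1L)
  i1 <- min(length(scout), max(keep) + 1L)
  # Simpson on the peak window (odd number of points)
  grid <- seq(scout[i0], scout[i1], length.out = 2001)
  lg2 <- log_g(grid)
  h <- grid[2] - grid[1]
  w <- c(1, rep(c(4, 2), length.out = length(grid) - 2), 1)
  w[length(w) - 1] <- 4
  m2 <- max(lg2)
  m2 + log(sum(w * exp(lg2 - m2)) * h / 3)
}

#' Jeffreys-prior evidence on variance structure
#'
#' Compares Gaussian models of two sets of zero-mean residuals by their
#' marginal likelihoods under a normalised bounded Jeffreys prior
#' `p(sigma) ~ 1/sigma` on `[prior_bounds[1], prior_bounds[2]]`:
#'
#' * `"unequal_vs_equal"`: each set has its own sigma, versus one shared
#'   sigma.
#' * `"A_greater_vs_equal"`: two sigmas constrained to `sigma_A > sigma_B`
#'   (the constrained prior renormalised by its constraint-region mass,
#'   a factor 2 by symmetry), versus one shared sigma.
#'
#' Positive evidence favours the first-named (two-variance) model. The
#' evidence that horizontal variance exceeds vertical variance, as used for
#' the anisotropy analyses, is `A_greater_vs_equal` with A the horizontal
#' and B the vertical residuals.
#'
#' @param residuals_A,residuals_B Numeric vectors of residuals about a known
#'   zero mean (n >= 1 each).
#' @param comparison Which model pair to compare.
#' @param prior_bounds Length-2 positive numeric, sigma bounds in mm.
#' @return An `evidence_result`: list with `evidence_db`,
#'   `log_marginal_alt`, `log_marginal_equal`, `n_A`, `n_B`, `comparison`
#'   and `prior_bounds`.
#' @export
variance_structure_evidence <- function(residuals_A, residuals_B,
                                        comparison = c("A_greater_vs_equal",
                                                       "unequal_vs_equal"),
                                        prior_bounds = c(0.1, 100)) {
  comparison <- match.arg(comparison)
  stopifnot(length(residuals_A) >= 1, length(residuals_B) >= 1,
            all(is.finite(residuals_A)), all(is.finite(residuals_B)),
            length(prior_bounds) == 2, prior_bounds[1] > 0,
            prior_bounds[2] > prior_bounds[1])
  lo <- prior_bounds[1]
  hi <- prior_bounds[2]
  n_A <- length(residuals_A)
  n_B <- length(residuals_B)
  S_A <- sum(residuals_A^2)
  S_B <- sum(residuals_B^2)
  for (S in c(S_A, S_B)) {
    if (S > 0) {
      s_hat <- sqrt(S / max(n_A, 1))
      if (s_hat < lo || s_hat > hi) {
        warning("residual scale outside the prior bounds [", lo, ", ", hi,
                "] mm; evidence may be prior-dominated")
      }
      break
    }
  }
  log_z <- log(log(hi / lo))  # normalisation of the 1/sigma prior

  log_m_equal <- .log_jeffreys_integral(n_A + n_B, S_A + S_B, lo, hi) - log_z

  log_m_alt <- if (comparison == "unequal_vs_equal") {
    .log_jeffreys_integral(n_A, S_A, lo, hi) +
      .log_jeffreys_integral(n_B, S_B, lo, hi) - 2 * log_z
  } else {
    log(2) + .log_constrained_integral(n_A, S_A, n_B, S_B, lo, hi) - 2 * log_z
  }

  structure(
    list(evidence_db = 10 / log(10) * (log_m_alt - log_m_equal),
         log_marginal_alt = log_m_alt, log_marginal_equal = log_m_equal,
         n_A = n_A, n_B = n_B, comparison = comparison,
         prior_bounds = prior_bounds),
    class = "evidence_result"
  )
}

#' Sequential evidence trace for horizontal-greater-than-vertical variance
#'
#' Cumulative decibel evidence, after each reach, that the horizontal
#' residual variance exceeds the vertical residual variance (versus equal
#' variances), using the same horizontal and vertical residuals of each
#' reach and [variance_structure_evidence()] with comparison
#' `"A_greater_vs_equal"`. The trace starts at 0 dB before any reach; under
#' sustained anisotropy it grows roughly linearly with trial count, and
#' under isotropy it drifts negative.
#'
#' @param residuals_xy n x 2 matrix of endpoint residuals about the known
#'   aimpoint (mm), in schedule order.
#' @param prior_bounds Sigma bounds of the Jeffreys prior, mm.
#' @param every Evaluate the evidence every `every` trials (1 = all).
#' @return An `evidence_trace` data frame with columns `n_trials` and
#'   `evidence_db`, beginning at `(0, 0)`.
#' @export
evidence_trace <- function(residuals_xy, prior_bounds = c(0.1, 100),
                           every = 1) {
  residuals_xy <- as.matrix(residuals_xy)
  stopifnot(ncol(residuals_xy) == 2, every >= 1)
  n <- nrow(residuals_xy)
  cs_x <- cumsum(residuals_xy[, 1]^2)
  cs_y <- cumsum(residuals_xy[, 2]^2)
  ks <- unique(c(seq(every, n, by = every), n))
  ks <- ks[ks >= 1]
  lo <- prior_bounds[1]
  hi <- prior_bounds[2]
  log_z <- log(log(hi / lo))
  ev <- vapply(ks, function(k) {
    log_m_eq <- .log_jeffreys_integral(2 * k, cs_x[k] + cs_y[k], lo, hi) -
      log_z
    log_m_alt <- log(2) +
      .log_constrained_integral(k, cs_x[k], k, cs_y[k], lo, hi) - 2 * log_z
    10 / log(10) * (log_m_alt - log_m_eq)
  }, numeric(1))
  out <- data.frame(n_trials = c(0L, ks), evidence_db = c(0, ev))
  attr(out, "prior_bounds") <- prior_bounds
  class(out) <- c("evidence_trace", "data.frame")
  out
}

#' Export an evidence trace as delimited text
#'
#' @param trace An `evidence_trace`.
#' @param path Output CSV path (`n_trials`, `evidence_db`).
#' @return `path`, invisibly.
#' @export
write_evidence_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
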