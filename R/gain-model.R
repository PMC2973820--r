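#' Gaussian endpoint-noise model
#'
#' Describes the bivariate Gaussian scatter of reach endpoints about an
#' aimpoint. Only the diagonal of the covariance is carried: the horizontal
#' and vertical screen directions are the task-relevant axes and the
#' off-diagonal covariance is taken to be zero throughout.
#'
#' @param var_x_mm2 Horizontal endpoint variance, mm^2.
#' @param var_y_mm2 Vertical endpoint variance, mm^2. If omitted the model is
#'   isotropic (circular) with common variance `var_x_mm2`.
#' @return An object of class `noise_model` with fields `kind`
#'   (`"isotropic"` or `"full"`), `var_x_mm2` and `var_y_mm2`.
#' @examples
#' noise_model(9)        # circular, SD 3 mm
#' noise_model(27, 9)    # horizontal SD ~5.2 mm, vertical 3 mm
#' @export
noise_model <- function(var_x_mm2, var_y_mm2 = NULL) {
  kind <- if (is.null(var_y_mm2)) "isotropic" else "full"
  if (is.null(var_y_mm2)) var_y_mm2 <- var_x_mm2
  stopifnot(is_number(var_x_mm2), is_number(var_y_mm2))
  if (var_x_mm2 <= 0 || var_y_mm2 <= 0) {
    stop("noise_model variances must be > 0")
  }
  structure(
    list(kind = kind, var_x_mm2 = var_x_mm2, var_y_mm2 = var_y_mm2),
    class = "noise_model"
  )
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "<noise_model: %s, SD x = %.3f mm, SD y = %.3f mm>\n",
    x$kind, sqrt(x$var_x_mm2), sqrt(x$var_y_mm2)
  ))
  invisible(x)
}

#' Target/penalty display configuration
#'
#' Geometry and gains of one target-penalty pair, in target-centred
#' coordinates (x rightward, y upward, mm). The defaults reproduce the
#' experimental display: 1 cm diameter circles whose centres are 7.5 mm
#' apart, 1 point for a target hit and -5 for a penalty hit. A hit in the
#' overlap lens earns both.
#'
#' @param penalty_center_mm Length-2 numeric, centre of the penalty disk.
#' @param gain_target Points awarded for landing in the target disk.
#' @param gain_penalty Points awarded for landing in the penalty disk
#'   (a loss is negative).
#' @param target_radius_mm,penalty_radius_mm Disk radii, mm.
#' @param target_center_mm Centre of the target disk (origin by default).
#' @return An object of class `target_penalty_config`.
#' @seealso [penalty_config_for()] to build one from a penalty direction.
#' @export
target_penalty_config <- function(penalty_center_mm,
                                  gain_target = 1,
                                  gain_penalty = -5,
                                  target_radius_mm = 5,
                                  penalty_radius_mm = 5,
                                  target_center_mm = c(0, 0)) {
  stopifnot(
    is_point(penalty_center_mm), is_point(target_center_mm),
    is_number(gain_target), is_number(gain_penalty),
    is_number(target_radius_mm), is_number(penalty_radius_mm)
  )
  if (target_radius_mm <= 0 || penalty_radius_mm <= 0) {
    stop("radii must be > 0")
  }
  structure(
    list(
      target_center_mm = as.numeric(target_center_mm),
      target_radius_mm = target_radius_mm,
      penalty_center_mm = as.numeric(penalty_center_mm),
      penalty_radius_mm = penalty_radius_mm,
      gain_target = gain_target,
      gain_penalty = gain_penalty
    ),
    class = "target_penalty_config"
  )
}

#' Build a target/penalty configuration from a penalty direction
#'
#' @param direction One of `"left"`, `"right"`, `"above"`, `"below"`: where
#'   the penalty disk sits relative to the target.
#' @param offset_mm Centre-to-centre distance, mm (7.5 mm in the experiment).
#' @inheritParams target_penalty_config
#' @return A `target_penalty_config`.
#' @export
penalty_config_for <- function(direction,
                               gain_target = 1,
                               gain_penalty = -5,
                               offset_mm = 7.5,
                               target_radius_mm = 5,
                               penalty_radius_mm = 5) {
  u <- switch(match.arg(direction, c("left", "right", "above", "below")),
    left = c(-1, 0), right = c(1, 0), above = c(0, 1), below = c(0, -1)
  )
  target_penalty_config(
    penalty_center_mm = u * offset_mm,
    gain_target = gain_target, gain_penalty = gain_penalty,
    target_radius_mm = target_radius_mm, penalty_radius_mm = penalty_radius_mm
  )
}

# Probability mass of N(aim, diag(sx^2, sy^2)) over a disk, vectorised over
# aims (n x 2 matrix). The disk integral is reduced to one dimension: the
# vertical slice through the disk at horizontal position x integrates the
# Gaussian exactly via pnorm, and the outer integral over x uses
# Gauss-Legendre after the substitution x = cx + R sin(t), which absorbs the
# square-root edge singularity of the slice height and leaves a smooth
# integrand (error ~1e-12 at 64 nodes).
.disk_prob <- function(aims, center, radius, sd_x, sd_y, n_nodes = 64) {
  gl <- gauss_legendre(n_nodes, -pi / 2, pi / 2)
  xs <- center[1] + radius * sin(gl$x)      # slice positions
  hs <- radius * cos(gl$x)                  # slice half-heights
  ws <- gl$w * radius * cos(gl$x)           # includes dx = R cos(t) dt
  ax <- aims[, 1]
  ay <- aims[, 2]
  # n_aims x n_nodes
  fx <- outer(ax, xs, function(a, x) stats::dnorm(x, a, sd_x))
  py <- outer(ay, hs, function(a, h) {
    stats::pnorm(center[2] + h, a, sd_y) - stats::pnorm(center[2] - h, a, sd_y)
  })
  p <- as.vector((fx * py) %*% ws)
  pmin(pmax(p, 0), 1)
}

# Single-aim disk probability with piecewise quadrature: the t-domain is
# split at the images of the aim's +-9 SD horizontal window and of the
# slice-boundary crossings of the aim's vertical coordinate, so that very
# small noise scales (near-point-mass endpoints) are still resolved.
.disk_prob_scalar <- function(aim, center, radius, sd_x, sd_y,
                              n_nodes = 64) {
  brk_x <- c(aim[1] - 9 * sd_x, aim[1] + 9 * sd_x)
  dy <- abs(aim[2] - center[2])
  if (dy < radius) {
    w <- sqrt(radius^2 - dy^2)
    brk_x <- c(brk_x, center[1] - w, center[1] + w)
  }
  u <- (brk_x - center[1]) / radius
  brk_t <- asin(pmin(pmax(u, -1), 1))
  ts <- sort(unique(c(-pi / 2, brk_t, pi / 2)))
  total <- 0
  for (j in seq_len(length(ts) - 1)) {
    if (ts[j + 1] - ts[j] < 1e-14) next
    gl <- gauss_legendre(n_nodes, ts[j], ts[j + 1])
    xs <- center[1] + radius * sin(gl$x)
    hs <- radius * cos(gl$x)
    ws <- gl$w * radius * cos(gl$x)
    py <- stats::pnorm(center[2] + hs, aim[2], sd_y) -
      stats::pnorm(center[2] - hs, aim[2], sd_y)
    total <- total + sum(ws * stats::dnorm(xs, aim[1], sd_x) * py)
  }
  min(max(total, 0), 1)
}

#' Probability that an endpoint lands in a disk
#'
#' Integrates the bivariate Gaussian endpoint distribution, centred on the
#' aimpoint with diagonal covariance, over a circular region.
#'
#' @param center Length-2 numeric, disk centre (mm).
#' @param radius Disk radius (mm), > 0.
#' @param aim Length-2 numeric, aimpoint (mean of the endpoint distribution).
#' @param noise A [noise_model()].
#' @param n_nodes Quadrature nodes per smooth piece (the default is accurate
#'   to ~1e-12).
#' @return Probability in \[0, 1\].
#' @examples
#' # aiming at the centre of a 5 mm disk with 3 mm circular noise:
#' disk_hit_probability(c(0, 0), 5, c(0, 0), noise_model(9))
#' 1 - exp(-25 / 18)  # closed form for the centred isotropic case
#' @export
disk_hit_probability <- function(center, radius, aim, noise, n_nodes = 64) {
  stopifnot(is_point(center), is_point(aim), inherits(noise, "noise_model"))
  if (!is_number(radius) || radius <= 0) stop("radius must be > 0")
  .disk_prob_scalar(aim, center, radius,
                    sqrt(noise$var_x_mm2), sqrt(noise$var_y_mm2), n_nodes)
}

# Expected gain for an n x 2 matrix of aims.
.eg_aims <- function(aims, config, noise) {
  sd_x <- sqrt(noise$var_x_mm2)
  sd_y <- sqrt(noise$var_y_mm2)
  p_t <- .disk_prob(aims, config$target_center_mm, config$target_radius_mm,
                    sd_x, sd_y)
  p_p <- .disk_prob(aims, config$penalty_center_mm, config$penalty_radius_mm,
                    sd_x, sd_y)
  config$gain_target * p_t + config$gain_penalty * p_p
}

#' Expected gain of an aimpoint
#'
#' Expected points per trial when aiming at `aim`:
#' `EG = G_target * P(target) + G_penalty * P(penalty)`, with both disk
#' probabilities computed under the Gaussian endpoint model. A landing in
#' the target-penalty overlap contributes both terms, which the two-term sum
#' handles automatically.
#'
#' @param aim Length-2 numeric aimpoint (mm).
#' @param config A [target_penalty_config()].
#' @param noise A [noise_model()].
#' @return Expected gain in points per trial.
#' @export
expected_gain <- function(aim, config, noise) {
  stopifnot(is_point(aim), inherits(config, "target_penalty_config"),
            inherits(noise, "noise_model"))
  .eg_aims(matrix(aim, 1), config, noise)
}

#' Expected-gain landscape over a grid of aimpoints
#'
#' Evaluates expected gain on a square grid covering the target disk plus a
#' margin of `margin_sd` noise SDs, for plotting or export.
#'
#' @inheritParams expected_gain
#' @param spacing_mm Grid spacing, mm.
#' @param margin_sd Margin beyond the target disk, in units of the larger
#'   marginal SD.
#' @return A data frame with columns `x_mm`, `y_mm`, `eg`, of class
#'   `gain_landscape`; grid metadata in attributes.
#' @export
gain_landscape <- function(config, noise, spacing_mm = 0.25, margin_sd = 2) {
  stopifnot(spacing_mm > 0, margin_sd >= 0)
  sd_max <- sqrt(max(noise$var_x_mm2, noise$var_y_mm2))
  half <- config$target_radius_mm + margin_sd * sd_max
  ax <- seq(config$target_center_mm[1] - half,
            config$target_center_mm[1] + half, by = spacing_mm)
  ay <- seq(config$target_center_mm[2] - half,
            config$target_center_mm[2] + half, by = spacing_mm)
  grid <- as.matrix(expand.grid(x_mm = ax, y_mm = ay))
  out <- data.frame(grid, eg = .eg_aims(grid, config, noise))
  attr(out, "spacing_mm") <- spacing_mm
  class(out) <- c("gain_landscape", "data.frame")
  out
}

#' Write a gain landscape as delimited text
#'
#' @param landscape A [gain_landscape()].
#' @param path Output file path (CSV with header `x_mm,y_mm,eg`).
#' @return `path`, invisibly.
#' @export
write_gain_landscape <- function(landscape, path) {
  utils::write.csv(as.data.frame(landscape), path, row.names = FALSE)
  invisible(path)
}

# 1-D expected gain along the target-penalty axis: aim = target_center + s*u
# where u is the unit vector from the penalty centre towards the target.
.eg_along_axis <- function(s, config, noise) {
  u <- .away_unit(config)
  aims <- cbind(config$target_center_mm[1] + s * u[1],
                config$target_center_mm[2] + s * u[2])
  .eg_aims(aims, config, noise)
}

# Unit vector pointing from the penalty centre to the target centre
# (the direction in which a positive aimpoint shift moves away from the
# penalty).
.away_unit <- function(config) {
  v <- config$target_center_mm - config$penalty_center_mm
  n <- sqrt(sum(v^2))
  if (n == 0) stop("penalty and target centres coincide")
  v / n
}

.is_axis_aligned <- function(config) {
  d <- config$penalty_center_mm - config$target_center_mm
  any(abs(d) < 1e-12) && !all(abs(d) < 1e-12)
}

#' Maximum-expected-gain (MEG) aimpoint
#'
#' Finds the aimpoint maximising expected gain for a target-penalty
#' configuration under a Gaussian noise model. When the penalty sits on a
#' coordinate axis relative to the target (as in the experiment) and the
#' noise is axis-aligned, the landscape is mirror-symmetric about the
#' target-penalty axis and the search runs in one dimension along that axis
#' (fine grid plus golden-section refinement), followed by a local 2-D
#' Nelder-Mead polish. Other geometries use a 2-D grid plus Nelder-Mead.
#' Grid ties are broken towards the target centre.
#'
#' @inheritParams expected_gain
#' @param grid_spacing_mm Coarse-grid spacing, mm.
#' @param margin_sd Search extent beyond the target disk, in larger-SD units.
#' @param refine Refine the grid optimum continuously (recommended; makes the
#'   result grid-independent to well under 0.05 mm).
#' @return Length-2 numeric aimpoint. If the landscape admits no positive
#'   expected gain anywhere on the grid the best grid point is still
#'   returned, with attribute `warning_flag = TRUE`.
#' @export
meg_aimpoint <- function(config, noise, grid_spacing_mm = 0.1,
                         margin_sd = 2, refine = TRUE) {
  stopifnot(inherits(config, "target_penalty_config"),
            inherits(noise, "noise_model"))
  sd_max <- sqrt(max(noise$var_x_mm2, noise$var_y_mm2))
  half <- config$target_radius_mm + margin_sd * sd_max

  if (.is_axis_aligned(config)) {
    s_grid <- seq(-half, half, by = grid_spacing_mm)
    eg <- .eg_along_axis(s_grid, config, noise)
    best <- which(eg > max(eg) - 1e-12)
    s0 <- s_grid[best[which.min(abs(s_grid[best]))]]   # ties toward centre
    if (refine) {
      lo <- max(-half, s0 - 2 * grid_spacing_mm)
      hi <- min(half, s0 + 2 * grid_spacing_mm)
      opt <- stats::optimize(function(s) .eg_along_axis(s, config, noise),
                             c(lo, hi), maximum = TRUE, tol = 1e-8)
      if (opt$objective >= max(eg)) s0 <- opt$maximum
    }
    u <- .away_unit(config)
    aim <- config$target_center_mm + s0 * u
    eg_best <- .eg_along_axis(s0, config, noise)
  } else {
    ax <- seq(config$target_center_mm[1] - half,
              config$target_center_mm[1] + half, by = grid_spacing_mm)
    ay <- seq(config$target_center_mm[2] - half,
              config$target_center_mm[2] + half, by = grid_spacing_mm)
    grid <- as.matrix(expand.grid(ax, ay))
    eg <- .eg_aims(grid, config, noise)
    best <- which(eg > max(eg) - 1e-12)
    d2 <- rowSums((grid[best, , drop = FALSE] -
                     matrix(config$target_center_mm, length(best), 2,
                            byrow = TRUE))^2)
    aim <- grid[best[which.min(d2)], ]
    eg_best <- max(eg)
  }

  if (refine) {
    opt <- stats::optim(aim, function(a) -.eg_aims(matrix(a, 1), config, noise),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 500))
    if (-opt$value >= eg_best) {
      aim <- opt$par
      eg_best <- -opt$value
    }
  }

  aim <- as.numeric(aim)
  if (eg_best <= 0) {
    warning("expected gain is non-positive everywhere searched; ",
            "returning best grid point")
    attr(aim, "warning_flag") <- TRUE
  }
  aim
}

#' Signed aimpoint shift along the target-penalty axis
#'
#' The displacement of an aimpoint from the target centre, projected onto the
#' unit vector pointing from the penalty centre to the target centre.
#' Positive values are aimpoints on the side of the target away from the
#' penalty.
#'
#' @param aim Length-2 numeric aimpoint, or an n x 2 matrix of aimpoints.
#' @param config A [target_penalty_config()] (the penalty must be present,
#'   i.e. not coincident with the target).
#' @return Signed shift(s) in mm.
#' @export
delta_aim <- function(aim, config) {
  stopifnot(inherits(config, "target_penalty_config"))
  u <- .away_unit(config)
  if (is.matrix(aim)) {
    as.vector((aim[, 1] - config$target_center_mm[1]) * u[1] +
              (aim[, 2] - config$target_center_mm[2]) * u[2])
  } else {
    stopifnot(is_point(aim))
    sum((aim - config$target_center_mm) * u)
  }
}

#' Efficiency of an observed aimpoint
#'
#' Ratio of the expected gain at an observed aimpoint to the expected gain of
#' the ideal MEG aimpoint, both evaluated under the true (generating,
#' possibly anisotropic) noise model. At most 1 whenever the ideal expected
#' gain is positive.
#'
#' @param observed_aim Length-2 numeric aimpoint.
#' @param config A [target_penalty_config()].
#' @param true_noise The generating [noise_model()].
#' @return Efficiency ratio (dimensionless).
#' @export
efficiency <- function(observed_aim, config, true_noise) {
  ideal <- meg_aimpoint(config, true_noise)
  eg_ideal <- expected_gain(ideal, config, true_noise)
  if (eg_ideal <= 0) {
    stop("ideal expected gain is non-positive; efficiency undefined")
  }
  expected_gain(observed_aim, config, true_noise) / eg_ideal
}
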