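#' Fit full and isotropic noise models to endpoint scatter
#'
#' The full model carries the diagonal of the sample covariance (horizontal
#' and vertical sample variances); the isotropic model pools them,
#' `var = (var_x + var_y) / 2`.
#'
#' @param points n x 2 matrix (or data frame) of endpoints, n >= 2.
#' @return `list(full =, isotropic =)` of [noise_model()]s.
#' @export
fit_noise_models <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points to fit a noise model")
  vx <- stats::var(points[, 1])
  vy <- stats::var(points[, 2])
  if (vx <= 0 || vy <= 0) {
    stop("degenerate (zero-variance) endpoint sample")
  }
  list(full = noise_model(vx, vy), isotropic = noise_model((vx + vy) / 2))
}

#' Per-axis endpoint bias with confidence intervals
#'
#' Mean displacement of endpoints from the target centre per axis, with a
#' t-based confidence interval.
#'
#' @param points n x 2 matrix of endpoints, n >= 2.
#' @param target_center Length-2 numeric (origin by default).
#' @param conf_level Confidence level (0.95).
#' @return Data frame with one row per axis: `axis`, `bias_mm`, `ci_lo_mm`,
#'   `ci_hi_mm`, `n`.
#' @export
bias_summary <- function(points, target_center = c(0, 0),
                         conf_level = 0.95) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points")
  stopifnot(is_point(target_center))
  out <- lapply(1:2, function(k) {
    dev <- points[, k] - target_center[k]
    m <- mean(dev)
    se <- stats::sd(dev) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
    data.frame(axis = c("x", "y")[k], bias_mm = m,
               ci_lo_mm = m - tq * se, ci_hi_mm = m + tq * se, n = n)
  })
  do.call(rbind, out)
}

#' One-sided F test on a ratio of sample variances
#'
#' Tests whether the numerator variance is significantly greater than the
#' denominator variance: `F = var_num / var_den` with
#' `(n_num - 1, n_den - 1)` degrees of freedom and an upper-tail p value.
#'
#' @param var_num,var_den Sample variances (> 0).
#' @param n_num,n_den Sample sizes (>= 2).
#' @return `list(F =, df1 =, df2 =, p_value =)`.
#' @export
variance_ratio_test <- function(var_num, n_num, var_den, n_den) {
  stopifnot(is_number(var_num), var_num > 0, is_number(var_den), var_den > 0)
  if (n_num < 2 || n_den < 2) stop("need n >= 2 in both samples")
  f <- var_num / var_den
  df1 <- n_num - 1
  df2 <- n_den - 1
  list(F = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Per-trial signed aimpoint shifts for the penalty trials of a dataset.
.trial_delta_aims <- function(dataset, configs) {
  pen <- dataset[dataset$block_kind == "penalty", ]
  if (nrow(pen) == 0) stop("no penalty trials in dataset")
  delta <- numeric(nrow(pen))
  for (d in unique(pen$penalty_direction)) {
    i <- pen$penalty_direction == d
    delta[i] <- delta_aim(cbind(pen$x_mm[i], pen$y_mm[i]), configs[[d]])
  }
  pen$delta_aim_mm <- delta
  pen
}

#' Per-condition aimpoint summary
#'
#' Mean endpoint (the operational aimpoint), signed aimpoint shift along the
#' target-penalty axis, and its standard error across trials, for every
#' penalty direction in every session present in the dataset. When both
#' sessions are present, a Welch t test comparing the drift and no-drift
#' per-trial shifts is attached per direction (attribute `"session_tests"`).
#'
#' @param dataset An `endpoint_dataset` containing penalty trials.
#' @param configs Named list of [target_penalty_config()]s keyed by penalty
#'   direction (defaults to the study geometry).
#' @return A data frame of class `aimpoint_summary` with columns `session`,
#'   `penalty_direction`, `orientation`, `n`, `aim_x_mm`, `aim_y_mm`,
#'   `delta_aim_mm`, `sem_mm`.
#' @export
delta_aim_summary <- function(dataset, configs = NULL) {
  if (is.null(configs)) configs <- default_configs()
  pen <- .trial_delta_aims(dataset, configs)
  cells <- expand.grid(session = unique(pen$session),
                       penalty_direction = unique(pen$penalty_direction),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- pen[pen$session == cells$session[i] &
                 pen$penalty_direction == cells$penalty_direction[i], ]
    if (nrow(sub) == 0) stop("empty condition cell: ", cells$session[i], "/",
                             cells$penalty_direction[i])
    data.frame(
      session = cells$session[i],
      penalty_direction = cells$penalty_direction[i],
      orientation = .orientation_of(cells$penalty_direction[i]),
      n = nrow(sub),
      aim_x_mm = mean(sub$x_mm),
      aim_y_mm = mean(sub$y_mm),
      delta_aim_mm = mean(sub$delta_aim_mm),
      sem_mm = stats::sd(sub$delta_aim_mm) / sqrt(nrow(sub))
    )
  })
  out <- do.call(rbind, rows)
  if (all(c("drift", "no_drift") %in% pen$session)) {
    tests <- lapply(unique(pen$penalty_direction), function(d) {
      a <- pen$delta_aim_mm[pen$session == "drift" &
                              pen$penalty_direction == d]
      b <- pen$delta_aim_mm[pen$session == "no_drift" &
                              pen$penalty_direction == d]
      tt <- stats::t.test(a, b)  # Welch
      data.frame(penalty_direction = d, t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 mean_diff_mm = mean(a) - mean(b))
    })
    attr(out, "session_tests") <- do.call(rbind, tests)
  }
  class(out) <- c("aimpoint_summary", "data.frame")
  out
}

.orientation_of <- function(direction) {
  ifelse(direction %in% c("left", "right"), "horizontal", "vertical")
}

#' Default study target/penalty configurations
#'
#' The four penalty-direction configurations of the study geometry.
#'
#' @inheritParams penalty_config_for
#' @return Named list of [target_penalty_config()]s.
#' @export
default_configs <- function(gain_target = 1, gain_penalty = -5,
                            offset_mm = 7.5) {
  dirs <- c("left", "right", "above", "below")
  stats::setNames(lapply(dirs, penalty_config_for, gain_target = gain_target,
                         gain_penalty = gain_penalty, offset_mm = offset_mm),
                  dirs)
}

#' Half-block time course of aimpoint shifts
#'
#' Averages per-trial aimpoint shifts over successive half-blocks of the
#' penalty blocks, separately for horizontally and vertically oriented
#' target-penalty pairs (4 penalty blocks of 120 trials give 8 half-block
#' points per orientation).
#'
#' @inheritParams delta_aim_summary
#' @return Data frame with columns `session`, `halfblock`, `orientation`,
#'   `mean_delta_aim_mm`, `sem_mm`, `n`.
#' @export
halfblock_timecourse <- function(dataset, configs = NULL) {
  if (is.null(configs)) configs <- default_configs()
  pen <- .trial_delta_aims(dataset, configs)
  pen$orientation <- .orientation_of(pen$penalty_direction)
  out <- list()
  for (sess in unique(pen$session)) {
    sub <- pen[pen$session == sess, ]
    sub <- sub[order(sub$trial_index), ]
    blocks <- sort(unique(sub$block_index))
    hb <- 0L
    for (b in blocks) {
      bt <- sub[sub$block_index == b, ]
      half_size <- ceiling(nrow(bt) / 2)
      halves <- split(seq_len(nrow(bt)),
                      rep(1:2, c(half_size, nrow(bt) - half_size)))
      for (h in halves) {
        hb <- hb + 1L
        for (orient in c("horizontal", "vertical")) {
          cell <- bt[h, ][bt$orientation[h] == orient, ]
          if (nrow(cell) == 0) {
            stop("empty half-block cell (session ", sess, ", half-block ",
                 hb, ", ", orient, ")")
          }
          out[[length(out) + 1L]] <- data.frame(
            session = sess, halfblock = hb, orientation = orient,
            mean_delta_aim_mm = mean(cell$delta_aim_mm),
            sem_mm = stats::sd(cell$delta_aim_mm) / sqrt(nrow(cell)),
            n = nrow(cell)
          )
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Zero-penalty experimental endpoints of a session
#'
#' Convenience extractor for the endpoints used to estimate endpoint
#' covariance (zero-penalty experimental trials only, as in the analysis;
#' set `include_training = TRUE` for the residual pool the
#' continually-updating learner sees).
#'
#' @param dataset An `endpoint_dataset`.
#' @param session `"drift"` or `"no_drift"`.
#' @param include_training Also include training-trial endpoints.
#' @return n x 2 matrix of endpoints (mm).
#' @export
zero_penalty_points <- function(dataset, session,
                                include_training = FALSE) {
  kinds <- c("zero_penalty", if (include_training) "training")
  sub <- dataset[dataset$session == session &
                   dataset$block_kind %in% kinds, ]
  cbind(sub$x_mm, sub$y_mm)
}
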