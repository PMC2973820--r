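#' Fixed per-direction aimpoints for a model-based planner
#'
#' Aimpoints used by the non-adaptive planners for each of the four penalty
#' directions: the `anisotropic` planner maximises expected gain under the
#' full (diagonal) covariance, the `circular` planner first pools the two
#' marginal variances into one isotropic variance, and the `static` planner
#' always aims at the target centre.
#'
#' @param planner_kind `"circular"`, `"anisotropic"` or `"static"`.
#' @param configs Named list of [target_penalty_config()]s keyed by penalty
#'   direction (`left`, `right`, `above`, `below`).
#' @param noise Full [noise_model()] describing the endpoint scatter the
#'   planner believes in.
#' @return Named list of length-2 aimpoints, one per direction.
#' @export
planner_aimpoints <- function(planner_kind, configs, noise) {
  planner_kind <- match.arg(planner_kind,
                            c("circular", "anisotropic", "static"))
  use <- switch(planner_kind,
    static = NULL,
    circular = noise_model((noise$var_x_mm2 + noise$var_y_mm2) / 2),
    anisotropic = noise_model(noise$var_x_mm2, noise$var_y_mm2)
  )
  lapply(configs, function(cfg) {
    if (planner_kind == "static") cfg$target_center_mm
    else meg_aimpoint(cfg, use)
  })
}

#' MEG aimpoint predictions of the two internal-model planners
#'
#' Fits a noise model to a subject's zero-penalty endpoints and computes the
#' MEG aimpoint for each penalty configuration. Model `M_a` (anisotropic)
#' uses the diagonal sample covariance; model `M_c` (circular) uses the
#' isotropic fit obtained by pooling the horizontal and vertical variances.
#'
#' @param zero_penalty_points n x 2 matrix of zero-penalty endpoints (mm),
#'   n >= 2, with non-degenerate scatter.
#' @param model_kind `"M_a"` or `"M_c"`.
#' @param configs Named list of [target_penalty_config()]s keyed by penalty
#'   direction.
#' @return An object of class `planner_prediction`: list with `model_kind`,
#'   `aimpoints` (named list of length-2 vectors), and `noise_used`.
#' @export
predict_model_aimpoints <- function(zero_penalty_points,
                                    model_kind = c("M_a", "M_c"),
                                    configs) {
  model_kind <- match.arg(model_kind)
  fits <- fit_noise_models(zero_penalty_points)
  noise <- if (model_kind == "M_a") fits$full else fits$isotropic
  structure(
    list(
      model_kind = model_kind,
      aimpoints = lapply(configs, meg_aimpoint, noise = noise),
      noise_used = noise
    ),
    class = "planner_prediction"
  )
}

#' Hill-climbing learner hyperparameters
#'
#' The hill climber holds one aimpoint per penalty direction, executes
#' `aim + u` with a small random exploration offset `u`, and after seeing
#' the realised reward `r` moves the aim by `step_size * (r - rbar) * u`,
#' where `rbar` is an exponential moving average of that direction's
#' rewards. This is the simplest reward-only stochastic-approximation
#' scheme: no noise model is formed, yet the long-run aims climb the
#' expected-gain landscape of the true (possibly anisotropic) noise.
#'
#' @param step_size Learning rate applied to the reward-weighted
#'   exploration offset (1/points, so the product is in mm).
#' @param explore_sd_mm SD of the isotropic exploration offset, mm.
#' @param reward_ema Smoothing weight of the running reward baseline.
#' @return A list of hyperparameters.
#' @export
hill_climb_control <- function(step_size = 0.3, explore_sd_mm = 1.5,
                               reward_ema = 0.05) {
  stopifnot(is_number(step_size), is.finite(step_size),
            is_number(explore_sd_mm), explore_sd_mm >= 0,
            is_number(reward_ema), reward_ema > 0, reward_ema <= 1)
  list(step_size = step_size, explore_sd_mm = explore_sd_mm,
       reward_ema = reward_ema)
}

# Core hill-climbing recursion. `directions` is the penalty-trial direction
# sequence, `residuals` the matching motor-noise draws (endpoint = executed
# aim + residual). Returns executed aims and per-trial base aims.
.hill_climb_run <- function(directions, configs, residuals, control) {
  dirs <- names(configs)
  base <- stats::setNames(lapply(dirs, function(d) c(0, 0)), dirs)
  rbar <- stats::setNames(rep(0, length(dirs)), dirs)
  n <- length(directions)
  aims <- matrix(0, n, 2)
  for (t in seq_len(n)) {
    d <- directions[t]
    cfg <- configs[[d]]
    u <- stats::rnorm(2, 0, control$explore_sd_mm)
    a_exec <- base[[d]] + u
    endpoint <- a_exec + residuals[t, ]
    r <- .score_endpoint(endpoint, cfg)
    base[[d]] <- base[[d]] + control$step_size * (r - rbar[d]) * u
    rbar[d] <- (1 - control$reward_ema) * rbar[d] + control$reward_ema * r
    aims[t, ] <- a_exec
  }
  list(aims = aims, final_base = base)
}

.score_endpoint <- function(endpoint, cfg) {
  in_t <- sum((endpoint - cfg$target_center_mm)^2) <= cfg$target_radius_mm^2
  in_p <- sum((endpoint - cfg$penalty_center_mm)^2) <= cfg$penalty_radius_mm^2
  cfg$gain_target * in_t + cfg$gain_penalty * in_p
}

#' Simulate a hill-climbing aimpoint trajectory
#'
#' Runs the reward-only hill climber of [hill_climb_control()] over a
#' sequence of penalty trials, drawing motor noise (and drift shifts, in the
#' drift session) from the subject's generating model. The trajectory
#' starts at the target centre and, over many trials, the per-direction mean
#' aims approach the MEG aimpoints of the true anisotropic noise.
#'
#' @param directions Character vector of penalty directions, one per trial
#'   (the trial schedule); or a single integer `n` to draw `n` directions
#'   uniformly.
#' @param configs Named list of [target_penalty_config()]s keyed by
#'   direction.
#' @param subject A [subject_spec()].
#' @param session `"drift"` or `"no_drift"` (controls the drift mixture).
#' @param control Hyperparameters from [hill_climb_control()].
#' @param rng_seed Optional seed.
#' @return A `learner_trajectory` data frame: `trial`, `penalty_direction`,
#'   `aim_x_mm`, `aim_y_mm`, `delta_aim_mm` (executed aims, exploration
#'   included).
#' @export
hill_climb_trajectory <- function(directions, configs, subject,
                                  session = c("drift", "no_drift"),
                                  control = hill_climb_control(),
                                  rng_seed = NULL) {
  session <- match.arg(session)
  with_seed(rng_seed, {
    if (length(directions) == 1 && is.numeric(directions)) {
      directions <- sample(names(configs), directions, replace = TRUE)
    }
    n <- length(directions)
    drift <- if (session == "drift") {
      sample(c("left", "none", "right"), n, replace = TRUE)
    } else {
      rep("none", n)
    }
    resid <- cbind(
      .drift_shift(drift, subject$mfr_displacement_mm) +
        stats::rnorm(n, 0, subject$baseline_sd_mm),
      stats::rnorm(n, 0, subject$baseline_sd_mm)
    )
    run <- .hill_climb_run(directions, configs, resid, control)
    .as_trajectory(run$aims, directions, configs, "hill_climb", control)
  })
}

.as_trajectory <- function(aims, directions, configs, kind, hyper) {
  traj <- data.frame(
    trial = seq_along(directions),
    penalty_direction = directions,
    aim_x_mm = aims[, 1],
    aim_y_mm = aims[, 2],
    delta_aim_mm = vapply(seq_along(directions), function(i) {
      delta_aim(aims[i, ], configs[[directions[i]]])
    }, numeric(1))
  )
  attr(traj, "learner_kind") <- kind
  attr(traj, "hyperparameters") <- hyper
  class(traj) <- c("learner_trajectory", "data.frame")
  traj
}

# Aims of the continually-updating planner for the penalty trials of one
# session. The planner's very first experimental model is the circular
# (pooled) fit to the training residuals; from the next update point on it
# re-fits the full diagonal covariance to all residuals observed so far
# (training + experimental). Refits happen every `update_every` penalty
# trials.
.continual_update_aims <- function(sched, resid, pen, configs, update_every) {
  aims <- matrix(0, length(pen), 2)
  train_idx <- which(sched$block_kind == "training")
  if (length(train_idx) < 2) stop("continual-update planner needs >= 2 prior observations")
  current <- NULL
  for (i in seq_along(pen)) {
    if ((i - 1) %% update_every == 0) {
      if (i == 1) {
        fits <- fit_noise_models(resid[train_idx, , drop = FALSE])
        model <- fits$isotropic
      } else {
        prior <- which(seq_len(nrow(sched)) < pen[i])
        model <- fit_noise_models(resid[prior, , drop = FALSE])$full
      }
      current <- lapply(configs, meg_aimpoint, noise = model)
    }
    aims[i, ] <- current[[sched$penalty_direction[pen[i]]]]
  }
  aims
}

#' Continually-updating planner trajectory from a dataset stream
#'
#' Replays a session's trials in schedule order and computes, for every
#' penalty trial, the aimpoint a planner would choose if it kept re-fitting
#' its noise model to all motor residuals observed so far. The residual on
#' each trial is `endpoint - planned aim`, which does not depend on where
#' the original planner aimed, so any session dataset carrying aim columns
#' can be replayed. The first experimental aim uses the circular fit to the
#' training residuals (the transitory first model); subsequent refits use
#' the full diagonal covariance of all residuals to date, recomputed every
#' `update_every` penalty trials.
#'
#' @param dataset A single-session `endpoint_dataset` with `aim_x_mm` /
#'   `aim_y_mm` columns.
#' @param configs Named list of [target_penalty_config()]s keyed by
#'   direction.
#' @param update_every Refit cadence in penalty trials (default: one
#'   half-block of the study design).
#' @return A `learner_trajectory` data frame as in
#'   [hill_climb_trajectory()].
#' @export
continual_update_trajectory <- function(dataset, configs, update_every = 60) {
  stopifnot(inherits(dataset, "data.frame"),
            all(c("aim_x_mm", "aim_y_mm") %in% names(dataset)))
  if (length(unique(dataset$session)) != 1) {
    stop("continual_update_trajectory expects a single-session dataset")
  }
  sched <- dataset[order(dataset$trial_index), ]
  resid <- cbind(sched$x_mm - sched$aim_x_mm, sched$y_mm - sched$aim_y_mm)
  pen <- which(sched$block_kind == "penalty")
  if (length(pen) == 0) stop("no penalty trials in dataset")
  aims <- .continual_update_aims(sched, resid, pen, configs, update_every)
  .as_trajectory(aims, sched$penalty_direction[pen], configs,
                 "continual_update", list(update_every = update_every))
}

#' Stable-circular planner trajectory
#'
#' The constant trajectory of a planner that fixes its circular noise model
#' after training and never revises it: every penalty trial of a direction
#' uses the same MEG aimpoint computed under the pooled isotropic fit to the
#' training residuals.
#'
#' @inheritParams continual_update_trajectory
#' @return A `learner_trajectory` data frame.
#' @export
stable_circular_trajectory <- function(dataset, configs) {
  stopifnot(inherits(dataset, "data.frame"))
  sched <- dataset[order(dataset$trial_index), ]
  resid <- cbind(sched$x_mm - sched$aim_x_mm, sched$y_mm - sched$aim_y_mm)
  train <- which(sched$block_kind == "training")
  pen <- which(sched$block_kind == "penalty")
  if (length(train) < 2) stop("need >= 2 training trials")
  if (length(pen) == 0) stop("no penalty trials in dataset")
  model <- fit_noise_models(resid[train, , drop = FALSE])$isotropic
  plan <- lapply(configs, meg_aimpoint, noise = model)
  dirs <- sched$penalty_direction[pen]
  aims <- t(vapply(dirs, function(d) plan[[d]], numeric(2)))
  .as_trajectory(aims, dirs, configs, "stable_circular", list())
}

#' Export a learner trajectory as delimited text
#'
#' @param trajectory A `learner_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
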