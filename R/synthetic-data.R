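#' Experiment design
#'
#' Counts, gains and geometry of one two-session reaching experiment. The
#' defaults reproduce the study design: per session, 3 training blocks of 69
#' reaches to crosshairs followed by 6 experimental blocks of 120 reaches to
#' a target-penalty pair, of which 2 are zero-penalty blocks (one scheduled
#' in the first three experimental blocks and one in the last three); target
#' hits earn 1 point, penalty hits lose 5, timeouts lose 7; circle radii are
#' 5 mm with 7.5 mm centre separation; in the drift session the three visual
#' drift conditions (left, none, right) occur with equal probability.
#'
#' @param n_training_blocks,trials_per_training_block Training schedule.
#' @param n_experimental_blocks,trials_per_experimental_block Experimental
#'   schedule.
#' @param n_zero_penalty_blocks Number of experimental blocks in which the
#'   penalty is worth 0 points. Must be even so the blocks can be balanced
#'   across the two halves of the session.
#' @param penalty_points Points for a penalty hit in penalty blocks (<= 0).
#' @param target_points Points for a target hit (>= 0).
#' @param timeout_points Points lost on a timeout (<= 0; timeouts are not
#'   simulated, the cost is carried for completeness).
#' @param drift_probabilities Probabilities of the (left, none, right) drift
#'   conditions; must sum to 1.
#' @param penalty_offset_mm Target-to-penalty centre distance, mm.
#' @param target_radius_mm,penalty_radius_mm Disk radii, mm.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_training_blocks = 3,
                              trials_per_training_block = 69,
                              n_experimental_blocks = 6,
                              trials_per_experimental_block = 120,
                              n_zero_penalty_blocks = 2,
                              penalty_points = -5,
                              target_points = 1,
                              timeout_points = -7,
                              drift_probabilities = c(1, 1, 1) / 3,
                              penalty_offset_mm = 7.5,
                              target_radius_mm = 5,
                              penalty_radius_mm = 5) {
  counts <- c(n_training_blocks, trials_per_training_block,
              n_experimental_blocks, trials_per_experimental_block,
              n_zero_penalty_blocks)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("block/trial counts must be non-negative integers")
  }
  if (length(drift_probabilities) != 3 ||
      abs(sum(drift_probabilities) - 1) > 1e-8 ||
      any(drift_probabilities < 0)) {
    stop("drift_probabilities must be 3 non-negative values summing to 1")
  }
  if (penalty_points > 0 || timeout_points > 0 || target_points < 0) {
    stop("penalty/timeout points must be <= 0 and target points >= 0")
  }
  stopifnot(penalty_offset_mm > 0, target_radius_mm > 0, penalty_radius_mm > 0)
  structure(
    list(
      n_training_blocks = n_training_blocks,
      trials_per_training_block = trials_per_training_block,
      n_experimental_blocks = n_experimental_blocks,
      trials_per_experimental_block = trials_per_experimental_block,
      n_zero_penalty_blocks = n_zero_penalty_blocks,
      penalty_points = penalty_points,
      target_points = target_points,
      timeout_points = timeout_points,
      drift_probabilities = drift_probabilities,
      penalty_offset_mm = penalty_offset_mm,
      target_radius_mm = target_radius_mm,
      penalty_radius_mm = penalty_radius_mm
    ),
    class = "experiment_design"
  )
}

#' Simulated subject specification
#'
#' Describes one simulated subject: which movement planner selects aimpoints
#' on penalty trials, the baseline (isotropic) endpoint noise, and the
#' magnitude of the horizontal drift perturbation.
#'
#' The drift perturbation emulates the manual following response (MFR): on
#' each drift-session trial the reach endpoint is shifted horizontally by
#' -d, 0 or +d mm according to the trial's drift condition. With the default
#' d = sd * sqrt(3) the equal-probability mixture triples the horizontal
#' endpoint variance (variance sd^2 + (2/3) d^2 = 3 sd^2) while leaving the
#' vertical variance untouched, matching the observed variance-ratio regime.
#' `mfr_displacement_mm = 0` emulates a perturbation non-responder.
#'
#' @param planner_kind One of `"circular"` (isotropic internal noise model),
#'   `"anisotropic"` (full diagonal model), `"hill_climb"` (reward-only
#'   learner), `"continual_update"` (keeps re-fitting its noise model), or
#'   `"static"` (always aims at the target centre).
#' @param baseline_sd_mm Isotropic endpoint noise SD, mm (> 0).
#' @param mfr_displacement_mm Horizontal shift magnitude d per drift trial,
#'   mm (>= 0).
#' @param target_points_override Optional per-subject target gain overriding
#'   the design value (the study paid some subjects 2 points per hit).
#' @param rng_seed Integer seed making the subject's data reproducible.
#' @return An object of class `subject_spec`.
#' @export
subject_spec <- function(planner_kind = c("circular", "anisotropic",
                                          "hill_climb", "continual_update",
                                          "static"),
                         baseline_sd_mm = 3,
                         mfr_displacement_mm = baseline_sd_mm * sqrt(3),
                         target_points_override = NULL,
                         rng_seed = 1L) {
  planner_kind <- match.arg(planner_kind)
  stopifnot(is_number(baseline_sd_mm), baseline_sd_mm > 0,
            is_number(mfr_displacement_mm), mfr_displacement_mm >= 0)
  if (!is.null(target_points_override)) {
    stopifnot(is_number(target_points_override), target_points_override >= 0)
  }
  structure(
    list(
      planner_kind = planner_kind,
      baseline_sd_mm = baseline_sd_mm,
      mfr_displacement_mm = mfr_displacement_mm,
      target_points_override = target_points_override,
      rng_seed = as.integer(rng_seed)
    ),
    class = "subject_spec"
  )
}

#' True endpoint covariance of a session
#'
#' The generating marginal variances for a subject in a session: the drift
#' session's equal-probability horizontal shift mixture adds (2/3) d^2 to
#' the horizontal variance (for the default probabilities), leaving the
#' vertical variance at the baseline.
#'
#' @param subject A [subject_spec()].
#' @param session `"drift"` or `"no_drift"`.
#' @param drift_probabilities Probabilities of the (left, none, right) drift
#'   conditions.
#' @return A full [noise_model()] with the session's marginal variances.
#' @export
session_noise_model <- function(subject, session = c("drift", "no_drift"),
                                drift_probabilities = c(1, 1, 1) / 3) {
  session <- match.arg(session)
  v <- subject$baseline_sd_mm^2
  if (session == "drift") {
    d <- subject$mfr_displacement_mm
    p <- drift_probabilities
    shifts <- c(-d, 0, d)
    m <- sum(p * shifts)
    var_shift <- sum(p * (shifts - m)^2)
    noise_model(v + var_shift, v)
  } else {
    noise_model(v, v)
  }
}

#' Build a trial schedule for one session
#'
#' Generates the ordered trial stubs (no endpoints) for one session:
#' training blocks first, then the experimental blocks with the zero-penalty
#' blocks balanced across the two halves of the experimental sequence (one
#' in each half under the default design). Penalty directions are drawn
#' uniformly from the four orientations on every experimental trial, and
#' drift conditions i.i.d. with the design probabilities in drift sessions.
#'
#' @param design An [experiment_design()].
#' @param session `"drift"` or `"no_drift"`.
#' @param rng_seed Optional integer seed.
#' @return A data frame with one row per trial and columns `session`,
#'   `block_index`, `trial_index` (within session), `trial_in_block`,
#'   `block_kind` (`training`/`zero_penalty`/`penalty`), `drift_condition`,
#'   `penalty_direction` and `penalty_points`.
#' @export
build_schedule <- function(design, session = c("drift", "no_drift"),
                           rng_seed = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  session <- match.arg(session)
  nz <- design$n_zero_penalty_blocks
  ne <- design$n_experimental_blocks
  if (nz > ne) stop("more zero-penalty blocks than experimental blocks")
  if (nz %% 2 != 0) {
    stop("n_zero_penalty_blocks must be even to balance the session halves")
  }
  half1 <- seq_len(ne %/% 2)
  half2 <- setdiff(seq_len(ne), half1)
  if (nz / 2 > length(half1) || nz / 2 > length(half2)) {
    stop("cannot place ", nz, " zero-penalty blocks balanced across halves")
  }

  with_seed(rng_seed, {
    zero_blocks <- c(
      if (nz > 0) sample(half1, nz / 2),
      if (nz > 0) sample(half2, nz / 2)
    )
    blocks <- list()
    idx <- 0L
    for (b in seq_len(design$n_training_blocks)) {
      nt <- design$trials_per_training_block
      blocks[[length(blocks) + 1L]] <- data.frame(
        block_index = idx + b, trial_in_block = seq_len(nt),
        block_kind = "training", penalty_direction = "none",
        penalty_points = 0
      )
    }
    idx <- design$n_training_blocks
    for (b in seq_len(ne)) {
      nt <- design$trials_per_experimental_block
      kind <- if (b %in% zero_blocks) "zero_penalty" else "penalty"
      blocks[[length(blocks) + 1L]] <- data.frame(
        block_index = idx + b, trial_in_block = seq_len(nt),
        block_kind = kind,
        penalty_direction = sample(c("above", "below", "left", "right"),
                                   nt, replace = TRUE),
        penalty_points = if (kind == "penalty") design$penalty_points else 0
      )
    }
    sched <- do.call(rbind, blocks)
    n <- nrow(sched)
    sched$drift_condition <- if (session == "drift") {
      sample(c("left", "none", "right"), n, replace = TRUE,
             prob = design$drift_probabilities)
    } else {
      rep("none", n)
    }
    sched <- data.frame(session = session, sched[, c("block_index",
      "trial_in_block", "block_kind", "drift_condition",
      "penalty_direction", "penalty_points")])
    sched$trial_index <- seq_len(n)
    sched[, c("session", "block_index", "trial_index", "trial_in_block",
              "block_kind", "drift_condition", "penalty_direction",
              "penalty_points")]
  })
}

# Shift applied by a drift condition, vectorised.
.drift_shift <- function(drift_condition, d) {
  d * (as.numeric(drift_condition == "right") -
         as.numeric(drift_condition == "left"))
}

#' Simulate a single reach endpoint
#'
#' Endpoint = aim + isotropic Gaussian motor noise + a horizontal shift of
#' -d, 0 or +d mm according to the drift condition. The vertical marginal is
#' unaffected by drift. Uses the current RNG stream.
#'
#' @param aim Length-2 numeric aimpoint (mm).
#' @param subject A [subject_spec()].
#' @param drift_condition `"left"`, `"none"` or `"right"`.
#' @param n Number of endpoints to draw.
#' @return An `n` x 2 matrix of endpoints (a length-2 vector when `n = 1`).
#' @export
simulate_endpoint <- function(aim, subject, drift_condition = "none", n = 1) {
  stopifnot(is_point(aim), inherits(subject, "subject_spec"))
  drift_condition <- match.arg(drift_condition, c("left", "none", "right"))
  s <- subject$baseline_sd_mm
  shift <- .drift_shift(drift_condition, subject$mfr_displacement_mm)
  pts <- cbind(aim[1] + shift + stats::rnorm(n, 0, s),
               aim[2] + stats::rnorm(n, 0, s))
  if (n == 1) as.numeric(pts) else pts
}

#' Simulate a complete two-session experiment
#'
#' Composes [build_schedule()], the subject's movement planner and the
#' endpoint noise model into a full trial-level dataset for the drift and
#' no-drift sessions. Training and zero-penalty aims are the target centre;
#' penalty-trial aims come from the subject's planner: the `circular`,
#' `anisotropic` and `static` planners use fixed per-direction MEG aimpoints
#' (computed from the session's true covariance, pooled to a single variance
#' for the circular planner), while `hill_climb` and `continual_update`
#' adapt trial by trial.
#'
#' @param design An [experiment_design()].
#' @param subject A [subject_spec()].
#' @param sessions Which sessions to simulate.
#' @return An `endpoint_dataset`: a data frame with one row per trial, the
#'   schedule columns of [build_schedule()] plus the planned aim
#'   (`aim_x_mm`, `aim_y_mm`) and the realised endpoint (`x_mm`, `y_mm`).
#' @export
simulate_experiment <- function(design, subject,
                                sessions = c("no_drift", "drift")) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(subject, "subject_spec"))
  sessions <- match.arg(sessions, c("no_drift", "drift"), several.ok = TRUE)
  out <- lapply(seq_along(sessions), function(i) {
    seed <- (subject$rng_seed + c(no_drift = 0L, drift = 500009L)[sessions[i]])
    .simulate_session(design, subject, sessions[i], as.integer(seed))
  })
  ds <- do.call(rbind, out)
  rownames(ds) <- NULL
  class(ds) <- c("endpoint_dataset", "data.frame")
  ds
}

.session_configs <- function(design, subject) {
  gt <- if (is.null(subject$target_points_override)) design$target_points
        else subject$target_points_override
  dirs <- c("left", "right", "above", "below")
  stats::setNames(lapply(dirs, function(d) {
    penalty_config_for(d, gain_target = gt,
                       gain_penalty = design$penalty_points,
                       offset_mm = design$penalty_offset_mm,
                       target_radius_mm = design$target_radius_mm,
                       penalty_radius_mm = design$penalty_radius_mm)
  }), dirs)
}

.simulate_session <- function(design, subject, session, seed) {
  sched <- build_schedule(design, session, seed)
  with_seed(seed + 1L, {
    n <- nrow(sched)
    s <- subject$baseline_sd_mm
    resid <- cbind(
      .drift_shift(sched$drift_condition, subject$mfr_displacement_mm) +
        stats::rnorm(n, 0, s),
      stats::rnorm(n, 0, s)
    )
    aims <- matrix(0, n, 2)  # training + zero-penalty aims: target centre
    pen <- which(sched$block_kind == "penalty")
    if (length(pen) > 0) {
      configs <- .session_configs(design, subject)
      if (subject$planner_kind %in% c("circular", "anisotropic", "static")) {
        plan <- planner_aimpoints(subject$planner_kind, configs,
                                  session_noise_model(subject, session,
                                    design$drift_probabilities))
        aims[pen, ] <- t(vapply(sched$penalty_direction[pen],
                                function(d) plan[[d]], numeric(2)))
      } else if (subject$planner_kind == "hill_climb") {
        traj <- .hill_climb_run(sched$penalty_direction[pen], configs,
                                resid[pen, , drop = FALSE],
                                hill_climb_control())
        aims[pen, ] <- traj$aims
      } else if (subject$planner_kind == "continual_update") {
        aims[pen, ] <- .continual_update_aims(
          sched, resid, pen, configs,
          update_every = design$trials_per_experimental_block %/% 2
        )
      } else {
        stop("unknown planner_kind: ", subject$planner_kind)
      }
    }
    ds <- sched
    ds$aim_x_mm <- aims[, 1]
    ds$aim_y_mm <- aims[, 2]
    ds$x_mm <- aims[, 1] + resid[, 1]
    ds$y_mm <- aims[, 2] + resid[, 2]
    ds
  })
}

#' Write / read trial-level datasets as CSV
#'
#' One `TrialRecord` per row with a header; coordinates in mm at full
#' precision.
#'
#' @param dataset An `endpoint_dataset` from [simulate_experiment()].
#' @param path File path.
#' @return `write_endpoint_dataset` returns `path` invisibly;
#'   `read_endpoint_dataset` returns the dataset.
#' @export
write_endpoint_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_endpoint_dataset
#' @export
read_endpoint_dataset <- function(path) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("session", "block_index", "trial_index", "block_kind",
              "drift_condition", "penalty_direction", "penalty_points",
              "x_mm", "y_mm")
  missing <- setdiff(needed, names(ds))
  if (length(missing) > 0) {
    stop("dataset file ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  }
  class(ds) <- c("endpoint_dataset", "data.frame")
  ds
}

#' Write / read an experiment configuration as JSON
#'
#' @param design An [experiment_design()].
#' @param subjects A list of [subject_spec()]s.
#' @param path File path.
#' @return `write_experiment_config` returns `path` invisibly;
#'   `read_experiment_config` returns `list(design =, subjects =)`.
#' @export
write_experiment_config <- function(design, subjects, path) {
  cfg <- list(design = unclass(design),
              subjects = lapply(subjects, unclass))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- do.call(experiment_design, cfg$design)
  subjects <- lapply(seq_len(nrow(cfg$subjects)), function(i) {
    sj <- as.list(cfg$subjects[i, ])
    sj <- sj[!vapply(sj, function(x) is.null(x) || all(is.na(x)), logical(1))]
    do.call(subject_spec, sj)
  })
  list(design = design, subjects = subjects)
}
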