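#' End-to-end analysis of a simulated (or loaded) cohort
#'
#' Runs the full analysis chain for a cohort of subjects: simulate (or take)
#' each subject's two-session dataset; fit full and isotropic noise models
#' to the zero-penalty experimental endpoints of each session; compute the
#' MEG aimpoint predictions of the anisotropic (`M_a`) and circular (`M_c`)
#' planners from those fits; summarise observed per-condition aimpoint
#' shifts; score the penalty trials of the drift session for the
#' circular-vs-anisotropic aimpoint evidence; compute per-session
#' efficiency (expected gain at the observed aimpoint relative to the ideal
#' anisotropic-model aimpoint, averaged over penalty directions); and the
#' end-of-training evidence that drift-session noise is anisotropic. At the
#' cohort level it pools the aimpoint evidence (sum of per-subject dB),
#' regresses observed on predicted aimpoint shifts for each model, and runs
#' a one-sample t test on per-subject differences in mean absolute
#' prediction error (`M_a` error minus `M_c` error).
#'
#' @param design An [experiment_design()].
#' @param subjects List of [subject_spec()]s (simulated cohort), or `NULL`
#'   when `datasets` is given.
#' @param datasets Optional named list of `endpoint_dataset`s, one per
#'   subject, bypassing simulation.
#' @param gain_targets Optional numeric vector of per-subject target gains
#'   used with `datasets` (defaults to the design's target points).
#' @param include_all_in_regression Include every subject in the
#'   observed-vs-predicted regression (set `FALSE` to drop subjects whose
#'   drift data are isotropic non-responders, flagged by
#'   `mfr_displacement_mm == 0`).
#' @param prior_bounds Jeffreys-prior sigma bounds for the anisotropy
#'   evidence, mm.
#' @return An `analysis_report`: nested list with a `subjects` list and a
#'   `cohort` list (see the vignette for the schema).
#' @export
run_full_analysis <- function(design, subjects = NULL, datasets = NULL,
                              gain_targets = NULL,
                              include_all_in_regression = TRUE,
                              prior_bounds = c(0.1, 100)) {
  stopifnot(inherits(design, "experiment_design"))
  if (is.null(datasets)) {
    if (is.null(subjects) || length(subjects) == 0) {
      stop("empty cohort: supply subjects or datasets")
    }
    datasets <- lapply(subjects, simulate_experiment, design = design)
    gain_targets <- vapply(subjects, function(sj) {
      if (is.null(sj$target_points_override)) design$target_points
      else sj$target_points_override
    }, numeric(1))
    names(datasets) <- sprintf("S%d", seq_along(datasets))
  } else {
    if (length(datasets) == 0) stop("empty cohort: no datasets")
    if (is.null(gain_targets)) {
      gain_targets <- rep(design$target_points, length(datasets))
    }
    if (is.null(names(datasets))) {
      names(datasets) <- sprintf("S%d", seq_along(datasets))
    }
  }

  subject_reports <- vector("list", length(datasets))
  names(subject_reports) <- names(datasets)
  for (i in seq_along(datasets)) {
    subject_reports[[i]] <- .analyze_subject(
      datasets[[i]], design, gain_targets[i], prior_bounds
    )
  }

  cohort <- .analyze_cohort(subject_reports, subjects,
                            include_all_in_regression)
  structure(list(design = design, subjects = subject_reports,
                 cohort = cohort),
            class = "analysis_report")
}

.analyze_subject <- function(dataset, design, gain_target, prior_bounds) {
  configs <- default_configs(gain_target = gain_target,
                             gain_penalty = design$penalty_points,
                             offset_mm = design$penalty_offset_mm)
  sessions <- intersect(c("no_drift", "drift"), unique(dataset$session))
  if (length(sessions) == 0) stop("dataset contains no recognised sessions")
  summ <- delta_aim_summary(dataset, configs)

  per_session <- list()
  for (sess in sessions) {
    zp <- zero_penalty_points(dataset, sess)
    fits <- fit_noise_models(zp)
    pred_a <- predict_model_aimpoints(zp, "M_a", configs)
    pred_c <- predict_model_aimpoints(zp, "M_c", configs)
    obs <- summ[summ$session == sess, ]
    # efficiency: observed vs ideal (anisotropic-model) aimpoint, per
    # direction under the full fitted noise, averaged
    eff <- vapply(seq_len(nrow(obs)), function(j) {
      efficiency(c(obs$aim_x_mm[j], obs$aim_y_mm[j]),
                 configs[[obs$penalty_direction[j]]], fits$full)
    }, numeric(1))
    per_session[[sess]] <- list(
      noise_full = fits$full,
      noise_isotropic = fits$isotropic,
      predictions_a = pred_a,
      predictions_c = pred_c,
      observed = obs,
      efficiency = mean(eff)
    )
  }

  drift_block <- NULL
  if ("drift" %in% sessions) {
    sd_sess <- per_session[["drift"]]
    ev <- aimpoint_model_evidence(
      dataset[dataset$session == "drift", ],
      sd_sess$predictions_a, sd_sess$predictions_c, sd_sess$noise_full
    )
    train <- dataset[dataset$session == "drift" &
                       dataset$block_kind == "training", ]
    anis <- if (nrow(train) > 0) {
      resid <- cbind(train$x_mm - train$aim_x_mm,
                     train$y_mm - train$aim_y_mm)
      tr <- evidence_trace(resid, prior_bounds, every = nrow(resid))
      tr$evidence_db[nrow(tr)]
    } else {
      NA_real_
    }
    drift_block <- list(aimpoint_evidence_db = ev$evidence_db,
                        training_anisotropy_evidence_db = anis)
  }

  list(sessions = per_session, drift = drift_block,
       delta_aim = summ, gain_target = gain_target)
}

.analyze_cohort <- function(subject_reports, subjects,
                            include_all_in_regression) {
  ids <- names(subject_reports)
  ev <- vapply(subject_reports, function(r) {
    if (is.null(r$drift)) NA_real_ else r$drift$aimpoint_evidence_db
  }, numeric(1))
  pooled <- if (all(is.na(ev))) NA_real_ else sum(ev, na.rm = TRUE)

  keep <- rep(TRUE, length(ids))
  if (!include_all_in_regression && !is.null(subjects)) {
    keep <- vapply(subjects, function(sj) sj$mfr_displacement_mm > 0,
                   logical(1))
  }

  # condition-level observed vs predicted aimpoint shifts, drift session
  obs_all <- pred_a_all <- pred_c_all <- numeric(0)
  err_a <- err_c <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    r <- subject_reports[[i]]
    sess <- r$sessions[["drift"]]
    if (is.null(sess)) next
    obs <- sess$observed
    cfgs <- default_configs(gain_target = r$gain_target)
    pa <- vapply(obs$penalty_direction, function(d) {
      delta_aim(sess$predictions_a$aimpoints[[d]], cfgs[[d]])
    }, numeric(1))
    pc <- vapply(obs$penalty_direction, function(d) {
      delta_aim(sess$predictions_c$aimpoints[[d]], cfgs[[d]])
    }, numeric(1))
    err_a[i] <- mean(abs(obs$delta_aim_mm - pa))
    err_c[i] <- mean(abs(obs$delta_aim_mm - pc))
    if (keep[i]) {
      obs_all <- c(obs_all, obs$delta_aim_mm)
      pred_a_all <- c(pred_a_all, pa)
      pred_c_all <- c(pred_c_all, pc)
    }
  }

  reg <- function(pred) {
    if (length(obs_all) < 3) return(list(intercept = NA_real_,
                                         slope = NA_real_))
    fit <- stats::lm(obs_all ~ pred)
    list(intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]))
  }

  tt <- NULL
  d_err <- err_a - err_c
  d_err <- d_err[is.finite(d_err)]
  if (length(d_err) >= 2 && stats::sd(d_err) > 0) {
    t0 <- stats::t.test(d_err)
    tt <- list(t = unname(t0$statistic), df = unname(t0$parameter),
               p_value = t0$p.value, mean_diff_mm = mean(d_err))
  }

  list(
    pooled_aimpoint_evidence_db = pooled,
    per_subject_evidence_db = stats::setNames(ev, ids),
    regression = list(M_a = reg(pred_a_all), M_c = reg(pred_c_all)),
    abs_error_t_test = tt,
    mean_efficiency = list(
      drift = mean(vapply(subject_reports, function(r) {
        s <- r$sessions[["drift"]]
        if (is.null(s)) NA_real_ else s$efficiency
      }, numeric(1)), na.rm = TRUE),
      no_drift = mean(vapply(subject_reports, function(r) {
        s <- r$sessions[["no_drift"]]
        if (is.null(s)) NA_real_ else s$efficiency
      }, numeric(1)), na.rm = TRUE)
    )
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  subjects: %d\n", length(x$subjects)))
  co <- x$cohort
  cat(sprintf("  pooled aimpoint evidence (dB, + favours circular): %.1f\n",
              co$pooled_aimpoint_evidence_db))
  cat(sprintf("  regression slope M_c: %.3f, M_a: %.3f\n",
              co$regression$M_c$slope, co$regression$M_a$slope))
  cat(sprintf("  mean efficiency drift: %.3f, no-drift: %.3f\n",
              co$mean_efficiency$drift, co$mean_efficiency$no_drift))
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' Flattens the report into a JSON document (per-subject noise fits,
#' aimpoint shifts, predictions, evidence, efficiency, plus the cohort
#' block).
#'
#' @param report An `analysis_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_analysis_report <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "noise_model") || inherits(x, "planner_prediction")) {
      x <- unclass(x)
    }
    if (is.list(x)) {
      lapply(x, strip)
    } else if (is.data.frame(x)) {
      x
    } else {
      x
    }
  }
  doc <- list(
    design = unclass(report$design),
    subjects = lapply(report$subjects, function(r) {
      list(
        gain_target = r$gain_target,
        sessions = lapply(r$sessions, function(s) list(
          noise_full = unclass(s$noise_full),
          noise_isotropic = unclass(s$noise_isotropic),
          aimpoints_a = s$predictions_a$aimpoints,
          aimpoints_c = s$predictions_c$aimpoints,
          observed = as.data.frame(s$observed),
          efficiency = s$efficiency
        )),
        drift = r$drift
      )
    }),
    cohort = strip(report$cohort)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
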