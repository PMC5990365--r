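# Whole-experiment replications on synthetic cohorts, session metrics and the
# variance-explained decomposition.

#' Frozen experiment geometry
#'
#' Court centres, reach starting positions and targets in the robot frame,
#' mirroring the study protocol: two 0.2 m lateral courts meeting at the body
#' midline (plus a frontal court on the midline), and a three-target fan
#' (0.14 m, 45 degrees apart) from a starting position in each court. The
#' midline offset and court distance come from the linkage calibration.
#'
#' @return list with \code{x_mid}, \code{y0} (m) and per-group accessors used
#'   by \code{\link{group_geometry}}.
#' @export
default_geometry <- function() {
  list(x_mid = .calib$x_mid, y0 = .calib$y0)
}

#' Geometry and timing constants for one experimental group
#'
#' @param group one of \code{"FP"} (frontal pong), \code{"LP_R"},
#'   \code{"LP_L"} (lateral pong, right/left court).
#' @return list with the court side, court centre, delay, reach start and the
#'   three-target fan.
#' @export
group_geometry <- function(group = c("FP", "LP_R", "LP_L")) {
  group <- match.arg(group)
  g <- default_geometry()
  side <- switch(group, FP = "frontal", LP_R = "lateral_right",
                 LP_L = "lateral_left")
  centre <- switch(group,
                   FP = c(g$x_mid, g$y0),
                   LP_R = c(g$x_mid + 0.1, g$y0),
                   LP_L = c(g$x_mid - 0.1, g$y0))
  list(group = group, court_side = side, court_centre = centre,
       tau = if (group == "FP") 0.080 else 0.120,
       reach_start = centre,
       targets = target_fan(centre))
}

#' Cohort specification
#'
#' A synthetic cohort of artificial players with normally distributed
#' contact-timing offsets.
#'
#' @param n_subjects cohort size (the study ran 8 per group).
#' @param delta_mean,delta_sd mean and SD of the timing offsets (s).
#' @param group experimental group, see \code{\link{group_geometry}}.
#' @param seed integer RNG seed.
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 8, delta_mean = 0, delta_sd = 0.01,
                        group = "LP_R", seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be at least 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 delta_mean = delta_mean, delta_sd = delta_sd,
                 group = match.arg(group, c("FP", "LP_R", "LP_L")),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Replicate one group of the reaching-pong-reaching experiment
#'
#' Per synthetic subject: draw a timing offset, play a delayed pong session,
#' estimate the mass modifier from the trailing window, and predict the blind
#' reach battery before (modifier 0, plus endpoint noise emulating baseline
#' reach variability) and after (estimated modifier) adaptation. Subject-level
#' failures are recorded and the cohort continues.
#'
#' @param cohort a \code{\link{cohort_spec}}.
#' @param params true linkage parameters.
#' @param session_min session length (minutes).
#' @param window_min trailing analysis window (minutes).
#' @param pre_noise_sd SD of Gaussian endpoint noise added to the
#'   pre-adaptation extent (m).
#' @param reach_sides which courts to run the reach battery in; defaults to
#'   both lateral courts.
#' @return object of class \code{experiment_result}: per-subject data.frame
#'   (\code{subject}, \code{delta}, \code{m_hat}, \code{hit_rate},
#'   \code{timing_offset}, one \code{extent_change_*} per reach side) plus
#'   group summaries.
#' @export
run_group_experiment <- function(cohort, params = default_linkage(),
                                 session_min = 6, window_min = 5,
                                 pre_noise_sd = 0.005,
                                 reach_sides = c("LP_R", "LP_L")) {
  geo <- group_geometry(cohort$group)
  set.seed(cohort$seed)
  deltas <- stats::rnorm(cohort$n_subjects, cohort$delta_mean,
                         cohort$delta_sd)
  subject_seeds <- sample.int(2^30, cohort$n_subjects)
  rows <- vector("list", cohort$n_subjects)
  for (i in seq_len(cohort$n_subjects)) {
    row <- list(subject = i, delta = deltas[i], m_hat = NA_real_,
                hit_rate = NA_real_, timing_offset = NA_real_)
    for (side in reach_sides)
      row[[paste0("extent_change_", tolower(side))]] <- NA_real_
    res <- tryCatch({
      config <- pong_config(court_side = geo$court_side,
                            court_centre = geo$court_centre,
                            delay_tau = geo$tau)
      player <- player_model(timing_offset = deltas[i])
      session <- run_pong_session(config, player,
                                  duration = session_min * 60,
                                  seed = subject_seeds[i], params = params)
      est <- session_mass_estimate(params, session, window_min = window_min)
      row$m_hat <- est$m_hat
      row$hit_rate <- nrow(session$hits) / (session_min)
      row$timing_offset <- timing_offset_metric(session,
                                                window_min = window_min)
      set.seed(subject_seeds[i] + 1L)
      for (side in reach_sides) {
        sg <- group_geometry(side)
        post <- reach_battery(params, est$m_hat, sg$targets)
        pre <- reach_battery(params, 0, sg$targets)
        pre_noise <- stats::rnorm(nrow(pre), 0, pre_noise_sd)
        row[[paste0("extent_change_", tolower(side))]] <-
          mean(post$extent_error_m, na.rm = TRUE) -
          mean(pre$extent_error_m + pre_noise, na.rm = TRUE)
      }
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[i]] <- res
  }
  errs <- vapply(rows, function(r) !is.null(r$error), logical(1))
  per_subject <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r[setdiff(names(r), "error")])
  }))
  change_cols <- grep("^extent_change_", names(per_subject), value = TRUE)
  summary <- c(list(group = cohort$group, n = cohort$n_subjects,
                    n_failed = sum(errs),
                    mean_m_hat = mean(per_subject$m_hat, na.rm = TRUE)),
               stats::setNames(lapply(change_cols, function(cn)
                 mean(per_subject[[cn]], na.rm = TRUE)),
                 paste0("mean_", change_cols)))
  structure(list(cohort = cohort, per_subject = per_subject,
                 summary = summary,
                 errors = vapply(rows[errs], `[[`, character(1), "error")),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Group %s (n = %d, %d failed)\n", s$group, s$n, s$n_failed))
  cat(sprintf("  mean mass modifier: %+.3f kg\n", s$mean_m_hat))
  for (cn in grep("^mean_extent_change_", names(s), value = TRUE))
    cat(sprintf("  %s: %+.4f m\n", cn, s[[cn]]))
  invisible(x)
}

#' Fraction of variance explained
#'
#' \code{1 - SS_res / SS_tot} with the total sum of squares taken about the
#' observation mean; can be negative for predictors worse than the mean.
#'
#' @param predictions,observations equal-length numeric vectors, n >= 2.
#' @return scalar in (-Inf, 1].
#' @export
variance_explained <- function(predictions, observations) {
  if (length(predictions) != length(observations) || length(observations) < 2)
    stop("need equal-length vectors with n >= 2")
  ss_tot <- sum((observations - mean(observations))^2)
  if (ss_tot == 0) stop("zero total variance in the observations")
  1 - sum((observations - predictions)^2) / ss_tot
}

#' Mean hit-to-peak timing offset of a session
#'
#' Per hit, locates the peak of the smoothed hand speed within half a stroke
#' around the hit and averages the signed lag (positive = hit after the peak,
#' i.e. in the decelerating phase).
#'
#' @param session a \code{pong_session}.
#' @param window_min trailing window (minutes).
#' @param cfg a \code{\link{filter_config}}.
#' @param half_window search half-window around each hit (s).
#' @return mean timing offset (s).
#' @export
timing_offset_metric <- function(session, window_min = 5,
                                 cfg = filter_config(), half_window = 0.4) {
  traj <- session$trajectory
  hits <- session$hits
  t_end <- max(traj$t)
  hits <- hits[hits$t_hit >= max(0, t_end - window_min * 60), , drop = FALSE]
  if (!nrow(hits)) stop("no hits (or strokes) in the window")
  sp <- sqrt(smooth_velocity(traj$vx, cfg)^2 +
               smooth_velocity(traj$vy, cfg)^2)
  dt <- traj$t[2] - traj$t[1]
  offs <- vapply(hits$t_hit, function(th) {
    i0 <- max(1L, as.integer(round((th - half_window) / dt)) + 1L)
    i1 <- min(length(sp), as.integer(round((th + half_window) / dt)) + 1L)
    th - traj$t[i0 + which.max(sp[i0:i1]) - 1L]
  }, numeric(1))
  mean(offs)
}

#' Mean visuomotor gain of a session
#'
#' Per hit, the ratio of the path length travelled by the arm to that of the
#' (delayed) visual paddle, from movement initiation to contact; initiation is
#' the last upward crossing of 5% of the stroke's peak speed before the peak.
#' Hits with zero visual-paddle displacement are skipped.
#'
#' @param session a \code{pong_session}.
#' @param window_min trailing window (minutes).
#' @param cfg a \code{\link{filter_config}}.
#' @param init_frac initiation threshold as a fraction of peak stroke speed.
#' @return mean gain (dimensionless).
#' @export
visuomotor_gain <- function(session, window_min = 5, cfg = filter_config(),
                            init_frac = 0.05) {
  traj <- session$trajectory
  hits <- session$hits
  t_end <- max(traj$t)
  hits <- hits[hits$t_hit >= max(0, t_end - window_min * 60), , drop = FALSE]
  if (!nrow(hits)) stop("no hits in the window")
  sp <- sqrt(smooth_velocity(traj$vx, cfg)^2 +
               smooth_velocity(traj$vy, cfg)^2)
  dt <- traj$t[2] - traj$t[1]
  gains <- vapply(hits$t_hit, function(th) {
    ih <- min(length(sp), as.integer(round(th / dt)) + 1L)
    i0s <- max(1L, ih - as.integer(round(0.8 / dt)))
    ipk <- i0s + which.max(sp[i0s:ih]) - 1L
    thr <- init_frac * sp[ipk]
    # movement initiation: last sub-threshold sample before the peak,
    # searched backward past the window start if needed
    i0b <- max(1L, ipk - as.integer(round(2 / dt)))
    below <- which(sp[i0b:ipk] <= thr)
    if (!length(below)) return(NA_real_)
    i_init <- i0b + max(below) - 1L
    idx <- i_init:ih
    arm <- sum(sqrt(diff(traj$x[idx])^2 + diff(traj$y[idx])^2))
    vis <- sum(sqrt(diff(traj$xv[idx])^2 + diff(traj$yv[idx])^2))
    if (vis == 0) return(NA_real_)
    arm / vis
  }, numeric(1))
  gains <- gains[is.finite(gains)]
  if (!length(gains)) stop("no usable strokes for the gain metric")
  mean(gains)
}

#' Mean spatial vision-proprioception mismatch at hits
#'
#' Euclidean distance between the true and the delayed paddle position at each
#' hit, averaged over the window.
#'
#' @param session a \code{pong_session}.
#' @param window_min trailing window (minutes).
#' @return mean mismatch (m).
#' @export
spatial_mismatch <- function(session, window_min = 5) {
  traj <- session$trajectory
  hits <- session$hits
  t_end <- max(traj$t)
  hits <- hits[hits$t_hit >= max(0, t_end - window_min * 60), , drop = FALSE]
  if (!nrow(hits)) stop("no hits in the window")
  px <- stats::approx(traj$t, traj$x, xout = hits$t_hit)$y
  py <- stats::approx(traj$t, traj$y, xout = hits$t_hit)$y
  vx <- stats::approx(traj$t, traj$xv, xout = hits$t_hit)$y
  vy <- stats::approx(traj$t, traj$yv, xout = hits$t_hit)$y
  mean(sqrt((px - vx)^2 + (py - vy)^2))
}
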