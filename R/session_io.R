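# Session persistence: JSON header plus two CSV tables.

#' Write / read a pong session
#'
#' A session is persisted as \code{header.json} (config, player, seed,
#' duration, counters) plus \code{trajectory.csv} and \code{hits.csv} (and
#' \code{haptics.csv}) in a directory.
#'
#' @param session a \code{pong_session}.
#' @param dir output directory (created if missing).
#' @return \code{read_session} returns a \code{pong_session}.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- list(
    config = unclass(session$header$config),
    player = unclass(session$header$player),
    seed = session$header$seed,
    duration = session$header$duration,
    hit_counts = session$hit_counts,
    misses = session$misses,
    n_strokes = session$n_strokes
  )
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(session$trajectory, file.path(dir, "trajectory.csv"),
                   row.names = FALSE)
  utils::write.csv(session$hits, file.path(dir, "hits.csv"),
                   row.names = FALSE)
  utils::write.csv(session$haptics, file.path(dir, "haptics.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "header.json"),
                                simplifyVector = TRUE)
  cfg <- header$config
  config <- pong_config(court_side = cfg$court_side,
                        court_centre = cfg$court_centre,
                        court_extent = cfg$court_extent,
                        delay_tau = cfg$delay_tau,
                        restitution = cfg$restitution,
                        paddle_coupling = cfg$paddle_coupling,
                        bounce_noise_halfwidth = cfg$bounce_noise_halfwidth,
                        friction_decay = cfg$friction_decay,
                        haptic_mass = cfg$haptic_mass,
                        haptic_duration = cfg$haptic_duration,
                        sample_rate = cfg$sample_rate,
                        ball_speed_init = cfg$ball_speed_init,
                        paddle_halflength = cfg$paddle_halflength,
                        serve_pause = cfg$serve_pause,
                        home_margin = cfg$home_margin,
                        hit_refractory = cfg$hit_refractory)
  pl <- header$player
  player <- player_model(stroke_amplitude = pl$stroke_amplitude,
                         stroke_duration = pl$stroke_duration,
                         timing_offset = pl$timing_offset,
                         timing_jitter = pl$timing_jitter,
                         amplitude_jitter = pl$amplitude_jitter,
                         adaptation_rate = pl$adaptation_rate)
  structure(list(
    header = list(config = config, player = player, seed = header$seed,
                  duration = header$duration),
    trajectory = utils::read.csv(file.path(dir, "trajectory.csv")),
    hits = utils::read.csv(file.path(dir, "hits.csv")),
    haptics = utils::read.csv(file.path(dir, "haptics.csv")),
    hit_counts = header$hit_counts,
    misses = header$misses,
    n_strokes = header$n_strokes
  ), class = "pong_session")
}
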