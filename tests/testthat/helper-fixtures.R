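# Shared fixtures: parameter sets and samplers used across test files.

# Near point-mass linkage: negligible link masses/inertias, all inertia lumped
# at the handle. In this limit M(q) -> m_e J'J and the effective mass is
# m_e in every direction.
point_mass_linkage <- function(m = 0.8) {
  linkage_params(
    base_separation  = 0.14,
    proximal_lengths = c(0.28, 0.28),
    distal_lengths   = c(0.34, 0.34),
    link_masses      = rep(1e-9, 4),
    link_com_offsets = c(0.14, 0.14, 0.17, 0.17),
    link_inertias    = rep(1e-12, 4),
    endpoint_mass    = m
  )
}

# Random well-conditioned joint configurations, sampled through workspace
# points over the court region.
random_configs <- function(params, n, seed = 1) {
  set.seed(seed)
  out <- matrix(0, n, 2)
  i <- 0
  while (i < n) {
    x <- c(stats::runif(1, -0.3, 0.12), stats::runif(1, 0.16, 0.4))
    q <- tryCatch(inverse_kinematics(params, x), error = function(e) NULL)
    if (is.null(q)) next
    i <- i + 1
    out[i, ] <- q
  }
  out
}

# A small cached lateral session shared by estimation/pipeline tests.
cached_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- pong_config("lateral_right")
      pl <- player_model(timing_offset = 0.03)
      cache <<- run_pong_session(cfg, pl, duration = 150, seed = 421)
    }
    cache
  }
})
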