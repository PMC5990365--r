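#!/usr/bin/env Rscript
# Simulate one example delayed-pong session per experimental group with the
# artificial player and persist the logs (JSON header + CSV tables).

library(eventmass)
dir.create("results/sessions", recursive = TRUE, showWarnings = FALSE)

player <- player_model(timing_offset = 0.03)   # decelerating-phase hitter
for (group in c("FP", "LP_R", "LP_L")) {
  geo <- group_geometry(group)
  config <- pong_config(court_side = geo$court_side,
                        court_centre = geo$court_centre,
                        delay_tau = geo$tau)
  session <- run_pong_session(config, player, duration = 6 * 60,
                              seed = 20260921)
  print(session)
  write_session(session, file.path("results/sessions", group))
}
cat("wrote results/sessions/{FP,LP_R,LP_L}/{header.json,trajectory.csv,hits.csv,haptics.csv}\n")
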