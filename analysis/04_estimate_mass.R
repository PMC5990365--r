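#!/usr/bin/env Rscript
# Estimate the mass modifier from the persisted sessions: per-hit visual and
# proprioceptive effective masses in the trailing five-minute window,
# 10-SD outlier rejection, maximum-likelihood fusion.

library(eventmass)
if (!dir.exists("results/sessions/LP_R"))
  stop("run analysis/03_simulate_sessions.R first")

p <- default_linkage()
rows <- list()
for (group in c("FP", "LP_R", "LP_L")) {
  session <- read_session(file.path("results/sessions", group))
  est <- session_mass_estimate(p, session, window_min = 5)
  cat(sprintf("\n%s (tau = %.0f ms):\n", group,
              1000 * session$header$config$delay_tau))
  print(est)
  rec <- list(group = group,
              m_r = est$m_r,
              mean_mv = mean(est$mv_samples), mean_mp = mean(est$mp_samples),
              sigma_v2 = est$sigma_v2, sigma_p2 = est$sigma_p2,
              w_v = est$w_v, w_p = est$w_p,
              E_m = est$E_m, m_hat = est$m_hat,
              n_hits_retained = est$n_hits_retained,
              n_hits_removed = est$n_hits_removed)
  jsonlite::write_json(rec,
                       file.path("results/sessions", group, "estimate.json"),
                       auto_unbox = TRUE, digits = NA)
  rows[[group]] <- as.data.frame(rec)
}
write.csv(do.call(rbind, rows), "results/mass_estimates.csv",
          row.names = FALSE)
cat("\nwrote results/mass_estimates.csv and per-session estimate.json files\n")
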