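#!/usr/bin/env Rscript
# Simulate the study population: sessions of alternating passive/active
# blocks (P1-A1-P2) with pupil-indexed arousal, state-modulated spiking and
# go/no-go behavior, plus stored ground truth. Session containers go to
# scratch/ (large, regenerable); a small inventory table goes to results/.

library(pupilstate)

seed <- 20260928
n_sites <- 4
cfg <- generative_config(trials_per_block = 15, n_stim = 12,
                         units = list(n = 4))

dir.create("scratch/sessions", showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

pop <- generate_population(n_sites, cfg, seed = seed)
inv <- NULL
for (g in pop) {
  id <- g$session$meta$session_id
  save_session(g$session, file.path("scratch/sessions", id))
  jsonlite::write_json(
    list(effect_types = as.list(g$truth$effect_types),
         params = as.data.frame(g$truth$params), seed = g$truth$seed),
    file.path("scratch/sessions", id, "truth.json"),
    auto_unbox = TRUE, digits = NA)
  rs <- suppressWarnings(extract_reference_responses(g$session))
  inv <- rbind(inv, data.frame(
    session = id, units = nrow(g$session$rate),
    trials = nrow(g$truth$trials),
    presentations = nrow(rs$trial_table),
    included = sum(rs$trial_table$included),
    duration_s = ncol(g$session$rate) / g$session$bin_rate))
}
write.csv(inv, "results/01_sessions.csv", row.names = FALSE)
cat("Simulated", n_sites, "sites;",
    sum(inv$included), "included reference presentations in total.\n")
print(inv)
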