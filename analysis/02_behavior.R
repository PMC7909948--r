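#!/usr/bin/env Rscript
# Score the simulated behavior: hit rate, false-alarm rate and d-prime per
# active block, from the saved session containers alone.

library(pupilstate)

dirs <- list.dirs("scratch/sessions", recursive = FALSE)
stopifnot(length(dirs) > 0)
beh <- NULL
for (d in dirs) {
  beh <- rbind(beh, behavior_summary(load_session(d)))
}
write.csv(beh, "results/02_behavior.csv", row.names = FALSE)
cat("Behavior across", nrow(beh), "active blocks: d' range",
    sprintf("%.2f-%.2f", min(beh$dprime), max(beh$dprime)),
    "- all sessions above the trained criterion (d' > 1):",
    all(beh$dprime > 1), "\n")
print(beh)
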