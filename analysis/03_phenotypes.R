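#!/usr/bin/env Rscript
# Stage 3: derive the eleven vascular phenotypes and the composite vascular
# health index from the raw measurement table and the skin-blood-flow
# traces.

library(telovasc)

raw <- utils::read.csv("results/simdata/vascular_raw.csv")
traces <- utils::read.csv("results/simdata/traces.csv")

ph <- derive_phenotypes(raw, traces)
utils::write.csv(ph, "results/phenotypes.csv", row.names = FALSE)

message(sprintf("Derived phenotypes for %d participants.", nrow(ph)))
summ <- sapply(c("rsh", "cardiac_index", "svri", "stroke_index", "taci",
                 "pwv", "abi", "sbp", "dbp", "map", "pp"),
               function(cl) c(mean = mean(ph[[cl]]), sd = sd(ph[[cl]])))
print(round(t(summ), 2))
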