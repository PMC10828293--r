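#!/usr/bin/env Rscript
# Stage 1: simulate one demonstration cohort with the measured-LTL scenario
# (planted effects on reactive skin hyperemia, cardiac index and SVRI) and
# write every raw input the downstream stages consume.  The demonstration
# uses 300 participants so the written tables stay small; the replicate
# recovery study (06) runs at the full study sample sizes.

library(telovasc)

out_dir <- "results/simdata"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- scenario_measured(n_participants = 300, seed = 42,
                         n_cpgs = 2000, n_causal_cpgs = 8)
gen <- generate_cohort(cfg)
vr <- generate_vascular_raw(gen$cohort, gen$truth, cfg)
# two deterministic QC faults are injected so the quantification stage has
# real exclusions to report: a displaced replicate on two samples and a
# degraded telomere standard curve on one plate
qp <- generate_qpcr_plates(gen$truth$ltl, cfg,
                           sample_ids = gen$cohort$participant_id,
                           plate_ids = as.character(gen$cohort$batch),
                           cv_fault_samples = gen$cohort$participant_id[c(7, 123)],
                           bad_curve_plates = "B07")
me <- generate_methylation(gen$cohort, standardize(gen$truth$ltl), cfg)

wt <- function(x, f, ...) utils::write.table(
  x, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE, ...)
wc <- function(x, f) utils::write.csv(
  x, file.path(out_dir, f), row.names = FALSE, quote = FALSE)

wc(gen$cohort, "cohort.csv")
wt(data.frame(participant_id = rownames(gen$dosages), gen$dosages,
              check.names = FALSE), "dosages.tsv")
wt(gen$weights, "weights.tsv")
wt(qp$plates, "qpcr_plates.tsv")
wc(vr$raw, "vascular_raw.csv")
wc(vr$traces, "traces.csv")
wt(data.frame(cpg = rownames(me$beta), me$beta, check.names = FALSE),
   "methylation.tsv")
wt(me$cpg_map, "cpg_map.tsv")
jsonlite::write_json(
  list(planted_effects = cfg$planted_effects,
       prs_to_ltl = cfg$prs_to_ltl,
       causal_cpgs = me$causal,
       true_ltl = gen$truth$ltl,
       configured_ts = as.list(stats::setNames(qp$configured_ts,
                                               gen$cohort$participant_id))),
  file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)

message(sprintf(
  "Simulated %d participants: %d variants, %d qPCR wells, %d CpGs.",
  nrow(gen$cohort), ncol(gen$dosages), nrow(qp$plates), nrow(me$beta)))
message("Mean age ", round(mean(gen$cohort$age), 1), " y; ",
        round(100 * mean(gen$cohort$sex == "woman"), 1), "% women; ",
        "latent LTL SD ", round(sd(gen$truth$ltl), 3), ".")
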