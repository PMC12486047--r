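#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study cohort.
#
# Ten participants, each with a folded two-hemisphere cortical surface,
# a midline sinus carrying a 25 mm stent at a random rostro-caudal
# position, a cued-block (10 s move / 10 s rest x 10) multichannel
# recording with planted high-gamma bursts, an activation map, and the
# clinical covariates. The planted relation ties burst-rate contrast to
# the analytic M1 overlap of the placement.

suppressMessages(library(vascbci))

seed <- 20260929L
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

co <- generate_cohort(10, seed = seed)
write.csv(co$cohort, file.path(out_dir, "cohort_truth.csv"),
          row.names = FALSE)

# persist the shared schedule and the compact per-participant geometry;
# recordings are regenerated from the seed by later stages (deterministic)
write_schedule_json(co$participants[[1]]$schedule,
                    file.path(out_dir, "schedule.json"))
for (p in co$participants) {
  write_vessel_csv(p$vessel, file.path(out_dir, paste0(p$id, "_vessel.csv")))
  write_stent_csv(p$stent, file.path(out_dir, paste0(p$id, "_stent.csv")))
}

cat(sprintf("simulated %d participants (seed %d)\n", nrow(co$cohort), seed))
cat(sprintf("planted M1 overlap range: %.0f%% to %.0f%%\n",
            min(co$cohort$planted_overlap_pct),
            max(co$cohort$planted_overlap_pct)))
cat(sprintf("planted strength range: %.2f to %.2f\n",
            min(co$cohort$planted_strength),
            max(co$cohort$planted_strength)))
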