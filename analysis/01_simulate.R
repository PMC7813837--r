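#!/usr/bin/env Rscript
# Step 1 — generative model of the two-cohort experiment.
#
# Builds the control and L-Dopa-like treated cohorts (vesicle populations
# calibrated to mean quantal charges of 14.3 and 26.6 fC, half-widths of
# 7.33 and 9.15 ms), schedules exocytotic events over two stimulation
# windows of a 4-min session at the per-cell rates implied by the
# reference counts (477 events / 16 cells and 3534 / 63 cells over the
# stimulated epochs of a 14-min session), and writes the ground-truth
# schedules. A small demo recording (2 cells, 30 s) is written in the
# long-CSV container so the on-disk format is exercised end to end.

suppressPackageStartupMessages(library(ampquant))
dir.create("results", showWarnings = FALSE)
seed <- 20260101L

dur <- 240
win <- default_stimulation_windows(dur)

ctrl_cells <- make_cohort(8, 477 / (16 * 720),
                          vesicles = population_from_charge(14.3, 0.08),
                          halfwidth_mean = 7.33, prefix = "ctrl",
                          seed = seed + 1)
trt_cells <- make_cohort(16, 3534 / (63 * 720),
                         vesicles = population_from_charge(26.6, 0.11),
                         halfwidth_mean = 9.15, prefix = "trt",
                         n_channels = 512L, seed = seed + 2)

sch_c <- generate_event_schedule(ctrl_cells, dur, win, seed = seed + 3)
sch_t <- generate_event_schedule(trt_cells, dur, win, seed = seed + 4)
write_schedule(sch_c, "results/schedule_control.csv")
write_schedule(sch_t, "results/schedule_treated.csv")

cell_map <- function(cells) data.frame(
  channel = vapply(cells, `[[`, integer(1), "channel"),
  cell_id = vapply(cells, function(c) as.character(c$cell_id), character(1)))
data.table::fwrite(cell_map(ctrl_cells), "results/cells_control.csv")
data.table::fwrite(cell_map(trt_cells), "results/cells_treated.csv")

cat(sprintf("control: %d cells, %d scheduled events (mean Q %.1f fC)\n",
            length(ctrl_cells), nrow(sch_c), mean(sch_c$q_true_fC)))
cat(sprintf("treated: %d cells, %d scheduled events (mean Q %.1f fC)\n",
            length(trt_cells), nrow(sch_t), mean(sch_t$q_true_fC)))

# demo recording through the full measurement chain, small enough for CSV
demo_cells <- make_cohort(2, 0.2, prefix = "demo", seed = seed + 5)
demo_sch <- generate_event_schedule(demo_cells, 30, list(c(0, 25)),
                                    seed = seed + 6)
chans <- vapply(demo_cells, `[[`, integer(1), "channel")
demo <- render_clean_traces(demo_sch, chans, 30, integrate = TRUE)
demo <- add_noise(demo, noise_model(), seed = seed + 7)
write_recording(demo, "results/demo_recording.csv")
cat(sprintf("demo recording: %d channels x %d samples -> results/demo_recording.csv\n",
            nrow(demo$traces), ncol(demo$traces)))
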