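#!/usr/bin/env Rscript
# Stage 1: simulate the screening campaign's raw data.
#
# Generates the behavioral battery schedule and four 96-well plates (8
# vehicle, 2 lethal-control, 2 hyperactive positive-control and 84
# single-concentration test wells each; 2% of test compounds carry a real
# strobe phenotype), plus a reference-compound dose series used by stage 2.
# Everything downstream reads only the files written here.

suppressMessages(library(strobescreen))

seed <- 20260901L
out <- "results"
dir.create(out, showWarnings = FALSE)

config <- sim_config(n_plates = 4L, rng_seed = seed)
schedule <- gen_battery_schedule(config)
write_schedule(schedule, file.path(out, "schedule.yaml"))

plate_ids <- sprintf("P%03d", 1:4)
maps <- lapply(plate_ids, function(pid) default_plate_map(config, pid,
                                                          hit_fraction = 0.02))
plates <- lapply(seq_along(plate_ids), function(i) {
  gen_plate(config, plate_ids[i], maps[[i]], schedule)
})
write_plate_map(do.call(rbind, maps), file.path(out, "plate_map.csv"))
write_mi_csv(do.call(c, lapply(plates, `[[`, "traces")),
             file.path(out, "mi_traces.csv"))

# reference dose series: hyperactive (endosulfan-like) compound spanning the
# sub-lethal window through toxic collapse, 12 wells per concentration
hyper <- stock_phenotypes()$hyperactive
doses <- c(0.05, 0.1, 0.2, 0.39, 0.78, 3.1, 12.5)
ref <- list(); rows <- list(); k <- 0L
for (d in doses) for (r in 1:12) {
  k <- k + 1L
  tr <- gen_well_trace(schedule, hyper, d, seed = stable_hash(seed, "ref", d, r))
  tr$plate <- "REF"; tr$well <- sprintf("ref_%g_%02d", d, r)
  tr$treatment <- "endosulfan_like"; tr$concentration_um <- d
  ref[[k]] <- tr
}
write_mi_csv(ref, file.path(out, "reference_doses_mi.csv"))

cat("simulated", length(plate_ids), "plates of", config$wells_per_plate,
    "wells and a", length(doses), "x 12 reference dose series\n")
cat("battery:", nrow(schedule), "segments,", schedule_duration(schedule),
    "s at", config$frame_rate_hz, "Hz\n")
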