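#!/usr/bin/env Rscript
# Stage 2: battery-average motion index, lethality calls and the
# reference-compound dose-response curve.
#
# Reads the MI traces written by stage 1, reduces each well to its
# battery-average MI, flags lethality (average < 1) and summarizes the
# endosulfan-like reference series per concentration with t-based 95% CIs,
# showing the hyperactive rise at sub-micromolar doses and the collapse to
# lethality at toxic ones.

suppressMessages(library(strobescreen))
out <- "results"

traces <- read_mi_csv(file.path(out, "mi_traces.csv"))
map <- read_plate_map(file.path(out, "plate_map.csv"))
validate_map_traces(map, traces)
key <- vapply(traces, function(tr) paste(tr$plate, tr$well), "")
traces <- traces[match(paste(map$plate, map$well), key)]

avg <- vapply(traces, battery_average_mi, numeric(1))
battery <- data.frame(plate = map$plate, well = map$well,
                      compound_id = map$compound_id, role = map$role,
                      concentration_um = map$concentration_um,
                      battery_avg_mi = unname(avg),
                      lethal = lethality_flag(unname(avg)))
write.csv(battery, file.path(out, "battery_summary.csv"), row.names = FALSE)

cat("lethality calls by role:\n")
print(table(battery$role, battery$lethal))

ref <- read_mi_csv(file.path(out, "reference_doses_mi.csv"))
ravg <- vapply(ref, battery_average_mi, numeric(1))
rconc <- vapply(ref, function(tr) tr$concentration_um, numeric(1))
dr <- dose_response_summary(ravg, rep("endosulfan_like", length(ravg)), rconc)
write.csv(dr, file.path(out, "reference_dose_response.csv"), row.names = FALSE)

peak <- dr[which.max(dr$mean_mi), ]
cat(sprintf("reference curve peaks at %.2f uM (mean MI %.1f, 95%% CI %.1f-%.1f)\n",
            peak$concentration_um, peak$mean_mi, peak$ci_lo, peak$ci_hi))
cat(sprintf("highest dose mean MI %.2f -> lethal: %s\n",
            dr$mean_mi[nrow(dr)], lethality_flag(max(dr$mean_mi[nrow(dr)], 0))))
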