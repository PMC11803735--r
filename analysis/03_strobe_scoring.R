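#!/usr/bin/env Rscript
# Stage 3: strobe scores and primary hit calling.
#
# Scores every screened well on the blue and green strobe assays (window-max
# average minus pre-strobe baseline), min-max normalizes each channel across
# the batch, and calls primary hits as test wells whose raw blue score is at
# least two solvent-SD above the highest solvent well.

suppressMessages(library(strobescreen))
out <- "results"

traces <- read_mi_csv(file.path(out, "mi_traces.csv"))
map <- read_plate_map(file.path(out, "plate_map.csv"))
schedule <- read_schedule(file.path(out, "schedule.yaml"))
key <- vapply(traces, function(tr) paste(tr$plate, tr$well), "")
traces <- traces[match(paste(map$plate, map$well), key)]

scores <- score_plate(list(traces = traces, map = map, schedule = schedule))
scores$normalized_blue <- normalize_scores(scores$blue_score)
scores$normalized_green <- normalize_scores(scores$green_score)
write.csv(scores, file.path(out, "scores.csv"), row.names = FALSE)

solvent <- scores$blue_score[scores$role == "vehicle"]
pos <- scores$blue_score[scores$role == "positive_control"]
cat(sprintf("solvent blue score: mean %.1f (max %.1f, sd %.1f, n %d)\n",
            mean(solvent), max(solvent), sd(solvent), length(solvent)))
cat(sprintf("positive-control blue score: mean %.1f (n %d)\n",
            mean(pos), length(pos)))

test <- scores[scores$role == "test", ]
hits <- call_hits(setNames(test$blue_score, test$compound_id), solvent)
write.csv(hits, file.path(out, "hits.csv"), row.names = FALSE)
cat(sprintf("threshold %.1f = solvent max %.1f + 2 x sd %.1f\n",
            hits$threshold[1], hits$solvent_max[1], hits$solvent_sd[1]))
cat(sprintf("%d primary hits out of %d test wells (%.2f%%)\n",
            sum(hits$is_hit), nrow(hits), 100 * mean(hits$is_hit)))

# retest: replicate dose series for each hit, scored against fresh vehicle wells
hit_ids <- hits$compound_id[hits$is_hit]
ph <- stock_phenotypes()
wb <- strobe_windows(schedule, "strobe_blue")
bb <- baseline_interval_for(schedule, "strobe_blue")
seed <- 20260901L
veh_scores <- vapply(1:12, function(r) {
  strobe_score(gen_well_trace(schedule, ph$vehicle, 0,
                              seed = stable_hash(seed, "retest_veh", r)), wb, bb)
}, numeric(1))
# dose series spanning the hyperactive window through the toxic cutoff
retest_doses <- c(0.05, 0.1, 0.2, 0.39, 0.78, 1.56, 3.12)
sc <- c(); cmp <- c(); conc <- c()
for (id in hit_ids) for (d in retest_doses) for (r in 1:6) {
  tr <- gen_well_trace(schedule, ph$hyperactive, d,
                       seed = stable_hash(seed, "retest", id, d, r))
  sc <- c(sc, strobe_score(tr, wb, bb)); cmp <- c(cmp, id); conc <- c(conc, d)
}
retest <- retest_dose_summary(sc, cmp, conc, veh_scores)
write.csv(retest, file.path(out, "retest_summary.csv"), row.names = FALSE)
confirmed <- tapply(retest$distinct, retest$compound, any)
cat(sprintf("retest: %d / %d hits distinct from vehicle at >= 1 concentration\n",
            sum(confirmed), length(confirmed)))
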