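#!/usr/bin/env Rscript
# Stage 6: target pharmacology and insect potency.
#
# Part A: voltage-clamp percent block. Simulates untreated control oocytes
# to estimate GABA-response rundown, then 4 oocytes per compound across a
# potency panel; reports rundown-adjusted mean percent block +/- SEM.
# Part B: diet-assay LC50. Simulates the 7-dose (2-16 ug/well), 12-replicate,
# 3-5 larvae/well design with least-affected-individual scoring and fits the
# maximum-likelihood log-logistic LC50 with a profile-likelihood CI.

suppressMessages(library(strobescreen))
out <- "results"
seed <- 20260901L

## A: percent block ------------------------------------------------------
controls <- lapply(1:4, function(i) {
  gen_ephys_trace(500, rundown_frac_per_epoch = 0.1, block_frac = 0,
                  noise_sd = 5, seed = stable_hash(seed, "ephys_ctrl", i),
                  oocyte_id = sprintf("ctrl%02d", i), treatment = "none")
})
stopifnot(all(vapply(controls, leak_qc, logical(1))))
rd <- rundown_fraction(controls)
cat(sprintf("rundown from %d untreated oocytes: %.3f\n", length(controls), rd))

panel <- c(full_blocker = 0.95, strong = 0.6, weak = 0.25, inactive = 0)
rows <- lapply(names(panel), function(cmp) {
  blocks <- vapply(1:4, function(i) {
    tr <- gen_ephys_trace(500, 0.1, panel[[cmp]], noise_sd = 5,
                          seed = stable_hash(seed, "ephys", cmp, i),
                          oocyte_id = sprintf("%s_oo%d", cmp, i), treatment = cmp)
    stopifnot(leak_qc(tr))
    percent_block(tr, rd)
  }, numeric(1))
  aggregate_block(blocks, cmp, rundown = rd)
})
block_tab <- do.call(rbind, rows)
write.csv(block_tab, file.path(out, "percent_block.csv"), row.names = FALSE)
cat("rundown-adjusted percent block (mean +/- SEM, n = 4 oocytes):\n")
for (i in seq_len(nrow(block_tab))) {
  cat(sprintf("  %-13s %5.1f +/- %.1f (planted %.0f)\n",
              block_tab$compound_id[i], block_tab$mean_block[i],
              block_tab$sem[i], 100 * panel[[block_tab$compound_id[i]]]))
}

## B: LC50 ---------------------------------------------------------------
doses <- 2 * 8^((0:6) / 6)   # 7 doses spanning 2-16 ug/well
tab <- gen_mortality(doses, lc50 = 8.6, slope = 4, n_reps = 12,
                     larvae_per_well = c(3, 5),
                     seed = stable_hash(seed, "mortality"))
write_mortality(tab, file.path(out, "mortality_table.csv"))
fit <- fit_lc50(read_mortality(file.path(out, "mortality_table.csv")))
write(jsonlite::toJSON(list(lc50_ug_per_well = fit$lc50, slope = fit$slope,
                            ci95 = fit$ci, converged = fit$converged,
                            model = fit$model),
                       auto_unbox = TRUE, digits = NA),
      file.path(out, "lc50_fit.json"))
cat(sprintf("LC50 %.2f ug/well (95%% CI %.2f-%.2f), slope %.2f; planted 8.6\n",
            fit$lc50, fit$ci[1], fit$ci[2], fit$slope))
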