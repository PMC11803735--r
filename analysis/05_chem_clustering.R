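#!/usr/bin/env Rscript
# Stage 5: chemotype triage of primary hits.
#
# Emulates the 35-hit triage: 35 fingerprints planted in 11 chemotype
# clusters, average-linkage clustering on 1 - Tanimoto cut at similarity
# 0.45, and one medoid representative per cluster. Also demonstrates the
# real-SMILES path on a small reference list.

suppressMessages(library(strobescreen))
out <- "results"
seed <- 20260901L

fps <- gen_fingerprints(n_clusters = 11, n_per_cluster = c(rep(4, 2), rep(3, 9)),
                        seed = stable_hash(seed, "chem"))
cat("planted:", length(fps), "fingerprints in 11 chemotypes\n")
assign <- cluster_compounds(fps, threshold = 0.45)
cat("recovered", assign$k, "clusters at Tanimoto threshold 0.45\n")
write.csv(data.frame(compound_id = names(assign$cluster),
                     cluster = unname(assign$cluster),
                     planted = unname(attr(fps, "cluster")[names(assign$cluster)])),
          file.path(out, "hit_clusters.csv"), row.names = FALSE)

reps <- pick_representatives(assign)
write.csv(reps, file.path(out, "cluster_representatives.csv"), row.names = FALSE)
cat("representatives (medoids):",
    paste(reps$compound_id, collapse = ", "), "\n")

# SMILES path: fingerprints for a small reference panel
panel <- data.frame(
  compound_id = c("phenol", "cresol", "ethanol", "octane", "benzene"),
  smiles = c("c1ccccc1O", "Cc1ccccc1O", "CCO", "CCCCCCCC", "c1ccccc1"))
pf <- lapply(seq_len(nrow(panel)), function(i) {
  make_fingerprint(panel$smiles[i], panel$compound_id[i])
})
names(pf) <- panel$compound_id
s <- tanimoto_matrix(pf)
write.csv(round(s, 3), file.path(out, "panel_tanimoto.csv"))
cat(sprintf("phenol vs cresol Tanimoto %.2f; phenol vs octane %.2f\n",
            s["phenol", "cresol"], s["phenol", "octane"]))
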