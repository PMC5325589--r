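#!/usr/bin/env Rscript
# Two-round PCA variable selection over a simulated per-cell feature
# table (colocalization indices, overlaps, object counts/volumes) and the
# two-factor comparison of first-component scores.

suppressMessages(library(lysoquant))
seed <- 1L
set.seed(seed)
dir.create("results", showWarnings = FALSE)

# Simulate 20 cells per marker x condition. ICQ-like variables carry the
# condition effect for two markers; overlap and object variables add
# correlated structure, the rest is noise (54 variables in round 1).
n_per <- 20
design <- expand.grid(marker = c("EEA1", "Lamp2", "Caveolin", "LC3"),
                      condition = c("control", "PQ"))
cells <- design[rep(seq_len(nrow(design)), each = n_per), ]
n <- nrow(cells)
effect <- with(cells, as.numeric(condition == "PQ" &
                                   marker %in% c("EEA1", "Lamp2")))
latent_icq <- 1.6 * effect + rnorm(n, 0, 0.4)
latent_ov <- rnorm(n, 0, 0.6)
feat <- data.frame(matrix(rnorm(n * 43, 0, 1), n, 43))
names(feat) <- paste0("aux", 1:43)
for (k in 1:3) feat[[paste0("icq", k)]] <- latent_icq + rnorm(n, 0, 0.25)
feat$overlap_apod <- latent_icq + rnorm(n, 0, 0.4)
for (k in 1:3) feat[[paste0("rel_overlap", k)]] <- latent_ov + rnorm(n, 0, 0.25)
feat$n_objects_apod <- 0.5 * latent_ov + rnorm(n, 0, 0.7)
feat$vol_objects_apod <- 0.5 * latent_ov + rnorm(n, 0, 0.7)
feat$n_objects_marker <- rnorm(n)
feat$vol_objects_marker <- rnorm(n)

wf <- pca_two_round(feat, n_keep = 11)
cat("round 1:", ncol(feat), "variables;", wf$n_informative,
    "informative components (eigenvalue > 1)\n")
cat("selected variables:\n")
print(wf$selected)
write_output_csv(wf$selected, "results/pca_selected_variables.csv",
                 seed = seed)

res <- component_score_test(wf$component1_score,
                            cells[, c("marker", "condition")])
write_output_csv(res$pairwise, "results/component_score_tests.csv",
                 seed = seed)
cat("\npairwise comparisons on component-1 scores:\n")
print(res$pairwise)
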