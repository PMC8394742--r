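#!/usr/bin/env Rscript
# Stage 3: "fair" 5-fold cross-validated grid search.
#
# Every ADL type is represented in every training partition; falls are test
# only. Each of the five one-class scorers is grid-searched over its
# hyperparameters and the two candidate feature sets; per fold a 2500-point
# threshold sweep yields the ROC, its AUC, and the geometric-mean optimal
# cut-point. Winners (and their per-fold thresholds) are persisted for the
# ensemble and ablation stages.

library(occfall)

seed <- 1L
manifest <- read_manifest("results/data/manifest.csv")
feats_tab <- read.csv("results/features.csv", stringsAsFactors = FALSE)

reports <- lapply(c("autoencoder", "gmm", "ppnn", "ocknn", "ocsvm"),
                  function(kind) {
  rep <- suppressWarnings(
    run_fair_experiment(manifest, kind,
                        feature_sets = list("BCDFGIK", "ABCDEFGHIJKL"),
                        seed = seed, feats = feats_tab))
  print(rep)
  rep
})
names(reports) <- vapply(reports, `[[`, "", "kind")

bundle <- structure(list(seed = seed, k = 5L, n_traces = nrow(manifest),
                         fair = reports), class = "report_bundle")
tab <- render_tables(bundle)$fair
write.csv(tab, "results/table_fair.csv", row.names = FALSE)

winners <- lapply(reports, function(r) {
  w <- r$winner
  list(kind = r$kind, feature_set = paste(w$feature_set, collapse = ""),
       params = w$params, thresholds = w$thresholds, mean_g = w$mean_g,
       mean_sp = w$mean_sp, mean_se = w$mean_se, mean_auc = w$mean_auc)
})
jsonlite::write_json(winners, "results/fair_winners.json",
                     auto_unbox = TRUE, digits = NA)

best <- which.max(vapply(winners, `[[`, 0, "mean_g"))
cat(sprintf("\nBest single model: %s (G = %.4f). Distance-based scorers\n",
            names(reports)[best], winners[[best]]$mean_g))
cat("separate falls from ADLs cleanly when all categories are trained on.\n")
cat("Wrote results/table_fair.csv and results/fair_winners.json\n")
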