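#!/usr/bin/env Rscript
# Stage 4: majority-voting ensemble.
#
# The three model kinds with the highest fair-case geometric mean vote with
# their own per-fold optimal thresholds; a trace is called a fall when at
# least two of the three agree.

library(occfall)

seed <- 1L
manifest <- read_manifest("results/data/manifest.csv")
feats_tab <- read.csv("results/features.csv", stringsAsFactors = FALSE)
winners <- jsonlite::read_json("results/fair_winners.json",
                               simplifyVector = TRUE, simplifyDataFrame = FALSE)

g <- vapply(winners, function(w) w$mean_g, 0)
top3 <- lapply(winners[order(-g)[1:3]], function(w)
  list(kind = w$kind, feature_set = w$feature_set, params = w$params,
       thresholds = unlist(w$thresholds)))
cat("Ensemble members:", paste(vapply(top3, `[[`, "", "kind"),
                               collapse = ", "), "\n")

ens <- run_ensemble(manifest, top3, seed = seed, feats = feats_tab)
tab <- data.frame(Algorithm = sprintf("Majority voting (%s)",
                                      paste(vapply(top3, `[[`, "", "kind"),
                                            collapse = "+")),
                  Se = sprintf("%.4f", ens$mean_se),
                  Sp = sprintf("%.4f", ens$mean_sp),
                  G = sprintf("%.4f ± %.4f", ens$mean_g, ens$sd_g))
write.csv(tab, "results/table_ensemble.csv", row.names = FALSE)

best_single <- max(g)
cat(sprintf("Ensemble G = %.4f vs best single G = %.4f\n",
            ens$mean_g, best_single))
cat("Wrote results/table_ensemble.csv\n")
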