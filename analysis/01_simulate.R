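#!/usr/bin/env Rscript
# Stage 1: simulate the benchmark dataset.
#
# Generates the synthetic study conditions: 20 ADL traces per intensity
# category (basic / standard / sporting) plus 30 falls, five subjects,
# 15 s traces at 100 Hz, written as one CSV per trace plus a manifest.

library(occfall)

seed <- 1L
out <- "results/data"

cfg <- generator_config(seed = seed)
manifest <- generate_dataset(cfg, out)

cat("Generated", nrow(manifest), "traces into", out, "\n")
print(table(manifest$label, manifest$category))
tr <- read_trace(manifest[manifest$label == "FALL", ][1, ], dir = out)
cat(sprintf("Example fall trace: peak SMV %.2f g, minimum SMV %.2f g\n",
            max(smv(tr$samples)), min(smv(tr$samples))))
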