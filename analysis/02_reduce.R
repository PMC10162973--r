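#!/usr/bin/env Rscript
# Stage 2 -- reduce trials to the canonical decoder input.
#
# Each trial is cropped to [-0.5, 0.5) s (kept for the signature analyses)
# and its post-stimulus [0, 0.5) block -- 68 ROIs x 100 samples at 200 Hz --
# becomes the decoder input.

suppressPackageStartupMessages(library(invcnn))

cohort <- readRDS("results/cohort.rds")
reduced <- reduce_cohort(cohort)
saveRDS(reduced, "results/reduced.rds")

d <- dim(reduced[[1]][[1]]$decoder$X)
cat(sprintf("Decoder input per trial: %d ROIs x %d samples\n", d[2], d[3]))
cat(sprintf("Epoch kept for signatures: %d samples spanning [-0.5, 0.5) s\n",
            dim(reduced[[1]][[1]]$epoch$X)[3]))
cat("Wrote results/reduced.rds\n")
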