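#!/usr/bin/env Rscript
# Full-resolution dual-band design (2500 samples, passband criterion 1e-7).
# This is an overnight computation; the test suite and acceptance script
# exercise the 512-sample reduced-resolution version instead.
#
# Usage: Rscript scripts/full_design.R [--out pulse.csv]

suppressPackageStartupMessages(library(mrsat))
args <- commandArgs(trailingOnly = TRUE)
i <- which(args == "--out")
out <- if (length(i) == 1L && i < length(args)) args[i + 1L] else "full_pulse.csv"

spec <- design_spec(max_iterations = 50000L)
res <- design_dual_band_saturation(spec)
write_pulse(res$pulse, out)
str(res$report, max.level = 1)
cat("pulse written to", out, "\n")
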