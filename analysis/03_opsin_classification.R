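#!/usr/bin/env Rscript
# Stage 3: predator visual-system typing. Classify the packaged SWS1
# spectral-tuning windows (sites 84-94) of the eight candidate predator
# species as ultraviolet- or violet-sensitive from the residues at the
# key tuning sites 86 and 90.

suppressPackageStartupMessages(library(mimicolor))
dir.create("results", showWarnings = FALSE)

fixture <- system.file("extdata", "sws1_windows.fasta", package = "mimicolor")
calls <- classify_fasta(fixture)
write_tsv(calls, "results/sws1_calls.tsv")

print(calls, row.names = FALSE)
counts <- attr(calls, "counts")
cat(sprintf("\n%d UVS and %d VS visual systems among %d species\n",
            counts[["UVS"]], counts[["VS"]], nrow(calls)))
cat("UVS species:", paste(calls$species[calls$type == "UVS"], collapse = ", "), "\n")
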