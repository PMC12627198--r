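#!/usr/bin/env Rscript
# Task design: build both 98-trial grids and an example 210-trial session,
# and check the printed design arithmetic (7x9 + 7x5 per domain, 14 blocks
# of 15 trials, 1 catch trial per block).

suppressPackageStartupMessages(library(ambiddm))
dir.create("results", showWarnings = FALSE)

itc <- build_intertemporal_grid()
rsk <- build_risky_grid()
sess <- assemble_session(seed = 1)

cat(sprintf("intertemporal grid: %d trials (%d exact, %d ambiguous)\n",
            nrow(itc), sum(itc$kind == "exact"),
            sum(itc$kind == "ambiguous")))
cat(sprintf("risky grid:         %d trials (%d exact, %d ambiguous)\n",
            nrow(rsk), sum(rsk$kind == "exact"),
            sum(rsk$kind == "ambiguous")))
cat(sprintf("session:            %d trials, %d blocks, %d catch trials\n",
            nrow(sess), length(unique(sess$block)),
            sum(sess$kind == "catch")))

write.csv(sess, "results/example_session.csv", row.names = FALSE)
cat("wrote results/example_session.csv\n")
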