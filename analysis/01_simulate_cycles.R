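#!/usr/bin/env Rscript
# Simulate force-ramp pull-cycle data sets for the sequence panel: the
# bulge-position series (TB-1, TB-2, TB-8), the no-bulge reference, and the
# vacancy-filling peptide condition. One events TSV per scenario.

suppressPackageStartupMessages(library(g4tweezers))
dir.create("results", showWarnings = FALSE)

scenarios <- c("T30695", "TB-1", "TB-2", "TB-8", "TB-1+GRPC")
n_cycles <- 5000
seed <- 7

for (nm in scenarios) {
  sc <- load_scenario(nm)
  cyc <- simulate_cycles(sc$mixture, sc$protocol, sc$polymer, sc$noise,
                         n_cycles, seed = seed)
  path <- file.path("results",
                    paste0("events_", gsub("[^A-Za-z0-9-]", "_", nm), ".tsv"))
  write_events(cyc, path)
  cat(sprintf(
    "%-10s %d cycles: %d ruptures, %d censored, %d never folded -> %s\n",
    nm, n_cycles, sum(cyc$ruptured), sum(cyc$censored),
    sum(!cyc$ruptured & !cyc$censored), path))
}
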