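#!/usr/bin/env Rscript
# Generate the synthetic study cohort: per-molecule DNA-only and
# protein-DNA pulling ramps for the three constructs (wild-type NompC,
# the 12-repeat truncation, the isolated AnkB ARD) plus a constant-force
# clamp ladder, all with ground-truth sidecars. Downstream scripts read
# these files exactly as the lab pipeline would read instrument exports.

library(gatingspring)

seed <- 1
out_dir <- "results/sim"
message("Simulating the cohort into ", out_dir, " (seed ", seed, ")")
files <- fixture_suite(out_dir, seed = seed, n_molecules = 10,
                       clamp_forces = c(5.5, 6.2, 6.9, 7.6, 8.5))
message("Wrote ", length(files), " files: ",
        sum(grepl("\\.tsv$", files)), " traces + ",
        sum(grepl("truth\\.json$", files)), " truth sidecars.")
message("Constructs: wt (truth k = 0.7 pN/nm), d12 (0.26), ankb (0.12); ",
        "clamp ladder at 5.5-8.5 pN with truth F_eq = 6.9 pN, ",
        "swing 4.7 nm.")
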