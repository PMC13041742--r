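#!/usr/bin/env Rscript
# Constant-force gating analysis: read the simulated clamp ladder, fit
# the bimodal extension densities, estimate the equilibrium force by
# log-odds interpolation, and convert the gating work into kBT and
# kcal/mol.

library(gatingspring)
dir.create("results", showWarnings = FALSE)
sim_dir <- "results/sim"
if (!dir.exists(sim_dir)) stop("run analysis/01_simulate_cohort.R first")

clamp_files <- sort(list.files(sim_dir, "^clamp_.*\\.tsv$",
                               full.names = TRUE))
ladder <- do.call(rbind, lapply(clamp_files, function(f) {
  truth <- jsonlite::read_json(sub("\\.tsv$", ".truth.json", f))
  tr <- read_trace(f, mean_force = truth$force)
  occ <- clamp_occupancy(tr)
  data.frame(force_pN = truth$force, occupancy_high = occ$occupancy_high)
}))
print(ladder)
f_eq <- equilibrium_force(ladder)
message(sprintf("equilibrium force: %.2f pN (truth 6.9)", f_eq))

# swing from the trace closest to equilibrium
near <- clamp_files[which.min(abs(ladder$force_pN - f_eq))]
truth <- jsonlite::read_json(sub("\\.tsv$", ".truth.json", near))
fit <- fit_two_gaussians(extension_density(read_trace(near,
                                                      mean_force = truth$force)))
message(sprintf("gating swing: %.2f nm (truth 4.7)", fit$separation_nm))

ge <- gating_energy(f_eq, fit$separation_nm)
message(sprintf("gating energy: %.1f pN nm = %.1f kBT = %.1f kcal/mol",
                ge$energy_pNnm, ge$energy_kBT, ge$energy_kcal_per_mol))
write_report(list(ladder = ladder, F_eq_pN = f_eq,
                  swing = unclass(fit)[c("mu_low", "mu_high",
                                         "separation_nm", "weight_high")],
                  gating_energy = unclass(ge)),
             "results/clamp_report.json", inputs = clamp_files, seed = 1)
message("report in results/clamp_report.json")
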