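#!/usr/bin/env Rscript
# Stage 1: validate the biased-sampling machinery on a known landscape.
#
# Multi-walker metadynamics (8 walkers, hills of 0.1 kcal/mol x 0.1 A every
# 200 steps) on a symmetric double well with a 5 kcal/mol barrier, followed
# by free-energy reconstruction and bottleneck-path barrier extraction.
# Ground truth: barrier 5 kcal/mol, basin free-energy difference 0.

library(ribotrim)

dir.create("results", showWarnings = FALSE)
seed <- 101

dw <- make_double_well(barrier = 5, separation = 2)
cfg <- sampler_config(n_walkers = 8, hill_height = 0.1, hill_width = 0.1,
                      pace = 200, steps_per_walker = 60000, seed = seed)
cat("sampling: 8 walkers x 60000 steps (0.5 fs), one hill per walker per 100 fs\n")
run <- run_multiwalker(dw, cfg, initial_s = -1)
cat(sprintf("deposited %d hills\n", n_hills(run$log)))

write_hills(run$log, "results/double_well.hills")

fes_raw <- reconstruct_fes(run$log)
fes_avg <- reconstruct_fes(run$log, average_from = 0.5)
write_fes(fes_avg, "results/double_well_fes.txt")

p <- minimax_path(fes_avg, -1, 1)
iL <- which.min(abs(fes_points(fes_avg)[, 1] + 1))
iR <- which.min(abs(fes_points(fes_avg)[, 1] - 1))
conv <- convergence_check(run$log)

summary <- data.frame(
  quantity = c("barrier_true", "barrier_recovered", "basin_dF_true",
               "basin_dF_recovered", "split_convergence", "n_hills"),
  kcal_per_mol = c(5, p$barrier, 0,
                   abs(fes_avg$values[iL] - fes_avg$values[iR]),
                   conv, n_hills(run$log)))
write.csv(summary, "results/double_well_recovery.csv", row.names = FALSE)
print(summary, row.names = FALSE)
cat(sprintf("\nbarrier recovered to %.2f kcal/mol (truth 5.00); basin dF %.2f (truth 0)\n",
            p$barrier, abs(fes_avg$values[iL] - fes_avg$values[iR])))
cat(sprintf("raw (final-bias) estimator for comparison: %.2f kcal/mol\n",
            minimax_path(fes_raw, -1, 1)$barrier))
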