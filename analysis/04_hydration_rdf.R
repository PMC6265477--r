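#!/usr/bin/env Rscript
# Stage 4: transition-state hydration analysis on synthetic solvation data.
#
# Radial distribution functions and integrated RDFs around a reference atom
# (standing in for a non-bridging phosphate oxygen at the TS), first-shell
# occupancy extraction, and distance time courses with RMSF bands across
# independent replicas.

library(ribotrim)
dir.create("results", showWarnings = FALSE)

# a planted 3-water first shell over a dilute background
shell <- sample_hydration_shell(n_shell = 3, r_shell = 2.8,
                                density_bulk = 0.01, n_frames = 100,
                                seed = 401)
rs <- rdf(shell, r_max = 8, bin_width = 0.1, density_bulk = 0.01)
fs <- first_shell_count(rs)
cat(sprintf("planted shell: first minimum at %.2f A, integrated occupancy %.2f (truth 3)\n",
            fs$r_min_first, fs$count))

# ideal-gas control at water-like number density
gas <- sample_hydration_shell(0, 2.8, density_bulk = 0.0334, n_frames = 200,
                              seed = 402)
rg <- rdf(gas, r_max = 8, bin_width = 0.1, density_bulk = 0.0334)
cat(sprintf("ideal-gas control: mean g(r) over 5-8 A = %.3f (expect 1)\n",
            mean(rg$g[rg$bin_centers >= 5])))

write.csv(data.frame(r = rs$bin_centers, g_shell = rs$g,
                     n_int_shell = rs$n_integrated, g_gas = rg$g,
                     n_int_gas = rg$n_integrated),
          "results/rdf_curves.csv", row.names = FALSE)

# distance time courses over 8 replicas (H-bond style monitoring)
set.seed(403)
traces <- lapply(1:8, function(i) 2.7 + rnorm(500, sd = 0.12))
tc <- distance_timecourse(traces)
cat(sprintf("time course: mean distance %.2f A, RMSF %.3f A over %d replicas\n",
            mean(tc$mean_trace), mean(tc$rmsf_trace), tc$n_trajectories))
write.csv(data.frame(frame = seq_along(tc$mean_trace), mean = tc$mean_trace,
                     rmsf = tc$rmsf_trace),
          "results/distance_timecourse.csv", row.names = FALSE)
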