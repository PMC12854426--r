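#!/usr/bin/env Rscript
# Stage 3 — internal validation of the fitted model: goodness-of-fit
# residuals, prediction-corrected visual predictive check, and a
# nonparametric bootstrap (demonstration size; scale n_boot up for
# production confidence intervals).
#
# Needs: results/dataset.csv (stage 1)
# Emits: results/gof.csv, results/vpc.csv, results/bootstrap.csv

library(pzapk)

n_boot <- 20L
seed <- 20260103L

ds <- apply_blloq_policy(read_nm_csv("results/dataset.csv"))
model <- pza_model()
f <- fit(model, ds, se = FALSE)

g <- gof_table(f$model, f, ds)
write.csv(g, "results/gof.csv", row.names = FALSE)
cat(sprintf(
  "GOF: mean CWRES %.3f, SD %.3f over %d observations\n",
  mean(g$CWRES), sd(g$CWRES), nrow(g)
))

v <- pc_vpc(f$model, ds, n_sim = 500, seed = seed)
write.csv(v$all, "results/vpc.csv", row.names = FALSE)
inside <- with(v$all, mean(obs_p50 >= sim_p50_lo & obs_p50 <= sim_p50_hi))
cat(sprintf(
  "pc-VPC: observed median inside its simulated 90%% band in %.0f%% of bins\n",
  100 * inside
))

# demonstration scale; the slightly looser outer tolerance is ample for
# percentile intervals (scale n_boot up for production CIs)
bs <- bootstrap(f$model, ds,
  n_resamples = n_boot, seed = seed + 1L,
  control = list(rel.tol = 1e-6)
)
write.csv(bs$summary, "results/bootstrap.csv", row.names = FALSE)
cat(sprintf("bootstrap: %d/%d replicates converged\n", n_boot - bs$n_failed, n_boot))
print(bs$summary, row.names = FALSE)
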