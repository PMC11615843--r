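#!/usr/bin/env Rscript
# Fit cumulative dwell-time distributions: phase-count comparison by AICc,
# rate and amplitude estimates with CIs, and the two amplitude corrections
# that convert observed event fractions into molecule fractions.

library(smatpase)

seed <- 404
dir.create("results", showWarnings = FALSE)
model <- reference_two_motor_model()

dw <- simulate_dwells(model, 1e4, seed = seed)
cd <- cumulative_distribution(dw)
fits <- lapply(1:3, function(m) fit_multiexp(cd, m))
cmp <- compare_models(fits)
utils::write.csv(cmp, "results/04_model_comparison.csv", row.names = FALSE)
sel <- fits[[which(cmp$selected)]]
write_fit_json(sel, "results/04_fit.json")
utils::write.csv(
  data.frame(t = cd$t, count = cd$count,
             fitted = sel$scale * as.vector(
               exp(-outer(cd$t, sel$phases$rate)) %*% sel$phases$amplitude)),
  "results/04_cumulative_curve.csv", row.names = FALSE)

cat(sprintf("selected %d phases (mixture-likelihood AICc)\n",
            cmp$n_phases[cmp$selected]))
print(sel)

eq1 <- correct_amplitudes_eq1(sel)
cyc <- cycle_corrected_fractions(sel, k_on = c(0.005, 0.0025), hot_conc = 5)
utils::write.csv(cbind(eq1, molecule_fraction = cyc$molecule_fraction),
                 "results/04_amplitude_corrections.csv", row.names = FALSE)
cat("\nobserved event fractions vs corrected molecule fractions:\n")
print(data.frame(rate = round(sel$phases$rate, 3),
                 observed = round(eq1$observed, 3),
                 dwell_weighted = round(eq1$corrected, 3),
                 cycle_corrected = round(cyc$molecule_fraction, 3)))
cat("\nthe dwell-weighted (lower-bound) correction under-counts the fast\n")
cat("class when binding limits the event rate; the cycle-time correction\n")
cat("recovers the one-molecule-per-class composition.\n")
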