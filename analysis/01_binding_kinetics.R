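#!/usr/bin/env Rscript
# Force-dependent binding and unbinding kinetics of full-length vinculin on
# the stretched talin R3 domain.
#
# Simulates magnetic-tweezers-like extension traces of binding/unbinding
# cycles at five forces, detects the ~3 nm contraction steps, extracts bound
# dwells, and refits the Bell-Evans unbinding law; evaluates the biphasic
# binding-rate curve and refits its binding branch; and compares the printed
# closed-form rate separations (full-length vinculin vs the D1 domain).
# Writes tables under results/.

suppressPackageStartupMessages(library(vinkin))
dir.create("results", showWarnings = FALSE)
set.seed(101)

th <- thermal_context()
flv <- bell_evans_params(6.6e-3, 0.72, "force_accelerated")
vd1 <- bell_evans_params(6.8e-6, 0.81, "force_accelerated")
lv <- level_map()

## 1. unbinding kinetics through the full trace pipeline -----------------
forces <- c(10, 12.5, 15, 17.5, 20)
sch <- kinetic_scheme(list(
  list(from = "talin_unfolded", to = "vinculin_weak", law = 0.5),
  list(from = "vinculin_weak", to = "talin_unfolded", law = flv)),
  states = c("talin_unfolded", "vinculin_weak"))

rows <- lapply(forces, function(f) {
  k_true <- bell_evans_rate(flv, f, th)
  dur <- 210 * (1 / k_true + 2) * 1.1
  traj <- simulate_scheme(sch, force_protocol(dur, f),
                          initial_state = "talin_unfolded")
  tr <- render_extension(traj, lv, rate_hz = 25, noise_sd = 0.8)
  dw <- classify_events(detect_steps(tr), lv, tr)
  ok <- !dw$flagged
  est <- mfpt_estimate(dw$dwell_s[ok], dw$censored[ok])
  data.frame(force_pN = f, n_events = sum(ok), rate_true = k_true,
             rate_est = 1 / est$mfpt_s,
             rate_se = est$se_s / est$mfpt_s^2)
})
tab <- do.call(rbind, rows)
fit <- fit_bell_evans(tab$force_pN, tab$rate_est, tab$rate_se,
                      "force_accelerated", th)
write.table(tab, "results/unbinding_rates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Unbinding pipeline at", paste(forces, collapse = "/"), "pN:\n")
print(fit)
cat(sprintf("  truth: k0 = 6.6e-3 /s, x-dagger = 0.72 nm (recovered within %.1f%% / %.1f%%)\n\n",
            100 * abs(fit$params$k0_per_s / 6.6e-3 - 1),
            100 * abs(fit$params$x_dagger_nm / 0.72 - 1)))

## 2. biphasic binding-rate curve and refit ------------------------------
talin <- default_talin_params(th)
bind <- bell_evans_params(0.3, 1.5, "force_suppressed")
model <- binding_model_params(bind, talin, concentration_nM = 20)
fgrid <- seq(2, 30, by = 0.25)
curve <- data.frame(force_pN = fgrid,
                    binding_rate_per_s = binding_rate(model, fgrid, th),
                    unfolding_prob = unfolding_probability(talin, fgrid, th))
write.table(curve, "results/binding_rate_curve.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
f_obs <- seq(4, 24, by = 2)
r_true <- binding_rate(model, f_obs, th)
r_obs <- pmax(r_true * (1 + rnorm(length(f_obs), 0, 0.08)), 0.2 * r_true)
bfit <- fit_biphasic_binding(f_obs, r_obs, se_per_s = 0.08 * r_true,
                             talin = talin, therm = th)
cat(sprintf("Biphasic binding refit (8%% noise): k0 = %.3g /s, x-dagger = %.3g nm; peak near %.1f pN\n\n",
            bfit$params$k0_per_s, bfit$params$x_dagger_nm,
            fgrid[which.max(curve$binding_rate_per_s)]))

## 3. closed-form separations printed by the fits ------------------------
sep <- data.frame(
  quantity = c("log10 k0 ratio (unbinding, FLV/Vd1)",
               "log10 expected-rate ratio at 200 pN (unraveling)",
               "log10 expected-rate ratio at 260 pN (unraveling)",
               "FLV unbinding rate extrapolated to 8.5 pN (1/s)",
               "dissociation constant at 9 pN (nM)"),
  value = c(log10(6.6e-3 / 6.8e-6),
            log10(bell_evans_rate(bell_evans_params(2.6e-7, 0.25,
                                                    "force_accelerated"),
                                  200, th) /
                  bell_evans_rate(bell_evans_params(4.5e-8, 0.23,
                                                    "force_accelerated"),
                                  200, th)),
            log10(bell_evans_rate(bell_evans_params(2.6e-7, 0.25,
                                                    "force_accelerated"),
                                  260, th) /
                  bell_evans_rate(bell_evans_params(4.5e-8, 0.23,
                                                    "force_accelerated"),
                                  260, th)),
            bell_evans_rate(flv, 8.5, th),
            dissociation_constant(model, flv, 9, th)))
write.table(sep, "results/closed_form_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Closed-form summary:\n")
print(sep, row.names = FALSE, digits = 4)
cat("\nNote: the weak-state law extrapolated to 8.5 pN gives ~0.03 1/s; the\n")
cat("hour-long bound times observed there instead reflect the matured state\n")
cat("(see 02_maturation.R), motivating the two-mode binding scheme.\n")
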