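# Shared fixtures: printed fit parameters and small constructors used across
# the suite.

th_ref <- thermal_context()          # 298 K, kT ~ 4.114 pN nm

# tweezers unbinding fits (full-length vinculin and D1 domain)
flv_unbind <- bell_evans_params(6.6e-3, 0.72, "force_accelerated")
vd1_unbind <- bell_evans_params(6.8e-6, 0.81, "force_accelerated")

# expected rates from the constant-force unraveling analysis (inverse MFPT)
flv_md <- bell_evans_params(2.6e-7, 0.25, "force_accelerated")
vd1_md <- bell_evans_params(4.5e-8, 0.23, "force_accelerated")

# two-mode unbinding timescales at the 40 pN probe and maturation timescale
t_weak_ref <- 0.4
t_mature_ref <- 7.4
tau_mat_ref <- 37

# build a bare extension_trace from a numeric vector (for detector tests)
make_trace <- function(x, rate_hz = 100, force = 10) {
  structure(list(time_s = (seq_along(x) - 1) / rate_hz,
                 extension_nm = x,
                 force_pN = rep(force, length(x)),
                 rate_hz = rate_hz,
                 provenance = list(seed = NULL, noise_sd = NA, levels = NULL)),
            class = "extension_trace")
}

# two-state binding/unbinding cycle scheme (talin pinned unfolded)
two_state_scheme <- function(bind_rate, unbind_law) {
  kinetic_scheme(list(
    list(from = "talin_unfolded", to = "vinculin_weak", law = bind_rate),
    list(from = "vinculin_weak", to = "talin_unfolded", law = unbind_law)),
    states = c("talin_unfolded", "vinculin_weak"))
}
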