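test_that("log-linear Bell-Evans fit inverts exact data and is order-invariant", {
  f <- c(5, 10, 15, 20, 25)
  r <- bell_evans_rate(flv_unbind, f, th_ref)
  fit <- fit_bell_evans(f, r, sense = "force_accelerated", therm = th_ref)
  expect_equal(fit$params$k0_per_s, 6.6e-3, tolerance = 1e-10)
  expect_equal(fit$params$x_dagger_nm, 0.72, tolerance = 1e-10)
  # k0 rescaling leaves the distance to the transition state unchanged
  fit2 <- fit_bell_evans(f, 10 * r, sense = "force_accelerated", therm = th_ref)
  expect_equal(fit2$params$x_dagger_nm, fit$params$x_dagger_nm,
               tolerance = 1e-12)
  # reordering of points is irrelevant
  o <- c(3, 1, 5, 2, 4)
  fit3 <- fit_bell_evans(f[o], r[o], sense = "force_accelerated",
                         therm = th_ref)
  expect_equal(fit3$params$x_dagger_nm, fit$params$x_dagger_nm,
               tolerance = 1e-12)
  expect_error(fit_bell_evans(c(5, 10), r[1:2], sense = "force_accelerated"),
               "3 distinct")
  expect_error(fit_bell_evans(f, -r, sense = "force_accelerated"), "positive")
})

test_that("Bell-Evans parameters are recovered from simulated dwell data", {
  # 200 dwells per force drawn from the printed unbinding fit
  forces <- c(10, 12.5, 15, 17.5, 20)
  set.seed(12)
  rates <- se <- numeric(length(forces))
  for (i in seq_along(forces)) {
    k <- bell_evans_rate(flv_unbind, forces[i], th_ref)
    d <- rexp(200, k)
    est <- mfpt_estimate(d)
    rates[i] <- 1 / est$mfpt_s
    se[i] <- est$se_s / est$mfpt_s^2
  }
  fit <- fit_bell_evans(forces, rates, se, "force_accelerated", th_ref)
  expect_equal(fit$params$x_dagger_nm, 0.72, tolerance = 0.10)
  expect_lt(abs(log(fit$params$k0_per_s / 6.6e-3)), log(1.5))
})

test_that("biphasic binding fit recovers the binding branch with talin fixed", {
  talin <- default_talin_params(th_ref)
  bind <- bell_evans_params(0.3, 1.5, "force_suppressed")
  model <- binding_model_params(bind, talin, 20)
  f <- seq(4, 24, by = 2)
  r <- binding_rate(model, f, th_ref)
  fit <- fit_biphasic_binding(f, r, talin = talin, therm = th_ref)
  expect_equal(fit$params$k0_per_s, 0.3, tolerance = 1e-6)
  expect_equal(fit$params$x_dagger_nm, 1.5, tolerance = 1e-6)
  # talin pinned unfolded in truth and fit: reduces to the plain fit
  tal0 <- talin_folding_params(talin$unfold,
                               bell_evans_params(1e-300, 10, "force_suppressed"))
  m0 <- binding_model_params(bind, tal0, 20)
  r0 <- binding_rate(m0, f, th_ref)
  fit0 <- fit_biphasic_binding(f, r0, talin = tal0, therm = th_ref)
  plain <- fit_bell_evans(f, r0, sense = "force_suppressed", therm = th_ref)
  expect_equal(fit0$params$k0_per_s, plain$params$k0_per_s, tolerance = 1e-5)
  expect_equal(fit0$params$x_dagger_nm, plain$params$x_dagger_nm,
               tolerance = 1e-5)
})

test_that("biphasic fit tolerates 10% relative noise across seeded replicates", {
  talin <- default_talin_params(th_ref)
  bind <- bell_evans_params(0.3, 1.5, "force_suppressed")
  model <- binding_model_params(bind, talin, 20)
  f <- seq(4, 24, by = 2)
  r <- binding_rate(model, f, th_ref)
  ok <- 0L
  set.seed(77)
  for (rep in 1:100) {
    rn <- r * (1 + rnorm(length(r), 0, 0.10))
    rn[rn <= 0] <- min(r) * 0.05
    fit <- tryCatch(fit_biphasic_binding(f, rn, se_per_s = 0.1 * r,
                                         talin = talin, therm = th_ref),
                    error = function(e) NULL)
    if (!is.null(fit) &&
        abs(fit$params$k0_per_s / 0.3 - 1) < 0.2 &&
        abs(fit$params$x_dagger_nm / 1.5 - 1) < 0.2) ok <- ok + 1L
  }
  expect_gte(ok, 90L)
})

test_that("log-binned histogram is normalized, peaks at ln t0, and shifts under rescaling", {
  set.seed(14)
  d <- rexp(10000, 1)   # t0 = 1 s, so the peak sits at x = ln(1) = 0
  h <- sqrt_histogram(d, bins_per_decade = 8)
  expect_equal(sum(h$density * h$bin_width), 1, tolerance = 1e-6)
  expect_identical(sum(h$counts), 10000L)
  mode_bin <- which.max(h$density)
  expect_lte(h$breaks[mode_bin], 0)
  expect_gte(h$breaks[mode_bin + 1], 0)
  # analytic mode height g(x0) = exp(-1)
  expect_equal(h$density[mode_bin], exp(-1), tolerance = 0.05)
  # rescaling all dwells by c translates the histogram by ln(c)
  c0 <- 3.7
  h2 <- sqrt_histogram(d * c0, bins_per_decade = 8)
  expect_equal(h2$centers, h$centers + log(c0), tolerance = 1e-9)
  expect_equal(h2$density, h$density, tolerance = 1e-12)
  # normalization is bin-width independent
  h3 <- sqrt_histogram(d, bins_per_decade = 5)
  expect_equal(sum(h3$density * h3$bin_width), 1, tolerance = 1e-6)
  expect_error(sqrt_histogram(d[1:5]), "at least 10")
})

test_that("BIC selects one component for single-exponential dwell samples", {
  n_one <- 0L
  for (s in 1:200) {
    set.seed(1000 + s)
    fit <- fit_dwell_mixture(rexp(150, 1 / 2.5))
    if (fit$k == 1L) n_one <- n_one + 1L
  }
  expect_gte(n_one / 200, 0.95)
})

test_that("two-mode dwell mixtures are identified and the slow mode recovered", {
  d <- sample_dwell_mixture(2000, c(t_weak_ref, t_mature_ref), c(0.6, 0.4),
                            seed = 5)
  fit <- fit_dwell_mixture(d)
  expect_identical(fit$k, 2L)
  expect_equal(fit$timescales_s[2], t_mature_ref, tolerance = 0.2)
  expect_equal(fit$amplitudes[1], 0.6, tolerance = 0.1)
  expect_equal(fit$x0, log(fit$timescales_s))
  # duplicating every dwell leaves the estimates unchanged
  fit2 <- fit_dwell_mixture(c(d$dwell_s, d$dwell_s))
  expect_equal(fit2$timescales_s, fit$timescales_s, tolerance = 1e-6)
  expect_equal(fit2$amplitudes, fit$amplitudes, tolerance = 1e-6)
  # near-identical timescales collapse to a single component
  set.seed(6)
  fit3 <- fit_dwell_mixture(rexp(500, 1))
  expect_identical(fit3$k, 1L)
})

test_that("maturation relaxation fit inverts noiseless curves and obeys its limits", {
  t <- c(2, 5, 10, 20, 40, 80, 150)
  tw <- 0.4; tm <- 7.4; tau <- 37
  y <- tw + (tm - tw) * (1 - exp(-t / tau))
  fit <- fit_maturation(t, y)
  expect_equal(fit$t_w_s, tw, tolerance = 1e-4)
  expect_equal(fit$t_m_s, tm, tolerance = 1e-4)
  expect_equal(fit$tau_mat_s, tau, tolerance = 1e-3)
  # model limits: T(0) = t_w, T(Inf) = t_m
  expect_equal(fit$t_w_s + (fit$t_m_s - fit$t_w_s) * (1 - exp(0)), fit$t_w_s)
  expect_equal(fit$t_w_s + (fit$t_m_s - fit$t_w_s) * 1, fit$t_m_s)
  # the logistic alternative also follows the curve
  fl <- fit_maturation(t, y, model = "logistic")
  expect_gt(fl$t_m_s, fl$t_w_s)
  expect_error(fit_maturation(t[1:3], y[1:3]), "at least 4")
})

test_that("binding probability matches the two-state closed form", {
  # bind rate zero: never bound
  sch0 <- two_state_scheme(0, bell_evans_params(1, 0, "force_accelerated"))
  p0 <- binding_probability(sch0, 10, window_s = 5, n = 50, seed = 1,
                            initial_state = "talin_unfolded")
  expect_identical(p0$probability, 0)
  # no unbinding, fast binding: certain occupancy
  sch1 <- two_state_scheme(5, bell_evans_params(1e-300, 0, "force_accelerated"))
  p1 <- binding_probability(sch1, 10, window_s = 50, n = 50, seed = 2,
                            initial_state = "talin_unfolded")
  expect_identical(p1$probability, 1)
  # two-state occupancy: rB/(rB+rU) (1 - exp(-(rB+rU) t)) within 3 SE
  rB <- 0.5; rU <- 0.3; tw <- 4
  sch2 <- two_state_scheme(rB, bell_evans_params(rU, 0, "force_accelerated"))
  n <- 1500
  p2 <- binding_probability(sch2, 10, window_s = tw, n = n, seed = 3,
                            initial_state = "talin_unfolded")
  p_true <- rB / (rB + rU) * (1 - exp(-(rB + rU) * tw))
  expect_lt(abs(p2$probability - p_true),
            3 * sqrt(p_true * (1 - p_true) / n))
  expect_identical(p2$definition, "at_end")
})
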