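#' Weighted log-linear Bell-Evans fit of rate-versus-force data
#'
#' Fits ln k(F) = ln k0 +/- F x/kT by weighted least squares. When standard
#' errors are supplied, weights are (rate/SE)^2, the delta-method inverse
#' variance of ln(rate). Parameter standard errors come from the fit
#' covariance.
#'
#' @param force_pN Forces in pN (>= 3 distinct values).
#' @param rate_per_s Rates in 1/s (> 0).
#' @param se_per_s Optional standard errors of the rates.
#' @param sense \code{"force_accelerated"} or \code{"force_suppressed"}.
#' @param therm A \code{thermal_context}.
#' @return An object of class \code{bell_evans_fit}: list with \code{params}
#'   (a \code{bell_evans_params}), \code{se} (named: \code{log_k0},
#'   \code{x_dagger_nm}), \code{cov} (of \code{(log_k0, x_dagger)}),
#'   \code{kT_pN_nm}, and the underlying \code{lm} fit.
#' @export
fit_bell_evans <- function(force_pN, rate_per_s, se_per_s = NULL,
                           sense = c("force_accelerated", "force_suppressed"),
                           therm = thermal_context()) {
  sense <- match.arg(sense)
  if (length(unique(force_pN)) < 3L)
    stop("need at least 3 distinct forces")
  if (any(rate_per_s <= 0)) stop("rates must be positive")
  w <- if (is.null(se_per_s)) rep(1, length(rate_per_s)) else {
    if (any(se_per_s <= 0)) stop("standard errors must be positive")
    (rate_per_s / se_per_s)^2
  }
  fit <- stats::lm(log(rate_per_s) ~ force_pN, weights = w)
  co <- stats::coef(fit)
  sgn <- if (sense == "force_accelerated") 1 else -1
  slope <- unname(co[2L])
  if (sgn * slope <= 0)
    stop(sprintf("fitted slope (%.3g) is inconsistent with sense '%s'",
                 slope, sense))
  kT <- therm$kT_pN_nm
  # noiseless inputs trigger the harmless "essentially perfect fit" warning
  V <- suppressWarnings(stats::vcov(fit))
  params <- bell_evans_params(exp(unname(co[1L])), sgn * slope * kT, sense)
  structure(list(params = params,
                 se = c(log_k0 = sqrt(V[1L, 1L]),
                        x_dagger_nm = kT * sqrt(V[2L, 2L])),
                 cov = V, kT_pN_nm = kT, lm = fit),
            class = "bell_evans_fit")
}

#' @export
print.bell_evans_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Bell-Evans fit (%s): k0 = %.3g /s (ln k0 SE %.2g), x-dagger = %.3g nm (SE %.2g), kT = %.4g pN nm\n",
    p$sense, p$k0_per_s, x$se["log_k0"], p$x_dagger_nm,
    x$se["x_dagger_nm"], x$kT_pN_nm))
  invisible(x)
}

#' Fit the biphasic binding-rate model with talin kinetics held fixed
#'
#' Nonlinear least squares of r_B(F) = k0 exp(-F x/kT) P_U(F), where P_U is
#' the talin unfolding probability computed from the supplied (fixed) talin
#' parameters. Because P_U is fixed, ln(r_B/P_U) is linear in force; that
#' linearization provides the starting values, which are then refined by
#' weighted Levenberg-Marquardt on the original scale.
#'
#' @param force_pN Forces in pN (>= 3 points, spanning the rate peak).
#' @param rate_per_s Observed binding rates, 1/s.
#' @param se_per_s Optional standard errors (used as 1/SE^2 weights).
#' @param talin A \code{talin_folding_params}, held fixed.
#' @param therm A \code{thermal_context}.
#' @return A \code{bell_evans_fit}-like object of class
#'   \code{biphasic_binding_fit}: \code{params} (binding branch), \code{se},
#'   \code{talin}, \code{kT_pN_nm}, \code{nls} (the nlsLM fit),
#'   \code{residuals}.
#' @export
fit_biphasic_binding <- function(force_pN, rate_per_s, se_per_s = NULL,
                                 talin, therm = thermal_context()) {
  stopifnot(inherits(talin, "talin_folding_params"))
  if (length(force_pN) < 3L) stop("need at least 3 points")
  if (any(rate_per_s <= 0)) stop("rates must be positive")
  kT <- therm$kT_pN_nm
  pU <- unfolding_probability(talin, force_pN, therm)
  lin <- stats::lm(log(rate_per_s / pU) ~ force_pN)
  start <- list(log_k0 = unname(stats::coef(lin)[1L]),
                x_dagger = max(0, -unname(stats::coef(lin)[2L]) * kT))
  w <- if (is.null(se_per_s)) rep(1, length(rate_per_s)) else 1 / se_per_s^2
  df <- data.frame(F = force_pN, r = rate_per_s, pU = pU)
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ exp(log_k0) * exp(-F * x_dagger / kT) * pU,
                      data = df, start = start, weights = w,
                      lower = c(log_k0 = -Inf, x_dagger = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    res <- rate_per_s - exp(start$log_k0) *
      exp(-force_pN * start$x_dagger / kT) * pU
    stop(sprintf("biphasic fit failed to converge: %s; residuals at start: %s",
                 conditionMessage(fit),
                 paste(signif(res, 3), collapse = ", ")))
  }
  co <- stats::coef(fit)
  V <- tryCatch(suppressWarnings(stats::vcov(fit)),
                error = function(e) matrix(NA, 2, 2))
  structure(list(
    params = bell_evans_params(exp(unname(co["log_k0"])),
                               max(unname(co["x_dagger"]), 0),
                               "force_suppressed"),
    se = c(log_k0 = sqrt(V[1L, 1L]), x_dagger_nm = sqrt(V[2L, 2L])),
    talin = talin, kT_pN_nm = kT, nls = fit,
    residuals = stats::residuals(fit)),
    class = "biphasic_binding_fit")
}

#' Log-binned ("square-root") dwell-time histogram
#'
#' Histograms x = ln(t) with uniform bins in x. For a single-exponential dwell
#' distribution with timescale t0, the transformed density
#' g(x) = exp(x - x0 - exp(x - x0)) peaks at x0 = ln(t0) with height
#' exp(-1), so each kinetic timescale appears as a separate peak. Counts are
#' retained so the conventional square-root count ordinate can be displayed;
#' all computation uses densities.
#'
#' @param dwells A \code{dwell_table} (or numeric vector of dwell times, s).
#' @param bins_per_decade Bins per decade of dwell time (default 8).
#' @return An object of class \code{log_dwell_histogram}: \code{breaks},
#'   \code{centers} (in x = ln t), \code{counts}, \code{density},
#'   \code{bin_width}, \code{n}.
#' @export
sqrt_histogram <- function(dwells, bins_per_decade = 8) {
  t <- .dwell_times(dwells)
  if (length(t) < 10L) stop("need at least 10 uncensored dwells")
  x <- log(t)
  width <- log(10) / bins_per_decade
  # bins anchored on the smallest observation, so rescaling every dwell by c
  # translates the whole histogram by ln(c) exactly
  lo <- min(x) - width / 2
  nb <- max(1L, ceiling((max(x) - lo) / width + 1e-9))
  breaks <- lo + (0:nb) * width
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  structure(list(breaks = breaks,
                 centers = h$mids,
                 counts = h$counts,
                 density = h$counts / (length(x) * width),
                 bin_width = width,
                 n = length(x)),
            class = "log_dwell_histogram")
}

.dwell_times <- function(dwells, allow_censored = FALSE) {
  if (inherits(dwells, "dwell_table") || is.data.frame(dwells)) {
    cen <- if ("censored" %in% names(dwells)) dwells$censored else FALSE
    if (all(cen)) stop("all dwells are censored")
    t <- dwells$dwell_s[!cen]
  } else t <- as.numeric(dwells)
  t <- t[is.finite(t) & t > 0]
  t
}

# EM for a k-component exponential mixture on raw dwell times
.exp_mixture_em <- function(t, k, w0, t0, max_iter = 1000, tol = 1e-10) {
  n <- length(t)
  w <- w0; mu <- t0
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dexp(t, 1 / mu[j]), numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    gamma <- dens / rowsum_d
    ll <- sum(log(rowsum_d))
    nk <- colSums(gamma)
    w <- nk / n
    mu <- colSums(gamma * t) / nk
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(w = w, mu = mu, logLik = ll)
}

#' Maximum-likelihood exponential-mixture fit of dwell times
#'
#' Fits 1- and 2-component exponential mixtures directly to raw (unbinned)
#' dwell times by maximum likelihood (EM for the 2-component model, several
#' quantile-based starts) and selects the model with the lower BIC. The
#' log-binned histogram is a visualization and peak-finding device only; the
#' fit never touches binned data, so results are independent of binning. A
#' 2-component solution whose timescales agree within 5% is collapsed to one
#' component with a note.
#'
#' @param dwells A \code{dwell_table} or numeric vector of dwell times, s.
#' @param k_max Maximum number of components (1 or 2).
#' @return An object of class \code{mixture_fit}: \code{k},
#'   \code{amplitudes} (sum to 1), \code{timescales_s} (ascending),
#'   \code{x0} (= ln timescales, the histogram peak positions),
#'   \code{logLik}, \code{BIC} (named vector over candidate models),
#'   \code{note}.
#' @export
fit_dwell_mixture <- function(dwells, k_max = 2) {
  t <- .dwell_times(dwells)
  n <- length(t)
  if (n < 30L) stop("need at least 30 uncensored dwells")
  stopifnot(k_max %in% c(1, 2))

  mu1 <- mean(t)
  ll1 <- sum(stats::dexp(t, 1 / mu1, log = TRUE))
  bic1 <- -2 * ll1 + 1 * log(n)
  note <- NULL

  best2 <- NULL
  if (k_max == 2) {
    qs <- list(c(0.25, 0.75), c(0.1, 0.9), c(0.5, 0.95))
    for (q in qs) {
      t0 <- stats::quantile(t, q, names = FALSE)
      if (t0[1L] <= 0 || t0[2L] <= t0[1L]) next
      em <- .exp_mixture_em(t, 2L, c(0.5, 0.5), t0)
      if (is.null(best2) || em$logLik > best2$logLik) best2 <- em
    }
  }
  if (!is.null(best2)) {
    bic2 <- -2 * best2$logLik + 3 * log(n)
    ord <- order(best2$mu)
    mu2 <- best2$mu[ord]; w2 <- best2$w[ord]
    degenerate <- abs(mu2[2L] - mu2[1L]) / mu2[2L] < 0.05
    if (degenerate)
      note <- "2-component solution degenerate (timescales within 5%); collapsed to 1 component"
  } else {
    bic2 <- Inf
    degenerate <- FALSE
  }

  use2 <- !degenerate && is.finite(bic2) && bic2 < bic1
  out <- if (use2) {
    list(k = 2L, amplitudes = w2, timescales_s = mu2, x0 = log(mu2),
         logLik = best2$logLik,
         BIC = c(k1 = bic1, k2 = bic2), note = note)
  } else {
    list(k = 1L, amplitudes = 1, timescales_s = mu1, x0 = log(mu1),
         logLik = ll1, BIC = c(k1 = bic1, k2 = bic2), note = note)
  }
  structure(out, class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("exponential mixture fit: k = %d\n", x$k))
  for (i in seq_len(x$k))
    cat(sprintf("  component %d: amplitude %.3f, timescale %.4g s (x0 = %.3f)\n",
                i, x$amplitudes[i], x$timescales_s[i], x$x0[i]))
  cat(sprintf("  logLik %.2f; BIC k1 = %.2f, k2 = %.2f\n",
              x$logLik, x$BIC["k1"], x$BIC["k2"]))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

.maturation_model_y <- function(p, t, model) {
  if (model == "exponential")
    p["t_w"] + (p["t_m"] - p["t_w"]) * (1 - exp(-t / p["tau"]))
  else
    p["t_w"] + (p["t_m"] - p["t_w"]) /
      (1 + exp(-(log(t) - log(p["tau"])) / p["s"]))
}

.maturation_lm_fit <- function(t, y, w, start, model) {
  resid_fn <- function(p) {
    p <- exp(p)  # positivity via log parameterization
    names(p) <- names(start)
    sqrt(w) * (y - .maturation_model_y(p, t, model))
  }
  fit <- minpack.lm::nls.lm(log(unlist(start)), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-13, ptol = 1e-13))
  if (fit$info %in% c(0, 9))
    stop("maturation fit failed to converge: ", fit$message)
  p <- exp(fit$par); names(p) <- names(start)
  # covariance of the natural-scale parameters by the delta method
  V <- tryCatch({
    Vlog <- solve(fit$hessian) * 2 * fit$deviance /
      max(length(y) - length(p), 1L)
    diag(p) %*% Vlog %*% diag(p)
  }, error = function(e) matrix(NA_real_, length(p), length(p)))
  dimnames(V) <- list(names(p), names(p))
  list(par = p, cov = V, deviance = fit$deviance, lm = fit)
}

#' Fit the maturation timescale from unbinding time versus complex lifetime
#'
#' Default model is first-order maturation kinetics, the exponential
#' relaxation T(t) = t_w + (t_m - t_w)(1 - exp(-t/tau)): a complex held for
#' lifetime t has matured with probability 1 - exp(-t/tau), so its mean
#' unbinding time relaxes from the weak value t_w to the mature value t_m.
#' A phenomenological logistic-in-ln(t) form is available via
#' \code{model = "logistic"}. Weighting options, in order of precedence:
#' explicit \code{se_s} (1/SE^2 weights); \code{n_per_point}, which switches
#' on iteratively-reweighted least squares with the variance implied by the
#' fitted two-mode mixture at each lifetime (the recommended scheme when the
#' means come from counted replicates, since empirical per-point SEs are
#' correlated with the means and bias the curve); otherwise unweighted.
#'
#' @param lifetime_s Complex lifetimes, s (>= 4 points spanning the
#'   transition).
#' @param mean_unbind_s Mean unbinding time at each lifetime, s.
#' @param se_s Optional standard errors (1/SE^2 weights).
#' @param n_per_point Optional replicate count per lifetime point (scalar or
#'   vector) enabling model-based reweighting.
#' @param model \code{"exponential"} (mechanistic default) or
#'   \code{"logistic"}.
#' @return An object of class \code{maturation_fit}: \code{t_w_s},
#'   \code{t_m_s}, \code{tau_mat_s}, \code{se} (named), \code{cov},
#'   \code{model}, \code{fit}.
#' @export
fit_maturation <- function(lifetime_s, mean_unbind_s, se_s = NULL,
                           n_per_point = NULL,
                           model = c("exponential", "logistic")) {
  model <- match.arg(model)
  if (length(lifetime_s) < 4L) stop("need at least 4 lifetime points")
  stopifnot(length(lifetime_s) == length(mean_unbind_s),
            all(lifetime_s > 0), all(mean_unbind_s > 0))
  t <- lifetime_s; y <- mean_unbind_s
  start <- list(t_w = max(min(y), 1e-6), t_m = max(y),
                tau = stats::median(t))
  if (model == "logistic") start$s <- 1
  w <- if (!is.null(se_s)) {
    stopifnot(all(se_s > 0))
    1 / se_s^2
  } else rep(1, length(t))
  res <- .maturation_lm_fit(t, y, w, start, model)
  if (is.null(se_s) && !is.null(n_per_point) && model == "exponential") {
    n <- rep_len(n_per_point, length(t))
    for (iter in 1:3) {
      p <- res$par
      frac <- 1 - exp(-t / p["tau"])
      m <- .maturation_model_y(p, t, model)
      # variance of one dwell under the two-mode mixture at this lifetime
      v <- frac * 2 * p["t_m"]^2 + (1 - frac) * 2 * p["t_w"]^2 - m^2
      w <- n / pmax(v, 1e-12)
      res <- .maturation_lm_fit(t, y, w, start, model)
    }
  }
  p <- res$par
  if (p["t_m"] <= p["t_w"])
    stop("maturation fit degenerate: t_m <= t_w at the optimum")
  se <- sqrt(diag(res$cov)); names(se) <- names(p)
  structure(list(t_w_s = unname(p["t_w"]), t_m_s = unname(p["t_m"]),
                 tau_mat_s = unname(p["tau"]), se = se, cov = res$cov,
                 model = model, fit = res$lm),
            class = "maturation_fit")
}

#' @export
print.maturation_fit <- function(x, ...) {
  cat(sprintf(
    "maturation fit (%s): t_w = %.3g s, t_m = %.3g s, tau = %.3g s (SE %.2g)\n",
    x$model, x$t_w_s, x$t_m_s, x$tau_mat_s, x$se["tau"]))
  invisible(x)
}

#' Binding probability over a time window, by replicate simulation
#'
#' Runs seeded replicate simulations of the scheme at a constant force and
#' reports the fraction bound. Two operational definitions are supported:
#' occupancy of a bound state at the end of the window (default) or whether a
#' bound state was ever visited within the window. The definition used is
#' recorded in the output.
#'
#' @param scheme A \code{kinetic_scheme}.
#' @param force_pN Constant force, pN.
#' @param window_s Observation window, s (> 0).
#' @param n Number of replicates.
#' @param seed Optional integer seed.
#' @param definition \code{"at_end"} or \code{"ever"}.
#' @param initial_state Starting state.
#' @param therm A \code{thermal_context}.
#' @return A list: \code{probability}, \code{se} (binomial), \code{n},
#'   \code{definition}, \code{force_pN}, \code{window_s}.
#' @export
binding_probability <- function(scheme, force_pN, window_s = 50, n = 200,
                                seed = NULL,
                                definition = c("at_end", "ever"),
                                initial_state = "talin_folded",
                                therm = thermal_context()) {
  definition <- match.arg(definition)
  stopifnot(window_s > 0, n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  bound_states <- c("vinculin_weak", "vinculin_mature")
  protocol <- force_protocol(window_s, force_pN)
  hits <- 0L
  for (i in seq_len(n)) {
    traj <- simulate_scheme(scheme, protocol, seed = NULL,
                            initial_state = initial_state, therm = therm)
    ok <- if (definition == "at_end")
      traj$state[nrow(traj)] %in% bound_states
    else any(traj$state %in% bound_states)
    if (ok) hits <- hits + 1L
  }
  p <- hits / n
  list(probability = p, se = sqrt(p * (1 - p) / n), n = n,
       definition = definition, force_pN = force_pN, window_s = window_s)
}
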