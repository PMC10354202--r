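#' Kinetic scheme of talin-vinculin binding states
#'
#' Labelled states plus force-dependent transitions. The canonical scheme has
#' four states: \code{talin_folded}, \code{talin_unfolded} (binding sites
#' exposed), \code{vinculin_weak} (initial bound mode) and
#' \code{vinculin_mature} (reinforced bound mode). Each transition carries
#' either a \code{bell_evans_params} rate law or a constant force-independent
#' rate (a bare positive number), as used for the slow weak-to-mature
#' maturation step.
#'
#' @param transitions A list of transitions, each a list with elements
#'   \code{from}, \code{to} (state labels) and \code{law}
#'   (\code{bell_evans_params} or a single positive number).
#' @param states Character vector of state labels.
#' @return An object of class \code{kinetic_scheme}.
#' @seealso [default_scheme()] for the standard four-state scheme.
#' @export
kinetic_scheme <- function(transitions,
                           states = c("talin_folded", "talin_unfolded",
                                      "vinculin_weak", "vinculin_mature")) {
  stopifnot(is.character(states), length(states) >= 1L, !anyDuplicated(states))
  for (tr in transitions) {
    if (!all(c("from", "to", "law") %in% names(tr)))
      stop("each transition needs 'from', 'to' and 'law'")
    if (!tr$from %in% states || !tr$to %in% states)
      stop(sprintf("transition references undeclared state: %s -> %s",
                   tr$from, tr$to))
    if (tr$from == tr$to)
      stop("self-transitions are not allowed")
    ok <- inherits(tr$law, "bell_evans_params") ||
      (is.numeric(tr$law) && length(tr$law) == 1L && is.finite(tr$law) &&
         tr$law >= 0)
    if (!ok) stop("law must be bell_evans_params or a constant rate >= 0")
  }
  structure(list(states = states, transitions = transitions),
            class = "kinetic_scheme")
}

#' Standard four-state binding/maturation scheme
#'
#' Builds the scheme talin_folded <-> talin_unfolded -> vinculin_weak ->
#' vinculin_mature, with unbinding from either bound mode returning to
#' talin_unfolded (the binding site uncoils; talin stays unfolded) and an
#' irreversible, force-independent maturation step.
#'
#' @param bind Binding branch (\code{bell_evans_params}, force-suppressed).
#' @param talin A \code{talin_folding_params}.
#' @param weak_unbind,mature_unbind Unbinding laws for the two bound modes.
#' @param maturation_rate Constant weak-to-mature rate in 1/s (default
#'   1/37, the reinforcement timescale of the wild-type complex).
#' @return A \code{kinetic_scheme}.
#' @export
default_scheme <- function(bind, talin, weak_unbind, mature_unbind,
                           maturation_rate = 1 / 37) {
  kinetic_scheme(list(
    list(from = "talin_folded", to = "talin_unfolded", law = talin$unfold),
    list(from = "talin_unfolded", to = "talin_folded", law = talin$fold),
    list(from = "talin_unfolded", to = "vinculin_weak", law = bind),
    list(from = "vinculin_weak", to = "talin_unfolded", law = weak_unbind),
    list(from = "vinculin_weak", to = "vinculin_mature", law = maturation_rate),
    list(from = "vinculin_mature", to = "talin_unfolded", law = mature_unbind)))
}

#' Scheme calibrated to the 40 pN unbinding modes
#'
#' Convenience constructor for the scheme whose weak and mature unbinding laws
#' reproduce given unbinding timescales at the 40 pN probe force (defaults
#' 0.4 s weak / 7.4 s mature), sharing the measured 0.72 nm transition-state
#' distance, with maturation over \code{tau_mat} seconds.
#'
#' @param t_weak_s,t_mature_s Mean unbinding times at the probe force, s.
#' @param tau_mat_s Maturation timescale, s.
#' @param probe_force Probe force in pN at which the timescales are defined.
#' @param x_dagger_nm Transition-state distance for both unbinding branches.
#' @param bind Optional binding branch; default fast constant-rate binding is
#'   not included -- supply one for full binding/unbinding cycles.
#' @param talin Optional \code{talin_folding_params};
#'   default [default_talin_params()].
#' @param therm A \code{thermal_context}.
#' @return A \code{kinetic_scheme}.
#' @export
calibrated_scheme <- function(t_weak_s = 0.4, t_mature_s = 7.4,
                              tau_mat_s = 37, probe_force = 40,
                              x_dagger_nm = 0.72,
                              bind = bell_evans_params(0.3, 1.5,
                                                       "force_suppressed"),
                              talin = default_talin_params(therm),
                              therm = thermal_context()) {
  kT <- therm$kT_pN_nm
  weak <- bell_evans_params(
    (1 / t_weak_s) * exp(-probe_force * x_dagger_nm / kT),
    x_dagger_nm, "force_accelerated")
  mature <- bell_evans_params(
    (1 / t_mature_s) * exp(-probe_force * x_dagger_nm / kT),
    x_dagger_nm, "force_accelerated")
  default_scheme(bind, talin, weak, mature, maturation_rate = 1 / tau_mat_s)
}

#' Piecewise-constant force protocol
#'
#' @param duration_s Segment durations in s (> 0, finite).
#' @param force_pN Segment forces in pN (>= 0).
#' @return An object of class \code{force_protocol}; a data frame with
#'   columns \code{duration_s}, \code{force_pN}, \code{t_start_s},
#'   \code{t_end_s}.
#' @examples
#' force_protocol(c(30, 5), c(8.5, 40))
#' @export
force_protocol <- function(duration_s, force_pN) {
  stopifnot(length(duration_s) == length(force_pN), length(duration_s) >= 1L,
            is.numeric(duration_s), all(is.finite(duration_s)),
            all(duration_s > 0),
            is.numeric(force_pN), all(is.finite(force_pN)), all(force_pN >= 0))
  ends <- cumsum(duration_s)
  structure(data.frame(duration_s = duration_s, force_pN = force_pN,
                       t_start_s = c(0, ends[-length(ends)]), t_end_s = ends),
            class = c("force_protocol", "data.frame"))
}

#' Force at given times under a protocol
#' @param protocol A \code{force_protocol}.
#' @param t Times in s.
#' @return Forces in pN (times at/past the end take the final force).
#' @export
protocol_force <- function(protocol, t) {
  idx <- findInterval(t, c(0, protocol$t_end_s), rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(protocol)] <- nrow(protocol)
  protocol$force_pN[idx]
}

.law_rate <- function(law, force, therm) {
  if (inherits(law, "bell_evans_params")) bell_evans_rate(law, force, therm)
  else rep_len(law, length(force))
}

.scheme_rate_matrix <- function(scheme, force, therm) {
  # rows: transitions, at a single force
  vapply(scheme$transitions, function(tr) .law_rate(tr$law, force, therm),
         numeric(1))
}

#' Exact stochastic simulation of a kinetic scheme
#'
#' Kinetic Monte Carlo (Gillespie) simulation under a piecewise-constant force
#' protocol. Within a segment, waiting times are exponential with the total
#' exit rate of the current state at the segment force; a segment boundary
#' re-evaluates the rates and redraws the waiting time (valid by
#' memorylessness) without forcing a transition. Seeded runs are reproducible.
#'
#' @param scheme A \code{kinetic_scheme}.
#' @param protocol A \code{force_protocol}.
#' @param seed Integer seed (optional; set for reproducibility).
#' @param initial_state Starting state label.
#' @param therm A \code{thermal_context}.
#' @return An object of class \code{state_trajectory}: a data frame with
#'   columns \code{time_s}, \code{state}, \code{force_pN}; row 1 is the
#'   initial state at t = 0; attribute \code{duration_s} is the protocol
#'   length and \code{protocol} the protocol itself.
#' @export
simulate_scheme <- function(scheme, protocol, seed = NULL,
                            initial_state = "talin_folded",
                            therm = thermal_context()) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(protocol, "force_protocol"))
  if (!initial_state %in% scheme$states) stop("unknown initial state")
  if (!is.null(seed)) set.seed(seed)

  from_lab <- vapply(scheme$transitions, `[[`, "", "from")
  to_lab <- vapply(scheme$transitions, `[[`, "", "to")

  cap <- 1024L
  ev_t <- numeric(cap); ev_s <- character(cap); ev_f <- numeric(cap)
  n_ev <- 1L
  ev_t[1L] <- 0; ev_s[1L] <- initial_state
  ev_f[1L] <- protocol$force_pN[1L]

  state <- initial_state
  t <- 0
  for (seg in seq_len(nrow(protocol))) {
    f <- protocol$force_pN[seg]
    seg_end <- protocol$t_end_s[seg]
    # per-state exit rates at this force, computed once per segment
    rates <- .scheme_rate_matrix(scheme, f, therm)
    repeat {
      out <- which(from_lab == state & rates > 0)
      if (length(out) == 0L) { t <- seg_end; break }
      total <- sum(rates[out])
      dt <- stats::rexp(1L, total)
      if (t + dt >= seg_end) { t <- seg_end; break }
      t <- t + dt
      pick <- if (length(out) == 1L) out else
        out[sample.int(length(out), 1L, prob = rates[out])]
      state <- to_lab[pick]
      n_ev <- n_ev + 1L
      if (n_ev > cap) {
        cap <- cap * 2L
        length(ev_t) <- cap; length(ev_s) <- cap; length(ev_f) <- cap
      }
      ev_t[n_ev] <- t; ev_s[n_ev] <- state; ev_f[n_ev] <- f
    }
  }
  traj <- data.frame(time_s = ev_t[seq_len(n_ev)],
                     state = ev_s[seq_len(n_ev)],
                     force_pN = ev_f[seq_len(n_ev)],
                     stringsAsFactors = FALSE)
  structure(traj, class = c("state_trajectory", "data.frame"),
            duration_s = protocol$t_end_s[nrow(protocol)],
            protocol = protocol, seed = seed)
}

#' Extension level map for rendering trajectories
#'
#' Extension offsets per state relative to the folded-talin baseline. Talin
#' unfolding adds \code{unfolded_gain_nm}; vinculin binding contracts the
#' unfolded polypeptide by \code{contraction_nm} (the coil-to-helix
#' fingerprint, ~3 nm), so both bound states sit at
#' \code{unfolded_gain_nm - contraction_nm}. The 20 nm default unfolded gain
#' is a typical value for the talin rod domain at these forces, not a printed
#' number.
#'
#' @param unfolded_gain_nm Extension gained on talin unfolding, nm.
#' @param contraction_nm Contraction on vinculin binding, nm.
#' @return An object of class \code{level_map}: named numeric offsets.
#' @export
level_map <- function(unfolded_gain_nm = 20, contraction_nm = 3) {
  stopifnot(unfolded_gain_nm > 0, contraction_nm > 0,
            contraction_nm < unfolded_gain_nm)
  structure(c(talin_folded = 0,
              talin_unfolded = unfolded_gain_nm,
              vinculin_weak = unfolded_gain_nm - contraction_nm,
              vinculin_mature = unfolded_gain_nm - contraction_nm),
            contraction_nm = contraction_nm,
            unfolded_gain_nm = unfolded_gain_nm,
            class = "level_map")
}

#' Render a state trajectory as a noisy extension trace
#'
#' Produces a magnetic-tweezers-like record: piecewise-constant extension at
#' each state's level plus i.i.d. Gaussian noise, uniformly sampled.
#'
#' @param traj A \code{state_trajectory}.
#' @param levels A \code{level_map}.
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param noise_sd Gaussian noise standard deviation in nm (>= 0).
#' @param seed Optional integer seed for the noise.
#' @return An object of class \code{extension_trace}: a list with
#'   \code{time_s}, \code{extension_nm}, \code{force_pN}, \code{rate_hz} and
#'   a \code{provenance} list (seed, noise sd, level map).
#' @export
render_extension <- function(traj, levels, rate_hz = 1000, noise_sd = 0.8,
                             seed = NULL) {
  stopifnot(inherits(traj, "state_trajectory"), inherits(levels, "level_map"))
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  duration <- attr(traj, "duration_s")
  n <- ceiling(duration * rate_hz)
  t <- (seq_len(n) - 1L) / rate_hz
  idx <- findInterval(t, traj$time_s)
  idx[idx < 1L] <- 1L
  ext <- unname(levels[traj$state[idx]])
  if (noise_sd > 0) ext <- ext + stats::rnorm(n, 0, noise_sd)
  protocol <- attr(traj, "protocol")
  f <- protocol_force(protocol, t)
  structure(list(time_s = t, extension_nm = ext, force_pN = f,
                 rate_hz = rate_hz,
                 provenance = list(seed = seed, noise_sd = noise_sd,
                                   levels = levels)),
            class = "extension_trace")
}

#' @export
print.extension_trace <- function(x, ...) {
  cat(sprintf("extension trace: %d samples at %g Hz (%.3g s), forces %g-%g pN\n",
              length(x$time_s), x$rate_hz,
              length(x$time_s) / x$rate_hz,
              min(x$force_pN), max(x$force_pN)))
  invisible(x)
}

.scheme_law <- function(scheme, from, to) {
  for (tr in scheme$transitions)
    if (tr$from == from && tr$to == to) return(tr$law)
  NULL
}

#' Simulated hold-and-probe maturation experiment
#'
#' Emulates the protocol used to probe complex maturation: vinculin binds at a
#' low hold force, the complex is held bound for a prescribed lifetime during
#' which the irreversible weak-to-mature step may fire, then a high probe
#' force is applied and the unbinding time recorded. The hold phase tracks
#' maturation only: experimentally, lifetimes are measured on complexes that
#' are still bound when the pulse arrives, so hold-phase unbinding is
#' conditioned out. During the probe the bound modes evolve by the scheme's
#' own rates (late maturation is allowed, rebinding after release is not
#' counted: the record ends at first unbinding).
#'
#' @param scheme A \code{kinetic_scheme} containing the weak/mature unbinding
#'   laws and a constant weak-to-mature maturation rate.
#' @param hold_force Hold force in pN (context only; hold-phase dynamics
#'   reduce to the force-independent maturation step).
#' @param probe_force Probe force in pN.
#' @param lifetimes_s Complex lifetimes at the hold force, s (> 0).
#' @param reps Repetitions per lifetime.
#' @param seed Optional integer seed.
#' @param therm A \code{thermal_context}.
#' @return A \code{dwell_table} data frame: columns \code{state} (bound mode
#'   at probe onset), \code{dwell_s} (probe-force unbinding time),
#'   \code{force_pN}, \code{censored}, \code{lifetime_s}.
#' @export
simulate_maturation_experiment <- function(scheme, hold_force = 8.5,
                                           probe_force = 40, lifetimes_s,
                                           reps = 50, seed = NULL,
                                           therm = thermal_context()) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            all(lifetimes_s > 0), reps >= 1L)
  mat_law <- .scheme_law(scheme, "vinculin_weak", "vinculin_mature")
  if (is.null(mat_law)) stop("scheme has no weak -> mature transition")
  if (inherits(mat_law, "bell_evans_params"))
    mat_hold <- bell_evans_rate(mat_law, hold_force, therm)
  else mat_hold <- mat_law
  weak_law <- .scheme_law(scheme, "vinculin_weak", "talin_unfolded")
  mature_law <- .scheme_law(scheme, "vinculin_mature", "talin_unfolded")
  if (is.null(weak_law) || is.null(mature_law))
    stop("scheme must define unbinding from both bound modes")
  if (!is.null(seed)) set.seed(seed)

  r_weak <- .law_rate(weak_law, probe_force, therm)
  r_mature <- .law_rate(mature_law, probe_force, therm)
  r_mat_probe <- .law_rate(mat_law, probe_force, therm)

  out <- vector("list", length(lifetimes_s))
  for (i in seq_along(lifetimes_s)) {
    lt <- lifetimes_s[i]
    matured <- stats::runif(reps) < 1 - exp(-mat_hold * lt)
    dwell <- numeric(reps)
    for (j in seq_len(reps)) {
      t <- 0
      weak <- !matured[j]
      repeat {
        if (weak) {
          dt <- stats::rexp(1L, r_weak + r_mat_probe)
          t <- t + dt
          if (stats::runif(1L) < r_weak / (r_weak + r_mat_probe)) break
          weak <- FALSE
        } else {
          t <- t + stats::rexp(1L, r_mature)
          break
        }
      }
      dwell[j] <- t
    }
    out[[i]] <- data.frame(
      state = ifelse(matured, "vinculin_mature", "vinculin_weak"),
      dwell_s = dwell, force_pN = probe_force, censored = FALSE,
      lifetime_s = lt, stringsAsFactors = FALSE)
  }
  dt <- do.call(rbind, out)
  class(dt) <- c("dwell_table", "data.frame")
  dt
}

#' Constant-force first-passage traces for a two-level transition
#'
#' Emits extension traces that dwell at a start level and jump to an end level
#' after an exponentially distributed transition time with the Bell-Evans rate
#' at the given force; mimics the unraveling observable whose first-passage
#' time proxies unbinding kinetics. Traces that do not transition within the
#' horizon are emitted censored.
#'
#' @param rate_law A \code{bell_evans_params}.
#' @param start_level,end_level Levels in nm (\code{end_level > start_level}).
#' @param force Constant force in pN.
#' @param rate_hz Sampling rate in Hz.
#' @param noise_sd Gaussian noise sd in nm.
#' @param horizon_s Observation horizon in s.
#' @param n Number of traces.
#' @param seed Optional integer seed.
#' @param therm A \code{thermal_context}.
#' @return A list of \code{extension_trace} objects, each with attributes
#'   \code{transition_s} (NA if censored) and \code{censored}.
#' @export
simulate_fpt_traces <- function(rate_law, start_level, end_level, force,
                                rate_hz = 1000, noise_sd = 0.3, horizon_s = 10,
                                n = 1, seed = NULL,
                                therm = thermal_context()) {
  stopifnot(end_level > start_level, horizon_s > 0, n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  k <- bell_evans_rate(rate_law, force, therm)
  m <- ceiling(horizon_s * rate_hz)
  t <- (seq_len(m) - 1L) / rate_hz
  lapply(seq_len(n), function(i) {
    tt <- if (k > 0) stats::rexp(1L, k) else Inf
    censored <- tt > horizon_s
    ext <- ifelse(t < tt, start_level, end_level)
    if (noise_sd > 0) ext <- ext + stats::rnorm(m, 0, noise_sd)
    structure(list(time_s = t, extension_nm = ext,
                   force_pN = rep(force, m), rate_hz = rate_hz,
                   provenance = list(seed = seed, noise_sd = noise_sd,
                                     levels = NULL)),
              class = "extension_trace",
              transition_s = if (censored) NA_real_ else tt,
              censored = censored)
  })
}

#' Draw dwell times from an exponential mixture
#'
#' Synthetic-data helper for the two-mode unbinding distribution: each dwell
#' is exponential with one of the given timescales, chosen with the given
#' weights.
#'
#' @param n Number of dwells.
#' @param timescales_s Component mean dwell times in s.
#' @param weights Mixture weights (normalised internally).
#' @param seed Optional integer seed.
#' @return A \code{dwell_table} data frame with columns \code{state}
#'   (component index as \code{"mode1"}, \code{"mode2"}, ...), \code{dwell_s},
#'   \code{force_pN} (NA), \code{censored}.
#' @export
sample_dwell_mixture <- function(n, timescales_s = c(0.4, 7.4),
                                 weights = c(0.6, 0.4), seed = NULL) {
  stopifnot(length(timescales_s) == length(weights), all(timescales_s > 0),
            all(weights >= 0), sum(weights) > 0, n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  w <- weights / sum(weights)
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  dwell <- stats::rexp(n, 1 / timescales_s[comp])
  dt <- data.frame(state = paste0("mode", comp), dwell_s = dwell,
                   force_pN = NA_real_, censored = FALSE,
                   stringsAsFactors = FALSE)
  class(dt) <- c("dwell_table", "data.frame")
  dt
}
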