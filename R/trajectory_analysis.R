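# Change-point machinery: exact penalized least-squares partitioning of a
# piecewise-constant signal by optimal partitioning with PELT pruning.
# Returns the change points (last index of each left segment). Minimum
# segment length 2 samples.
.pelt_changepoints <- function(x, penalty, minseg = 2L) {
  n <- length(x)
  S <- c(0, cumsum(x))
  S2 <- c(0, cumsum(x * x))
  Fv <- rep(NA_real_, n + 1L)
  Fv[1L] <- -penalty
  cp_prev <- integer(n + 1L)
  cand <- 0L
  for (t in minseg:n) {
    cs <- cand[cand <= t - minseg]
    len <- t - cs
    cost <- (S2[t + 1L] - S2[cs + 1L]) - (S[t + 1L] - S[cs + 1L])^2 / len
    vals <- Fv[cs + 1L] + cost + penalty
    b <- which.min(vals)
    Fv[t + 1L] <- vals[b]
    cp_prev[t + 1L] <- cs[b]
    keep <- cs[Fv[cs + 1L] + cost <= Fv[t + 1L]]
    cand <- c(keep, cand[cand > t - minseg], t)
  }
  cps <- integer(0)
  t <- n
  while (t > 0L) {
    s <- cp_prev[t + 1L]
    if (s > 0L) cps <- c(s, cps)
    t <- s
  }
  cps
}

#' Detect extension steps by penalized change-point segmentation
#'
#' Fits a piecewise-constant signal by exact penalized least squares (optimal
#' partitioning with PELT pruning): the segmentation minimizes the residual
#' sum of squares plus a penalty per change point (default a BIC-style
#' 2 sigma^2 log N, with sigma estimated robustly from the median absolute
#' deviation of first differences). Steps smaller than \code{min_step_nm} in
#' magnitude are discarded. Deterministic: no randomness is involved.
#'
#' @param trace An \code{extension_trace} (>= 10 samples).
#' @param penalty RSS penalty per change point; default
#'   \code{2 * sigma^2 * log(N)}.
#' @param min_step_nm Minimum absolute step size to report, nm.
#' @return A data frame of class \code{step_events}: columns \code{time_s}
#'   (first sample at the new level), \code{index}, \code{size_nm},
#'   \code{pre_level_nm}, \code{post_level_nm}, \code{score} (RSS gain of the
#'   split).
#' @export
detect_steps <- function(trace, penalty = NULL, min_step_nm = 1.5) {
  stopifnot(inherits(trace, "extension_trace"))
  x <- trace$extension_nm
  n <- length(x)
  if (n < 10L) stop("trace must have at least 10 samples")
  sigma <- stats::mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma <= 0) sigma <- .Machine$double.eps
  if (is.null(penalty)) penalty <- 2 * sigma^2 * log(n)
  cp <- .pelt_changepoints(x, penalty)
  empty <- data.frame(time_s = numeric(0), index = integer(0),
                      size_nm = numeric(0), pre_level_nm = numeric(0),
                      post_level_nm = numeric(0), score = numeric(0))
  class(empty) <- c("step_events", "data.frame")
  if (length(cp) == 0L) return(empty)
  bounds <- c(0L, cp, n)
  seg_len <- diff(bounds)
  means <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(x[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  size <- diff(means)
  # score: local RSS gain of each change point given its two segments
  nA <- seg_len[-length(seg_len)]
  nB <- seg_len[-1L]
  gain <- nA * nB / (nA + nB) * size^2
  keep <- abs(size) >= min_step_nm
  out <- data.frame(time_s = trace$time_s[cp + 1L],
                    index = cp + 1L,
                    size_nm = size,
                    pre_level_nm = means[-length(means)],
                    post_level_nm = means[-1L],
                    score = gain)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("step_events", "data.frame")
  out
}

#' Classify detected steps into binding/unbinding events and dwells
#'
#' Downward steps of about one binding contraction starting from the
#' unfolded-talin level are labelled binding; matching upward steps are
#' labelled unbinding. Intervals between a binding and the next unbinding
#' become bound-state dwells; a trace ending while bound yields a censored
#' final dwell. Inconsistent pairings (two consecutive bindings or an
#' unbinding with no preceding binding) are flagged, never silently dropped.
#'
#' @param steps A \code{step_events} data frame (time-ordered).
#' @param levels The \code{level_map} used for rendering (supplies the
#'   contraction size and unfolded level).
#' @param trace The source \code{extension_trace} (for the observation end
#'   time and per-event force).
#' @param tolerance_nm Allowed deviation of step size and pre/post level from
#'   the nominal contraction geometry, nm.
#' @return A \code{dwell_table} data frame: columns \code{state},
#'   \code{dwell_s}, \code{force_pN} (force at binding), \code{censored},
#'   \code{t_start_s}, \code{t_end_s}, \code{flagged}.
#' @export
classify_events <- function(steps, levels, trace, tolerance_nm = 1.0) {
  stopifnot(inherits(levels, "level_map"), inherits(trace, "extension_trace"))
  if (is.unsorted(steps$time_s)) stop("steps must be time-ordered")
  contraction <- attr(levels, "contraction_nm")
  unfolded <- unname(levels["talin_unfolded"])
  end_time <- trace$time_s[length(trace$time_s)] + 1 / trace$rate_hz

  is_bind <- abs(steps$size_nm + contraction) <= tolerance_nm &
    abs(steps$pre_level_nm - unfolded) <= tolerance_nm
  is_unbind <- abs(steps$size_nm - contraction) <= tolerance_nm &
    abs(steps$post_level_nm - unfolded) <= tolerance_nm

  rec <- list()
  bound_since <- NA_real_
  bound_force <- NA_real_
  for (i in seq_len(nrow(steps))) {
    if (is_bind[i]) {
      if (!is.na(bound_since)) {
        # two consecutive bindings: close previous dwell, flag it
        rec[[length(rec) + 1L]] <- data.frame(
          state = "vinculin_bound", dwell_s = steps$time_s[i] - bound_since,
          force_pN = bound_force, censored = FALSE,
          t_start_s = bound_since, t_end_s = steps$time_s[i], flagged = TRUE)
      }
      bound_since <- steps$time_s[i]
      bound_force <- trace$force_pN[steps$index[i]]
    } else if (is_unbind[i]) {
      if (is.na(bound_since)) {
        rec[[length(rec) + 1L]] <- data.frame(
          state = "vinculin_bound", dwell_s = NA_real_,
          force_pN = trace$force_pN[steps$index[i]], censored = FALSE,
          t_start_s = NA_real_, t_end_s = steps$time_s[i], flagged = TRUE)
      } else {
        rec[[length(rec) + 1L]] <- data.frame(
          state = "vinculin_bound", dwell_s = steps$time_s[i] - bound_since,
          force_pN = bound_force, censored = FALSE,
          t_start_s = bound_since, t_end_s = steps$time_s[i], flagged = FALSE)
        bound_since <- NA_real_
      }
    }
  }
  if (!is.na(bound_since)) {
    rec[[length(rec) + 1L]] <- data.frame(
      state = "vinculin_bound", dwell_s = end_time - bound_since,
      force_pN = bound_force, censored = TRUE,
      t_start_s = bound_since, t_end_s = end_time, flagged = FALSE)
  }
  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(state = character(0), dwell_s = numeric(0),
               force_pN = numeric(0), censored = logical(0),
               t_start_s = numeric(0), t_end_s = numeric(0),
               flagged = logical(0))
  rownames(out) <- NULL
  class(out) <- c("dwell_table", "data.frame")
  out
}

#' First-passage time of an extension trace across a level
#'
#' Boxcar-smooths the signal, requires it to start below
#' \code{start_level + hysteresis}, and reports the first time it crosses
#' \code{end_level - hysteresis}. Censored (at the trace end) if the level is
#' never reached.
#'
#' @param trace An \code{extension_trace}.
#' @param start_level,end_level Levels in nm, \code{end_level > start_level}.
#' @param hysteresis_nm Hysteresis band in nm (>= 0).
#' @param smooth_window Boxcar width in samples (odd; default 5).
#' @return A list with \code{fpt_s} (NA when censored) and \code{censored}.
#' @export
first_passage_time <- function(trace, start_level, end_level,
                               hysteresis_nm = 0.3, smooth_window = 5L) {
  stopifnot(inherits(trace, "extension_trace"), end_level > start_level,
            hysteresis_nm >= 0)
  x <- trace$extension_nm
  if (smooth_window > 1L) {
    sm <- as.numeric(stats::filter(x, rep(1 / smooth_window, smooth_window),
                                   sides = 2))
    # partial windows at the edges instead of NA
    half <- smooth_window %/% 2L
    n <- length(x)
    for (i in which(is.na(sm)))
      sm[i] <- mean(x[max(1L, i - half):min(n, i + half)])
  } else sm <- x
  if (sm[1L] >= end_level - hysteresis_nm)
    stop("trace starts above the end threshold: invalid start state")
  if (sm[1L] > start_level + hysteresis_nm)
    stop("trace does not start at the start level")
  hit <- which(sm >= end_level - hysteresis_nm)
  if (length(hit) == 0L) return(list(fpt_s = NA_real_, censored = TRUE))
  list(fpt_s = trace$time_s[hit[1L]], censored = FALSE)
}

#' Censoring-aware mean first-passage time
#'
#' Exponential maximum-likelihood estimate under right censoring:
#' MFPT = (sum of all observed times, censored included) / (number of
#' uncensored events); SE = MFPT / sqrt(n_uncensored).
#'
#' @param times_s Observed times (first-passage or dwell), s.
#' @param censored Logical vector; censored entries contribute their
#'   observation horizon to the numerator only.
#' @return A list with \code{mfpt_s}, \code{se_s}, \code{n_uncensored},
#'   \code{n_censored}.
#' @export
mfpt_estimate <- function(times_s, censored = rep(FALSE, length(times_s))) {
  stopifnot(length(times_s) == length(censored), all(times_s > 0 | censored))
  n_unc <- sum(!censored)
  if (n_unc == 0L) stop("all observations censored: MFPT undefined")
  mfpt <- sum(times_s) / n_unc
  list(mfpt_s = mfpt, se_s = mfpt / sqrt(n_unc),
       n_uncensored = n_unc, n_censored = sum(censored))
}
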