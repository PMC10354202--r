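#' Synthetic actin filament field with known bundle fraction
#'
#' Renders randomly placed line segments on a 16-bit raster: single filaments
#' at the configured intensity, bundles at twice that intensity (two
#' filaments overlapping), over a flat background, with Poisson shot noise.
#' Returns the per-pixel ground-truth labels alongside the image.
#'
#' @param n_filaments Number of filaments.
#' @param bundle_fraction Fraction of filaments rendered as bundles, in
#'   [0, 1].
#' @param intensity Mean single-filament intensity above background (counts).
#' @param background Background level (counts).
#' @param noise \code{"poisson"} for shot noise or \code{"none"}.
#' @param dim Image dimensions (pixels).
#' @param seed Optional integer seed.
#' @return A list: \code{image} (numeric matrix, 16-bit range),
#'   \code{truth} (integer matrix: 0 background, 1 single filament,
#'   2 bundle), \code{bundle_fraction}, \code{intensity}.
#' @export
synthetic_filament_image <- function(n_filaments = 20, bundle_fraction = 0.25,
                                     intensity = 3000, background = 200,
                                     noise = c("poisson", "none"),
                                     dim = c(192L, 192L), seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(bundle_fraction >= 0, bundle_fraction <= 1, n_filaments >= 1L,
            intensity > 0)
  if (!is.null(seed)) set.seed(seed)
  count <- matrix(0L, dim[1L], dim[2L])
  occupied <- matrix(FALSE, dim[1L], dim[2L])  # filaments + 1 px margin
  n_bundle <- round(n_filaments * bundle_fraction)
  is_bundle <- seq_len(n_filaments) <= n_bundle
  for (i in seq_len(n_filaments)) {
    # rejection-sample non-overlapping placements so single-filament and
    # bundle intensities stay unambiguous
    for (try in 1:200) {
      p0 <- c(stats::runif(1, 10, dim[1L] - 10),
              stats::runif(1, 10, dim[2L] - 10))
      ang <- stats::runif(1, 0, pi)
      len <- stats::runif(1, 40, 90)
      p1 <- p0 + len * c(cos(ang), sin(ang))
      npt <- ceiling(2 * len)
      rr <- pmin(pmax(round(seq(p0[1L], p1[1L], length.out = npt)), 1L),
                 dim[1L])
      cc <- pmin(pmax(round(seq(p0[2L], p1[2L], length.out = npt)), 1L),
                 dim[2L])
      idx <- unique(cbind(rr, cc))
      if (!any(occupied[idx])) break
    }
    count[idx] <- count[idx] + if (is_bundle[i]) 2L else 1L
    for (dr in -1:1) for (dc in -1:1) {
      sh <- cbind(pmin(pmax(idx[, 1L] + dr, 1L), dim[1L]),
                  pmin(pmax(idx[, 2L] + dc, 1L), dim[2L]))
      occupied[sh] <- TRUE
    }
  }
  img <- background + count * intensity
  truth <- matrix(0L, dim[1L], dim[2L])
  truth[count == 1L] <- 1L
  truth[count >= 2L] <- 2L
  if (noise == "poisson") {
    img[] <- stats::rpois(length(img), lambda = img)
  }
  img[img > 65535] <- 65535
  list(image = img, truth = truth, bundle_fraction = bundle_fraction,
       intensity = intensity)
}

# Rolling-ball-style background: grayscale opening with a square structuring
# window (separable running min then running max), removing structures
# thinner than the radius. Sliding extrema by the doubling trick, O(log w)
# vectorized passes; windows truncate at the image edge.
.shift_rows <- function(M, k, fill) {
  n <- nrow(M)
  if (k == 0L) return(M)
  pad <- matrix(fill, abs(k), ncol(M))
  if (k > 0L) rbind(M[(k + 1L):n, , drop = FALSE], pad)
  else rbind(pad, M[seq_len(n + k), , drop = FALSE])
}

.roll_rows <- function(M, w, op, fill) {
  # centred extreme over rows (i-half)..(i+half), windows truncated at the
  # edges; pad with the op's identity, run the left-anchored doubling pass,
  # crop back
  half <- w %/% 2L
  P <- rbind(matrix(fill, half, ncol(M)), M,
             matrix(fill, w - 1L - half, ncol(M)))
  len <- 1L
  while (len < w) {
    sh <- min(len, w - len)
    P <- op(P, .shift_rows(P, sh, fill))
    len <- len + sh
  }
  P[seq_len(nrow(M)), , drop = FALSE]
}

.gray_extreme <- function(img, w, op, fill) {
  t(.roll_rows(t(.roll_rows(img, w, op, fill)), w, op, fill))
}

.gray_open <- function(img, radius) {
  w <- 2L * as.integer(radius) + 1L
  er <- .gray_extreme(img, w, pmin, Inf)
  .gray_extreme(er, w, pmax, -Inf)
}

#' Bundled-to-total actin pixel ratio
#'
#' Implements the bundle quantification used on TIRF images of actin
#' polymerization: subtract a smooth background (grayscale-opening analogue
#' of a rolling ball), bin gray values at 256 levels over the 16-bit range,
#' classify filament pixels by intensity against a single-filament
#' calibration, and report bundled pixels over all filament pixels. Pixels
#' brighter than \code{threshold_factor} times the mean single-filament
#' intensity count as bundled; pixels between half the calibration minimum
#' and the threshold count as single filaments.
#'
#' @param image Numeric matrix in the 16-bit range (0-65535).
#' @param single_filament_calibration Length-2 numeric, (min, max) intensity
#'   of single actin filaments after background subtraction.
#' @param threshold_factor Bundle threshold as a multiple of the mean
#'   single-filament intensity (default 1.5).
#' @param background_radius Structuring radius (pixels) for background
#'   subtraction; 0 or \code{subtract_background = FALSE} disables it.
#' @param subtract_background Apply the background step first (default TRUE).
#' @return Bundle ratio in [0, 1], with attributes \code{n_bundled} and
#'   \code{n_single}.
#' @export
bundle_ratio <- function(image, single_filament_calibration,
                         threshold_factor = 1.5, background_radius = 50,
                         subtract_background = TRUE) {
  stopifnot(is.matrix(image), length(single_filament_calibration) == 2L)
  cal <- as.numeric(single_filament_calibration)
  if (cal[1L] >= cal[2L]) stop("calibration min must be below max")
  if (subtract_background && background_radius > 0) {
    bg <- .gray_open(image, as.integer(background_radius))
    image <- image - bg
    image[image < 0] <- 0
  }
  bin <- 65535 / 256
  binned <- floor(image / bin) * bin
  single_mean <- mean(cal)
  thr_bundle <- threshold_factor * single_mean
  filament <- binned >= cal[1L] / 2
  bundled <- filament & binned > thr_bundle
  single <- filament & !bundled
  nb <- sum(bundled); ns <- sum(single)
  if (nb + ns == 0L) stop("no filament pixels found: bundle ratio undefined")
  structure(nb / (nb + ns), n_bundled = nb, n_single = ns)
}

#' Four-parameter Hill-Langmuir dose-response fit
#'
#' Fits Y = b + X^HillSlope (a - b) / (X^HillSlope + EC50^HillSlope) to
#' bundle-ratio dose series by weighted nonlinear least squares
#' (Levenberg-Marquardt). EC50, HillSlope and the lower plateau b are free
#' per dataset; the saturation plateau a is shared across all datasets when
#' \code{share_saturation = TRUE} (the configuration used for the bundling
#' dose-response), otherwise free per dataset. Responses are in percent of
#' the filament population (0-100).
#'
#' @param data Data frame with columns \code{dataset}, \code{conc_uM},
#'   \code{response_pct} and optionally \code{se}.
#' @param share_saturation Share the saturation plateau a across datasets.
#' @return An object of class \code{hill_fit}: \code{coefficients} (data
#'   frame per dataset: a, b, HillSlope, EC50_uM, R2, ec50_outside_range),
#'   \code{overall_r2}, \code{shared_saturation}, \code{converged},
#'   \code{fitted}, \code{data}.
#' @export
hill_fit <- function(data, share_saturation = TRUE) {
  need <- c("dataset", "conc_uM", "response_pct")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  if (any(data$conc_uM < 0)) stop("concentrations must be >= 0")
  ds <- unique(as.character(data$dataset))
  nd <- length(ds)
  for (d in ds) {
    sub <- data[data$dataset == d, ]
    if (nrow(sub) < 4L) stop("need >= 4 points per dataset (", d, ")")
    if (length(unique(sub$conc_uM[sub$conc_uM > 0])) < 2L)
      stop("need >= 2 positive concentrations per dataset (", d, ")")
  }
  w <- if ("se" %in% names(data)) 1 / data$se^2 else rep(1, nrow(data))
  di <- match(as.character(data$dataset), ds)
  X <- data$conc_uM
  Y <- data$response_pct

  # parameter vector: [a (1 or nd)], b[nd], h[nd], logEC50[nd]
  n_a <- if (share_saturation) 1L else nd
  unpack <- function(p) {
    a <- p[seq_len(n_a)]
    b <- p[n_a + seq_len(nd)]
    h <- p[n_a + nd + seq_len(nd)]
    lec <- p[n_a + 2L * nd + seq_len(nd)]
    list(a = if (n_a == 1L) rep(a, nd) else a, b = b, h = h,
         ec50 = exp(lec))
  }
  model_y <- function(p) {
    q <- unpack(p)
    a <- q$a[di]; b <- q$b[di]; h <- q$h[di]; ec <- q$ec50[di]
    xh <- ifelse(X > 0, X^h, 0)
    b + xh * (a - b) / (xh + ec^h)
  }
  resid_fn <- function(p) sqrt(w) * (Y - model_y(p))

  start_ec <- vapply(ds, function(d) {
    xx <- data$conc_uM[data$dataset == d & data$conc_uM > 0]
    stats::median(xx)
  }, numeric(1))
  p0 <- c(rep(max(Y), n_a),
          vapply(ds, function(d) min(Y[data$dataset == d]), numeric(1)),
          rep(1, nd), log(start_ec))
  fit <- minpack.lm::nls.lm(p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  if (fit$info %in% c(0, 9))
    stop("Hill fit failed to converge: ", fit$message)
  q <- unpack(fit$par)
  yhat <- model_y(fit$par)

  r2 <- function(obs, pred) {
    ssr <- sum((obs - pred)^2); sst <- sum((obs - mean(obs))^2)
    if (sst == 0) NA_real_ else 1 - ssr / sst
  }
  per <- data.frame(dataset = ds, a = q$a, b = q$b, HillSlope = q$h,
                    EC50_uM = q$ec50,
                    R2 = vapply(seq_len(nd), function(j)
                      r2(Y[di == j], yhat[di == j]), numeric(1)),
                    stringsAsFactors = FALSE)
  per$ec50_outside_range <- vapply(seq_len(nd), function(j) {
    xs <- X[di == j & X > 0]
    q$ec50[j] < min(xs) || q$ec50[j] > max(xs)
  }, logical(1))
  if (any(per$ec50_outside_range))
    warning("EC50 outside the sampled concentration range for: ",
            paste(per$dataset[per$ec50_outside_range], collapse = ", "))
  structure(list(coefficients = per, overall_r2 = r2(Y, yhat),
                 shared_saturation = share_saturation,
                 converged = TRUE, fitted = yhat, data = data),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill-Langmuir fit (%s saturation plateau), overall R2 = %.3f\n",
              if (x$shared_saturation) "shared" else "per-dataset",
              x$overall_r2))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}
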