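#' Segment the cell body by Otsu thresholding
#'
#' Computes the Otsu threshold from the full image histogram (256 levels),
#' keeps the largest connected foreground component as the main cell body,
#' and derives the equivalent cell radius r = sqrt(area / pi).
#'
#' @param actin_image Numeric matrix (any intensity scale; must not be
#'   constant).
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return An object of class \code{cell_mask}: \code{mask} (logical
#'   matrix), \code{pixel_size_um}, \code{area_um2}, \code{r_um},
#'   \code{threshold} (on the input intensity scale).
#' @export
segment_cell <- function(actin_image, pixel_size_um = 0.1) {
  stopifnot(is.matrix(actin_image), is.numeric(actin_image),
            pixel_size_um > 0)
  rng <- range(actin_image)
  if (rng[1L] == rng[2L]) stop("constant image: cannot segment")
  norm <- (actin_image - rng[1L]) / (rng[2L] - rng[1L])
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
  mask <- norm > th
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.integer(labels)
  if (max(lab) == 0L) stop("no foreground found after thresholding")
  areas <- tabulate(lab[lab > 0L])
  main <- which.max(areas)
  cell <- matrix(lab == main, nrow(actin_image), ncol(actin_image))
  area_um2 <- sum(cell) * pixel_size_um^2
  structure(list(mask = cell, pixel_size_um = pixel_size_um,
                 area_um2 = area_um2, r_um = sqrt(area_um2 / pi),
                 threshold = rng[1L] + th * (rng[2L] - rng[1L])),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("cell mask: %d px (%.2f um2), equivalent radius %.2f um\n",
              sum(x$mask), x$area_um2, x$r_um))
  invisible(x)
}

#' Filter labelled adhesions by minimum area
#'
#' Keeps objects strictly larger than \code{min_area_um2} (the
#' focal-adhesion-like size criterion); objects at or below the threshold are
#' removed.
#'
#' @param label_mask Integer matrix of non-negative labels (0 = background).
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param min_area_um2 Area threshold in square micrometres (default 0.3).
#' @return A list: \code{labels} (filtered label matrix), \code{kept_ids},
#'   \code{areas_um2} (named by id, survivors only), \code{n_kept},
#'   \code{n_removed}.
#' @export
filter_adhesions <- function(label_mask, pixel_size_um = 0.1,
                             min_area_um2 = 0.3) {
  stopifnot(is.matrix(label_mask), all(label_mask >= 0))
  lab <- as.integer(round(label_mask))
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L)
    return(list(labels = label_mask * 0L, kept_ids = integer(0),
                areas_um2 = numeric(0), n_kept = 0L, n_removed = 0L))
  areas_px <- tabulate(lab, nbins = max(ids))[ids]
  areas_um2 <- areas_px * pixel_size_um^2
  # strict "larger than", robust to floating-point ties at the threshold
  keep <- areas_um2 > min_area_um2 * (1 + 1e-9)
  out <- matrix(ifelse(label_mask %in% ids[keep], label_mask, 0L),
                nrow(label_mask), ncol(label_mask))
  list(labels = out, kept_ids = ids[keep],
       areas_um2 = stats::setNames(areas_um2[keep], ids[keep]),
       n_kept = sum(keep), n_removed = sum(!keep))
}

.object_pixels <- function(label_mask, id) {
  which(label_mask == id, arr.ind = TRUE)
}

#' Classify adhesions as central or peripheral
#'
#' Computes the exact Euclidean distance transform of the cell mask,
#' evaluates it at each adhesion's centre of mass (intensity-weighted when an
#' intensity image is given, binary otherwise), normalises by the equivalent
#' cell radius, and classifies as central when the normalised distance
#' strictly exceeds \code{threshold} (default 0.3).
#'
#' @param label_mask Integer label matrix of adhesions (post size filter).
#' @param cell A \code{cell_mask}.
#' @param intensity_image Optional intensity matrix for weighted centroids.
#' @param threshold Normalised-distance cutoff for "central" (default 0.3).
#' @return A data frame of class \code{adhesion_records}: \code{fa_id},
#'   \code{area_um2}, \code{row}, \code{col} (centroid, pixels),
#'   \code{dist_um}, \code{dist_norm}, \code{class}, \code{flagged}
#'   (centroid outside the cell mask).
#' @export
classify_adhesions <- function(label_mask, cell, intensity_image = NULL,
                               threshold = 0.3) {
  stopifnot(inherits(cell, "cell_mask"), is.matrix(label_mask))
  px <- cell$pixel_size_um
  D <- as.matrix(EBImage::distmap(EBImage::Image(cell$mask * 1)))
  ids <- sort(unique(label_mask[label_mask > 0]))
  rows <- lapply(ids, function(id) {
    pix <- .object_pixels(label_mask, id)
    w <- if (is.null(intensity_image)) rep(1, nrow(pix)) else {
      wi <- intensity_image[pix]
      if (all(wi <= 0)) rep(1, nrow(pix)) else pmax(wi, 0)
    }
    cr <- sum(w * pix[, 1L]) / sum(w)
    cc <- sum(w * pix[, 2L]) / sum(w)
    ri <- min(max(round(cr), 1L), nrow(D))
    ci <- min(max(round(cc), 1L), ncol(D))
    inside <- cell$mask[ri, ci]
    dist_um <- D[ri, ci] * px
    dist_norm <- dist_um / cell$r_um
    data.frame(fa_id = id, area_um2 = nrow(pix) * px^2, row = cr, col = cc,
               dist_um = dist_um, dist_norm = dist_norm,
               class = if (dist_norm > threshold) "central" else "peripheral",
               flagged = !inside, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(fa_id = integer(0), area_um2 = numeric(0),
                      row = numeric(0), col = numeric(0),
                      dist_um = numeric(0), dist_norm = numeric(0),
                      class = character(0), flagged = logical(0))
  rownames(out) <- NULL
  class(out) <- c("adhesion_records", "data.frame")
  out
}

#' Background-subtracted mean adhesion intensity
#'
#' For each adhesion, the local background is the mean intensity in a
#' dilation annulus around the object, restricted to pixels inside the cell
#' and outside every adhesion. The reported value is mean(object) minus that
#' background. If the annulus is empty (the object fills the cell locally),
#' the background falls back to the whole-cell non-adhesion mean and the
#' record is flagged.
#'
#' @param label_mask Integer label matrix of adhesions.
#' @param intensity_image Intensity matrix aligned with the masks.
#' @param cell A \code{cell_mask}.
#' @param annulus_px Width of the dilation band in pixels (default 5).
#' @return A data frame: \code{fa_id}, \code{mean_intensity},
#'   \code{background}, \code{intensity_bgsub}, \code{flagged_bg}.
#' @export
adhesion_intensity <- function(label_mask, intensity_image, cell,
                               annulus_px = 5L) {
  stopifnot(inherits(cell, "cell_mask"),
            all(dim(label_mask) == dim(intensity_image)))
  any_adh <- label_mask > 0
  cell_bg <- cell$mask & !any_adh
  brush <- EBImage::makeBrush(2L * as.integer(annulus_px) + 1L, "disc")
  ids <- sort(unique(label_mask[any_adh]))
  rows <- lapply(ids, function(id) {
    obj <- label_mask == id
    dil <- as.matrix(EBImage::dilate(EBImage::Image(obj * 1), brush)) > 0
    ann <- dil & !any_adh & cell$mask
    flagged <- sum(ann) == 0L
    bg <- if (flagged) mean(intensity_image[cell_bg])
          else mean(intensity_image[ann])
    mi <- mean(intensity_image[obj])
    data.frame(fa_id = id, mean_intensity = mi, background = bg,
               intensity_bgsub = mi - bg, flagged_bg = flagged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.stamp_ellipse <- function(nrow, ncol, cr, cc, a, b, theta) {
  rr <- pmax(1L, floor(cr - a - b)):pmin(nrow, ceiling(cr + a + b))
  cc2 <- pmax(1L, floor(cc - a - b)):pmin(ncol, ceiling(cc + a + b))
  grid <- expand.grid(r = rr, c = cc2)
  dx <- grid$r - cr; dy <- grid$c - cc
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(grid$r[inside], grid$c[inside])
}

#' Synthetic cell with planted adhesions
#'
#' Renders a cell silhouette (disk or ellipse), plants elliptical adhesions
#' at controlled normalised distances from the cell edge with known
#' intensities, and returns actin/intensity images, the adhesion label mask
#' and the per-adhesion ground truth. Placement uses the cell's own distance
#' transform, so the planted normalised distances are exact for any cell
#' shape. Adhesions are spread in angle and kept apart so local background
#' annuli stay clean.
#'
#' @param shape \code{"disk"} or \code{"ellipse"}.
#' @param n_adhesions Number of adhesions.
#' @param central_fraction Fraction planted at normalised distances > 0.3
#'   (the rest are planted at <= 0.3).
#' @param seed Optional integer seed.
#' @param dim Image dimensions in pixels.
#' @param pixel_size_um Pixel size in micrometres.
#' @param noise_sd Gaussian noise added to both images (counts).
#' @return A list: \code{actin_image}, \code{intensity_image},
#'   \code{label_mask}, \code{cell_mask} (logical), \code{pixel_size_um},
#'   \code{truth} (data frame: fa_id, d_norm, class, amplitude, area_px).
#' @export
synthetic_cell_fixture <- function(shape = c("disk", "ellipse"),
                                   n_adhesions = 8L, central_fraction = 0.5,
                                   seed = NULL, dim = c(220L, 220L),
                                   pixel_size_um = 0.1, noise_sd = 0) {
  shape <- match.arg(shape)
  stopifnot(central_fraction >= 0, central_fraction <= 1, n_adhesions >= 1L)
  if (!is.null(seed)) set.seed(seed)
  nr <- dim[1L]; nc <- dim[2L]
  ctr <- c(nr, nc) / 2
  R <- 0.4 * min(dim)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cell <- if (shape == "disk")
    (rows - ctr[1L])^2 + (cols - ctr[2L])^2 <= R^2
  else
    ((rows - ctr[1L]) / R)^2 + ((cols - ctr[2L]) / (0.7 * R))^2 <= 1
  area_px <- sum(cell)
  r_px <- sqrt(area_px / pi)
  D <- as.matrix(EBImage::distmap(EBImage::Image(cell * 1)))

  n_central <- round(central_fraction * n_adhesions)
  n_periph <- n_adhesions - n_central
  d_targets <- c(if (n_central > 0)
                   seq(0.40, min(0.85, 0.4 + 0.1 * n_central), length.out = n_central),
                 if (n_periph > 0) seq(0.08, 0.25, length.out = n_periph))
  d_targets <- pmin(d_targets, max(D) / r_px * 0.95)

  label_mask <- matrix(0L, nr, nc)
  placed <- matrix(numeric(0), ncol = 2)
  truth <- vector("list", n_adhesions)
  min_sep <- 18
  for (i in seq_len(n_adhesions)) {
    # progressively relax the target tolerance and the separation if the
    # candidate ring is crowded (narrow rings on elongated cells)
    cand <- NULL
    for (tol in c(0.01, 0.03, 0.06)) {
      for (sep in c(min_sep, 12, 8)) {
        cc <- which(abs(D / r_px - d_targets[i]) < tol & D > 4,
                    arr.ind = TRUE)
        ok <- rep(TRUE, nrow(cc))
        if (nrow(placed) > 0) {
          for (j in seq_len(nrow(placed)))
            ok <- ok & (sqrt((cc[, 1L] - placed[j, 1L])^2 +
                               (cc[, 2L] - placed[j, 2L])^2) > sep)
        }
        cc <- cc[ok, , drop = FALSE]
        if (nrow(cc) > 0L) { cand <- cc; break }
      }
      if (!is.null(cand)) break
    }
    if (is.null(cand)) stop("could not place adhesion ", i,
                            "; reduce n_adhesions or separation")
    pick <- cand[sample.int(nrow(cand), 1L), ]
    placed <- rbind(placed, pick)
    theta <- stats::runif(1, 0, pi)
    pix <- .stamp_ellipse(nr, nc, pick[1L], pick[2L], 5, 3, theta)
    keep <- cell[pix]
    pix <- pix[keep, , drop = FALSE]
    label_mask[pix] <- i
    cen <- colMeans(pix)
    d_norm <- D[round(cen[1L]), round(cen[2L])] / r_px
    truth[[i]] <- data.frame(
      fa_id = i, d_norm = d_norm,
      class = if (d_norm > 0.3) "central" else "peripheral",
      amplitude = 2000 + 400 * i, area_px = nrow(pix),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)

  actin <- matrix(10, nr, nc); actin[cell] <- 200
  intensity <- matrix(50, nr, nc); intensity[cell] <- 500
  for (i in seq_len(n_adhesions))
    intensity[label_mask == i] <- 500 + truth$amplitude[i]
  if (noise_sd > 0) {
    actin <- actin + stats::rnorm(length(actin), 0, noise_sd)
    intensity <- intensity + stats::rnorm(length(intensity), 0, noise_sd)
  }
  list(actin_image = actin, intensity_image = intensity,
       label_mask = label_mask, cell_mask = cell,
       pixel_size_um = pixel_size_um, truth = truth)
}
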