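# SEM pore detection: normalize a grayscale field, threshold-segment
# candidate holes, label connected components (8-connectivity), filter by
# physical size and border contact, and classify components as functional
# (dark) vs occluded (lighter gray). Areas and densities are reported in
# physical units via the um-per-pixel scale.

#' Construct a calibrated SEM image object
#'
#' @param pixels Numeric matrix of grayscale intensities.
#' @param scale_um_per_px Physical scale (micrometers per pixel, > 0).
#' @param normalized Set TRUE if `pixels` is already on `[0, 1]`.
#' @return Object of class `sem_image`.
#' @export
sem_image <- function(pixels, scale_um_per_px, normalized = FALSE) {
  if (!is.matrix(pixels) || !length(pixels)) stop("pixels must be a non-empty matrix")
  if (!is.finite(scale_um_per_px) || scale_um_per_px <= 0)
    stop("scale_um_per_px must be > 0")
  px <- if (normalized) pixels else normalize_image(pixels)
  structure(list(pixels = px, scale_um_per_px = scale_um_per_px,
                 field_area_um2 = prod(dim(px)) * scale_um_per_px^2),
            class = "sem_image")
}

#' Percentile-normalize a grayscale intensity array to [0, 1]
#'
#' Linear rescale mapping the 1st percentile to 0 and the 99th to 1, then
#' clipping; invariant to affine transforms of the input. A constant image
#' maps to all 0.5 with a warning.
#'
#' @param raw Numeric matrix of intensities.
#' @export
normalize_image <- function(raw) {
  if (!is.matrix(raw) || !length(raw)) stop("raw must be a non-empty matrix")
  q <- stats::quantile(raw, c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant (or near-constant) image; returning all-0.5")
    return(matrix(0.5, nrow(raw), ncol(raw)))
  }
  pmin(pmax((raw - q[1]) / (q[2] - q[1]), 0), 1)
}

# 8-connected labeling: EBImage::bwlabel (4-connected) plus a union-find
# merge of labels that touch diagonally.
label_components8 <- function(mask) {
  L <- EBImage::bwlabel(mask)
  L <- matrix(as.integer(L), nrow(mask), ncol(mask))
  nlab <- max(L)
  if (nlab <= 1) return(L)
  pairs <- rbind(
    cbind(as.vector(L[-nrow(L), -ncol(L)]), as.vector(L[-1, -1])),
    cbind(as.vector(L[-nrow(L), -1]), as.vector(L[-1, -ncol(L)])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  L[L > 0] <- relab[L[L > 0]]
  L
}

#' Detect and classify eggshell pores in a calibrated SEM image
#'
#' Pixels below `occluded_threshold` form the candidate mask; connected
#' components (8-connectivity) smaller than `min_area_um2` or touching the
#' image border are discarded; remaining components are classified as
#' `functional` when their mean interior intensity is at most
#' `dark_threshold`, otherwise `occluded`. Pore density counts functional
#' pores per mm^2 of field; mean pore area covers functional pores only.
#'
#' @param img An `sem_image` (normalized intensities).
#' @param dark_threshold Functional-pore intensity ceiling (default 0.2).
#' @param occluded_threshold Candidate-mask ceiling (default 0.5); must
#'   exceed `dark_threshold`.
#' @param min_area_um2 Minimum component area in um^2 (default 0.05).
#' @param otsu Use an Otsu threshold (on the normalized image) in place of
#'   `occluded_threshold` — intended for real SEM fields.
#' @return Object of class `pore_set`: `pores` data.frame (centroid_row,
#'   centroid_col — 0-based pixel coordinates —, n_pixels, area_um2,
#'   equiv_diameter_um, mean_intensity, class), `field_area_um2`,
#'   `density_per_mm2`, `mean_functional_area_um2`, `n_functional`,
#'   `n_occluded`.
#' @export
detect_pores <- function(img, dark_threshold = 0.2, occluded_threshold = 0.5,
                         min_area_um2 = 0.05, otsu = FALSE) {
  stopifnot(inherits(img, "sem_image"))
  if (otsu)
    occluded_threshold <- EBImage::otsu(EBImage::Image(img$pixels))
  if (dark_threshold >= occluded_threshold)
    stop("dark_threshold must be below occluded_threshold")
  px <- img$pixels
  scale <- img$scale_um_per_px
  L <- label_components8(px < occluded_threshold)
  empty <- data.frame(centroid_row = numeric(0), centroid_col = numeric(0),
                      n_pixels = integer(0), area_um2 = numeric(0),
                      equiv_diameter_um = numeric(0),
                      mean_intensity = numeric(0), class = character(0),
                      stringsAsFactors = FALSE)
  nlab <- max(L)
  pores <- empty
  if (nlab > 0) {
    idx <- which(L > 0)
    lab <- L[idx]
    rows <- (idx - 1) %% nrow(px) + 1
    cols <- (idx - 1) %/% nrow(px) + 1
    npix <- tabulate(lab, nlab)
    area <- npix * scale^2
    border <- vapply(seq_len(nlab), function(l) {
      sel <- lab == l
      any(rows[sel] == 1 | rows[sel] == nrow(px) |
            cols[sel] == 1 | cols[sel] == ncol(px))
    }, logical(1))
    keep <- which(area >= min_area_um2 & !border)
    if (length(keep)) {
      mi <- vapply(keep, function(l) mean(px[idx[lab == l]]), numeric(1))
      cr <- vapply(keep, function(l) mean(rows[lab == l]) - 1, numeric(1))
      cc <- vapply(keep, function(l) mean(cols[lab == l]) - 1, numeric(1))
      pores <- data.frame(
        centroid_row = cr, centroid_col = cc, n_pixels = npix[keep],
        area_um2 = area[keep],
        equiv_diameter_um = 2 * sqrt(area[keep] / pi),
        mean_intensity = mi,
        class = ifelse(mi <= dark_threshold, "functional", "occluded"),
        stringsAsFactors = FALSE)
    }
  }
  nf <- sum(pores$class == "functional")
  structure(list(
    pores = pores, field_area_um2 = img$field_area_um2,
    density_per_mm2 = 1e6 * nf / img$field_area_um2,
    mean_functional_area_um2 =
      if (nf) mean(pores$area_um2[pores$class == "functional"]) else NA_real_,
    n_functional = nf, n_occluded = sum(pores$class == "occluded"),
    params = list(dark_threshold = dark_threshold,
                  occluded_threshold = occluded_threshold,
                  min_area_um2 = min_area_um2,
                  border_policy = "discard")), class = "pore_set")
}

#' @export
print.pore_set <- function(x, ...) {
  cat(sprintf("Pore set: %d functional, %d occluded over %.1f um^2\n",
              x$n_functional, x$n_occluded, x$field_area_um2))
  cat(sprintf("  density = %.2f per mm^2, mean functional area = %.3f um^2\n",
              x$density_per_mm2, x$mean_functional_area_um2))
  invisible(x)
}

#' Average replicate pore measurements (or thickness readings)
#'
#' Replicate SEM fields (normally three per specimen) are averaged to one
#' structural record; the replicate values are retained for downstream
#' repeatability analysis. Also accepts a plain numeric vector of replicate
#' thickness measurements.
#'
#' @param replicates List of `pore_set` objects, or a numeric vector.
#' @return For pore sets: list with `pore_density_per_mm2`,
#'   `mean_pore_area_um2`, `n_replicates`, and `replicates` (per-replicate
#'   density/area). For a numeric vector: list with `mean`, `n_replicates`,
#'   `replicates`.
#' @export
summarize_structure <- function(replicates) {
  if (is.numeric(replicates)) {
    if (!length(replicates)) stop("zero replicates")
    if (length(replicates) != 3)
      warning("expected 3 replicates, got ", length(replicates))
    return(list(mean = mean(replicates), n_replicates = length(replicates),
                replicates = replicates))
  }
  stopifnot(is.list(replicates), all(vapply(replicates, inherits, logical(1), "pore_set")))
  if (!length(replicates)) stop("zero replicates")
  if (length(replicates) != 3)
    warning("expected 3 replicates, got ", length(replicates))
  dens <- vapply(replicates, `[[`, numeric(1), "density_per_mm2")
  area <- vapply(replicates, `[[`, numeric(1), "mean_functional_area_um2")
  list(pore_density_per_mm2 = mean(dens),
       mean_pore_area_um2 = mean(area, na.rm = TRUE),
       n_replicates = length(replicates),
       replicates = data.frame(density_per_mm2 = dens, mean_area_um2 = area))
}
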