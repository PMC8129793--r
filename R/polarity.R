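# bilinear interpolation of image intensities at continuous um positions
.bilinear <- function(pixels, pixel_size, x_um, y_um) {
  H <- nrow(pixels); W <- ncol(pixels)
  cx <- pmin(pmax(x_um / pixel_size + 0.5, 1), W)  # continuous col index
  cy <- pmin(pmax(y_um / pixel_size + 0.5, 1), H)
  j0 <- pmin(floor(cx), W - 1L); i0 <- pmin(floor(cy), H - 1L)
  fx <- cx - j0; fy <- cy - i0
  pixels[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    pixels[cbind(i0, j0 + 1L)] * fx * (1 - fy) +
    pixels[cbind(i0 + 1L, j0)] * (1 - fx) * fy +
    pixels[cbind(i0 + 1L, j0 + 1L)] * fx * fy
}

#' Extract a line-scan intensity profile
#'
#' Samples intensities along the segment from `p0` (anterior) to `p1`
#' (posterior), averaging `width` parallel samples taken perpendicular to the
#' line at one-pixel spacing — emulating a thick scan line drawn through the
#' centre of a cluster.
#'
#' @param image A [calibrated_image()], oriented anterior-left.
#' @param p0,p1 Endpoints `c(x, y)` in um; `p0` is the anterior end.
#' @param width Odd number of parallel samples (default 3 px).
#' @return A `line_profile` data frame: `position_um` (distance from `p0`),
#'   `intensity`.
#' @export
extract_line_profile <- function(image, p0, p1, width = 3L) {
  stopifnot(inherits(image, "calibrated_image"), width >= 1)
  px <- image$pixel_size
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0) stop("`p0` and `p1` must differ")
  lim_x <- ncol(image$pixels) * px; lim_y <- nrow(image$pixels) * px
  for (p in list(p0, p1)) {
    if (p[1] < 0 || p[1] > lim_x || p[2] < 0 || p[2] > lim_y)
      stop("line endpoints must lie within the image")
  }
  n <- max(2L, ceiling(len / px) + 1L)
  tt <- seq(0, 1, length.out = n)
  d <- (p1 - p0) / len
  nv <- c(-d[2], d[1])  # unit normal
  offsets <- (seq_len(width) - (width + 1) / 2) * px
  acc <- numeric(n)
  for (o in offsets) {
    xs <- p0[1] + tt * len * d[1] + o * nv[1]
    ys <- p0[2] + tt * len * d[2] + o * nv[2]
    acc <- acc + .bilinear(image$pixels, px, xs, ys)
  }
  structure(data.frame(position_um = tt * len, intensity = acc / width),
            scan_width = as.integer(width),
            class = c("line_profile", "data.frame"))
}

#' Detect peaks in a line profile
#'
#' Local maxima with prominence at least `min_prominence` are retained.
#' Each peak's support runs between its two flanking minima (searched between
#' adjacent retained apexes, or to the profile ends) and is truncated at the
#' midpoints between adjacent apexes so supports never overlap; the higher of
#' the two flanking-minimum intensities is recorded as `base_level`.
#'
#' @param profile A `line_profile` (data frame `position_um`, `intensity`).
#' @param min_prominence Minimum prominence; default 10% of the profile's
#'   dynamic range.
#' @return A `peak_set` data frame: `apex_position_um`, `apex_intensity`,
#'   `prominence`, `left_base_um`, `right_base_um`, `base_level`
#'   (empty for flat or monotone profiles).
#' @export
detect_peaks <- function(profile, min_prominence = NULL) {
  y <- profile$intensity
  x <- profile$position_um
  n <- length(y)
  if (is.null(min_prominence)) min_prominence <- 0.1 * diff(range(y))
  empty <- data.frame(apex_position_um = numeric(), apex_intensity = numeric(),
                      prominence = numeric(), left_base_um = numeric(),
                      right_base_um = numeric(), base_level = numeric())
  class(empty) <- c("peak_set", "data.frame")
  if (n < 3L || diff(range(y)) == 0) return(empty)
  apex <- which(y[-c(1, 2)] <= y[-c(1, n)] & y[-c(n - 1, n)] < y[-c(1, n)]) + 1L
  if (!length(apex)) return(empty)
  # scipy-style prominence: min toward the nearest higher point on each side
  prom <- vapply(apex, function(i) {
    lmin <- y[i]
    for (j in rev(seq_len(i - 1L))) {
      if (y[j] > y[i]) break
      lmin <- min(lmin, y[j])
    }
    rmin <- y[i]
    j <- i + 1L
    while (j <= n && y[j] <= y[i]) {
      rmin <- min(rmin, y[j])
      j <- j + 1L
    }
    y[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  apex <- apex[keep]; prom <- prom[keep]
  if (!length(apex)) return(empty)
  k <- length(apex)
  out <- lapply(seq_len(k), function(m) {
    i <- apex[m]
    lo <- if (m == 1L) 1L else apex[m - 1L]
    hi <- if (m == k) n else apex[m + 1L]
    lmin_pos <- lo - 1L + which.min(y[lo:i])
    rmin_pos <- i - 1L + which.min(y[i:hi])
    level <- max(y[lmin_pos], y[rmin_pos])
    # truncate supports at midpoints between adjacent apexes
    lcut <- if (m == 1L) x[1] else (x[apex[m - 1L]] + x[i]) / 2
    rcut <- if (m == k) x[n] else (x[i] + x[apex[m + 1L]]) / 2
    data.frame(apex_position_um = x[i], apex_intensity = y[i],
               prominence = prom[m],
               left_base_um = max(x[lmin_pos], lcut),
               right_base_um = min(x[rmin_pos], rcut),
               base_level = level)
  })
  res <- do.call(rbind, out)
  class(res) <- c("peak_set", "data.frame")
  res
}

#' Area under detected peaks
#'
#' Trapezoidal integral, over each peak's support, of the intensity above the
#' linear baseline joining the profile at the two support bases; negative
#' contributions are clamped to zero.
#'
#' @param profile The `line_profile` the peaks were detected in.
#' @param peaks A `peak_set` from [detect_peaks()].
#' @return The `peak_set` with an `area` column (units x um).
#' @export
area_under_peaks <- function(profile, peaks) {
  x <- profile$position_um
  y <- profile$intensity
  peaks$area <- vapply(seq_len(nrow(peaks)), function(m) {
    sel <- which(x >= peaks$left_base_um[m] & x <= peaks$right_base_um[m])
    if (length(sel) < 2L) return(0)
    xs <- x[sel]
    y0 <- y[sel[1]]; y1 <- y[sel[length(sel)]]
    base <- y0 + (y1 - y0) * (xs - xs[1]) / max(xs[length(xs)] - xs[1], 1e-12)
    h <- pmax(y[sel] - base, 0)
    sum((h[-1] + h[-length(h)]) / 2 * diff(xs))
  }, numeric(1))
  peaks
}

#' Back/middle/front fractions of peak area
#'
#' Assigns each peak to the back (anterior third), middle, or front
#' (posterior third) of the cluster extent by apex position, and normalizes
#' the per-region area sums to percentages of the total peak area. With zero
#' total area the fractions are undefined (`NA`).
#'
#' @param peaks A `peak_set` with areas (see [area_under_peaks()]).
#' @param cluster_extent `c(start, end)` of the cluster along the scan, um.
#' @return A `bmf_fractions` list: `back`, `middle`, `front` (percent).
#' @export
bmf_fractions <- function(peaks, cluster_extent) {
  stopifnot(length(cluster_extent) == 2L,
            cluster_extent[2] > cluster_extent[1])
  if (!"area" %in% names(peaks)) stop("run area_under_peaks() first")
  b1 <- cluster_extent[1] + diff(cluster_extent) / 3
  b2 <- cluster_extent[1] + 2 * diff(cluster_extent) / 3
  region <- ifelse(peaks$apex_position_um < b1, "back",
                   ifelse(peaks$apex_position_um < b2, "middle", "front"))
  tot <- sum(peaks$area)
  f <- function(r) if (tot > 0) 100 * sum(peaks$area[region == r]) / tot
                   else NA_real_
  structure(list(back = f("back"), middle = f("middle"), front = f("front")),
            class = "bmf_fractions")
}

#' @export
print.bmf_fractions <- function(x, ...) {
  cat(sprintf("<bmf_fractions> back %.1f%% / middle %.1f%% / front %.1f%%\n",
              x$back, x$middle, x$front))
  invisible(x)
}

#' Fold shift of the middle (interior-junction) fraction
#'
#' Ratio of the middle BMF fraction of a test condition to that of a
#' control: the readout for redistribution of a cortical signal toward
#' interior cell junctions.
#'
#' @param bmf_test,bmf_control [bmf_fractions()] results.
#' @return Fold (test middle / control middle).
#' @export
middle_fold_shift <- function(bmf_test, bmf_control) {
  if (is.na(bmf_control$middle) || bmf_control$middle <= 0)
    stop("control middle fraction must be > 0")
  bmf_test$middle / bmf_control$middle
}

#' Raw integrated density over a region
#'
#' Sum of pixel intensities within the mask, the standard region-intensity
#' statistic for mosaic quantification.
#'
#' @param image A [calibrated_image()].
#' @param mask Logical matrix.
#' @return Summed intensity (arbitrary units).
#' @export
raw_integrated_density <- function(image, mask) {
  stopifnot(inherits(image, "calibrated_image"),
            identical(dim(mask), dim(image$pixels)))
  sum(image$pixels[mask])
}

#' Intensity ratio between mosaic sibling regions
#'
#' Ratio of the test region's statistic (mean intensity or raw integrated
#' density) to the internal-control region's. The fold is reported as
#' control/test whenever the test region is dimmer, so a reduction reads as
#' a fold greater than 1.
#'
#' @param image A [calibrated_image()].
#' @param region_test,region_control Logical masks (nonempty).
#' @param mode `"mean"` (mean intensity) or `"rid"` (raw integrated density).
#' @return A `mosaic_ratio` list: `stat_test`, `stat_control`, `ratio`,
#'   `fold`, `mode`.
#' @export
mosaic_ratio <- function(image, region_test, region_control,
                         mode = c("mean", "rid")) {
  mode <- match.arg(mode)
  if (!any(region_test) || !any(region_control))
    stop("both region masks must be nonempty")
  stat <- function(mask) {
    v <- raw_integrated_density(image, mask)
    if (mode == "mean") v / sum(mask) else v
  }
  st <- stat(region_test); sc <- stat(region_control)
  if (sc <= 0) stop("control region statistic must be > 0")
  ratio <- st / sc
  structure(list(stat_test = st, stat_control = sc, ratio = ratio,
                 fold = if (ratio < 1) 1 / ratio else ratio, mode = mode),
            class = "mosaic_ratio")
}

#' @export
print.mosaic_ratio <- function(x, ...) {
  cat(sprintf("<mosaic_ratio> %s ratio %.3f (fold %.3f)\n",
              x$mode, x$ratio, x$fold))
  invisible(x)
}

#' Inner/outer junction intensity ratio
#'
#' Mean intensity within the inner (cluster-interior junction) mask divided
#' by the mean within the outer (nurse-cell junction) mask; invariant to
#' global intensity scaling.
#'
#' @param image A [calibrated_image()].
#' @param inner_mask,outer_mask Logical masks (nonempty).
#' @return The ratio of mean intensities.
#' @export
junction_ratio <- function(image, inner_mask, outer_mask) {
  if (!any(inner_mask) || !any(outer_mask))
    stop("both masks must be nonempty")
  mean(image$pixels[inner_mask]) / mean(image$pixels[outer_mask])
}
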