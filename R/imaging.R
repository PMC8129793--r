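#' Maximum-intensity projection over a z stack
#'
#' Collapses a stack of z slices to a single image by taking, at each pixel,
#' the maximum intensity over slices — the standard first step before
#' segmenting a fluorescently labelled cluster from confocal z stacks.
#'
#' @param stack An [image_stack()] whose frames are z slices.
#' @return A [calibrated_image()] with per-pixel maxima.
#' @export
max_project <- function(stack) {
  if (!inherits(stack, "image_stack")) stop("`stack` must be an image_stack")
  if (length(stack$frames) == 0L) stop("empty stack")
  out <- stack$frames[[1]]$pixels
  for (f in stack$frames[-1]) out <- pmax(out, f$pixels)
  calibrated_image(out, stack$frames[[1]]$pixel_size,
                   stack$frames[[1]]$oriented_anterior_left)
}

#' Orient an egg chamber image anterior-left
#'
#' Rotates/mirrors the image (lossless multiples of 90 degrees or mirror) so
#' that the anterior end of the egg chamber is at the left of the frame, the
#' reference frame in which the leading edge of the migrating cluster points
#' along +x.
#'
#' @param image A [calibrated_image()].
#' @param anterior_side Which side of the input frame currently holds the
#'   anterior end: `"left"`, `"right"`, `"top"` or `"bottom"`.
#' @return The reoriented image, flagged `oriented_anterior_left`.
#' @export
orient_anterior_left <- function(image,
                                 anterior_side = c("left", "right",
                                                   "top", "bottom")) {
  if (!inherits(image, "calibrated_image"))
    stop("`image` must be a calibrated_image")
  anterior_side <- match.arg(anterior_side)
  m <- image$pixels
  m <- switch(anterior_side,
    left   = m,
    right  = m[, rev(seq_len(ncol(m))), drop = FALSE],  # horizontal mirror
    top    = t(m),                                       # top edge -> left edge
    bottom = t(m)[, rev(seq_len(nrow(m))), drop = FALSE])
  calibrated_image(m, image$pixel_size, oriented_anterior_left = TRUE)
}

#' Subtract background signal
#'
#' Estimates a scalar background level and subtracts it, clamping at zero.
#' The estimate is recorded in the `background` attribute so analyses stay
#' reproducible.
#'
#' @param image A [calibrated_image()].
#' @param method `"percentile"` (background = the given intensity percentile,
#'   robust when most pixels are background) or `"constant"`.
#' @param value The percentile in `[0, 100]` (default 5) or the constant.
#' @return Background-subtracted `calibrated_image` with attribute
#'   `background` holding the estimate used.
#' @export
subtract_background <- function(image, method = c("percentile", "constant"),
                                value = 5) {
  if (!inherits(image, "calibrated_image"))
    stop("`image` must be a calibrated_image")
  method <- match.arg(method)
  est <- switch(method,
    percentile = {
      if (value < 0 || value > 100) stop("percentile must be in [0, 100]")
      unname(quantile(image$pixels, value / 100))
    },
    constant = {
      if (!is.numeric(value) || value < 0) stop("constant must be >= 0")
      value
    })
  out <- calibrated_image(pmax(image$pixels - est, 0), image$pixel_size,
                          image$oriented_anterior_left)
  attr(out, "background") <- est
  out
}

#' Threshold the border cell cluster
#'
#' Binarizes the image and returns the largest connected foreground component
#' as the cluster mask (egg chamber images contain a single cluster; smaller
#' blobs are debris). The default Otsu threshold replaces the manual
#' thresholding done interactively in image-analysis software, trading
#' operator judgement for reproducibility; an absolute threshold is available
#' as an override.
#'
#' @param image A [calibrated_image()], oriented anterior-left.
#' @param method `"otsu"` or `"absolute"`.
#' @param value Absolute intensity threshold (required for
#'   `method = "absolute"`).
#' @return Logical matrix: the full cluster mask, with attribute `threshold`.
#' @export
threshold_cluster <- function(image, method = c("otsu", "absolute"),
                              value = NULL) {
  if (!inherits(image, "calibrated_image"))
    stop("`image` must be a calibrated_image")
  method <- match.arg(method)
  px <- image$pixels
  thr <- switch(method,
    otsu = {
      rng <- range(px)
      if (diff(rng) == 0) stop("no cluster found: image is constant")
      # normalize so the threshold is invariant under intensity rescaling
      norm <- (px - rng[1]) / diff(rng)
      t01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
      rng[1] + t01 * diff(rng)
    },
    absolute = {
      if (is.null(value)) stop("`value` is required for method = 'absolute'")
      value
    })
  fg <- px > thr
  if (!any(fg)) stop("no cluster found: empty foreground at threshold ", thr)
  lab <- EBImage::bwlabel(fg)
  tab <- tabulate(lab[lab > 0])
  mask <- matrix(lab == which.max(tab), nrow(px), ncol(px))
  attr(mask, "threshold") <- thr
  mask
}

#' Split a cluster mask into cell body and cellular extensions
#'
#' Morphological opening with a disk removes thin lobes from the cluster
#' mask; what remains is the cell body, and the connected components of the
#' difference are the cellular extensions (protrusions). Components smaller
#' than `min_extension_area` are treated as boundary noise and folded back
#' into the body so that the body and extensions exactly partition the full
#' mask.
#'
#' @param full_mask Logical matrix from [threshold_cluster()].
#' @param pixel_size Micrometres per pixel.
#' @param opening_radius Opening disk radius in micrometres. Default
#'   `NULL` uses half the equivalent radius of the full mask
#'   (`0.5 * sqrt(area / pi)`), a scale-free choice that tracks cluster size.
#' @param min_extension_area Minimum extension area in um^2 (default 2,
#'   rejecting single-pixel noise at typical calibrations).
#' @return A `cluster_segmentation` object: `full_mask`, `body_mask`,
#'   `extensions` (list of logical masks) and `summary` (data frame with
#'   `component_id`, `area_um2`, `centroid_x_um`, `centroid_y_um`).
#' @export
split_body_extensions <- function(full_mask, pixel_size,
                                  opening_radius = NULL,
                                  min_extension_area = 2) {
  if (!is.matrix(full_mask) || !is.logical(full_mask))
    stop("`full_mask` must be a logical matrix")
  if (!any(full_mask)) stop("`full_mask` is empty")
  area_px <- sum(full_mask)
  if (is.null(opening_radius))
    opening_radius <- 0.5 * sqrt(area_px / pi) * pixel_size
  r_px <- max(1L, round(opening_radius / pixel_size))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  body <- EBImage::opening(EBImage::Image(full_mask * 1), brush)
  body <- matrix(as.numeric(body) > 0.5, nrow(full_mask), ncol(full_mask))
  if (!any(body))
    stop("opening removed the entire mask; use a smaller `opening_radius`")
  resid <- full_mask & !body
  lab <- EBImage::bwlabel(resid)
  lab <- matrix(as.integer(lab), nrow(full_mask), ncol(full_mask))
  exts <- list()
  if (max(lab) > 0) {
    for (k in seq_len(max(lab))) {
      comp <- lab == k
      if (sum(comp) * pixel_size^2 >= min_extension_area)
        exts[[length(exts) + 1L]] <- comp
    }
  }
  # fold sub-threshold residue back into the body: exact partition
  ext_union <- Reduce(`|`, exts, matrix(FALSE, nrow(full_mask), ncol(full_mask)))
  body <- full_mask & !ext_union
  summ <- if (length(exts)) {
    do.call(rbind, lapply(seq_along(exts), function(k) {
      cen <- .mask_centroid_um(exts[[k]], pixel_size)
      data.frame(component_id = k,
                 area_um2 = sum(exts[[k]]) * pixel_size^2,
                 centroid_x_um = unname(cen["x"]),
                 centroid_y_um = unname(cen["y"]))
    }))
  } else {
    data.frame(component_id = integer(), area_um2 = numeric(),
               centroid_x_um = numeric(), centroid_y_um = numeric())
  }
  structure(list(full_mask = full_mask, body_mask = body, extensions = exts,
                 summary = summ, pixel_size = pixel_size,
                 opening_radius = opening_radius,
                 min_extension_area = min_extension_area),
            class = "cluster_segmentation")
}

#' @export
print.cluster_segmentation <- function(x, ...) {
  cat(sprintf(
    "<cluster_segmentation> body %.1f um2, %d extension(s), opening %.2f um\n",
    sum(x$body_mask) * x$pixel_size^2, length(x$extensions),
    x$opening_radius))
  invisible(x)
}
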