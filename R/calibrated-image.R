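#' Calibrated fluorescence image
#'
#' A thin container coupling a 2-D intensity grid with its physical
#' calibration. All physical quantities downstream (areas, distances, speeds)
#' are derived from `pixel_size`, so images must carry it explicitly.
#'
#' @param pixels Numeric matrix of non-negative intensities, `[row, col]`
#'   indexed with x along columns and y along rows (y increases downward).
#' @param pixel_size Pixel size in micrometres per pixel (> 0).
#' @param oriented_anterior_left Logical; `TRUE` once the egg chamber has been
#'   rotated so its anterior end is at the left of the frame.
#' @return An object of class `calibrated_image`.
#' @seealso [orient_anterior_left()], [image_stack()]
#' @export
calibrated_image <- function(pixels, pixel_size,
                             oriented_anterior_left = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and >= 0")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/px)")
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         oriented_anterior_left = isTRUE(oriented_anterior_left)),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px @ %.3g um/px (%s)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              if (x$oriented_anterior_left) "anterior left" else "unoriented"))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' Time-lapse (or z) image stack
#'
#' An ordered list of [calibrated_image()] frames sharing shape and
#' calibration, with the acquisition interval between frames.
#'
#' @param frames List of `calibrated_image` objects with identical dimensions
#'   and pixel size.
#' @param frame_interval Minutes between consecutive frames (> 0). The default
#'   3 min matches typical confocal time-lapse acquisition of egg chambers.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval = 3) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must be a non-empty list of calibrated_image objects")
  ok <- vapply(frames, inherits, logical(1), "calibrated_image")
  if (!all(ok)) stop("all frames must be calibrated_image objects")
  d <- dim(frames[[1]]$pixels)
  px <- frames[[1]]$pixel_size
  for (f in frames) {
    if (!identical(dim(f$pixels), d))
      stop("all frames must share the same dimensions")
    if (f$pixel_size != px)
      stop("all frames must share the same pixel size")
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("`frame_interval` must be > 0 (minutes)")
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]]$pixels)
  cat(sprintf("<image_stack> %d frames, %d x %d px, %.3g um/px, %g min/frame\n",
              length(x$frames), d[1], d[2],
              x$frames[[1]]$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Read a single- or multi-page TIFF as a calibrated image or stack
#'
#' @param path Path to a TIFF file.
#' @param pixel_size Micrometres per pixel to attach to the image.
#' @param frame_interval Minutes between pages; only used for multi-page files.
#' @return A `calibrated_image` (single page) or `image_stack` (multi-page).
#' @export
read_calibrated_tiff <- function(path, pixel_size, frame_interval = 3) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # collapse greyscale-as-RGB
    calibrated_image(p, pixel_size)
  })
  if (length(frames) == 1L) frames[[1]] else
    image_stack(frames, frame_interval)
}

#' Write a calibrated image or stack as 16-bit TIFF
#'
#' Intensities are written as-is when already in `[0, 65535]`.
#'
#' @param x A `calibrated_image` or `image_stack`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibrated_tiff <- function(x, path) {
  to_page <- function(img) {
    m <- img$pixels
    if (max(m) > 65535) stop("intensities exceed 16-bit range")
    m / 65535
  }
  pages <- if (inherits(x, "image_stack")) lapply(x$frames, to_page)
           else list(to_page(x))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

# area centroid of a logical mask, in um: c(x, y)
.mask_centroid_um <- function(mask, pixel_size) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no centroid")
  c(x = .px_to_um(mean(idx[, 2]), pixel_size),
    y = .px_to_um(mean(idx[, 1]), pixel_size))
}
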