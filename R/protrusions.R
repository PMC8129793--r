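#' Angle from cluster centroid to an extension centroid
#'
#' Angles are measured in the oriented (anterior-left) frame: 0 degrees along
#' +x toward the posterior (the leading edge of migration), increasing
#' counterclockwise on screen. Because image y increases downward, a point
#' directly *above* the centroid on screen is at 90 degrees.
#'
#' @param body_centroid,ext_centroid Numeric `c(x, y)` positions in um.
#' @return Angle in degrees in `[0, 360)`.
#' @export
extension_angle <- function(body_centroid, ext_centroid) {
  dx <- ext_centroid[[1]] - body_centroid[[1]]
  dy <- ext_centroid[[2]] - body_centroid[[2]]
  if (dx == 0 && dy == 0) stop("coincident centroids have no angle")
  (atan2(-dy, dx) * 180 / pi) %% 360
}

#' Classify an angle into front / side / back sectors
#'
#' Sector boundaries relative to the leading edge: front spans 315-45 degrees,
#' sides span 45-135 and 225-315 degrees, back spans 135-225 degrees.
#' Intervals are half-open and left-inclusive, so 45 -> side, 135 -> back,
#' 225 -> side and 315 -> front; inputs are reduced modulo 360.
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Character vector: `"front"`, `"side"` or `"back"`.
#' @export
classify_sector <- function(angle) {
  a <- angle %% 360
  out <- character(length(a))
  out[a < 45 | a >= 315] <- "front"
  out[(a >= 45 & a < 135) | (a >= 225 & a < 315)] <- "side"
  out[a >= 135 & a < 225] <- "back"
  out
}

#' Summarize extensions by angular sector
#'
#' Tallies detected extensions by front/side/back sector: counts, percentage
#' of all extensions, mean area, and the per-frame total count. With no
#' extensions the percentages are undefined and reported as `NA`, not zero.
#'
#' @param extensions Data frame with columns `frame`, `angle_deg`,
#'   `area_um2` (and optionally `sector`, otherwise derived from the angle).
#' @return List with `by_sector` (data frame: sector, n, percent,
#'   mean_area_um2) and `per_frame` (data frame: frame, n_extensions).
#' @export
sector_summary <- function(extensions) {
  stopifnot(is.data.frame(extensions))
  if (!"sector" %in% names(extensions))
    extensions$sector <- classify_sector(extensions$angle_deg)
  sectors <- c("front", "side", "back")
  n_tot <- nrow(extensions)
  by_sector <- do.call(rbind, lapply(sectors, function(s) {
    sel <- extensions$sector == s
    data.frame(sector = s, n = sum(sel),
               percent = if (n_tot > 0) 100 * sum(sel) / n_tot else NA_real_,
               mean_area_um2 = if (any(sel)) mean(extensions$area_um2[sel])
                               else NA_real_)
  }))
  per_frame <- if (n_tot > 0) {
    agg <- aggregate(list(n_extensions = extensions$frame),
                     by = list(frame = extensions$frame), FUN = length)
    agg[order(agg$frame), ]
  } else data.frame(frame = integer(), n_extensions = integer())
  list(by_sector = by_sector, per_frame = per_frame)
}

#' Extensions table for one segmented frame
#'
#' Combines a [split_body_extensions()] result with the angular convention of
#' [extension_angle()]: each extension gets its centroid angle relative to the
#' full-cluster centroid and a front/side/back sector label.
#'
#' @param seg A `cluster_segmentation`.
#' @param frame Frame index recorded in the output.
#' @return Data frame: `frame`, `component_id`, `area_um2`, `angle_deg`,
#'   `sector`.
#' @export
frame_extensions <- function(seg, frame = 1L) {
  stopifnot(inherits(seg, "cluster_segmentation"))
  if (nrow(seg$summary) == 0L)
    return(data.frame(frame = integer(), component_id = integer(),
                      area_um2 = numeric(), angle_deg = numeric(),
                      sector = character()))
  cen <- .mask_centroid_um(seg$full_mask, seg$pixel_size)
  ang <- vapply(seq_len(nrow(seg$summary)), function(k) {
    extension_angle(cen, c(seg$summary$centroid_x_um[k],
                           seg$summary$centroid_y_um[k]))
  }, numeric(1))
  data.frame(frame = frame,
             component_id = seg$summary$component_id,
             area_um2 = seg$summary$area_um2,
             angle_deg = ang,
             sector = classify_sector(ang))
}
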