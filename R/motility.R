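#' Track the cluster centroid over a movie
#'
#' The cluster position at each frame is the area centroid of its full mask,
#' in micrometres.
#'
#' @param masks List of logical full-cluster masks, one per frame.
#' @param pixel_size Micrometres per pixel.
#' @param frame_interval Minutes between frames.
#' @return A `bc_track`: data frame with `frame`, `t_min`, `x_um`, `y_um` and
#'   a `frame_interval` attribute.
#' @export
track_centroid <- function(masks, pixel_size, frame_interval = 3) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  cen <- t(vapply(masks, .mask_centroid_um, numeric(2),
                  pixel_size = pixel_size))
  out <- data.frame(frame = seq_along(masks),
                    t_min = (seq_along(masks) - 1L) * frame_interval,
                    x_um = cen[, 1], y_um = cen[, 2])
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("bc_track", "data.frame")
  out
}

#' Forward-directed migration speed
#'
#' Mean, over consecutive frame pairs, of the x displacement of the cluster
#' centre divided by the frame interval. Positive values indicate movement
#' toward the posterior (rightward in the anterior-left frame). Averaging
#' consecutive increments equals net x displacement over total time for the
#' same window.
#'
#' @param track A `bc_track` from [track_centroid()], or a data frame with
#'   `x_um` and a `frame_interval` attribute (or pass `frame_interval`).
#' @param window Optional integer vector of frame indices to analyze
#'   (default: all frames).
#' @param frame_interval Minutes between frames; defaults to the track's
#'   attribute.
#' @return Speed in um/min.
#' @export
forward_speed <- function(track, window = NULL, frame_interval = NULL) {
  x <- track$x_um
  if (is.null(frame_interval)) frame_interval <- attr(track, "frame_interval")
  if (is.null(frame_interval)) stop("`frame_interval` is required")
  if (!is.null(window)) x <- x[window]
  if (length(x) < 2L) stop("need at least two frames to compute a speed")
  mean(diff(x)) / frame_interval
}

#' Percent reduction of a rate relative to control
#'
#' @param control Control value (> 0).
#' @param test Test value.
#' @return `100 * (control - test) / control`.
#' @export
percent_reduction <- function(control, test) {
  if (any(control <= 0)) stop("`control` must be > 0")
  100 * (control - test) / control
}

#' Migration index of a fixed cluster
#'
#' Percentage of the anterior-to-oocyte-boundary path traversed by the
#' cluster, clamped to `[0, 100]`: positions beyond the boundary count as
#' complete migration.
#'
#' @param cluster_x Cluster x position (um).
#' @param start_x Migration start x position (um).
#' @param oocyte_boundary_x Oocyte/nurse-cell boundary x position (um),
#'   must exceed `start_x`.
#' @return Percent in `[0, 100]`.
#' @export
migration_index <- function(cluster_x, start_x, oocyte_boundary_x) {
  if (oocyte_boundary_x <= start_x)
    stop("`oocyte_boundary_x` must be greater than `start_x`")
  pmin(pmax(100 * (cluster_x - start_x) / (oocyte_boundary_x - start_x), 0),
       100)
}

#' Circularity (roundness) of a binary mask
#'
#' `4 * pi * area / perimeter^2`: 1 for a perfect disk, smaller for elongated
#' or protrusive shapes. The perimeter is measured along the 8-connected
#' boundary chain with Kulpa's corner correction (`pi * (1 + sqrt(2)) / 8`
#' times the raw chain length), which keeps the estimate within about 1% of
#' the true perimeter for smooth shapes; values are clamped to 1 to absorb
#' residual discretization error.
#'
#' @param mask Logical matrix with a single foreground component (the largest
#'   component is used if there are several).
#' @return Circularity in `(0, 1]`.
#' @export
roundness <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("empty mask")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  contours <- EBImage::ocontour(lab)
  sizes <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  ctr <- contours[[which.max(sizes)]]
  area <- max(sizes)
  if (nrow(ctr) < 4L) return(1)
  nxt <- rbind(ctr[-1, , drop = FALSE], ctr[1, , drop = FALSE])
  step <- abs(nxt - ctr)
  diag_step <- step[, 1] > 0 & step[, 2] > 0
  raw <- sum(!diag_step) + sqrt(2) * sum(diag_step)
  per <- raw * pi * (1 + sqrt(2)) / 8
  min(4 * pi * area / per^2, 1)
}

#' Detect nuclei as local intensity maxima inside the cluster body
#'
#' Nuclear labels appear as bright blobs on top of the body signal; they are
#' located as local maxima (within a `min_separation` neighbourhood) that rise
#' above a relative threshold between the body's median and maximum intensity.
#'
#' @param image A [calibrated_image()].
#' @param body_mask Logical body mask restricting the search.
#' @param min_separation Minimum distance between nuclei in um (default 2).
#' @param rel_threshold Fraction of the median-to-maximum intensity range a
#'   maximum must exceed (default 0.3).
#' @param smooth_sigma Gaussian pre-smoothing sigma in um (default 0.6),
#'   suppressing noise-induced spurious maxima.
#' @return Data frame: `x_um`, `y_um`, `intensity`, ordered by decreasing
#'   intensity.
#' @export
detect_nuclei <- function(image, body_mask, min_separation = 2,
                          rel_threshold = 0.3, smooth_sigma = 0.6) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  if (smooth_sigma > 0)
    px <- as.matrix(EBImage::gblur(EBImage::Image(px),
                                   sigma = smooth_sigma / image$pixel_size))
  r_px <- max(1L, floor(min_separation / image$pixel_size / 2))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  dil <- as.matrix(EBImage::dilate(EBImage::Image(px), brush))
  body_vals <- px[body_mask]
  thr <- median(body_vals) + rel_threshold * (max(body_vals) - median(body_vals))
  cand <- which(body_mask & px >= dil & px > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(x_um = numeric(), y_um = numeric(),
                      intensity = numeric()))
  df <- data.frame(x_um = .px_to_um(cand[, 2], image$pixel_size),
                   y_um = .px_to_um(cand[, 1], image$pixel_size),
                   intensity = px[cand])
  df <- df[order(-df$intensity), ]
  # suppress plateau/near-duplicate maxima within min_separation
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    if (i < nrow(df)) {
      j <- (i + 1L):nrow(df)
      d2 <- (df$x_um[j] - df$x_um[i])^2 + (df$y_um[j] - df$y_um[i])^2
      keep[j[d2 < min_separation^2]] <- FALSE
    }
  }
  out <- df[keep, ]
  rownames(out) <- NULL
  out
}

# greedy closest-pair assignment between two point sets (n x 2 matrices);
# returns for each row of a the matched row of b (NA if unmatched)
.greedy_match <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  d <- outer(seq_len(na), seq_len(nb), function(i, j)
    sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2))
  match_ab <- rep(NA_integer_, na)
  d_work <- d
  for (k in seq_len(min(na, nb))) {
    ij <- arrayInd(which.min(d_work), dim(d_work))
    match_ab[ij[1]] <- ij[2]
    d_work[ij[1], ] <- Inf
    d_work[, ij[2]] <- Inf
  }
  match_ab
}

#' Detect rearrangement of nuclei between consecutive frames
#'
#' Nuclei are identity-matched between the two frames by greedy
#' nearest-neighbour assignment, then ordered by angle around each frame's
#' own centroid. Rearrangement is called when the cyclic order of identities
#' changes — rigid translations of the whole cluster preserve the order and
#' are not rearrangements. With unequal counts, the matched common subset is
#' compared and a message is emitted.
#'
#' @param nuclei_t,nuclei_t1 Data frames (or matrices) of nucleus positions
#'   with columns `x_um`, `y_um` (or two unnamed columns), at frames t and
#'   t + 1.
#' @param centroid_t,centroid_t1 Optional `c(x, y)` cluster centroids; default
#'   is the mean nucleus position of each frame.
#' @return `TRUE` if the circular order changed.
#' @export
detect_rearrangement <- function(nuclei_t, nuclei_t1,
                                 centroid_t = NULL, centroid_t1 = NULL) {
  as_xy <- function(p) {
    if (is.data.frame(p)) {
      if (all(c("x_um", "y_um") %in% names(p)))
        return(cbind(p$x_um, p$y_um))
      return(as.matrix(p[, 1:2]))
    }
    as.matrix(p)[, 1:2, drop = FALSE]
  }
  a <- as_xy(nuclei_t); b <- as_xy(nuclei_t1)
  if (nrow(a) < 3L || nrow(b) < 3L)
    stop("need at least three nuclei per frame to define a circular order")
  if (nrow(a) != nrow(b))
    message(sprintf(
      "nucleus counts differ (%d vs %d); comparing the matched subset",
      nrow(a), nrow(b)))
  m <- .greedy_match(a, b)
  matched <- which(!is.na(m))
  a <- a[matched, , drop = FALSE]
  b <- b[m[matched], , drop = FALSE]
  if (is.null(centroid_t)) centroid_t <- colMeans(a)
  if (is.null(centroid_t1)) centroid_t1 <- colMeans(b)
  ang <- function(p, c0) atan2(-(p[, 2] - c0[[2]]), p[, 1] - c0[[1]]) %% (2 * pi)
  ord_a <- order(ang(a, centroid_t))
  ord_b <- order(ang(b, centroid_t1))
  # identities listed in angular order; compare as cyclic sequences
  seq_a <- matched[ord_a]
  seq_b <- matched[ord_b]
  n <- length(seq_a)
  for (s in 0:(n - 1)) {
    if (all(seq_b == seq_a[((seq_len(n) - 1L + s) %% n) + 1L]))
      return(FALSE)
  }
  TRUE
}

#' Tumbling index of a movie
#'
#' A frame counts as tumbling when the cluster is rounded *and* its nuclei
#' are rearranged, and the frame belongs to a run of at least two consecutive
#' such frames — transient single-frame events are excluded. The index is the
#' percentage of tumbling frames among the frames of the first half of
#' migration (by default the first `ceiling(T/2)` frames of the movie).
#'
#' @param rounded,rearranged Logical vectors, one entry per frame.
#' @param first_half Integer vector of frame indices defining the first half
#'   of migration; default `1:ceiling(T/2)`.
#' @return Percent of first-half frames that are tumbling, in `[0, 100]`.
#' @export
tumbling_index <- function(rounded, rearranged, first_half = NULL) {
  stopifnot(length(rounded) == length(rearranged))
  n <- length(rounded)
  if (is.null(first_half)) first_half <- seq_len(ceiling(n / 2))
  if (length(first_half) == 0L) stop("`first_half` must be nonempty")
  qual <- rounded & rearranged
  runs <- rle(qual)
  in_run2 <- inverse.rle(list(lengths = runs$lengths,
                              values = runs$values & runs$lengths >= 2))
  100 * sum(in_run2[first_half]) / length(first_half)
}

#' Analyze a border cell time-lapse movie end to end
#'
#' Runs the full motility pipeline on an oriented GFP movie: per-frame
#' cluster thresholding, body/extension splitting, sector classification of
#' extensions, centroid tracking, roundness, nucleus detection and
#' rearrangement calls, then the summary metrics (forward speed, tumbling
#' index, per-sector percentages). A frame is flagged rearranged when either
#' adjacent frame transition shows a change in the circular nucleus order, so
#' a continuous tumbling episode marks every frame it spans.
#'
#' @param stack An [image_stack()] of oriented single-channel frames.
#' @param threshold_method,threshold_value Passed to [threshold_cluster()].
#' @param opening_radius,min_extension_area Passed to
#'   [split_body_extensions()].
#' @param circularity_threshold Roundness at or above which a frame counts as
#'   rounded (default 0.85).
#' @param nucleus_min_separation Minimum nucleus spacing in um for
#'   [detect_nuclei()].
#' @param first_half Frame indices treated as the first half of migration
#'   (default the first `ceiling(T/2)` frames).
#' @return A `bc_movie_analysis` list: `track`, `extensions`, `sector`
#'   (from [sector_summary()]), `roundness`, `rounded`, `rearranged`,
#'   `n_nuclei`, `forward_speed_um_min`, `tumbling_index_pct`.
#' @export
analyze_movie <- function(stack,
                          threshold_method = "otsu", threshold_value = NULL,
                          opening_radius = NULL, min_extension_area = 2,
                          circularity_threshold = 0.85,
                          nucleus_min_separation = 2,
                          first_half = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  n <- length(stack$frames)
  px_size <- stack$frames[[1]]$pixel_size
  masks <- vector("list", n)
  ext_tabs <- vector("list", n)
  round_vals <- numeric(n)
  nuclei <- vector("list", n)
  for (t in seq_len(n)) {
    img <- stack$frames[[t]]
    full <- threshold_cluster(img, method = threshold_method,
                              value = threshold_value)
    seg <- split_body_extensions(full, px_size,
                                 opening_radius = opening_radius,
                                 min_extension_area = min_extension_area)
    masks[[t]] <- full
    ext_tabs[[t]] <- frame_extensions(seg, frame = t)
    round_vals[t] <- roundness(full)
    nuclei[[t]] <- detect_nuclei(img, seg$body_mask,
                                 min_separation = nucleus_min_separation)
  }
  extensions <- do.call(rbind, ext_tabs)
  track <- track_centroid(masks, px_size, stack$frame_interval)
  trans <- logical(n)  # trans[t]: rearrangement between frames t-1 and t
  for (t in 2:n) {
    trans[t] <- tryCatch(
      detect_rearrangement(nuclei[[t - 1L]], nuclei[[t]]),
      error = function(e) FALSE)
  }
  rearranged <- trans | c(trans[-1], FALSE)
  rounded <- round_vals >= circularity_threshold
  if (is.null(first_half)) first_half <- seq_len(ceiling(n / 2))
  structure(list(
    track = track,
    extensions = extensions,
    sector = sector_summary(extensions),
    roundness = round_vals,
    rounded = rounded,
    rearranged = rearranged,
    n_nuclei = vapply(nuclei, nrow, integer(1)),
    forward_speed_um_min = forward_speed(track),
    tumbling_index_pct = tumbling_index(rounded, rearranged, first_half)
  ), class = "bc_movie_analysis")
}

#' @export
print.bc_movie_analysis <- function(x, ...) {
  cat("<bc_movie_analysis>\n")
  cat(sprintf("  frames: %d, extensions: %d\n",
              nrow(x$track), nrow(x$extensions)))
  cat(sprintf("  forward speed: %.3f um/min\n", x$forward_speed_um_min))
  cat(sprintf("  tumbling index: %.1f%%\n", x$tumbling_index_pct))
  pct <- x$sector$by_sector
  cat(sprintf("  sector %%: front %.1f / side %.1f / back %.1f\n",
              pct$percent[pct$sector == "front"],
              pct$percent[pct$sector == "side"],
              pct$percent[pct$sector == "back"]))
  invisible(x)
}
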