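#' Specification of a synthetic border cell cluster
#'
#' Describes the imaged cluster emulated by the generators: a bright body
#' disk bearing nuclear spots, over background, blurred by a Gaussian point
#' spread function and corrupted by additive Gaussian noise. The defaults
#' approximate a 20x confocal acquisition of a stage-9 egg chamber: 0.62
#' um/px calibration, a cluster of ~18 um diameter with six nuclei, and a
#' signal-to-background ratio typical of a good GFP labelling.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param body_radius Cluster body radius in um.
#' @param centroid_xy Initial cluster centre `c(x, y)` in um.
#' @param n_nuclei Number of nuclei (>= 1).
#' @param intensity_fg,intensity_bg Foreground/background intensity
#'   (arbitrary units, `intensity_fg > intensity_bg >= 0`).
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param psf_sigma Gaussian blur sigma in um (0 disables blurring).
#' @return A `cluster_spec` list.
#' @export
cluster_spec <- function(image_shape = c(160L, 160L), pixel_size = 0.62,
                         body_radius = 9, centroid_xy = c(30, 50),
                         n_nuclei = 6L, intensity_fg = 200,
                         intensity_bg = 20, noise_sd = 6, psf_sigma = 0.8) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16),
            pixel_size > 0, body_radius > 0, n_nuclei >= 1,
            intensity_fg > intensity_bg, intensity_bg >= 0,
            noise_sd >= 0, psf_sigma >= 0)
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, body_radius = body_radius,
                 centroid_xy = centroid_xy, n_nuclei = as.integer(n_nuclei),
                 intensity_fg = intensity_fg, intensity_bg = intensity_bg,
                 noise_sd = noise_sd, psf_sigma = psf_sigma),
            class = "cluster_spec")
}

#' Specification of synthetic protrusions
#'
#' Protrusions (cellular extensions) are lobes attached to the cluster body,
#' with sectors drawn from configurable front/side/back weights and angles
#' uniform within the drawn sector. The default weights give the front bias
#' characteristic of healthy migrating clusters (54% front); lengths and
#' widths are drawn uniformly from the given ranges.
#'
#' @param sector_weights Named or positional probabilities
#'   `c(front, side, back)`, summing to 1.
#' @param n_per_frame Mean number of protrusions per frame (Poisson).
#' @param length_um,width_um Length/width ranges in um (`c(min, max)`).
#' @param explicit_angles_deg Optional vector of angles; when given, exactly
#'   these protrusions are rendered (deterministically, with mid-range
#'   length and width) and no sampling occurs.
#' @return A `protrusion_spec` list.
#' @export
protrusion_spec <- function(sector_weights = c(front = 0.54, side = 0.30,
                                               back = 0.16),
                            n_per_frame = 2, length_um = c(4, 8),
                            width_um = c(2, 3.5),
                            explicit_angles_deg = NULL) {
  stopifnot(length(sector_weights) == 3L,
            abs(sum(sector_weights) - 1) < 1e-8, all(sector_weights >= 0),
            all(length_um > 0), all(width_um > 0), n_per_frame >= 0)
  names(sector_weights) <- c("front", "side", "back")
  structure(list(sector_weights = sector_weights, n_per_frame = n_per_frame,
                 length_um = range(length_um), width_um = range(width_um),
                 explicit_angles_deg = explicit_angles_deg),
            class = "protrusion_spec")
}

#' Specification of synthetic cluster motion
#'
#' @param forward_speed Forward (posterior-directed, +x) speed in um/min.
#' @param frame_interval Minutes per frame (default 3, the standard
#'   time-lapse acquisition interval for egg chamber culture).
#' @param n_frames Number of frames (>= 2).
#' @param tumbling_frames Integer vector of 1-based frame indices rendered as
#'   tumbling: rounded (protrusion-suppressed) body with nuclei rearranged
#'   relative to the previous frame.
#' @param jitter_sd Per-frame centroid jitter standard deviation in um.
#' @return A `motion_spec` list.
#' @export
motion_spec <- function(forward_speed = 0.45, frame_interval = 3,
                        n_frames = 20L, tumbling_frames = integer(0),
                        jitter_sd = 0) {
  stopifnot(frame_interval > 0, n_frames >= 2, jitter_sd >= 0)
  tumbling_frames <- as.integer(tumbling_frames)
  if (length(tumbling_frames) &&
      (min(tumbling_frames) < 1L || max(tumbling_frames) > n_frames))
    stop("`tumbling_frames` must lie within 1..n_frames")
  structure(list(forward_speed = forward_speed,
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 tumbling_frames = tumbling_frames, jitter_sd = jitter_sd),
            class = "motion_spec")
}

#' Maximal-tumbling motion preset
#'
#' Every frame of the first half of the movie tumbles, with the slow forward
#' speed measured for tumbling mutant clusters (0.09 um/min); such a movie
#' scores a tumbling index of 100%.
#'
#' @param n_frames Number of frames (default 20).
#' @param forward_speed Forward speed in um/min (default 0.09).
#' @return A `motion_spec`.
#' @export
motion_spec_max_tumbling <- function(n_frames = 20L, forward_speed = 0.09) {
  motion_spec(forward_speed = forward_speed, n_frames = n_frames,
              tumbling_frames = seq_len(ceiling(n_frames / 2)),
              jitter_sd = 0)
}

# run expr with a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Sample protrusion geometries from a protrusion specification
#'
#' Draws sectors from the front/side/back weights, angles uniformly within
#' the drawn sector, and lengths/widths uniformly from their ranges. Angles
#' are re-drawn so that no two protrusions of one draw lie within
#' `min_separation_deg` of each other (keeping rendered lobes disjoint).
#'
#' @param protrusions A [protrusion_spec()].
#' @param n Number of protrusions to draw.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @param min_separation_deg Minimum angular separation between draws.
#' @return Data frame: `sector`, `angle_deg`, `length_um`, `width_um`.
#' @export
sample_protrusions <- function(protrusions, n, seed = NULL,
                               min_separation_deg = 25) {
  stopifnot(inherits(protrusions, "protrusion_spec"))
  if (!is.null(seed)) return(.with_seed(seed, sample_protrusions(
    protrusions, n, NULL, min_separation_deg)))
  draw_angle <- function(sector) {
    switch(sector,
      front = runif(1, -45, 45) %% 360,
      side  = if (runif(1) < 0.5) runif(1, 45, 135) else runif(1, 225, 315),
      back  = runif(1, 135, 225))
  }
  circ_dist <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  sectors <- character(n); angles <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      s <- sample(c("front", "side", "back"), 1,
                  prob = protrusions$sector_weights)
      a <- draw_angle(s)
      if (i == 1L || all(circ_dist(a, angles[seq_len(i - 1L)]) >=
                         min_separation_deg)) break
    }
    sectors[i] <- s; angles[i] <- a
  }
  data.frame(sector = sectors, angle_deg = angles,
             length_um = runif(n, protrusions$length_um[1],
                               protrusions$length_um[2]),
             width_um = runif(n, protrusions$width_um[1],
                              protrusions$width_um[2]))
}

# nucleus slot layout: n_nuclei + 2 angular slots on a common orbit
.nucleus_slots <- function(cluster) {
  n_slots <- cluster$n_nuclei + 2L
  list(n_slots = n_slots,
       slot_angles = (seq_len(n_slots) - 1L) * 360 / n_slots,
       orbit = 0.5 * cluster$body_radius)
}

# nucleus positions (um) for a slot assignment and cluster centre
.nucleus_positions <- function(slots, assignment, centre) {
  ang <- slots$slot_angles[assignment] * pi / 180
  data.frame(x_um = centre[1] + slots$orbit * cos(ang),
             y_um = centre[2] - slots$orbit * sin(ang))
}

.cyclic_equal <- function(a, b) {
  n <- length(a)
  if (length(b) != n) return(FALSE)
  for (s in 0:(n - 1)) {
    if (all(b == a[((seq_len(n) - 1L + s) %% n) + 1L])) return(TRUE)
  }
  FALSE
}

# relocate one nucleus to a vacant slot so the cyclic order changes;
# returns the new assignment (uses the current RNG stream)
.rearrange_assignment <- function(slots, assignment) {
  order_of <- function(asgn) order(slots$slot_angles[asgn])
  before <- order_of(assignment)
  vacant <- setdiff(seq_len(slots$n_slots), assignment)
  for (try in 1:100) {
    mover <- sample(seq_along(assignment), 1)
    target <- if (length(vacant) == 1L) vacant else sample(vacant, 1)
    cand <- assignment
    cand[mover] <- target
    if (!.cyclic_equal(before, order_of(cand))) return(cand)
  }
  stop("could not generate an order-changing rearrangement")
}

# rasterize one frame: body disk + protrusion lobes + nuclei, blur, noise
# protr: data.frame(angle_deg, length_um, width_um); may have zero rows
.render_frame <- function(cluster, protr, nuclei_xy, centre) {
  H <- cluster$image_shape[1]; W <- cluster$image_shape[2]
  px <- cluster$pixel_size
  X <- matrix(.px_to_um(seq_len(W), px), H, W, byrow = TRUE)
  Y <- matrix(.px_to_um(seq_len(H), px), H, W)
  dx <- X - centre[1]; dy <- Y - centre[2]
  body <- dx^2 + dy^2 <= cluster$body_radius^2
  ext_masks <- list()
  if (nrow(protr) > 0) {
    for (k in seq_len(nrow(protr))) {
      th <- protr$angle_deg[k] * pi / 180
      L <- protr$length_um[k]; Wd <- protr$width_um[k]
      tip <- centre + (cluster$body_radius + L) * c(cos(th), -sin(th))
      if (tip[1] < 0 || tip[1] > W * px || tip[2] < 0 || tip[2] > H * px)
        stop(sprintf(
          "protrusion at %.0f deg (length %.1f um) exceeds the image extent",
          protr$angle_deg[k], L))
      u <- dx * cos(th) - dy * sin(th)
      v <- dx * sin(th) + dy * cos(th)
      lobe <- u >= 0.5 * cluster$body_radius &
              u <= cluster$body_radius + L & abs(v) <= Wd / 2
      ext_masks[[k]] <- lobe & !body
    }
  }
  full <- Reduce(`|`, ext_masks, body)
  field <- (cluster$intensity_fg - cluster$intensity_bg) * full
  if (nrow(nuclei_xy) > 0) {
    amp <- 0.9 * cluster$intensity_fg
    sig <- 0.7  # nucleus spot sigma, um
    for (k in seq_len(nrow(nuclei_xy))) {
      d2 <- (X - nuclei_xy$x_um[k])^2 + (Y - nuclei_xy$y_um[k])^2
      field <- field + amp * exp(-d2 / (2 * sig^2))
    }
  }
  if (cluster$psf_sigma > 0) {
    sig_px <- cluster$psf_sigma / px
    field <- as.matrix(EBImage::gblur(EBImage::Image(field), sigma = sig_px))
  }
  img <- cluster$intensity_bg + field
  if (cluster$noise_sd > 0)
    img <- img + matrix(rnorm(H * W, 0, cluster$noise_sd), H, W)
  img <- pmax(img, 0)
  list(image = img, body_mask = body, ext_masks = ext_masks,
       full_mask = full)
}

#' Generate a fixed (single-frame) synthetic cluster image
#'
#' Renders background + blurred body disk + blurred protrusion lobes +
#' nuclear spots + Gaussian noise, and returns the image together with exact
#' (pre-blur, pre-noise) ground-truth masks and protrusion annotations.
#' Output is deterministic for a given seed, and the truth is independent of
#' the seed entirely when `explicit_angles_deg` is given.
#'
#' @param cluster A [cluster_spec()].
#' @param protrusions A [protrusion_spec()].
#' @param seed Integer seed for all randomness.
#' @return List with `image` (a [calibrated_image()], oriented anterior-left)
#'   and `truth` (list: `extensions` data frame with `sector`, `angle_deg`,
#'   `area_um2`; `body_mask`; `full_mask`; `ext_masks`; `nuclei`;
#'   `centroid_xy`).
#' @export
make_fixed_cluster_image <- function(cluster, protrusions, seed = 1L) {
  stopifnot(inherits(cluster, "cluster_spec"),
            inherits(protrusions, "protrusion_spec"))
  .with_seed(seed, {
    protr <- if (!is.null(protrusions$explicit_angles_deg)) {
      a <- protrusions$explicit_angles_deg
      data.frame(sector = classify_sector(a), angle_deg = a,
                 length_um = mean(protrusions$length_um),
                 width_um = mean(protrusions$width_um))
    } else {
      n <- rpois(1, protrusions$n_per_frame)
      sample_protrusions(protrusions, n)
    }
    slots <- .nucleus_slots(cluster)
    assignment <- seq_len(cluster$n_nuclei)
    nuclei <- .nucleus_positions(slots, assignment, cluster$centroid_xy)
    fr <- .render_frame(cluster, protr, nuclei, cluster$centroid_xy)
    truth_ext <- if (nrow(protr) > 0) {
      data.frame(protr,
                 area_um2 = vapply(fr$ext_masks, sum, numeric(1)) *
                   cluster$pixel_size^2)
    } else cbind(protr, area_um2 = numeric(0))
    list(image = calibrated_image(fr$image, cluster$pixel_size,
                                  oriented_anterior_left = TRUE),
         truth = list(extensions = truth_ext, body_mask = fr$body_mask,
                      full_mask = fr$full_mask, ext_masks = fr$ext_masks,
                      nuclei = nuclei, centroid_xy = cluster$centroid_xy))
  })
}

#' Generate a synthetic time-lapse movie of a migrating cluster
#'
#' The cluster centre advances along +x by `forward_speed * frame_interval`
#' per frame (plus optional jitter). Frames listed in `tumbling_frames`
#' render a rounded, protrusion-suppressed body whose nuclei have been
#' rearranged relative to the previous frame (one nucleus relocated to a
#' vacant angular slot such that the circular nucleus order changes); all
#' other frames carry freshly sampled protrusions.
#'
#' @param cluster A [cluster_spec()]; `centroid_xy` is the frame-1 position.
#' @param protrusions A [protrusion_spec()].
#' @param motion A [motion_spec()].
#' @param seed Integer seed for all randomness.
#' @return List with `stack` (an [image_stack()]) and `truth` (list: `track`
#'   data frame of exact centres, `tumbling` logical flags, `rearranged`
#'   per-transition flags, per-frame `extensions`, `nuclei`, `body_masks`,
#'   `full_masks`).
#' @export
make_timelapse <- function(cluster, protrusions, motion, seed = 1L) {
  stopifnot(inherits(cluster, "cluster_spec"),
            inherits(protrusions, "protrusion_spec"),
            inherits(motion, "motion_spec"))
  .with_seed(seed, {
    n <- motion$n_frames
    px <- cluster$pixel_size
    H <- cluster$image_shape[1]; W <- cluster$image_shape[2]
    step <- motion$forward_speed * motion$frame_interval
    centres <- matrix(NA_real_, n, 2)
    for (t in seq_len(n)) {
      jit <- if (motion$jitter_sd > 0) rnorm(2, 0, motion$jitter_sd)
             else c(0, 0)
      centres[t, ] <- cluster$centroid_xy + c(step * (t - 1L), 0) + jit
    }
    margin <- cluster$body_radius + max(protrusions$length_um)
    for (t in seq_len(n)) {
      if (centres[t, 1] - margin < 0 || centres[t, 1] + margin > W * px ||
          centres[t, 2] - margin < 0 || centres[t, 2] + margin > H * px)
        stop(sprintf("track leaves the image frame at frame %d", t))
    }
    tumbling <- seq_len(n) %in% motion$tumbling_frames
    slots <- .nucleus_slots(cluster)
    assignment <- seq_len(cluster$n_nuclei)
    frames <- vector("list", n)
    ext_list <- vector("list", n)
    nuc_list <- vector("list", n)
    body_masks <- vector("list", n)
    full_masks <- vector("list", n)
    rearranged <- logical(n)  # rearranged[t]: permuted between t-1 and t
    for (t in seq_len(n)) {
      if (tumbling[t] && t > 1L) {
        assignment <- .rearrange_assignment(slots, assignment)
        rearranged[t] <- TRUE
      }
      protr <- if (tumbling[t]) {
        data.frame(sector = character(0), angle_deg = numeric(0),
                   length_um = numeric(0), width_um = numeric(0))
      } else if (!is.null(protrusions$explicit_angles_deg)) {
        a <- protrusions$explicit_angles_deg
        data.frame(sector = classify_sector(a), angle_deg = a,
                   length_um = mean(protrusions$length_um),
                   width_um = mean(protrusions$width_um))
      } else {
        sample_protrusions(protrusions, rpois(1, protrusions$n_per_frame))
      }
      nuclei <- .nucleus_positions(slots, assignment, centres[t, ])
      fr <- .render_frame(cluster, protr, nuclei, centres[t, ])
      frames[[t]] <- calibrated_image(fr$image, px,
                                      oriented_anterior_left = TRUE)
      ext_list[[t]] <- if (nrow(protr) > 0)
        data.frame(frame = t, protr,
                   area_um2 = vapply(fr$ext_masks, sum, numeric(1)) * px^2)
      else NULL
      nuc_list[[t]] <- nuclei
      body_masks[[t]] <- fr$body_mask
      full_masks[[t]] <- fr$full_mask
    }
    extensions <- do.call(rbind, ext_list)
    if (is.null(extensions))
      extensions <- data.frame(frame = integer(), sector = character(),
                               angle_deg = numeric(), length_um = numeric(),
                               width_um = numeric(), area_um2 = numeric())
    list(stack = image_stack(frames, motion$frame_interval),
         truth = list(
           track = data.frame(frame = seq_len(n), x_um = centres[, 1],
                              y_um = centres[, 2]),
           tumbling = tumbling, rearranged = rearranged,
           extensions = extensions, nuclei = nuc_list,
           body_masks = body_masks, full_masks = full_masks))
  })
}

#' Write a ground-truth sidecar as JSON
#'
#' Serializes the scalar/tabular parts of a generator truth record (masks are
#' omitted; they are reproducible from the seed) next to an image file.
#'
#' @param truth A truth list from one of the generators.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  keep <- truth[!vapply(truth, function(x)
    is.matrix(x) || (is.list(x) && !is.data.frame(x)), logical(1))]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
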