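#' Replicate-level descriptive summary
#'
#' Summarizes measurements grouped by biological replicate the way
#' "SuperPlot"-style figures report them: per-replicate means, the grand
#' mean of the replicate means, and the SEM of the replicate means
#' (`sd / sqrt(n_replicates)`, `NA` for a single replicate).
#'
#' @param values Data frame with columns `replicate_id` and `value`, or a
#'   numeric vector together with `replicate_id`.
#' @param replicate_id Replicate labels when `values` is a vector.
#' @return A `replicate_summary` list: `per_replicate` (data frame
#'   `replicate_id`, `n`, `mean`), `grand_mean`, `sem`, `n_replicates`.
#' @export
summarize_replicates <- function(values, replicate_id = NULL) {
  if (is.data.frame(values)) {
    stopifnot(all(c("replicate_id", "value") %in% names(values)))
    df <- values
  } else {
    stopifnot(!is.null(replicate_id), length(values) == length(replicate_id))
    df <- data.frame(replicate_id = replicate_id, value = values)
  }
  if (nrow(df) == 0L) stop("need at least one measurement")
  per <- aggregate(list(mean = df$value),
                   by = list(replicate_id = df$replicate_id), FUN = mean)
  per$n <- as.integer(table(df$replicate_id)[as.character(per$replicate_id)])
  per <- per[, c("replicate_id", "n", "mean")]
  k <- nrow(per)
  structure(list(per_replicate = per,
                 grand_mean = mean(per$mean),
                 sem = if (k > 1L) sd(per$mean) / sqrt(k) else NA_real_,
                 n_replicates = k),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("<replicate_summary> %d replicate(s): mean %.3f +/- %s (SEM)\n",
              x$n_replicates, x$grand_mean,
              if (is.na(x$sem)) "NA" else sprintf("%.3f", x$sem)))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("inputs must have nonzero variance")
  cor(x, y, method = "pearson")
}

.default_config <- function() {
  list(
    seed = 1L,
    outdir = ".",
    calibration = list(pixel_size_um = 0.62, frame_interval_min = 3),
    movie = list(n_frames = 20L, forward_speed_um_min = 0.45,
                 jitter_sd_um = 0, tumbling_frames = integer(0),
                 n_protrusions_per_frame = 2,
                 sector_weights = c(front = 0.54, side = 0.30, back = 0.16)),
    segmentation = list(threshold_method = "otsu",
                        min_extension_area_um2 = 2),
    tumbling = list(circularity_threshold = 0.85)
  )
}

#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML or JSON with the sections `seed`, `outdir`,
#' `calibration`, `movie`, `segmentation` and `tumbling`; omitted keys take
#' their defaults, unknown keys are rejected, and physical parameters must
#' be positive.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file, or a named
#'   list already in memory.
#' @return Validated config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path
         else if (grepl("\\.json$", path, ignore.case = TRUE))
           jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  def <- .default_config()
  merge_section <- function(user, default, where) {
    if (is.null(user)) return(default)
    unknown <- setdiff(names(user), names(default))
    if (length(unknown))
      stop(sprintf("unknown config key%s in %s: %s",
                   if (length(unknown) > 1) "s" else "", where,
                   paste(unknown, collapse = ", ")))
    for (k in names(user)) default[[k]] <- user[[k]]
    default
  }
  top_unknown <- setdiff(names(cfg), names(def))
  if (length(top_unknown))
    stop("unknown config key: ", paste(top_unknown, collapse = ", "))
  out <- def
  for (sec in c("calibration", "movie", "segmentation", "tumbling"))
    out[[sec]] <- merge_section(cfg[[sec]], def[[sec]], sec)
  if (!is.null(cfg$seed)) out$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$outdir)) out$outdir <- cfg$outdir
  for (key in c("pixel_size_um", "frame_interval_min")) {
    if (out$calibration[[key]] <= 0)
      stop(sprintf("config error: calibration$%s must be > 0", key))
  }
  # normalize containers so configs round-trip through YAML/JSON
  out$movie$n_frames <- as.integer(out$movie$n_frames)
  out$movie$tumbling_frames <- as.integer(unlist(out$movie$tumbling_frames))
  if (out$movie$n_frames < 2) stop("config error: movie$n_frames must be >= 2")
  w <- unlist(out$movie$sector_weights)
  if (length(w) != 3L || abs(sum(w) - 1) > 1e-6)
    stop("config error: movie$sector_weights must be 3 values summing to 1")
  names(w) <- c("front", "side", "back")
  out$movie$sector_weights <- w
  class(out) <- c("run_config", "list")
  out
}

#' Serialize a run configuration
#'
#' @param config A `run_config`.
#' @param path Output `.yaml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the simulate-segment-measure pipeline
#'
#' Generates a synthetic movie per the configuration, runs the full motility
#' analysis, and writes `extensions.csv`, `track.csv`, `summary.json` and a
#' provenance log (parameters, seed, package version) into the output
#' directory. Reruns with the same configuration are bit-identical.
#'
#' @param config A config list/path accepted by [read_run_config()].
#' @return The [analyze_movie()] result, invisibly, with the written paths
#'   in attribute `paths`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  cl <- cluster_spec(pixel_size = cfg$calibration$pixel_size_um)
  pr <- protrusion_spec(
    sector_weights = unlist(cfg$movie$sector_weights),
    n_per_frame = cfg$movie$n_protrusions_per_frame)
  mo <- motion_spec(forward_speed = cfg$movie$forward_speed_um_min,
                    frame_interval = cfg$calibration$frame_interval_min,
                    n_frames = cfg$movie$n_frames,
                    tumbling_frames = cfg$movie$tumbling_frames,
                    jitter_sd = cfg$movie$jitter_sd_um)
  sim <- make_timelapse(cl, pr, mo, seed = cfg$seed)
  res <- analyze_movie(
    sim$stack,
    threshold_method = cfg$segmentation$threshold_method,
    min_extension_area = cfg$segmentation$min_extension_area_um2,
    circularity_threshold = cfg$tumbling$circularity_threshold)
  ext_path <- file.path(cfg$outdir, "extensions.csv")
  write.csv(res$extensions, ext_path, row.names = FALSE)
  track_path <- file.path(cfg$outdir, "track.csv")
  write.csv(as.data.frame(res$track), track_path, row.names = FALSE)
  pct <- res$sector$by_sector
  summary <- list(
    forward_speed_um_per_min = round(res$forward_speed_um_min, 6),
    tumbling_index_pct = round(res$tumbling_index_pct, 6),
    sector_pct = list(
      front = round(pct$percent[pct$sector == "front"], 6),
      side = round(pct$percent[pct$sector == "side"], 6),
      back = round(pct$percent[pct$sector == "back"], 6)),
    n_extensions = nrow(res$extensions),
    n_frames = cfg$movie$n_frames)
  sum_path <- file.path(cfg$outdir, "summary.json")
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  prov_path <- file.path(cfg$outdir, "provenance.log")
  writeLines(c(
    sprintf("bordercell %s", as.character(utils::packageVersion("bordercell"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("config: %s",
            jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))),
    prov_path)
  attr(res, "paths") <- c(extensions = ext_path, track = track_path,
                          summary = sum_path, provenance = prov_path)
  invisible(res)
}
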