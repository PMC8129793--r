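#' Generate a synthetic line-scan intensity profile
#'
#' Builds a 1-D profile emulating a line scan through a cluster: a flat
#' baseline plus three Gaussian peaks at the centres of the back, middle and
#' front thirds of the cluster extent, whose analytic areas are in the
#' requested back/middle/front ratios. A zero target fraction omits the
#' corresponding peak.
#'
#' @param target_bmf Back/middle/front area fractions, summing to 1.
#' @param peak_sigma Peak sigma(s) in um (recycled to 3).
#' @param n_points Number of sample positions.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param seed Integer seed.
#' @param cluster_extent Cluster length along the scan in um.
#' @param margin Baseline margin on each side of the cluster in um.
#' @param baseline Baseline intensity.
#' @param total_area Total analytic peak area (units x um).
#' @return List with `profile` (a `line_profile`: data frame `position_um`,
#'   `intensity`) and `truth` (peak positions, analytic areas, fractions,
#'   `cluster_extent` as `c(start, end)` um, and `overlap_warning` when peaks
#'   are closer than four sigma).
#' @export
make_line_profile <- function(target_bmf = c(0.4, 0.2, 0.4),
                              peak_sigma = 1.5, n_points = 240,
                              noise_sd = 0, seed = 1L,
                              cluster_extent = 24, margin = 4,
                              baseline = 5, total_area = 300) {
  stopifnot(length(target_bmf) == 3L, abs(sum(target_bmf) - 1) < 1e-8,
            all(target_bmf >= 0), n_points >= 20, cluster_extent > 0)
  sig <- rep_len(peak_sigma, 3L)
  L <- cluster_extent + 2 * margin
  pos <- seq(0, L, length.out = n_points)
  centers <- margin + cluster_extent * c(1, 3, 5) / 6
  if (any(centers - 3 * sig < 0) || any(centers + 3 * sig > L))
    stop("peaks do not fit within the profile; reduce `peak_sigma`")
  areas <- total_area * target_bmf
  amp <- ifelse(areas > 0, areas / (sig * sqrt(2 * pi)), 0)
  y <- rep(baseline, n_points)
  for (k in 1:3) {
    if (amp[k] > 0)
      y <- y + amp[k] * exp(-(pos - centers[k])^2 / (2 * sig[k]^2))
  }
  present <- which(areas > 0)
  overlap_warning <- FALSE
  if (length(present) > 1L) {
    gaps <- diff(centers[present])
    need <- 2 * (sig[present][-length(present)] + sig[present][-1])
    overlap_warning <- any(gaps < need)
  }
  if (noise_sd > 0)
    y <- .with_seed(seed, y + rnorm(n_points, 0, noise_sd))
  y <- pmax(y, 0)
  profile <- structure(data.frame(position_um = pos, intensity = y),
                       scan_width = NA_integer_,
                       class = c("line_profile", "data.frame"))
  list(profile = profile,
       truth = list(peak_positions = centers, peak_areas = areas,
                    fractions_pct = 100 * target_bmf,
                    cluster_extent = c(margin, margin + cluster_extent),
                    baseline = baseline,
                    overlap_warning = overlap_warning))
}

#' Generate a synthetic mosaic-cluster image
#'
#' Emulates a genetically mosaic cluster: two labelled sibling regions
#' (half-disks of a common cluster disk) whose mean intensities differ by a
#' known fold, plus additive Gaussian noise. The control (brighter) region is
#' on the left.
#'
#' @param fold Intensity fold between control and test regions (>= 1 puts
#'   the reduction in the test region).
#' @param seed Integer seed.
#' @param image_shape `c(rows, cols)` pixels.
#' @param pixel_size Micrometres per pixel.
#' @param radius Cluster disk radius in um.
#' @param intensity_control Mean intensity of the control region.
#' @param intensity_bg Background intensity outside the cluster.
#' @param noise_sd Additive Gaussian noise SD. The region signal-to-noise
#'   ratio is `intensity_control / noise_sd`.
#' @return List with `image` (a [calibrated_image()]) and `truth` (list:
#'   `control_mask`, `test_mask`, `fold`, region intensities).
#' @export
make_mosaic <- function(fold, seed = 1L, image_shape = c(80L, 80L),
                        pixel_size = 0.62, radius = 12,
                        intensity_control = 150, intensity_bg = 0,
                        noise_sd = 0) {
  stopifnot(fold > 0, radius > 0, intensity_control > 0, noise_sd >= 0)
  H <- image_shape[1]; W <- image_shape[2]
  cx <- W * pixel_size / 2; cy <- H * pixel_size / 2
  X <- matrix(.px_to_um(seq_len(W), pixel_size), H, W, byrow = TRUE)
  Y <- matrix(.px_to_um(seq_len(H), pixel_size), H, W)
  disk <- (X - cx)^2 + (Y - cy)^2 <= radius^2
  control_mask <- disk & X < cx
  test_mask <- disk & X >= cx
  img <- matrix(intensity_bg, H, W)
  img[control_mask] <- intensity_control
  img[test_mask] <- intensity_control / fold
  if (noise_sd > 0)
    img <- .with_seed(seed, img + matrix(rnorm(H * W, 0, noise_sd), H, W))
  img <- pmax(img, 0)
  list(image = calibrated_image(img, pixel_size),
       truth = list(control_mask = control_mask, test_mask = test_mask,
                    fold = fold, intensity_control = intensity_control,
                    intensity_test = intensity_control / fold))
}

#' Generate a genomic fixture for promoter-assignment tests
#'
#' Produces random gene models (TSS and strand) and, per replicate, a set of
#' peaks with known promoter-window overlap status: a mix of peaks placed
#' inside a gene's promoter window, peaks touching a window edge (which under
#' half-open arithmetic do *not* overlap), and peaks placed uniformly at
#' random. The truth table is computed by brute-force all-pairs overlap
#' against the same window rule as [promoter_windows()].
#'
#' @param n_genes,n_peaks Number of genes, and peaks per replicate.
#' @param n_replicates Number of peak replicates (default 2).
#' @param seed Integer seed.
#' @param dir Directory to write `genes.tsv` and `peaks_rep<k>.bed` into;
#'   `NULL` writes nothing.
#' @param upstream,downstream Promoter window geometry in bases.
#' @return List with `genes` (data frame `gene_id`, `chrom`, `tss`,
#'   `strand`; `tss` 1-based), `peaks` (list of per-replicate data frames
#'   `chrom`, `start`, `end`, 0-based half-open), `files` (written paths or
#'   `NULL`) and `truth` (data frame `gene_id`, `replicate_id`,
#'   `n_peaks_overlapping`, `overlap`).
#' @export
make_promoter_fixture <- function(n_genes = 100L, n_peaks = 300L,
                                  n_replicates = 2L, seed = 1L, dir = NULL,
                                  upstream = 1000L, downstream = 200L) {
  stopifnot(n_genes >= 1, n_peaks >= 1, n_replicates >= 1)
  .with_seed(seed, {
    chroms <- c("chr2L", "chr2R", "chr3L")
    genes <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      chrom = sample(chroms, n_genes, replace = TRUE),
      tss = sample(5000:995000, n_genes, replace = TRUE),
      strand = sample(c("+", "-"), n_genes, replace = TRUE))
    win <- promoter_windows(genes, upstream = upstream,
                            downstream = downstream)
    make_rep <- function() {
      kind <- sample(c("inside", "edge", "random"), n_peaks, replace = TRUE,
                     prob = c(0.4, 0.2, 0.4))
      out <- data.frame(chrom = character(n_peaks), start = integer(n_peaks),
                        end = integer(n_peaks))
      for (i in seq_len(n_peaks)) {
        wlen <- sample(100:600, 1)
        if (kind[i] == "random") {
          out$chrom[i] <- sample(chroms, 1)
          out$start[i] <- sample(0:998000, 1)
        } else {
          g <- sample(n_genes, 1)
          out$chrom[i] <- win$chrom[g]
          if (kind[i] == "inside") {
            # start anywhere that guarantees >= 1 base of overlap
            out$start[i] <- sample(
              max(0L, win$start[g] - wlen + 1L):(win$end[g] - 1L), 1)
          } else {
            # touch an edge exactly: no overlap under half-open arithmetic
            out$start[i] <- if (runif(1) < 0.5) max(0L, win$start[g] - wlen)
                            else win$end[g]
          }
        }
        out$end[i] <- out$start[i] + wlen
      }
      out
    }
    peaks <- lapply(seq_len(n_replicates), function(k) make_rep())
    names(peaks) <- sprintf("rep%d", seq_len(n_replicates))
    # brute-force all-pairs truth
    truth <- do.call(rbind, lapply(seq_len(n_replicates), function(k) {
      pk <- peaks[[k]]
      n_ov <- vapply(seq_len(n_genes), function(g) {
        sum(pk$chrom == win$chrom[g] & pk$start < win$end[g] &
            pk$end > win$start[g])
      }, numeric(1))
      data.frame(gene_id = genes$gene_id, replicate_id = names(peaks)[k],
                 n_peaks_overlapping = as.integer(n_ov),
                 overlap = n_ov > 0)
    }))
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      gene_file <- file.path(dir, "genes.tsv")
      write.table(genes, gene_file, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      bed_files <- vapply(seq_len(n_replicates), function(k) {
        f <- file.path(dir, sprintf("peaks_rep%d.bed", k))
        bed <- data.frame(peaks[[k]],
                          name = sprintf("peak%04d", seq_len(n_peaks)))
        write.table(bed, f, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
        f
      }, character(1))
      files <- list(genes = gene_file, beds = bed_files)
    }
    list(genes = genes, peaks = peaks, files = files, truth = truth)
  })
}
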