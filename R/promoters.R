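#' Promoter window around a transcription start site
#'
#' Builds the promoter interval spanning `upstream` bases before to
#' `downstream` bases after the TSS (defaults -1000..+200), in the gene's
#' transcriptional orientation. Coordinates are 0-based half-open
#' internally; the TSS is taken 1-based. For a minus-strand gene the window
#' is mirrored so that "upstream" lies at higher genomic coordinates; with
#' `strand_aware = FALSE` the plus-strand geometry is applied regardless of
#' strand. Windows are clamped at the chromosome start.
#'
#' @param gene A one-row data frame (or list) with `gene_id`, `chrom`,
#'   `tss` (1-based), `strand` (`"+"` or `"-"`).
#' @param upstream,downstream Window extent in bases.
#' @param strand_aware Mirror the window for minus-strand genes
#'   (default `TRUE`).
#' @return List: `gene_id`, `chrom`, `start`, `end` (0-based half-open).
#' @export
promoter_window <- function(gene, upstream = 1000L, downstream = 200L,
                            strand_aware = TRUE) {
  w <- promoter_windows(as.data.frame(gene), upstream, downstream,
                        strand_aware)
  as.list(w[1, ])
}

#' Promoter windows for a gene table
#'
#' Vectorized form of [promoter_window()].
#'
#' @param genes Data frame with `gene_id`, `chrom`, `tss` (1-based),
#'   `strand`.
#' @inheritParams promoter_window
#' @return Data frame: `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @export
promoter_windows <- function(genes, upstream = 1000L, downstream = 200L,
                             strand_aware = TRUE) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "tss", "strand") %in% names(genes)))
  if (!all(genes$strand %in% c("+", "-")))
    stop("unknown strand value; must be '+' or '-'")
  if (any(genes$tss < 1)) stop("`tss` must be 1-based (>= 1)")
  t0 <- as.integer(genes$tss) - 1L  # 0-based TSS position
  plus <- genes$strand == "+" | !strand_aware
  start <- ifelse(plus, t0 - upstream, t0 - downstream + 1L)
  end <- ifelse(plus, t0 + downstream, t0 + upstream + 1L)
  start <- pmax(start, 0L)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = genes$strand)
}

#' Read a BED3+ file of peaks
#'
#' Parses the first three columns (chrom, start, end; 0-based half-open) and
#' validates each line, reporting the offending line number on error.
#'
#' @param path Path to a BED file.
#' @return Data frame: `chrom`, `start`, `end` (plus `name` when present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  keep <- !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t| +")[[1]]
    if (length(f) < 3L)
      stop(sprintf("malformed BED line %d: fewer than 3 fields", i))
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || s >= e)
      stop(sprintf("malformed BED line %d: bad interval [%s, %s)",
                   i, f[2], f[3]))
    out[[i]] <- data.frame(chrom = f[1], start = s, end = e,
                           name = if (length(f) >= 4L) f[4] else NA_character_)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character())
  res
}

#' Read a gene table (TSV or GTF)
#'
#' A TSV must have columns `gene_id`, `chrom`, `tss` (1-based), `strand`.
#' A GTF is reduced to its `gene` features, taking the TSS as the feature
#' start (plus strand) or end (minus strand); GTF parsing uses rtracklayer
#' when available.
#'
#' @param path Path to a `.tsv`/`.txt` gene table or a `.gtf` file.
#' @return Data frame: `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_gene_table <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF requires the rtracklayer package")
    gr <- as.data.frame(rtracklayer::import(path))
    gr <- gr[gr$type == "gene", ]
    strand <- as.character(gr$strand)
    if (any(!strand %in% c("+", "-")))
      stop("unknown strand value in GTF gene records")
    return(data.frame(
      gene_id = gr$gene_id,
      chrom = as.character(gr$seqnames),
      tss = ifelse(strand == "+", gr$start, gr$end),
      strand = strand))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(tab)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  tab[need]
}

#' Assign ChIP peaks to gene promoter windows
#'
#' Calls a gene promoter-bound in a replicate when any peak of that replicate
#' overlaps the gene's promoter window by at least one base (half-open
#' interval arithmetic on the same chromosome; a peak merely touching a
#' window edge does not overlap). A peak overlapping several windows counts
#' for every gene it hits. Overlap is computed with interval trees
#' (IRanges), so large fixtures remain fast; output order is by gene then
#' replicate, independent of peak input order.
#'
#' @param peaks Named list of per-replicate peak data frames (`chrom`,
#'   `start`, `end`, 0-based half-open) or BED file paths; an unnamed list
#'   gets `rep1`, `rep2`, ... identifiers.
#' @param genes Gene table data frame (see [read_gene_table()]) or a path.
#' @inheritParams promoter_window
#' @return Data frame: `gene_id`, `replicate_id`, `n_peaks_overlapping`,
#'   `overlap`.
#' @export
assign_peaks <- function(peaks, genes, upstream = 1000L, downstream = 200L,
                         strand_aware = TRUE) {
  if (is.character(genes)) genes <- read_gene_table(genes)
  if (is.data.frame(peaks)) peaks <- list(rep1 = peaks)
  peaks <- lapply(peaks, function(p) if (is.character(p)) read_bed(p) else p)
  if (is.null(names(peaks)) || any(!nzchar(names(peaks))))
    names(peaks) <- sprintf("rep%d", seq_along(peaks))
  win <- promoter_windows(genes, upstream, downstream, strand_aware)
  do.call(rbind, lapply(names(peaks), function(rep_id) {
    pk <- peaks[[rep_id]]
    n_ov <- integer(nrow(win))
    for (chr in unique(win$chrom)) {
      gi <- which(win$chrom == chr)
      pi <- which(pk$chrom == chr)
      if (!length(pi)) next
      # convert half-open 0-based to closed 1-based for IRanges
      qry <- IRanges::IRanges(start = win$start[gi] + 1L, end = win$end[gi])
      sbj <- IRanges::IRanges(start = pk$start[pi] + 1L, end = pk$end[pi])
      n_ov[gi] <- IRanges::countOverlaps(qry, sbj)
    }
    data.frame(gene_id = win$gene_id, replicate_id = rep_id,
               n_peaks_overlapping = n_ov, overlap = n_ov > 0)
  }))
}

#' Per-gene replicate binding counts
#'
#' Summarizes a peak-assignment table into, per gene, the number of
#' replicates in which at least one peak overlapped the promoter window,
#' out of the total number of replicates.
#'
#' @param assignments Output of [assign_peaks()].
#' @return Data frame: `gene_id`, `n_bound`, `N_replicates`.
#' @export
replicate_counts <- function(assignments) {
  stopifnot(all(c("gene_id", "replicate_id", "overlap") %in%
                names(assignments)))
  N <- length(unique(assignments$replicate_id))
  agg <- aggregate(list(n_bound = assignments$overlap),
                   by = list(gene_id = assignments$gene_id), FUN = sum)
  agg$n_bound <- as.integer(agg$n_bound)
  agg$N_replicates <- N
  agg[order(agg$gene_id), ]
}
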