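## ---------------------------------------------------------------------------
## Signal aggregation over gene windows
##
## The quantitative core: rank-normalize binned tracks, extend each gene to
## its window (transcribed region + 1 kb upstream + 500 bp downstream,
## strand-aware), sum ranked signal over the window with proportional overlap
## weighting, and pool member genes into per-set densities.
## ---------------------------------------------------------------------------

#' Rank-normalize a signal track
#'
#' Replaces every bin value by its genome-wide fractional rank in (0, 1]:
#' `rank(value) / N` with average ranks for ties, where N is the total bin
#' count across all chromosomes.  Order-preserving and invariant to any
#' monotone rescaling of the raw values, which makes densities comparable
#' across marks profiled at different depths.
#'
#' @param track a [signal_track()] object.
#' @return A `SignalTrack` with `ranked = TRUE`.
#' @export
rank_normalize <- function(track) {
  stopifnot(inherits(track, "SignalTrack"))
  if (!nrow(track$bins)) stop("cannot rank-normalize an empty track")
  b <- track$bins
  b$value <- rank(b$value, ties.method = "average") / nrow(b)
  signal_track(track$mark_name, b, ranked = TRUE)
}

#' Build strand-aware gene windows
#'
#' Each gene's window covers its transcribed region plus `upstream_bp`
#' upstream of the transcription start and `downstream_bp` past the
#' transcription end, on the strand-appropriate sides.  Windows are clipped to
#' chromosome bounds and flagged when clipping occurred.
#'
#' @param annotation a [genome_annotation()] object.
#' @param upstream_bp bp added upstream of the TSS (default 1000).
#' @param downstream_bp bp added downstream of the transcription end
#'   (default 500).
#' @return data.frame with columns `gene_id`, `chrom`, `win_start`, `win_end`,
#'   `clipped` (0-based half-open).
#' @export
build_windows <- function(annotation, upstream_bp = 1000, downstream_bp = 500) {
  stopifnot(inherits(annotation, "GenomeAnnotation"),
            upstream_bp >= 0, downstream_bp >= 0)
  g <- annotation$genes
  plus <- g$strand == "+"
  raw_start <- ifelse(plus, g$start - upstream_bp, g$start - downstream_bp)
  raw_end <- ifelse(plus, g$end + downstream_bp, g$end + upstream_bp)
  chrom_len <- annotation$chrom_sizes[g$chrom]
  win_start <- pmax(raw_start, 0)
  win_end <- pmin(raw_end, chrom_len)
  data.frame(
    gene_id = g$gene_id,
    chrom = g$chrom,
    win_start = win_start,
    win_end = win_end,
    clipped = raw_start < 0 | raw_end > chrom_len,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Per-gene window signal and density
#'
#' Sums a (rank-normalized) track over each gene window with proportional
#' overlap weighting: a bin contributes `value * overlap_bp / bin_len`, so the
#' sum equals a per-bp accumulation of `value / bin_len` over the window
#' regardless of bin size.  Density is the window sum divided by window
#' length.  Windows on chromosomes absent from the track get signal 0 with a
#' warning.
#'
#' @param windows data.frame from [build_windows()] (or any frame with
#'   `gene_id`, `chrom`, `win_start`, `win_end`).
#' @param track a rank-normalized [signal_track()]; raw tracks are rejected
#'   unless `allow_raw = TRUE`.
#' @param allow_raw permit aggregation of non-rank-normalized values.
#' @return data.frame of class `GeneSignal` with columns `gene_id`,
#'   `mark_name`, `signal_sum`, `window_len`, `density`.
#' @export
gene_signal <- function(windows, track, allow_raw = FALSE) {
  stopifnot(is.data.frame(windows), inherits(track, "SignalTrack"))
  if (!isTRUE(track$ranked) && !allow_raw) {
    stop("track '", track$mark_name, "' is not rank-normalized; ",
         "call rank_normalize() first or set allow_raw = TRUE")
  }
  b <- track$bins
  missing_chroms <- setdiff(unique(windows$chrom), unique(b$chrom))
  if (length(missing_chroms)) {
    warning("track '", track$mark_name, "' has no bins on chromosome(s): ",
            paste(missing_chroms, collapse = ", "), "; signal set to 0")
  }
  win_gr <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = windows$win_start + 1L, end = windows$win_end)
  )
  bin_gr <- GenomicRanges::GRanges(
    b$chrom, IRanges::IRanges(start = b$start + 1L, end = b$end)
  )
  # differing seqlevel sets are already handled (absent chrom -> signal 0)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(win_gr, bin_gr))
  signal_sum <- numeric(nrow(windows))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- pmin(windows$win_end[qi], b$end[si]) -
      pmax(windows$win_start[qi], b$start[si])
    contrib <- b$value[si] * ov / (b$end[si] - b$start[si])
    sums <- rowsum(contrib, qi)
    signal_sum[as.integer(rownames(sums))] <- sums[, 1L]
  }
  window_len <- windows$win_end - windows$win_start
  out <- data.frame(
    gene_id = windows$gene_id,
    mark_name = track$mark_name,
    signal_sum = signal_sum,
    window_len = window_len,
    density = signal_sum / window_len,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(out) <- c("GeneSignal", "data.frame")
  out
}

#' Per-gene signals for several tracks
#'
#' Convenience wrapper running [gene_signal()] for each track and binding the
#' long-format results.
#'
#' @inheritParams gene_signal
#' @param tracks list of [signal_track()] objects.
#' @return A long-format `GeneSignal` data.frame covering all marks.
#' @export
gene_signals <- function(windows, tracks, allow_raw = FALSE) {
  stopifnot(is.list(tracks), length(tracks) > 0L)
  out <- do.call(rbind, lapply(tracks, gene_signal, windows = windows,
                               allow_raw = allow_raw))
  rownames(out) <- NULL
  class(out) <- c("GeneSignal", "data.frame")
  out
}

#' Pooled signal density of a gene set
#'
#' Set density is the sum of member window signals divided by the summed
#' member window lengths — a length-weighted pooling, not a mean of per-gene
#' densities.  The background density of an analysis is simply `set_density`
#' over the full metabolic gene universe.
#'
#' @param gene_signals a `GeneSignal` frame for a single mark (from
#'   [gene_signal()]), or a multi-mark frame together with `mark`.
#' @param member_ids character vector of member gene ids (non-empty, all
#'   present in `gene_signals`).
#' @param set_id identifier for the set.
#' @param mark optional mark name selecting rows of a multi-mark frame.
#' @return One-row data.frame with `set_id`, `mark_name`, `total_signal`,
#'   `total_len`, `density`, `n_genes`.
#' @export
set_density <- function(gene_signals, member_ids, set_id, mark = NULL) {
  stopifnot(is.data.frame(gene_signals))
  gs <- gene_signals
  if (!is.null(mark)) gs <- gs[gs$mark_name == mark, , drop = FALSE]
  if (length(unique(gs$mark_name)) != 1L) {
    stop("gene_signals spans several marks; select one with 'mark'")
  }
  if (!length(member_ids)) stop("empty member set for '", set_id, "'")
  idx <- match(member_ids, gs$gene_id)
  if (anyNA(idx)) {
    stop("set '", set_id, "' member(s) missing from gene signals: ",
         paste(member_ids[is.na(idx)], collapse = ", "))
  }
  total_signal <- sum(gs$signal_sum[idx])
  total_len <- sum(gs$window_len[idx])
  data.frame(
    set_id = set_id,
    mark_name = gs$mark_name[1L],
    total_signal = total_signal,
    total_len = total_len,
    density = total_signal / total_len,
    n_genes = length(member_ids),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
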