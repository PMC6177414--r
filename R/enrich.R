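# Regulatory-element overlap enrichment by p-value bin.

#' Load a peak interval set
#'
#' Reads a BED file (0-based half-open, converted to 1-based closed ranges
#' on import) or accepts a data.frame with `chrom`, `start`, `end` (BED
#' conventions). Overlapping intervals are merged, with the merge logged;
#' chromosome names are normalized (leading "chr" stripped).
#'
#' @param x BED file path or data.frame.
#' @param cell_type label for the set (defaults to the file name).
#' @return a `GRanges` of merged intervals with a `cell_type` attribute.
#' @export
read_peaks <- function(x, cell_type = NULL) {
  if (is.character(x) && length(x) == 1) {
    cell_type <- cell_type %||% sub("\\.bed(\\.gz)?$", "", basename(x))
    gr <- rtracklayer::import(x, format = "BED")
  } else {
    stopifnot(is.data.frame(x))
    if (any(x$start >= x$end)) stop("peak intervals must satisfy start < end")
    cell_type <- cell_type %||% "peaks"
    gr <- GenomicRanges::GRanges(
      seqnames = norm_chrom(x$chrom),
      ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
  }
  GenomeInfoDb::seqlevels(gr) <- norm_chrom(GenomeInfoDb::seqlevels(gr))
  merged <- GenomicRanges::reduce(gr)
  if (length(merged) < length(gr)) {
    message("read_peaks(", cell_type, "): merged ", length(gr),
            " intervals into ", length(merged))
  }
  attr(merged, "cell_type") <- cell_type
  merged
}

#' Assign markers to significance bins
#'
#' On the p scale (default), `edges` must be strictly decreasing from 1 to
#' 0 and bins are the intervals between consecutive edges, the first
#' (0.05, 1] bin serving as baseline; a p-value exactly on an edge goes to
#' the more significant bin. On the `-log10` scale, `edges` are increasing
#' `-log10(p)` cut points, the first bin (\[0, 0.05) by default) is the
#' baseline, and a value on an edge again goes to the more significant bin.
#'
#' @param p_values numeric p-values (or an `indirect_stat`).
#' @param edges bin edges (see above).
#' @param scale `"p"` or `"mlog10"`.
#' @return factor of bin labels, ordered baseline first; NA for missing p.
#' @export
bin_by_p <- function(p_values,
                     edges = if (scale == "p") c(1, 0.05, 1e-2, 1e-3, 1e-4, 1e-5, 0)
                             else c(0, 0.05, 1, 2, 3, 4, 5),
                     scale = c("p", "mlog10")) {
  scale <- match.arg(scale)
  if (inherits(p_values, "indirect_stat")) p_values <- p_values$p_value
  if (scale == "p") {
    if (any(diff(edges) >= 0)) stop("p-scale edges must be strictly decreasing")
    vec <- rev(edges)
    k <- length(edges) - 1
    i <- findInterval(p_values, vec, left.open = TRUE)
    i[!is.na(p_values) & p_values <= vec[1]] <- 0L # p at/below the floor
    bin <- length(vec) - i
    bin[bin > k] <- k # values below the smallest positive edge
    labels <- sprintf("(%g, %g]", edges[-1], edges[-length(edges)])
  } else {
    if (any(diff(edges) <= 0)) stop("-log10 edges must be strictly increasing")
    x <- -log10(p_values)
    k <- length(edges)
    bin <- findInterval(x, edges) # value on an edge joins the higher bin
    bin[bin < 1] <- 1L
    labels <- c(sprintf("[%g, %g)", edges[-length(edges)], edges[-1]),
                sprintf("[%g, Inf)", edges[length(edges)]))
  }
  factor(labels[bin], levels = labels)
}

#' Overlap fractions of markers with peak sets, per significance bin
#'
#' Markers are treated as single 1-based positions. For every peak set and
#' bin, reports the number of markers, the number overlapping a peak, the
#' overlap fraction, and the fraction relative to the baseline (least
#' significant) bin; the baseline's relative fraction is exactly 1, and the
#' relative fraction is missing where the baseline fraction is zero or a
#' bin is empty. With `exclude_mhc = TRUE` markers inside the extended MHC
#' window (chr6:25-34 Mb) are removed first.
#'
#' @param markers data.frame with `marker_id`, `chrom`, `pos` (or a
#'   [genotype_matrix()]).
#' @param p_values named or marker-aligned p-values (or an `indirect_stat`,
#'   matched by `marker_id`).
#' @param peaks a `GRanges` from [read_peaks()] or a named list of them
#'   (one per cell type).
#' @param exclude_mhc drop MHC-window markers before binning.
#' @param ... passed to [bin_by_p()] (`edges`, `scale`).
#' @return an `enrichment_table` data.frame: `cell_type`, `bin`,
#'   `n_markers`, `n_overlapping`, `fraction`, `relative_fraction`.
#' @export
overlap_fractions <- function(markers, p_values, peaks, exclude_mhc = FALSE,
                              ...) {
  if (inherits(markers, "genotype_matrix")) markers <- markers$markers
  if (inherits(p_values, "indirect_stat")) {
    p_values <- setNames(p_values$p_value, p_values$marker_id)
  }
  p <- if (!is.null(names(p_values))) {
    unname(p_values[markers$marker_id])
  } else {
    stopifnot(length(p_values) == nrow(markers))
    p_values
  }
  if (exclude_mhc) {
    drop <- markers$marker_id %in% mhc_markers(markers)
    markers <- markers[!drop, , drop = FALSE]
    p <- p[!drop]
  }
  keep <- is.finite(p)
  markers <- markers[keep, , drop = FALSE]
  p <- p[keep]
  bin <- bin_by_p(p, ...)
  pts <- GenomicRanges::GRanges(seqnames = norm_chrom(markers$chrom),
                                ranges = IRanges::IRanges(start = markers$pos,
                                                          width = 1))
  if (!inherits(peaks, "list")) peaks <- setNames(
    list(peaks), attr(peaks, "cell_type") %||% "peaks")
  rows <- list()
  for (ct in names(peaks)) {
    gr <- peaks[[ct]]
    GenomeInfoDb::seqlevels(gr) <- norm_chrom(GenomeInfoDb::seqlevels(gr))
    hit <- IRanges::overlapsAny(pts, gr)
    for (b in levels(bin)) {
      w <- which(bin == b)
      rows[[length(rows) + 1]] <- data.frame(
        cell_type = ct, bin = b, n_markers = length(w),
        n_overlapping = sum(hit[w]),
        fraction = if (length(w)) mean(hit[w]) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  base <- levels(bin)[1]
  for (ct in unique(out$cell_type)) {
    bf <- out$fraction[out$cell_type == ct & out$bin == base]
    sel <- out$cell_type == ct
    out$relative_fraction[sel] <-
      if (is.na(bf) || bf == 0) NA_real_ else out$fraction[sel] / bf
  }
  class(out) <- c("enrichment_table", "data.frame")
  out
}
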