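#' Regulatory peak integration (ATAC / H3K27ac)
#'
#' TSS-distance annotation of accessible peaks, the 3000-bp promoter
#' proximal/distal split, H3K27ac quantification in a 1000-bp window around
#' each peak summit, NB differential-region calling (fold change > 2 and
#' adjusted p < 0.05), and hand-off of differential regions to motif
#' enrichment. Coordinates are 0-based half-open (BED convention)
#' throughout.
#'
#' @name regulatory_peaks
NULL

.check_peaks <- function(peaks) {
  stopifnot(all(c("id", "chrom", "start", "end") %in% names(peaks)))
  if (any(peaks$start >= peaks$end)) stop("peak start must be < end")
  if (anyDuplicated(peaks$id)) stop("duplicate peak ids")
  if (is.null(peaks$summit))
    peaks$summit <- (peaks$start + peaks$end) %/% 2
  peaks
}

#' Annotate peaks with signed distance to the nearest TSS
#'
#' Distance = summit - TSS of the nearest TSS on the same chromosome, with
#' the sign flipped for minus-strand genes so that negative always means
#' upstream of the gene. Ties in |distance| are broken by the smaller gene
#' id. Peaks on chromosomes absent from the TSS table get NA distance and
#' an `excluded` flag (with a warning); they are dropped from downstream
#' proximal/distal logic.
#'
#' @param peaks Data frame: `id`, `chrom`, `start`, `end` (0-based
#'   half-open) and optional `summit` (midpoint when absent).
#' @param tss Data frame: `gene`, `chrom`, `tss` (0-based), `strand`.
#' @return `peaks` with `tss_distance`, `nearest_gene`, `proximal`
#'   (|distance| <= 3000) and `excluded` columns.
#' @export
annotate_tss_distance <- function(peaks, tss) {
  peaks <- .check_peaks(peaks)
  stopifnot(all(c("gene", "chrom", "tss", "strand") %in% names(tss)))
  peaks$tss_distance <- NA_integer_
  peaks$nearest_gene <- NA_character_
  for (ch in unique(peaks$chrom)) {
    t_ch <- tss[tss$chrom == ch, , drop = FALSE]
    sel <- which(peaks$chrom == ch)
    if (!nrow(t_ch)) next
    # stable order: by position, then gene id for the tie-break
    t_ch <- t_ch[order(t_ch$tss, t_ch$gene), , drop = FALSE]
    for (i in sel) {
      d_abs <- abs(peaks$summit[i] - t_ch$tss)
      cand <- which(d_abs == min(d_abs))
      if (length(cand) > 1)
        cand <- cand[order(t_ch$gene[cand])][1]
      d <- peaks$summit[i] - t_ch$tss[cand]
      if (t_ch$strand[cand] == "-") d <- -d
      peaks$tss_distance[i] <- d
      peaks$nearest_gene[i] <- t_ch$gene[cand]
    }
  }
  peaks$excluded <- is.na(peaks$tss_distance)
  if (any(peaks$excluded))
    warning(sum(peaks$excluded), " peak(s) on chromosomes absent from the ",
            "TSS table; flagged excluded")
  peaks$proximal <- abs(peaks$tss_distance) <= 3000
  peaks
}

#' Split peaks into promoter-proximal and distal sets
#'
#' Proximal iff |TSS distance| <= `cutoff` (inclusive boundary: a peak at
#' exactly 3000 bp is proximal). Excluded (unannotated) peaks are allowed
#' only when flagged by [annotate_tss_distance()].
#'
#' @param peaks Annotated peaks.
#' @param cutoff Proximal cutoff in bp (default 3000).
#' @return List with `proximal` and `distal` data frames (disjoint; their
#'   union is the annotated peak set).
#' @export
split_proximal_distal <- function(peaks, cutoff = 3000) {
  if (is.null(peaks$tss_distance))
    stop("peaks are not annotated; run annotate_tss_distance() first")
  if (anyNA(peaks$tss_distance) &&
      (is.null(peaks$excluded) ||
       !all(peaks$excluded[is.na(peaks$tss_distance)])))
    stop("unannotated peak present without an excluded flag")
  keep <- !is.na(peaks$tss_distance)
  ann <- peaks[keep, , drop = FALSE]
  prox <- abs(ann$tss_distance) <= cutoff
  list(proximal = ann[prox, , drop = FALSE],
       distal = ann[!prox, , drop = FALSE])
}

#' Quantify signal in a fixed window around each peak summit
#'
#' Sums per-sample tag counts in the half-open window
#' `[summit - half_width, summit + half_width)` (default a 1000-bp window),
#' mirroring H3K27ac quantification around ATAC summits; downstream motif
#' work uses the original peak intervals, not these windows.
#'
#' @param peaks Peak data frame (summit required or derived).
#' @param signal Data frame of per-position tags: `chrom`, `pos` (0-based)
#'   and one numeric column per sample.
#' @param half_width Half window width in bp (default 500).
#' @return Matrix of window counts, peaks x samples, with a `truncated`
#'   attribute flagging windows clipped at position 0.
#' @export
quantify_window <- function(peaks, signal, half_width = 500) {
  peaks <- .check_peaks(peaks)
  stopifnot(all(c("chrom", "pos") %in% names(signal)))
  samp <- setdiff(names(signal), c("chrom", "pos"))
  if (!length(samp)) stop("signal table has no sample columns")
  out <- matrix(0, nrow(peaks), length(samp),
                dimnames = list(peaks$id, samp))
  truncated <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    lo <- peaks$summit[i] - half_width
    hi <- peaks$summit[i] + half_width   # half-open upper bound
    if (lo < 0) { lo <- 0; truncated[i] <- TRUE }
    sel <- signal$chrom == peaks$chrom[i] & signal$pos >= lo &
      signal$pos < hi
    if (any(sel))
      out[i, ] <- colSums(signal[sel, samp, drop = FALSE])
  }
  attr(out, "truncated") <- peaks$id[truncated]
  out
}

#' Differential peak calling
#'
#' Runs the NB Wald machinery ([size_factors()], [estimate_dispersion()],
#' [wald_contrast()]) on the peak x sample tag table and flags peaks with
#' fold change > 2 (|log2fc| > 1, strict) and adjusted p < 0.05 as
#' differential. Also emits the scatter-table columns used for tag-count
#' plots, with a plain >2-fold flag independent of significance.
#'
#' @param counts Peak x sample tag count matrix.
#' @param samples Sample sheet with a `condition` column.
#' @param condition_pair Character vector `c(numerator, denominator)`.
#' @param fc_min Fold-change threshold (default 2).
#' @param padj_max Adjusted-p ceiling (default 0.05).
#' @param dispersions Optional known dispersions; estimated when NULL
#'   (pooled-dispersion fallback: with no replicated condition the median
#'   dispersion across peaks from the pooled table would be required, and
#'   an error is raised instead).
#' @return A `"differential_peaks"` data frame: peak id, mean tags per
#'   condition, `log2fc`, `pvalue`, `padj`, `fc2` (>2-fold flag),
#'   `significant`, `direction`.
#' @export
differential_peaks <- function(counts, samples, condition_pair,
                               fc_min = 2, padj_max = 0.05,
                               dispersions = NULL) {
  stopifnot(length(condition_pair) == 2)
  spec <- contrast_spec(paste(condition_pair, collapse = "_vs_"),
                        condition_pair[1], condition_pair[2])
  res <- wald_contrast(counts, samples, spec, dispersions = dispersions)
  lfc_min <- log2(fc_min)
  sig <- !is.na(res$padj) & abs(res$log2fc) > lfc_min & res$padj < padj_max
  cond <- sample_conditions(samples)
  f <- size_factors(counts)
  norm <- sweep(as.matrix(counts), 2, f, "/")
  out <- data.frame(
    peak = res$gene,
    mean_num = rowMeans(norm[, cond == condition_pair[1], drop = FALSE]),
    mean_den = rowMeans(norm[, cond == condition_pair[2], drop = FALSE]),
    log2fc = res$log2fc, pvalue = res$pvalue, padj = res$padj,
    fc2 = abs(res$log2fc) > lfc_min,
    significant = sig,
    direction = ifelse(res$log2fc > 0, "up", "down")
  )
  class(out) <- c("differential_peaks", "data.frame")
  out
}

#' Foreground/background sequences for motif enrichment
#'
#' Foreground = significant differential peaks in the requested direction;
#' background = all tested peaks. Sequences come from the original peak
#' intervals (not quantification windows), uppercased. `sequences` may be
#' chromosome-level (named by chromosome; substrings are extracted) or
#' per-peak (named by peak id).
#'
#' @param diff A `"differential_peaks"` result.
#' @param peaks Peak data frame with intervals.
#' @param sequences Named character vector of sequences.
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return List with `foreground` (peak ids), `background` (peak ids) and
#'   `sequences` (named per-peak character vector over the background). If
#'   no peak is significant in the requested direction the foreground is
#'   empty and a message is emitted.
#' @export
regions_to_enrichment <- function(diff, peaks, sequences,
                                  direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  peaks <- .check_peaks(peaks)
  tested <- diff$peak[!is.na(diff$pvalue)]
  sig <- diff$significant %in% TRUE
  if (direction != "both") sig <- sig & diff$direction == direction
  fg <- diff$peak[sig]
  if (!length(fg))
    message("no significant peaks in direction '", direction,
            "'; enrichment will be skipped")
  idx <- match(tested, peaks$id)
  if (anyNA(idx)) stop("differential result contains unknown peak ids")
  if (all(tested %in% names(sequences))) {
    seqs <- toupper(sequences[tested])
  } else {
    seqs <- vapply(idx, function(i) {
      chs <- sequences[[peaks$chrom[i]]]
      if (is.null(chs)) stop("no sequence for chromosome ", peaks$chrom[i])
      if (peaks$end[i] > nchar(chs) || peaks$start[i] < 0)
        stop("peak interval outside sequence bounds: ", peaks$id[i])
      toupper(substr(chs, peaks$start[i] + 1, peaks$end[i]))
    }, character(1))
    names(seqs) <- tested
  }
  list(foreground = fg, background = tested, sequences = seqs)
}
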