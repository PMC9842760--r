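#' Hypergeometric motif enrichment of a region set against background
#'
#' For each motif, tests whether foreground regions (e.g. differentially
#' acetylated/accessible peaks) carry at least one motif hit more (or less)
#' often than the background region universe, with a two-tailed
#' hypergeometric test and Benjamini-Hochberg adjustment across motifs.
#'
#' The two-tailed p-value uses the minimum-likelihood rule: with
#' `N = |background|` regions of which `K` carry a hit, drawing
#' `n = |foreground|` and observing `k` hits,
#' `p = sum over achievable x of P(X = x)` for all `x` with
#' `P(X = x) <= P(X = k)`. The one-sided upper tail
#' (`P(X >= k)`) is available via `alternative = "greater"`.
#'
#' @param foreground Character vector of foreground region ids (must be a
#'   subset of `background`).
#' @param background Character vector of all tested region ids.
#' @param hits Hit data frame (columns `seq_id`, `motif`), or a named list
#'   of character vectors of region ids with >= 1 hit per motif.
#' @param motif_names Motifs to test; default all motifs present in `hits`.
#' @param alternative `"two.sided"` (minimum-likelihood rule) or
#'   `"greater"` (upper tail).
#' @return Data frame with one row per motif: `motif`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment` = (k/n)/(K/N), `pvalue`, `padj`.
#' @export
hypergeometric_enrichment <- function(foreground, background, hits,
                                      motif_names = NULL,
                                      alternative = c("two.sided",
                                                      "greater")) {
  alternative <- match.arg(alternative)
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  if (!length(background)) stop("background region set is empty")
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  if (is.data.frame(hits)) {
    stopifnot(all(c("seq_id", "motif") %in% names(hits)))
    if (is.null(motif_names)) motif_names <- unique(hits$motif)
    hit_sets <- lapply(setNames(motif_names, motif_names), function(m)
      unique(hits$seq_id[hits$motif == m]))
  } else {
    stopifnot(is.list(hits))
    if (is.null(motif_names)) motif_names <- names(hits)
    hit_sets <- lapply(setNames(motif_names, motif_names), function(m)
      unique(as.character(hits[[m]])))
  }
  N <- length(background)
  n <- length(foreground)
  rows <- lapply(motif_names, function(m) {
    in_bg <- intersect(hit_sets[[m]], background)
    K <- length(in_bg)
    k <- length(intersect(in_bg, foreground))
    p <- hyper_two_tailed_p(k, K, N, n, alternative = alternative)
    fe <- if (K == 0 || n == 0) NA_real_ else (k / n) / (K / N)
    data.frame(motif = m, k = k, n = n, K = K, N = N,
               fold_enrichment = fe, pvalue = p)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$pvalue)
  rownames(out) <- NULL
  out
}

#' Two-tailed hypergeometric p-value (minimum-likelihood rule)
#'
#' @param k Observed foreground successes.
#' @param K Background successes.
#' @param N Background size.
#' @param n Foreground size.
#' @param alternative `"two.sided"` or `"greater"`.
#' @return p-value in \[0, 1\].
#' @export
hyper_two_tailed_p <- function(k, K, N, n,
                               alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(k >= 0, K >= 0, n >= 0, N >= n, K <= N, k <= n, k <= K)
  if (alternative == "greater")
    return(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  support <- max(0, n - (N - K)):min(n, K)
  dens <- stats::dhyper(support, K, N - K, n)
  pk <- stats::dhyper(k, K, N - K, n)
  # relative tolerance guards against ties lost to floating-point rounding
  min(1, sum(dens[dens <= pk * (1 + 1e-7)]))
}
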