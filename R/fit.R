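#' Fit the ISG landscape model to a factorial count matrix
#'
#' The central fitting function: given a gene x sample count matrix and a
#' 2x2 genotype x treatment sample sheet it computes median-of-ratios size
#' factors, per-gene NB dispersions, the four canonical NB Wald contrasts
#' (C1 = WT+IFN vs WT, C2 = KO+IFN vs KO, C3 = KO+IFN vs WT+IFN,
#' C4 = KO vs WT), applies the regulation thresholds, and classifies each
#' gene as a typical or atypical ISG with heatmap cluster A/D flags.
#' Atypical genes can subsequently be subdivided with [classify_isgs()].
#'
#' @param counts Gene x sample non-negative integer matrix.
#' @param samples Sample sheet: one row per column of `counts`, with
#'   `genotype` in WT/KO and `treatment` in untreated/IFN (or a
#'   precombined `condition` column).
#' @param thresholds A [call_thresholds()] object; default
#'   `log2fc > 1` and `padj < 0.05`.
#' @param dispersions Optional per-gene NB dispersions; estimated by
#'   [estimate_dispersion()] when NULL.
#' @return An object of class `"isg_fit"` with components `results`
#'   (named list of `"contrast_result"` for C1-C4), `calls`,
#'   `classification`, `size_factors`, `dispersions`, `thresholds`,
#'   `counts`, `samples`.
#' @seealso [summary.isg_fit()], [coef.isg_fit()], [plot.isg_fit()],
#'   [simulate.isg_fit()], [classify_isgs()]
#' @export
isg_fit <- function(counts, samples, thresholds = call_thresholds(),
                    dispersions = NULL) {
  counts <- .check_counts(counts)
  condition <- sample_conditions(samples)
  if (length(condition) != ncol(counts))
    stop("sample sheet does not match count matrix columns")
  needed <- c("WT_untreated", "WT_IFN", "KO_untreated", "KO_IFN")
  missing_cond <- setdiff(needed, condition)
  if (length(missing_cond))
    stop("conditions absent from the design: ",
         paste(missing_cond, collapse = ", "))
  f <- size_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(counts, f, condition)
  specs <- canonical_contrasts()
  results <- lapply(specs, function(sp)
    call_regulated(wald_contrast(counts, condition, sp, factors = f,
                                 dispersions = dispersions),
                   thresholds))
  calls <- contrast_call_table(results, thresholds)
  classification <- assign_heatmap_clusters(calls)
  structure(
    list(counts = counts, samples = samples, condition = condition,
         size_factors = f, dispersions = dispersions,
         thresholds = thresholds, results = results, calls = calls,
         classification = classification),
    class = "isg_fit"
  )
}

#' Subdivide the atypical ISGs of a fit
#'
#' @param fit An `"isg_fit"`.
#' @param known_isgs Character vector of reference (reported) ISG ids.
#' @param motif_presence Named logical vector of ISRE/STAT1 motif evidence
#'   per gene (see [motif_presence()]); a user-supplied binding-evidence
#'   flag may be OR-ed in via `extra_evidence`.
#' @param extra_evidence Optional named logical vector OR-ed into
#'   `motif_presence` (e.g. external ChIP evidence).
#' @return The fit with its classification's `sublabel` filled.
#' @export
classify_isgs <- function(fit, known_isgs, motif_presence,
                          extra_evidence = NULL) {
  stopifnot(inherits(fit, "isg_fit"))
  if (!is.null(extra_evidence)) {
    g <- union(names(motif_presence), names(extra_evidence))
    motif_presence <- setNames(
      motif_presence[g] %in% TRUE | extra_evidence[g] %in% TRUE, g)
  }
  fit$classification <- subdivide_atypical(fit$classification, known_isgs,
                                           motif_presence)
  fit
}

#' @export
print.isg_fit <- function(x, ...) {
  cat("ISG landscape fit:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  tab <- table(x$condition)
  cat("design:", paste(sprintf("%s (n=%d)", names(tab), tab),
                       collapse = ", "), "\n")
  th <- x$thresholds
  cat(sprintf("up-call: log2fc > %g and %s < %g\n", th$lfc_min,
              if (th$use_adjusted) "padj" else "p",
              if (th$use_adjusted) th$padj_max else th$p_max))
  up <- vapply(x$results, function(r) sum(r$up, na.rm = TRUE), numeric(1))
  cat("up-regulated genes:",
      paste(sprintf("%s=%d", names(up), up), collapse = ", "), "\n")
  lab <- table(factor(x$classification$label,
                      c("typical", "atypical", "none")))
  cat(sprintf("classes: %d typical ISGs, %d atypical ISGs, %d other\n",
              lab[["typical"]], lab[["atypical"]], lab[["none"]]))
  invisible(x)
}

#' Summary of an ISG landscape fit
#'
#' @param object An `"isg_fit"`.
#' @param ... Unused.
#' @return A `"classification_report"` (printed with per-class counts and
#'   cluster totals).
#' @export
summary.isg_fit <- function(object, ...) {
  classification_report(object$classification)
}

#' Log2 fold change matrix of a fit
#'
#' @param object An `"isg_fit"`.
#' @param ... Unused.
#' @return Gene x contrast matrix of log2 fold changes.
#' @export
coef.isg_fit <- function(object, ...) {
  out <- vapply(object$results, function(r) r$log2fc,
                numeric(nrow(object$counts)))
  rownames(out) <- object$results[[1]]$gene
  out
}

#' Fitted NB means of a fit
#'
#' @param object An `"isg_fit"`.
#' @param ... Unused.
#' @return Gene x sample matrix of fitted means (per-condition normalized
#'   mean scaled by each sample's size factor).
#' @export
fitted.isg_fit <- function(object, ...) {
  norm <- sweep(object$counts, 2, object$size_factors, "/")
  cond_mean <- vapply(unique(object$condition), function(cc)
    rowMeans(norm[, object$condition == cc, drop = FALSE]),
    numeric(nrow(norm)))
  mu <- cond_mean[, object$condition, drop = FALSE]
  mu <- sweep(mu, 2, object$size_factors, "*")
  dimnames(mu) <- dimnames(object$counts)
  mu
}

#' Pearson residuals of a fit
#'
#' @param object An `"isg_fit"`.
#' @param ... Unused.
#' @return Gene x sample matrix `(count - mu) / sqrt(mu + alpha mu^2)`.
#' @export
residuals.isg_fit <- function(object, ...) {
  mu <- fitted(object)
  alpha <- as.numeric(object$dispersions)
  (object$counts - mu) / sqrt(mu + alpha * mu^2)
}

#' Parametric simulation from a fit
#'
#' Draws new count matrices from the fitted NB model (fitted means and
#' per-gene dispersions), e.g. for parametric-bootstrap checks.
#'
#' @param object An `"isg_fit"`.
#' @param nsim Number of matrices.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of `nsim` gene x sample integer matrices.
#' @export
simulate.isg_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  alpha <- as.numeric(object$dispersions)
  lapply(seq_len(nsim), function(i) {
    m <- matrix(stats::rnbinom(length(mu), mu = mu,
                               size = rep(1 / pmax(alpha, 1e-8),
                                          ncol(mu))),
                nrow(mu), ncol(mu), dimnames = dimnames(mu))
    m
  })
}

#' Volcano plot of one contrast
#'
#' @param x An `"isg_fit"`.
#' @param contrast One of `"C1"`..`"C4"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted contrast result.
#' @export
plot.isg_fit <- function(x, contrast = "C2", ...) {
  r <- x$results[[contrast]]
  if (is.null(r)) stop("unknown contrast: ", contrast)
  pv <- pmax(r$pvalue, 1e-300)
  col <- ifelse(r$up %in% TRUE, "firebrick",
                ifelse(r$down %in% TRUE, "steelblue", "grey60"))
  graphics::plot(r$log2fc, -log10(pv), pch = 20, col = col,
                 xlab = expression(log[2] ~ "fold change"),
                 ylab = expression(-log[10] ~ italic(p)),
                 main = sprintf("%s: %s vs %s", contrast,
                                attr(r, "contrast")$numerator,
                                attr(r, "contrast")$denominator), ...)
  graphics::abline(v = c(-1, 1) * x$thresholds$lfc_min, lty = 2,
                   col = "grey40")
  invisible(r)
}
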