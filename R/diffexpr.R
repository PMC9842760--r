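#' Negative-binomial Wald differential expression
#'
#' A deliberately transparent NB differential-expression stack for pairwise
#' condition contrasts of the genotype x interferon factorial design:
#' median-of-ratios size factors, method-of-moments per-gene dispersion,
#' a delta-method Wald test on the log2 ratio of normalized group means,
#' and Benjamini-Hochberg adjustment. It follows the NB-Wald test family
#' without dispersion-trend or fold-change shrinkage, so every number it
#' reports can be reproduced by hand.
#'
#' @name diffexpr
NULL

.check_counts <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  counts
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over reference-usable genes of the ratio of
#' its count to the gene's geometric mean across samples; genes with a zero
#' count in any sample are excluded from the reference set. Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param counts Gene x sample matrix of non-negative integer counts.
#' @return Named vector of positive per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- .check_counts(counts)
  ref <- rowSums(counts == 0) == 0
  if (!any(ref))
    stop("no reference-usable genes (every gene has a zero count in some ",
         "sample); consider a pseudo-reference on filtered genes")
  lg <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(lg)
  logratios <- lg - loggeo
  f <- exp(apply(logratios, 2, stats::median))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Method-of-moments NB dispersion per gene
#'
#' Normalized counts are pooled within condition; for each gene the NB
#' dispersion `alpha` in `var = mu + alpha * mu^2` is estimated as a
#' replicate-weighted method-of-moments pool over conditions,
#' `alpha = (sum_c (n_c - 1) (v_c - m_c)) / (sum_c (n_c - 1) m_c^2)`,
#' clipped below at a small floor. Genes whose within-condition variance
#' does not exceed the mean (Poisson-like or constant) land on the floor.
#'
#' @param counts Gene x sample count matrix.
#' @param factors Per-sample size factors (see [size_factors()]).
#' @param condition Factor/character vector of per-sample condition labels.
#' @param floor Minimum dispersion returned (default 1e-8).
#' @return Named per-gene dispersion vector, with attribute
#'   `"flagged"` marking all-zero genes.
#' @export
estimate_dispersion <- function(counts, factors, condition, floor = 1e-8) {
  counts <- .check_counts(counts)
  stopifnot(length(factors) == ncol(counts),
            length(condition) == ncol(counts))
  condition <- as.character(condition)
  tab <- table(condition)
  if (!any(tab >= 2))
    stop("dispersion estimation needs >= 2 replicates in >= 1 condition")
  norm <- sweep(counts, 2, factors, "/")
  num <- numeric(nrow(counts))
  den <- numeric(nrow(counts))
  for (cond in names(tab)[tab >= 2]) {
    sel <- condition == cond
    n_c <- sum(sel)
    m <- rowMeans(norm[, sel, drop = FALSE])
    v <- apply(norm[, sel, drop = FALSE], 1, stats::var)
    w <- n_c - 1
    num <- num + w * (v - m)
    den <- den + w * m^2
  }
  alpha <- ifelse(den > 0, pmax(floor, num / den), floor)
  flagged <- rowSums(counts) == 0
  alpha[flagged] <- floor
  alpha <- setNames(alpha, rownames(counts))
  attr(alpha, "flagged") <- names(alpha)[flagged]
  alpha
}

#' Specify a pairwise contrast
#'
#' The four canonical contrasts of the 2x2 design are named C1 (WT+IFN vs
#' WT), C2 (KO+IFN vs KO), C3 (KO+IFN vs WT+IFN) and C4 (KO vs WT, both
#' untreated); arbitrary condition pairs are allowed.
#'
#' @param name Contrast label.
#' @param numerator,denominator Condition labels (must differ).
#' @return A `"contrast_spec"` object.
#' @export
contrast_spec <- function(name, numerator, denominator) {
  if (identical(numerator, denominator))
    stop("numerator and denominator conditions must differ")
  structure(list(name = name, numerator = numerator,
                 denominator = denominator),
            class = "contrast_spec")
}

#' Canonical contrasts of the genotype x treatment design
#'
#' @param condition_of Function mapping (genotype, treatment) to the
#'   condition label used in the sample sheet; default pastes them with
#'   `"_"` (e.g. `"WT_IFN"`).
#' @return Named list of the four `"contrast_spec"` objects C1-C4.
#' @export
canonical_contrasts <- function(condition_of = function(g, t)
                                  paste(g, t, sep = "_")) {
  list(
    C1 = contrast_spec("C1", condition_of("WT", "IFN"),
                       condition_of("WT", "untreated")),
    C2 = contrast_spec("C2", condition_of("KO", "IFN"),
                       condition_of("KO", "untreated")),
    C3 = contrast_spec("C3", condition_of("KO", "IFN"),
                       condition_of("WT", "IFN")),
    C4 = contrast_spec("C4", condition_of("KO", "untreated"),
                       condition_of("WT", "untreated"))
  )
}

#' NB Wald test for one pairwise contrast
#'
#' The log2 fold change is `log2((m_num + c) / (m_den + c))` on
#' size-factor-normalized group means with pseudo-mean `c` (default 0.5
#' normalized counts) keeping it finite at zero means. Its standard error
#' comes from the delta method under the NB variance law,
#' `se^2 = (1/ln 2)^2 * sum_g (mu_g + alpha mu_g^2) / (n_g mu_g^2)`
#' over the two groups (pseudo-mean applied to `mu_g` as well), the Wald
#' statistic is `log2fc / se`, and the p-value is the two-sided standard
#' normal tail. Genes with zero counts in every sample of both groups are
#' excluded from testing and from the BH family (their p and padj are NA).
#'
#' @param counts Gene x sample count matrix.
#' @param samples Data frame with a `condition` column (or `genotype` +
#'   `treatment`, combined as `genotype_treatment`), rows matching columns
#'   of `counts`.
#' @param spec A `"contrast_spec"`, or a string `"num:den"`, or one of
#'   `"C1"`..`"C4"`.
#' @param factors Size factors; computed from `counts` when NULL.
#' @param dispersions Per-gene dispersions; estimated when NULL.
#' @param pseudo_mean Pseudo-mean `c` in normalized counts.
#' @return A `"contrast_result"` data frame: `gene`, `base_mean`,
#'   `log2fc`, `se_log2fc`, `wald_z`, `pvalue`, `padj`, `up`, `down`
#'   (up/down are filled by [call_regulated()]; NA here).
#' @export
wald_contrast <- function(counts, samples, spec, factors = NULL,
                          dispersions = NULL, pseudo_mean = 0.5) {
  counts <- .check_counts(counts)
  condition <- sample_conditions(samples)
  stopifnot(length(condition) == ncol(counts))
  spec <- .resolve_spec(spec)
  sel_num <- condition == spec$numerator
  sel_den <- condition == spec$denominator
  if (!any(sel_num) || !any(sel_den))
    stop("contrast '", spec$name, "': condition with no samples (",
         spec$numerator, " vs ", spec$denominator, ")")
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(counts, factors, condition)
  norm <- sweep(counts, 2, factors, "/")
  n1 <- sum(sel_num); n0 <- sum(sel_den)
  m1 <- rowMeans(norm[, sel_num, drop = FALSE])
  m0 <- rowMeans(norm[, sel_den, drop = FALSE])
  alpha <- as.numeric(dispersions[rownames(counts)])
  mu1 <- m1 + pseudo_mean
  mu0 <- m0 + pseudo_mean
  log2fc <- log2(mu1 / mu0)
  se <- (1 / log(2)) * sqrt((mu1 + alpha * mu1^2) / (n1 * mu1^2) +
                            (mu0 + alpha * mu0^2) / (n0 * mu0^2))
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))
  tested <- rowSums(counts[, sel_num | sel_den, drop = FALSE]) > 0
  p[!tested] <- NA_real_
  z[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- bh_adjust(p[tested])
  out <- data.frame(
    gene = rownames(counts),
    base_mean = rowMeans(norm[, sel_num | sel_den, drop = FALSE]),
    log2fc = log2fc, se_log2fc = se, wald_z = z,
    pvalue = p, padj = padj,
    up = NA, down = NA,
    row.names = NULL
  )
  attr(out, "contrast") <- spec
  class(out) <- c("contrast_result", "data.frame")
  out
}

.resolve_spec <- function(spec) {
  if (inherits(spec, "contrast_spec")) return(spec)
  if (is.character(spec) && length(spec) == 1) {
    cc <- canonical_contrasts()
    if (spec %in% names(cc)) return(cc[[spec]])
    if (grepl(":", spec, fixed = TRUE)) {
      parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
      return(contrast_spec(spec, parts[1], parts[2]))
    }
  }
  stop("cannot interpret contrast specification")
}

#' Condition labels from a sample sheet
#'
#' @param samples Data frame with either a `condition` column or
#'   `genotype` and `treatment` columns (combined `genotype_treatment`).
#' @return Character vector of per-sample condition labels.
#' @export
sample_conditions <- function(samples) {
  if (is.character(samples) || is.factor(samples))
    return(as.character(samples))
  if ("condition" %in% names(samples))
    return(as.character(samples$condition))
  if (all(c("genotype", "treatment") %in% names(samples)))
    return(paste(samples$genotype, samples$treatment, sep = "_"))
  stop("sample sheet needs a 'condition' column or 'genotype'+'treatment'")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: sort ascending, `q_i = p_(i) * m / i`, enforce monotone
#' non-increasing from the largest rank, cap at 1, return in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Regulation thresholds
#'
#' @param lfc_min Minimum |log2 fold change| (strict `>`).
#' @param p_max Raw p-value ceiling (strict `<`); used when
#'   `use_adjusted = FALSE`.
#' @param padj_max Adjusted p-value ceiling (strict `<`); used when
#'   `use_adjusted = TRUE`.
#' @param use_adjusted Whether the ceiling applies to `padj` (default) or
#'   raw `p`.
#' @return A `"call_thresholds"` object.
#' @export
call_thresholds <- function(lfc_min = 1, p_max = NULL, padj_max = 0.05,
                            use_adjusted = !is.null(padj_max)) {
  if (is.null(p_max) && is.null(padj_max))
    stop("at least one of p_max / padj_max must be set")
  if (use_adjusted && is.null(padj_max))
    stop("use_adjusted = TRUE requires padj_max")
  if (!use_adjusted && is.null(p_max))
    stop("use_adjusted = FALSE requires p_max")
  stopifnot(lfc_min >= 0)
  structure(list(lfc_min = lfc_min, p_max = p_max, padj_max = padj_max,
                 use_adjusted = use_adjusted),
            class = "call_thresholds")
}

#' Call up/down regulation on a contrast result
#'
#' `up` iff `log2fc > lfc_min` and the chosen p (raw or adjusted) is
#' strictly below its ceiling; `down` symmetric with `log2fc < -lfc_min`.
#' All inequalities are strict, so boundary values never pass. Untested
#' genes (NA p) are never called.
#'
#' @param result A `"contrast_result"` from [wald_contrast()].
#' @param thresholds A `"call_thresholds"` object.
#' @return The result with `up`/`down` logical columns filled.
#' @export
call_regulated <- function(result, thresholds) {
  stopifnot(inherits(thresholds, "call_thresholds"))
  pv <- if (thresholds$use_adjusted) result$padj else result$pvalue
  ceiling_ <- if (thresholds$use_adjusted) thresholds$padj_max
              else thresholds$p_max
  ok <- !is.na(pv) & pv < ceiling_
  result$up <- ok & result$log2fc > thresholds$lfc_min
  result$down <- ok & result$log2fc < -thresholds$lfc_min
  result
}

#' @export
print.contrast_result <- function(x, ...) {
  spec <- attr(x, "contrast")
  if (!is.null(spec))
    cat(sprintf("NB Wald contrast %s: %s vs %s\n", spec$name,
                spec$numerator, spec$denominator))
  n_up <- sum(x$up, na.rm = TRUE); n_dn <- sum(x$down, na.rm = TRUE)
  cat(sprintf("%d genes (%d tested); %s\n", nrow(x),
              sum(!is.na(x$pvalue)),
              if (all(is.na(x$up))) "regulation not yet called"
              else sprintf("%d up, %d down", n_up, n_dn)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
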