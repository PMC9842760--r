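#' Four-contrast ISG classification
#'
#' Set logic over the up-calls of the four canonical contrasts:
#' C1 = WT+IFN vs WT, C2 = KO+IFN vs KO, C3 = KO+IFN vs WT+IFN,
#' C4 = KO vs WT (untreated). A gene is a typical ISG when induced by IFN
#' in both genotypes (up in C1 and C2) and an atypical ISG when induced by
#' IFN only in the KO (up in C2, not up in C1). Heatmap cluster A is the
#' canonical IFN response (up in C1 and C2, not already elevated at
#' baseline, i.e. not up in C4); cluster D is the KO-specific IFN response
#' (up in C3 and C2, not up in C1 or C4). Atypical ISGs are subdivided by
#' known-ISG reference membership and ISRE/STAT1 motif evidence into
#' reported, hidden and non-canonical classes.
#'
#' @name isg_classifier
NULL

#' Build the contrast call table
#'
#' @param results Named list of `"contrast_result"` objects for `C1`, `C2`
#'   and optionally `C3`, `C4` (same gene universe).
#' @param thresholds A `"call_thresholds"` applied identically to every
#'   contrast.
#' @return Data frame with `gene` and logical columns `C1`..`C4` (absent
#'   contrasts omitted).
#' @export
contrast_call_table <- function(results, thresholds = call_thresholds()) {
  stopifnot(is.list(results), all(names(results) %in%
                                    c("C1", "C2", "C3", "C4")))
  genes <- results[[1]]$gene
  for (r in results)
    if (!identical(r$gene, genes))
      stop("gene universe differs between contrasts")
  out <- data.frame(gene = genes)
  for (nm in names(results)) {
    called <- call_regulated(results[[nm]], thresholds)
    out[[nm]] <- called$up
  }
  out
}

#' Classify genes as typical / atypical ISGs
#'
#' `atypical` iff up in C2 and not up in C1; `typical` iff up in both;
#' `none` otherwise.
#'
#' @param calls Call table from [contrast_call_table()] (needs `C1`, `C2`).
#' @return A `"gene_classification"` data frame: `gene`, `label` in
#'   `{typical, atypical, none}`, `sublabel` (NA until
#'   [subdivide_atypical()]), `cluster_A`, `cluster_D` (NA until
#'   [assign_heatmap_clusters()]).
#' @export
classify_typical_atypical <- function(calls) {
  if (!all(c("C1", "C2") %in% names(calls)))
    stop("missing contrast: C1 and C2 calls are required")
  up1 <- calls$C1 %in% TRUE
  up2 <- calls$C2 %in% TRUE
  label <- ifelse(up2 & up1, "typical",
                  ifelse(up2 & !up1, "atypical", "none"))
  n <- length(calls$gene)
  out <- data.frame(gene = calls$gene, label = as.character(label),
                    sublabel = rep(NA_character_, n),
                    cluster_A = rep(NA, n), cluster_D = rep(NA, n))
  class(out) <- c("gene_classification", "data.frame")
  out
}

#' Assign heatmap clusters A and D
#'
#' `A` iff up(C1) and up(C2) and not up(C4); `D` iff up(C3) and up(C2) and
#' not up(C1) and not up(C4). Clusters B and C are not defined.
#'
#' @param calls Call table with all four contrasts.
#' @param classification Optional `"gene_classification"` to annotate;
#'   created from `calls` when NULL.
#' @return The classification with `cluster_A`/`cluster_D` filled.
#' @export
assign_heatmap_clusters <- function(calls, classification = NULL) {
  if (!all(c("C1", "C2", "C3", "C4") %in% names(calls)))
    stop("missing contrast: cluster assignment needs C1-C4")
  if (is.null(classification))
    classification <- classify_typical_atypical(calls)
  stopifnot(identical(classification$gene, calls$gene))
  up <- lapply(calls[c("C1", "C2", "C3", "C4")], function(x) x %in% TRUE)
  classification$cluster_A <- up$C1 & up$C2 & !up$C4
  classification$cluster_D <- up$C3 & up$C2 & !up$C1 & !up$C4
  classification
}

#' Subdivide atypical ISGs
#'
#' Atypical genes present in the known-ISG reference become `reported`;
#' the remainder become `hidden` when they carry ISRE/STAT1 (GAS) motif
#' evidence in their regulatory regions and `noncanonical` otherwise.
#' Atypical genes missing from `motif_presence` are left `unassigned` with
#' a warning.
#'
#' @param classification A `"gene_classification"`.
#' @param known_isgs Character vector of reference ISG ids.
#' @param motif_presence Named logical vector (see [motif_presence()]);
#'   an optional user-supplied binding-evidence flag can be OR-ed in by
#'   the caller before passing.
#' @return The classification with `sublabel` filled on atypical genes.
#' @export
subdivide_atypical <- function(classification, known_isgs, motif_presence) {
  stopifnot(inherits(classification, "gene_classification"))
  aty <- classification$label == "atypical"
  sub <- rep(NA_character_, nrow(classification))
  g <- classification$gene
  reported <- aty & g %in% known_isgs
  rest <- aty & !reported
  pres <- motif_presence[g]
  missing_motif <- rest & is.na(pres)
  if (any(missing_motif))
    warning("atypical gene(s) absent from motif_presence left unassigned: ",
            paste(g[missing_motif], collapse = ", "))
  sub[reported] <- "reported"
  sub[rest & !is.na(pres) & pres] <- "hidden"
  sub[rest & !is.na(pres) & !pres] <- "noncanonical"
  sub[missing_motif] <- "unassigned"
  classification$sublabel <- sub
  classification
}

#' Summarize a classification
#'
#' @param classification A `"gene_classification"`.
#' @return A `"classification_report"` list: `class_counts`,
#'   `sublabel_counts`, `cluster_counts`, `class_by_cluster` crosstab and
#'   the per-gene table; `as_json()`-able via [jsonlite::toJSON].
#' @export
classification_report <- function(classification) {
  stopifnot(inherits(classification, "gene_classification"))
  lab <- factor(classification$label,
                levels = c("typical", "atypical", "none"))
  sub <- factor(classification$sublabel,
                levels = c("reported", "hidden", "noncanonical",
                           "unassigned"))
  rep_ <- list(
    n_genes = nrow(classification),
    class_counts = table(label = lab),
    sublabel_counts = table(sublabel = sub),
    cluster_counts = c(A = sum(classification$cluster_A %in% TRUE),
                       D = sum(classification$cluster_D %in% TRUE)),
    class_by_cluster_A = table(label = lab,
                               cluster_A = classification$cluster_A %in% TRUE),
    genes = classification
  )
  class(rep_) <- "classification_report"
  rep_
}

#' @export
print.classification_report <- function(x, ...) {
  cat("ISG classification over", x$n_genes, "genes\n")
  print(x$class_counts)
  if (any(x$sublabel_counts > 0)) {
    cat("atypical subdivision:\n")
    print(x$sublabel_counts)
  }
  cat(sprintf("heatmap clusters: A = %d, D = %d\n",
              x$cluster_counts[["A"]], x$cluster_counts[["D"]]))
  invisible(x)
}

#' JSON form of a classification report
#'
#' @param x A `"classification_report"`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
classification_report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "classification_report"))
  obj <- list(
    n_genes = x$n_genes,
    class_counts = as.list(setNames(as.integer(x$class_counts),
                                    names(x$class_counts))),
    sublabel_counts = as.list(setNames(as.integer(x$sublabel_counts),
                                       names(x$sublabel_counts))),
    cluster_counts = as.list(x$cluster_counts),
    genes = x$genes
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
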