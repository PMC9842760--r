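#' Position weight matrices and motif scanning
#'
#' Tools to build, read and score position weight matrices (PWMs) for the
#' transcription-factor motifs that drive interferon-stimulated gene (ISG)
#' transcription: the ISRE (bound by the ISGF3 = STAT1-STAT2-IRF9 complex),
#' the GAS element (STAT1 homodimers), NF-kB sites, and the minimal "IRE"
#' core element TTTC. Scanning is log-odds scoring in bits against a
#' background base model, on both strands.
#'
#' @name motifs
NULL

.BASES <- c("A", "C", "G", "T")

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Construct a PWM object
#'
#' @param name Motif name.
#' @param mat 4 x L numeric matrix of base counts or probabilities, rows in
#'   A, C, G, T order. A pseudocount is added to every cell and columns are
#'   renormalized to sum to 1.
#' @param pseudocount Pseudocount added per cell before normalization.
#' @param background Background base probabilities (A, C, G, T); default
#'   uniform.
#' @param threshold Score threshold as a fraction of the maximum achievable
#'   log-odds score, in (0, 1].
#' @param exact Optional literal word; when set, scanning matches the word
#'   exactly on both strands instead of scoring the matrix. Used for the
#'   4-mer IRE core, where any PWM threshold degenerates to string matching.
#' @return An object of class `"pwm"`.
#' @export
pwm <- function(name, mat, pseudocount = 0.01,
                background = rep(0.25, 4), threshold = 0.8,
                exact = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) == 4, ncol(mat) >= 4 || !is.null(exact))
  if (ncol(mat) < 4 && is.null(exact))
    stop("PWM must have length >= 4")
  if (any(mat < 0) || any(!is.finite(mat)))
    stop("PWM cells must be finite and non-negative")
  if (threshold <= 0 || threshold > 1)
    stop("threshold fraction must be in (0, 1]")
  if (length(background) != 4 || any(background <= 0))
    stop("background must be 4 positive probabilities")
  background <- background / sum(background)
  mat <- mat + pseudocount
  mat <- sweep(mat, 2, colSums(mat), "/")
  dimnames(mat) <- list(.BASES, NULL)
  structure(
    list(name = name, mat = mat, pseudocount = pseudocount,
         background = background, threshold = threshold, exact = exact),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (L = %d, threshold = %.2f x max score%s)\n",
              x$name, ncol(x$mat), x$threshold,
              if (!is.null(x$exact)) sprintf(", exact matcher '%s'", x$exact)
              else ""))
  print(round(x$mat, 3))
  invisible(x)
}

#' Build a PWM from an IUPAC consensus string
#'
#' Each consensus letter contributes probability 1 split equally over the
#' bases it allows (e.g. N gives 0.25 each, R gives 0.5 to A and G), then
#' the pseudocount is applied.
#'
#' @inheritParams pwm
#' @param consensus IUPAC consensus string.
#' @return A `"pwm"` object.
#' @export
pwm_from_consensus <- function(name, consensus, pseudocount = 0.01,
                               background = rep(0.25, 4), threshold = 0.8,
                               exact = NULL) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(letters, names(.IUPAC))
  if (length(bad)) stop("unknown IUPAC code(s): ", paste(bad, collapse = ", "))
  mat <- vapply(letters, function(ch) {
    col <- numeric(4)
    names(col) <- .BASES
    allowed <- .IUPAC[[ch]]
    col[allowed] <- 1 / length(allowed)
    col
  }, numeric(4))
  pwm(name, mat, pseudocount = pseudocount, background = background,
      threshold = threshold, exact = exact)
}

#' Bundled default motif models
#'
#' Consensus-derived placeholder matrices for the four motif families used
#' throughout the pipeline: ISRE (`AGTTTCNNTTTC` family), GAS
#' (`TTCNNNGAA`), NF-kB (`GGGRNNYYCC`) and the minimal IRE core element
#' `TTTC`, which is matched as an exact word on both strands. Editable
#' PFM files with the same matrices ship under
#' `system.file("extdata/motifs", package = "isgland")` and can be replaced
#' by JASPAR-format matrices via [read_pfm()].
#'
#' @param threshold Score threshold fraction applied to all PWMs.
#' @return Named list of `"pwm"` objects: ISRE, GAS, NFKB, IRE.
#' @export
default_motifs <- function(threshold = 0.8) {
  list(
    ISRE = pwm_from_consensus("ISRE", "AGTTTCNNTTTC", threshold = threshold),
    GAS  = pwm_from_consensus("GAS", "TTCNNNGAA", threshold = threshold),
    NFKB = pwm_from_consensus("NFKB", "GGGRNNYYCC", threshold = threshold),
    IRE  = pwm_from_consensus("IRE", "TTTC", threshold = threshold,
                              exact = "TTTC")
  )
}

#' Consensus (maximum-probability) sequence of a PWM
#'
#' @param x A `"pwm"` object.
#' @return Character string; the highest-probability base at each position
#'   (ties broken in A, C, G, T order). For exact matchers, the literal word.
#' @export
consensus_sequence <- function(x) {
  stopifnot(inherits(x, "pwm"))
  if (!is.null(x$exact)) return(x$exact)
  paste(.BASES[apply(x$mat, 2, which.max)], collapse = "")
}

#' Maximum achievable log-odds score of a PWM (bits)
#'
#' @param x A `"pwm"` object.
#' @return Sum over positions of the best per-base log2 odds.
#' @export
max_score <- function(x) {
  stopifnot(inherits(x, "pwm"))
  sum(apply(log2(x$mat / x$background), 2, max))
}

#' Log-odds score of a single window (bits)
#'
#' Scores one window of exactly the motif length: the sum over positions of
#' `log2(p_base / background_base)`. The ambiguity base N contributes 0
#' (it scores as the background scoring itself); other ambiguity codes are
#' rejected.
#'
#' @param x A `"pwm"` object.
#' @param window Character string of length `ncol(x$mat)` over A/C/G/T/N.
#' @return Score in bits.
#' @export
pwm_logodds_score <- function(x, window) {
  stopifnot(inherits(x, "pwm"))
  L <- ncol(x$mat)
  chars <- strsplit(toupper(window), "")[[1]]
  if (length(chars) != L)
    stop(sprintf("window length %d does not match motif length %d",
                 length(chars), L))
  idx <- match(chars, c(.BASES, "N"))
  if (anyNA(idx))
    stop("window contains characters outside A/C/G/T/N")
  lo <- rbind(log2(x$mat / x$background), 0)  # row 5: N scores 0
  sum(lo[cbind(idx, seq_len(L))])
}

.revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Reverse complement of an A/C/G/T/N string
#'
#' @param seq Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  vapply(seq, .revcomp, character(1), USE.NAMES = FALSE)
}

# vectorized sliding-window scores on the forward strand of one sequence;
# returns numeric vector of length n - L + 1 (or length 0)
.slide_scores <- function(lo5, idx, L) {
  n <- length(idx)
  nw <- n - L + 1
  if (nw < 1) return(numeric(0))
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    sc <- sc + lo5[cbind(idx[j:(j + nw - 1)], j)]
  }
  sc
}

.check_bases <- function(chars, what = "sequence") {
  idx <- match(chars, c(.BASES, "N"))
  if (anyNA(idx))
    stop(sprintf("%s contains characters outside A/C/G/T/N: %s", what,
                 paste(unique(chars[is.na(idx)]), collapse = ", ")))
  idx
}

#' Scan a sequence with a PWM on both strands
#'
#' Slides the motif over every position of the forward strand and of the
#' reverse complement, reporting windows whose log-odds score reaches
#' `threshold x max_score`. Reverse-strand hits are reported in
#' forward-strand coordinates (0-based start of the matched window).
#' For exact matchers (IRE) the literal word is matched on both strands.
#'
#' @param x A `"pwm"` object.
#' @param seq Sequence string (A/C/G/T/N; other ambiguity codes rejected).
#' @param seq_id Identifier recorded in the hit table.
#' @return Data frame with columns `seq_id`, `motif`, `start` (0-based),
#'   `strand` (`"+"`/`"-"`) and `score` (bits), one row per hit.
#' @export
scan_sequence <- function(x, seq, seq_id = "seq") {
  stopifnot(inherits(x, "pwm"), is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (nchar(seq) == 0) stop("empty sequence")
  L <- if (is.null(x$exact)) ncol(x$mat) else nchar(x$exact)
  n <- nchar(seq)
  empty <- data.frame(seq_id = character(0), motif = character(0),
                      start = integer(0), strand = character(0),
                      score = numeric(0))
  if (n < L) return(empty)
  if (!is.null(x$exact)) {
    word <- toupper(x$exact)
    bits <- sum(log2(0.25^-1) * rep(1, nchar(word)))  # exact word vs uniform bg
    hit0 <- function(subject, pattern) {
      m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
      if (m[1] == -1L) integer(0) else as.integer(m) - 1L
    }
    fwd <- hit0(seq, word)
    rc <- hit0(seq, .revcomp(word))
    nh <- length(fwd) + length(rc)
    if (nh == 0) return(empty)
    out <- data.frame(
      seq_id = rep(seq_id, nh),
      motif = rep(x$name, nh),
      start = c(fwd, rc),
      strand = c(rep("+", length(fwd)), rep("-", length(rc))),
      score = rep(bits, nh)
    )
    return(out[order(out$start, out$strand), , drop = FALSE])
  }
  chars <- strsplit(seq, "")[[1]]
  idx <- .check_bases(chars)
  lo5 <- rbind(log2(x$mat / x$background), 0)
  cutoff <- x$threshold * max_score(x)
  fwd_sc <- .slide_scores(lo5, idx, L)
  # reverse strand: score the reverse complement, map starts back
  rc_idx <- rev(c(4L, 3L, 2L, 1L, 5L)[idx])
  rc_sc <- .slide_scores(lo5, rc_idx, L)
  fwd_hit <- which(fwd_sc >= cutoff)
  rc_hit <- which(rc_sc >= cutoff)
  nh <- length(fwd_hit) + length(rc_hit)
  if (nh == 0) return(empty)
  out <- data.frame(
    seq_id = rep(seq_id, nh),
    motif = rep(x$name, nh),
    start = c(fwd_hit - 1L, n - L + 1L - rc_hit),
    strand = c(rep("+", length(fwd_hit)), rep("-", length(rc_hit))),
    score = c(fwd_sc[fwd_hit], rc_sc[rc_hit])
  )
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan many sequences with many motifs
#'
#' @param motifs Named list of `"pwm"` objects.
#' @param seqs Named character vector of sequences.
#' @return Combined hit data frame (see [scan_sequence()]).
#' @export
scan_sequences <- function(motifs, seqs) {
  stopifnot(is.list(motifs), length(names(seqs)) == length(seqs))
  res <- vector("list", length(motifs) * length(seqs))
  k <- 0
  for (m in motifs) {
    for (i in seq_along(seqs)) {
      k <- k + 1
      res[[k]] <- scan_sequence(m, seqs[[i]], seq_id = names(seqs)[i])
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-gene motif presence
#'
#' A gene is flagged TRUE when at least one hit of any of the listed motifs
#' falls in any of the gene's assigned regions (promoter and any linked
#' distal elements).
#'
#' @param hits Hit data frame from [scan_sequence()]/[scan_sequences()].
#' @param gene_regions Data frame with columns `gene` and `seq_id` mapping
#'   genes to region/sequence ids (a gene may map to several regions).
#' @param motif_names Motifs that count as evidence (default ISRE and GAS,
#'   the STAT1/ISGF3-binding elements).
#' @return Named logical vector over the genes in `gene_regions`.
#' @export
motif_presence <- function(hits, gene_regions,
                           motif_names = c("ISRE", "GAS")) {
  stopifnot(all(c("gene", "seq_id") %in% names(gene_regions)))
  genes <- unique(gene_regions$gene)
  if (!nrow(gene_regions)) return(setNames(logical(0), character(0)))
  hit_seqs <- unique(hits$seq_id[hits$motif %in% motif_names])
  has <- tapply(gene_regions$seq_id %in% hit_seqs, gene_regions$gene, any)
  out <- setNames(as.logical(has[genes]), genes)
  if (anyNA(out)) {
    warning("gene(s) with no region: ",
            paste(genes[is.na(out)], collapse = ", "))
    out[is.na(out)] <- FALSE
  }
  out
}

#' Read JASPAR-style PFM files
#'
#' Accepts the common text layout: a `>name` header line followed by four
#' rows for A, C, G, T, each either `A [ 3 0 12 ... ]` or a plain run of
#' numbers (counts or probabilities).
#'
#' @param path File containing one or more PFMs.
#' @inheritParams pwm
#' @return Named list of `"pwm"` objects.
#' @export
read_pfm <- function(path, pseudocount = 0.01, background = rep(0.25, 4),
                     threshold = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' header lines found in ", path)
  out <- list()
  for (s in starts) {
    header <- trimws(sub("^>", "", lines[s]))
    name <- strsplit(header, "[ \t]+")[[1]][1]
    block <- lines[(s + 1):(s + 4)]
    rows <- lapply(block, function(ln) {
      ln <- gsub("^[ \t]*[ACGTacgt][ \t]*", "", ln)
      ln <- gsub("[][]", " ", ln)
      as.numeric(strsplit(trimws(ln), "[ \t,]+")[[1]])
    })
    L <- unique(lengths(rows))
    if (length(L) != 1)
      stop("PFM '", name, "': rows have unequal lengths")
    mat <- do.call(rbind, rows)
    exact <- NULL
    if (identical(toupper(name), "IRE")) exact <- "TTTC"
    # already-normalized probability matrices keep their cells as-is
    pc <- if (all(mat > 0) && all(abs(colSums(mat) - 1) < 1e-3)) 0
          else pseudocount
    out[[name]] <- pwm(name, mat, pseudocount = pc,
                       background = background, threshold = threshold,
                       exact = exact)
  }
  out
}

#' Write PWMs as JASPAR-style PFM text
#'
#' @param motifs Named list of `"pwm"` objects.
#' @param path Output file.
#' @param digits Digits for probabilities.
#' @export
write_pfm <- function(motifs, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m$name), con)
    for (i in 1:4) {
      writeLines(sprintf("%s [ %s ]", .BASES[i],
                         paste(signif(m$mat[i, ], digits), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
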