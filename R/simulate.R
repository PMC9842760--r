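#' Synthetic factorial ISG experiment with planted ground truth
#'
#' Generates every input the pipeline consumes — NB counts under the 2x2
#' genotype (WT/KO) x treatment (untreated/IFN) design with planted gene
#' classes, promoter sequences with planted motif instances, a known-ISG
#' reference list, and peak tag-count tables with planted differential
#' regions — so each downstream stage can be validated against known truth.
#'
#' @name synthetic_data
NULL

.SIM_CLASSES <- c("typical", "atypical_hidden", "atypical_noncanonical",
                  "constitutive", "null")

#' Simulation configuration
#'
#' Defaults describe the reference scenario: 2,000 genes, triplicates per
#' condition, planted log2 effects of 2 for both typical and atypical ISGs,
#' NB dispersion 0.1 for expression and 0.05 for peak tags, log-uniform
#' baseline means, and mild log-normal library-size variation.
#'
#' @param n_genes Number of genes.
#' @param n_reps Replicates per condition.
#' @param class_fractions Named non-negative fractions over
#'   `typical`, `atypical_hidden`, `atypical_noncanonical`, `constitutive`;
#'   must sum to <= 1, the remainder are null genes.
#' @param lfc_typical Log2 IFN effect of typical ISGs (both genotypes).
#' @param lfc_atypical Log2 IFN effect of atypical ISGs (KO only).
#' @param lfc_constitutive Log2 KO-vs-WT baseline shift of constitutive
#'   genes (applied in both KO conditions).
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param baseline_mean_range Range for log-uniform baseline means.
#' @param library_size_factors Optional per-sample positive factors
#'   (length `4 * n_reps`); when NULL drawn log-normal with sdlog
#'   `library_size_sdlog`.
#' @param library_size_sdlog sdlog of the log-normal library-size draw.
#' @param seed Integer seed; identical configs give identical outputs.
#' @param promoter_length Promoter length (bp) upstream of each TSS.
#' @param motif_plant_rate_by_class Named list: per class, named vector of
#'   per-motif plant probabilities. Hidden atypical ISGs carry an ISRE;
#'   non-canonical atypical ISGs get no ISRE/GAS (NF-kB only).
#' @param n_peaks Number of peaks to simulate.
#' @param peak_diff_fraction Fraction of peaks planted as differential.
#' @param peak_lfc Planted log2 fold change of differential peaks
#'   (default 2, i.e. 4-fold).
#' @param peak_dispersion NB dispersion of peak tag counts.
#' @param peak_reps Replicates per condition in the peak experiment.
#' @param peak_mean_range Range for log-uniform baseline peak tag means.
#' @param peak_width Peak width (bp).
#' @param tss_distance_range Range (bp) of |summit - TSS| distances planted
#'   for peaks; must span both sides of the 3000-bp proximal cutoff.
#' @return A validated `"sim_config"` object.
#' @export
sim_config <- function(n_genes = 2000, n_reps = 3,
                       class_fractions = c(typical = 0.032,
                                           atypical_hidden = 0.022,
                                           atypical_noncanonical = 0.021,
                                           constitutive = 0.01),
                       lfc_typical = 2, lfc_atypical = 2,
                       lfc_constitutive = 1,
                       dispersion = 0.1,
                       baseline_mean_range = c(20, 2000),
                       library_size_factors = NULL,
                       library_size_sdlog = 0.2,
                       seed = 1,
                       promoter_length = 1000,
                       motif_plant_rate_by_class = list(
                         typical = c(ISRE = 1),
                         atypical_hidden = c(ISRE = 1),
                         atypical_noncanonical = c(NFKB = 0.5),
                         constitutive = c(),
                         null = c()
                       ),
                       n_peaks = 2000, peak_diff_fraction = 0.2,
                       peak_lfc = 2, peak_dispersion = 0.05,
                       peak_reps = 2,
                       peak_mean_range = c(50, 500),
                       peak_width = 200,
                       tss_distance_range = c(500, 20000)) {
  cfg <- list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
              class_fractions = class_fractions,
              lfc_typical = lfc_typical, lfc_atypical = lfc_atypical,
              lfc_constitutive = lfc_constitutive,
              dispersion = dispersion,
              baseline_mean_range = baseline_mean_range,
              library_size_factors = library_size_factors,
              library_size_sdlog = library_size_sdlog,
              seed = as.integer(seed),
              promoter_length = as.integer(promoter_length),
              motif_plant_rate_by_class = motif_plant_rate_by_class,
              n_peaks = as.integer(n_peaks),
              peak_diff_fraction = peak_diff_fraction,
              peak_lfc = peak_lfc, peak_dispersion = peak_dispersion,
              peak_reps = as.integer(peak_reps),
              peak_mean_range = peak_mean_range,
              peak_width = as.integer(peak_width),
              tss_distance_range = tss_distance_range)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg A `"sim_config"` object.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1) stop("n_genes must be positive")
  if (cfg$n_reps < 1) stop("replicate count must be positive")
  fr <- cfg$class_fractions
  if (length(fr) == 0) stop("empty class set")
  if (!all(names(fr) %in% setdiff(.SIM_CLASSES, "null")))
    stop("unknown class name(s): ",
         paste(setdiff(names(fr), .SIM_CLASSES), collapse = ", "))
  if (any(fr < 0) || sum(fr) > 1 + 1e-12)
    stop("class fractions must be non-negative and sum to <= 1")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (any(cfg$baseline_mean_range <= 0) ||
      diff(cfg$baseline_mean_range) < 0)
    stop("baseline_mean_range must be an increasing pair of positive reals")
  if (!is.null(cfg$library_size_factors)) {
    if (length(cfg$library_size_factors) != 4 * cfg$n_reps ||
        any(cfg$library_size_factors <= 0))
      stop("library_size_factors must be ", 4 * cfg$n_reps,
           " positive values")
  }
  if (cfg$promoter_length < 20) stop("promoter_length too short")
  invisible(cfg)
}

.rnbinom_mu <- function(n, mu, alpha) {
  # NB with variance mu + alpha mu^2; alpha = 0 degenerates to Poisson
  if (alpha == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu,
                                                          size = 1 / alpha)
}

.planted_classes <- function(cfg) {
  fr <- cfg$class_fractions
  n_per <- floor(fr * cfg$n_genes)
  cls <- rep("null", cfg$n_genes)
  i <- 1
  for (nm in names(n_per)) {
    if (n_per[[nm]] > 0) {
      cls[i:(i + n_per[[nm]] - 1)] <- nm
      i <- i + n_per[[nm]]
    }
  }
  cls
}

#' Simulate NB counts under the 2x2 factorial with planted classes
#'
#' Counts are NB with mean `baseline x size factor x 2^(planted effects
#' active in that condition)` and dispersion alpha. Typical ISGs carry
#' `lfc_typical` under IFN in both genotypes; atypical (hidden and
#' non-canonical) ISGs carry `lfc_atypical` under IFN in KO only;
#' constitutive genes are shifted in KO regardless of treatment; null genes
#' carry no effect.
#'
#' @param cfg A `"sim_config"`.
#' @return List with `counts` (gene x sample integer matrix), `samples`
#'   (sample sheet: sample, genotype, treatment, replicate, condition),
#'   and `truth` (per-gene: class and true log2 effects for contrasts
#'   C1-C4).
#' @export
simulate_counts <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  cls <- .planted_classes(cfg)
  conds <- expand.grid(treatment = c("untreated", "IFN"),
                       genotype = c("WT", "KO"),
                       stringsAsFactors = FALSE)[, c("genotype", "treatment")]
  samples <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i)
    data.frame(genotype = conds$genotype[i], treatment = conds$treatment[i],
               replicate = seq_len(cfg$n_reps))))
  samples$condition <- paste(samples$genotype, samples$treatment, sep = "_")
  samples$sample <- paste(samples$condition, samples$replicate, sep = "_")
  samples <- samples[, c("sample", "genotype", "treatment", "replicate",
                         "condition")]
  sf <- cfg$library_size_factors
  if (is.null(sf))
    sf <- stats::rlnorm(nrow(samples), 0, cfg$library_size_sdlog)
  baseline <- exp(stats::runif(cfg$n_genes,
                               log(cfg$baseline_mean_range[1]),
                               log(cfg$baseline_mean_range[2])))
  # per-gene true log2 effect in each condition relative to WT untreated
  eff <- matrix(0, cfg$n_genes, 4,
                dimnames = list(genes, c("WT_untreated", "WT_IFN",
                                         "KO_untreated", "KO_IFN")))
  is_typ <- cls == "typical"
  is_aty <- cls %in% c("atypical_hidden", "atypical_noncanonical")
  is_con <- cls == "constitutive"
  eff[is_typ, "WT_IFN"] <- cfg$lfc_typical
  eff[is_typ, "KO_IFN"] <- cfg$lfc_typical
  eff[is_aty, "KO_IFN"] <- cfg$lfc_atypical
  eff[is_con, "KO_untreated"] <- eff[is_con, "KO_untreated"] +
    cfg$lfc_constitutive
  eff[is_con, "KO_IFN"] <- eff[is_con, "KO_IFN"] + cfg$lfc_constitutive
  counts <- matrix(0L, cfg$n_genes, nrow(samples),
                   dimnames = list(genes, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- baseline * sf[j] * 2^eff[, samples$condition[j]]
    counts[, j] <- .rnbinom_mu(cfg$n_genes, mu, cfg$dispersion)
  }
  truth <- data.frame(
    gene = genes, class = cls, baseline_mean = baseline,
    lfc_c1 = eff[, "WT_IFN"] - eff[, "WT_untreated"],
    lfc_c2 = eff[, "KO_IFN"] - eff[, "KO_untreated"],
    lfc_c3 = eff[, "KO_IFN"] - eff[, "WT_IFN"],
    lfc_c4 = eff[, "KO_untreated"] - eff[, "WT_untreated"],
    row.names = NULL
  )
  list(counts = counts, samples = samples, truth = truth,
       size_factors_true = setNames(sf, samples$sample))
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate promoter sequences with planted motif instances
#'
#' Each gene receives an i.i.d. uniform-base background promoter; motif
#' consensus (maximum-probability) instances are planted at random
#' non-overlapping positions on a random strand according to the per-class
#' plant rates. Hidden atypical ISGs carry an ISRE instance; non-canonical
#' atypical ISGs are never given an ISRE or GAS instance.
#'
#' @param cfg A `"sim_config"`.
#' @param truth Per-gene truth table from [simulate_counts()].
#' @param motifs Motif models used for consensus planting (default
#'   [default_motifs()]).
#' @return List with `sequences` (named character vector, one promoter per
#'   gene), `tss` (gene, chrom, tss 0-based, strand), and `plants`
#'   (gene, motif, start 0-based, strand), the planted-instance record.
#' @export
simulate_promoters <- function(cfg, truth, motifs = default_motifs()) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  cons <- vapply(motifs, consensus_sequence, character(1))
  if (any(nchar(cons) > cfg$promoter_length))
    stop("promoter_length shorter than a motif")
  forbidden <- c("ISRE", "GAS")
  plants <- list()
  seqs <- character(nrow(truth))
  names(seqs) <- truth$gene
  for (i in seq_len(nrow(truth))) {
    s <- .random_seq(cfg$promoter_length)
    rates <- cfg$motif_plant_rate_by_class[[truth$class[i]]]
    if (truth$class[i] == "atypical_noncanonical" &&
        any(names(rates) %in% forbidden))
      stop("non-canonical atypical genes must not be planted with ISRE/GAS")
    occupied <- integer(0)
    if (length(rates)) {
      for (m in names(rates)) {
        if (stats::runif(1) >= rates[[m]]) next
        word <- cons[[m]]
        L <- nchar(word)
        strand <- sample(c("+", "-"), 1)
        inst <- if (strand == "+") word else .revcomp(word)
        # rejection-sample a position that does not overlap earlier plants
        for (try in 1:100) {
          start0 <- sample.int(cfg$promoter_length - L + 1, 1) - 1L
          span <- start0:(start0 + L - 1)
          if (!length(intersect(span, occupied))) break
        }
        occupied <- c(occupied, span)
        substr(s, start0 + 1, start0 + L) <- inst
        plants[[length(plants) + 1]] <- data.frame(
          gene = truth$gene[i], motif = m, start = start0, strand = strand)
      }
    }
    seqs[i] <- s
  }
  plants <- if (length(plants)) do.call(rbind, plants)
            else data.frame(gene = character(0), motif = character(0),
                            start = integer(0), strand = character(0))
  # one gene per "chromosome" region: TSS right after the promoter
  tss <- data.frame(gene = truth$gene, chrom = paste0("chr_", truth$gene),
                    tss = cfg$promoter_length, strand = "+")
  list(sequences = seqs, tss = tss, plants = plants)
}

#' Simulate the known-ISG reference list
#'
#' Emulates a database lookup of previously reported interferon-inducible
#' genes: all typical ISGs plus a random `reported_fraction` of the planted
#' atypical genes (which thereby become "reported atypical" downstream).
#'
#' @param truth Per-gene truth table.
#' @param reported_fraction Probability that an atypical gene is already
#'   in the reference, in \[0, 1\].
#' @param seed Integer seed.
#' @return Character vector of gene ids.
#' @export
simulate_known_isg_reference <- function(truth, reported_fraction = 0.43,
                                         seed = 1) {
  stopifnot(reported_fraction >= 0, reported_fraction <= 1)
  set.seed(seed + 2L)
  typical <- truth$gene[truth$class == "typical"]
  atypical <- truth$gene[truth$class %in% c("atypical_hidden",
                                            "atypical_noncanonical")]
  reported <- atypical[stats::runif(length(atypical)) < reported_fraction]
  sort(c(typical, reported))
}

#' Simulate peaks with planted differential regions
#'
#' Places peaks at known signed distances from gene TSSs on a synthetic
#' chromosome layout (one widely spaced gene per peak), draws NB tag
#' counts for a two-condition design, plants a `peak_diff_fraction` subset
#' with a true log2 fold change of `peak_lfc` in the second condition, and
#' plants an ISRE consensus instance in the sequence of every differential
#' peak so that motif enrichment has a known answer.
#'
#' @param cfg A `"sim_config"`.
#' @param conditions Labels for the two peak-experiment conditions.
#' @return List with `peaks` (id, chrom, start, end, summit, 0-based
#'   half-open), `counts` (peak x sample tag matrix), `samples`, `tss`
#'   (gene, chrom, tss, strand), `sequences` (per-peak, named by peak id),
#'   and `truth` (peak, is_diff, true_lfc, tss_distance, nearest_gene).
#' @export
simulate_peaks <- function(cfg, conditions = c("WT", "KO_IFN")) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 3L)
  dr <- cfg$tss_distance_range
  if (max(abs(dr)) <= 3000 || min(abs(dr)) >= 3000)
    warning("tss_distance_range does not span both sides of the 3000-bp ",
            "proximal cutoff")
  n <- cfg$n_peaks
  spacing <- 2 * (max(abs(dr)) + cfg$peak_width + 1000)
  if (spacing <= 0) stop("degenerate genome length")
  ids <- sprintf("peak%05d", seq_len(n))
  gene <- sprintf("pg%05d", seq_len(n))
  tss_pos <- as.integer(spacing) * seq_len(n)
  dist <- sample(seq(as.integer(dr[1]), as.integer(dr[2])), n,
                 replace = TRUE) *
    sample(c(-1L, 1L), n, replace = TRUE)
  summit <- tss_pos + dist
  start <- summit - cfg$peak_width %/% 2L
  end <- start + cfg$peak_width
  peaks <- data.frame(id = ids, chrom = "chrS", start = start, end = end,
                      summit = summit)
  tss <- data.frame(gene = gene, chrom = "chrS", tss = tss_pos,
                    strand = sample(c("+", "-"), n, replace = TRUE))
  n_diff <- round(cfg$peak_diff_fraction * n)
  is_diff <- c(rep(TRUE, n_diff), rep(FALSE, n - n_diff))
  samples <- data.frame(
    sample = paste(rep(conditions, each = cfg$peak_reps),
                   seq_len(cfg$peak_reps), sep = "_"),
    condition = rep(conditions, each = cfg$peak_reps)
  )
  base <- exp(stats::runif(n, log(cfg$peak_mean_range[1]),
                           log(cfg$peak_mean_range[2])))
  counts <- matrix(0L, n, nrow(samples),
                   dimnames = list(ids, samples$sample))
  for (j in seq_len(nrow(samples))) {
    fc <- ifelse(is_diff & samples$condition[j] == conditions[2],
                 2^cfg$peak_lfc, 1)
    counts[, j] <- .rnbinom_mu(n, base * fc, cfg$peak_dispersion)
  }
  isre <- consensus_sequence(default_motifs()$ISRE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- .random_seq(cfg$peak_width)
    if (is_diff[i]) {
      pos <- sample.int(cfg$peak_width - nchar(isre) + 1, 1)
      substr(s, pos, pos + nchar(isre) - 1) <- isre
    }
    s
  }, character(1))
  names(seqs) <- ids
  truth <- data.frame(peak = ids, is_diff = is_diff,
                      true_lfc = ifelse(is_diff, cfg$peak_lfc, 0),
                      tss_distance = dist, nearest_gene = gene)
  list(peaks = peaks, counts = counts, samples = samples, tss = tss,
       sequences = seqs, truth = truth)
}
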