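test_that("identical configs give bit-identical outputs", {
  cfg <- sim_config(n_genes = 120, n_reps = 2, seed = 77,
                    n_peaks = 60, promoter_length = 200)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  pa <- simulate_promoters(cfg, a$truth)
  pb <- simulate_promoters(cfg, b$truth)
  expect_identical(pa$sequences, pb$sequences)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(pa$sequences, f1); write_fasta(pb$sequences, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  ka <- simulate_peaks(cfg); kb <- simulate_peaks(cfg)
  expect_identical(ka$counts, kb$counts)
  b1 <- withr::local_tempfile(); b2 <- withr::local_tempfile()
  write_bed(ka$peaks, b1); write_bed(kb$peaks, b2)
  expect_identical(readLines(b1), readLines(b2))
})

test_that("the mean model is exact in the zero-dispersion limit", {
  cfg <- sim_config(n_genes = 40, n_reps = 400, dispersion = 0,
                    lfc_typical = 1,
                    class_fractions = c(typical = 0.5),
                    baseline_mean_range = c(100, 1000),
                    library_size_factors = rep(1, 1600), seed = 19)
  sim <- simulate_counts(cfg)
  typ <- sim$truth$class == "typical"
  m_ifn <- rowMeans(sim$counts[typ, sim$samples$condition == "WT_IFN"])
  m_unt <- rowMeans(sim$counts[typ, sim$samples$condition == "WT_untreated"])
  expect_equal(mean(m_ifn / m_unt), 2, tolerance = 0.02)
})

test_that("simulated counts obey the NB mean/variance law", {
  # 4 conditions x 2500 null replicates = 10000 iid draws per gene
  cfg <- sim_config(n_genes = 5, n_reps = 2500,
                    class_fractions = c(typical = 0), dispersion = 0.1,
                    library_size_factors = rep(1, 10000), seed = 3)
  sim <- simulate_counts(cfg)
  for (i in 1:5) {
    mu <- sim$truth$baseline_mean[i]
    expect_equal(var(as.numeric(sim$counts[i, ])), mu + 0.1 * mu^2,
                 tolerance = 0.05)
  }
})

test_that("an all-null simulation yields nominal false-positive rates", {
  cfg <- sim_config(n_genes = 5000, n_reps = 3,
                    class_fractions = c(typical = 0), dispersion = 0.1,
                    seed = 13)
  sim <- simulate_counts(cfg)
  r <- wald_contrast(sim$counts, sim$samples, "C2",
                     dispersions = uniform_disp(sim$counts, 0.1))
  frac <- mean(r$pvalue < 0.05, na.rm = TRUE)
  band <- 3 * sqrt(0.05 * 0.95 / sum(!is.na(r$pvalue)))
  expect_gt(frac, 0.05 - band)
  expect_lt(frac, 0.05 + band)
})

test_that("truth records are complete over a closed class vocabulary", {
  cfg <- sim_config(n_genes = 300, seed = 5, n_peaks = 80)
  sim <- simulate_counts(cfg)
  expect_equal(nrow(sim$truth), 300)
  expect_equal(anyDuplicated(sim$truth$gene), 0L)
  expect_true(all(sim$truth$class %in%
                    c("typical", "atypical_hidden", "atypical_noncanonical",
                      "constitutive", "null")))
  pk <- simulate_peaks(cfg)
  expect_equal(nrow(pk$truth), 80)
  # planted effects follow the factorial structure
  expect_true(all(sim$truth$lfc_c1[sim$truth$class == "typical"] ==
                    cfg$lfc_typical))
  aty <- grepl("^atypical", sim$truth$class)
  expect_true(all(sim$truth$lfc_c1[aty] == 0))
  expect_true(all(sim$truth$lfc_c2[aty] == cfg$lfc_atypical))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_reps = 0), "positive")
  expect_error(sim_config(class_fractions = c()), "empty")
  expect_error(sim_config(class_fractions = c(typical = 0.7,
                                              atypical_hidden = 0.5)),
               "sum")
  expect_error(sim_config(class_fractions = c(bogus = 0.1)), "unknown")
  expect_error(sim_config(dispersion = -1), "dispersion")
})

test_that("promoters carry planted motifs consistent with the class", {
  cfg <- sim_config(n_genes = 200, promoter_length = 300, seed = 41)
  sim <- simulate_counts(cfg)
  prom <- simulate_promoters(cfg, sim$truth)
  nonc <- sim$truth$gene[sim$truth$class == "atypical_noncanonical"]
  expect_false(any(prom$plants$motif %in% c("ISRE", "GAS") &
                     prom$plants$gene %in% nonc))
  hid <- sim$truth$gene[sim$truth$class == "atypical_hidden"]
  expect_true(all(hid %in% prom$plants$gene[prom$plants$motif == "ISRE"]))
  # motif longer than the promoter is rejected
  tiny <- sim_config(n_genes = 5, promoter_length = 20, seed = 1)
  expect_error(sim_config(promoter_length = 8), "short")
  expect_s3_class(tiny, "sim_config")
})

test_that("planted consensus instances are recovered by the scanner", {
  cfg <- sim_config(n_genes = 120,
                    class_fractions = c(atypical_hidden = 1),
                    promoter_length = 400, seed = 23)
  sim <- simulate_counts(cfg)
  prom <- simulate_promoters(cfg, sim$truth)
  hits <- scan_sequences(default_motifs()["ISRE"], prom$sequences)
  planted <- prom$plants[prom$plants$motif == "ISRE", ]
  expect_equal(nrow(planted), 120)  # plant rate 1.0
  found <- merge(planted, hits,
                 by.x = c("gene", "start", "strand"),
                 by.y = c("seq_id", "start", "strand"))
  expect_equal(nrow(found), nrow(planted))  # 100% recovery
})

test_that("the known-ISG reference follows the reported fraction", {
  truth <- data.frame(
    gene = sprintf("g%04d", 1:1000),
    class = c(rep("typical", 200), rep("atypical_hidden", 303),
              rep("atypical_noncanonical", 302), rep("null", 195))
  )
  # fraction 0: typical genes only
  expect_setequal(simulate_known_isg_reference(truth, 0, seed = 1),
                  truth$gene[truth$class == "typical"])
  # fraction 1: every atypical gene reported -> no hidden/non-canonical left
  all_ref <- simulate_known_isg_reference(truth, 1, seed = 1)
  expect_setequal(all_ref, truth$gene[truth$class != "null"])
  # fraction 0.43 over 605 atypical genes: binomial expectation ~260
  ref <- simulate_known_isg_reference(truth, 0.43, seed = 7)
  n_rep <- sum(!ref %in% truth$gene[truth$class == "typical"])
  expect_gt(n_rep, 605 * 0.43 - 3 * sqrt(605 * 0.43 * 0.57))
  expect_lt(n_rep, 605 * 0.43 + 3 * sqrt(605 * 0.43 * 0.57))
})

test_that("peak simulation respects the TSS-distance layout", {
  cfg <- sim_config(n_peaks = 100, seed = 9,
                    tss_distance_range = c(100, 2500))
  expect_warning(pk <- simulate_peaks(cfg), "3000")
  ann <- annotate_tss_distance(pk$peaks, pk$tss)
  sets <- split_proximal_distal(ann)
  expect_equal(nrow(sets$distal), 0)  # everything within 3000 bp
  expect_equal(nrow(sets$proximal), 100)
})
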