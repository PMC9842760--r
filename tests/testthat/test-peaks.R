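test_that("TSS distances follow the strand-aware sign convention", {
  peaks <- data.frame(id = c("p1", "p2"), chrom = "chr1",
                      start = c(4900, 4900), end = c(5100, 5100))
  tss_plus <- data.frame(gene = "gA", chrom = "chr1", tss = 4000,
                         strand = "+")
  ann <- annotate_tss_distance(peaks, tss_plus)
  expect_equal(ann$tss_distance, c(1000, 1000))  # summit 5000, downstream
  expect_true(all(ann$proximal))
  tss_minus <- transform(tss_plus, strand = "-")
  ann2 <- annotate_tss_distance(peaks, tss_minus)
  expect_equal(ann2$tss_distance, c(-1000, -1000))  # upstream in gene frame
  # ties broken by the smaller gene id
  tie <- data.frame(gene = c("zz", "aa"), chrom = "chr1",
                    tss = c(4000, 6000), strand = "+")
  ann3 <- annotate_tss_distance(peaks, tie)
  expect_equal(ann3$nearest_gene, c("aa", "aa"))
  # unknown chromosome flagged and excluded
  far <- data.frame(id = "p3", chrom = "chrX", start = 0, end = 10)
  expect_warning(ann4 <- annotate_tss_distance(rbind(peaks, far), tss_plus),
                 "absent")
  expect_true(ann4$excluded[3])
})

test_that("nearest-TSS assignment equals brute-force minimization", {
  set.seed(99)
  for (rep in 1:3) {
    n_peaks <- 150; n_tss <- 60
    peaks <- data.frame(id = sprintf("p%03d", 1:n_peaks),
                        chrom = sample(c("c1", "c2"), n_peaks, TRUE),
                        start = sample.int(1e6, n_peaks))
    peaks$end <- peaks$start + 200
    tss <- data.frame(gene = sprintf("g%03d", 1:n_tss),
                      chrom = sample(c("c1", "c2"), n_tss, TRUE),
                      tss = sample.int(1e6, n_tss),
                      strand = sample(c("+", "-"), n_tss, TRUE))
    ann <- annotate_tss_distance(peaks, tss)
    for (i in seq_len(n_peaks)) {
      cand <- tss[tss$chrom == peaks$chrom[i], ]
      if (!nrow(cand)) { expect_true(ann$excluded[i]); next }
      summit <- (peaks$start[i] + peaks$end[i]) %/% 2
      d <- abs(summit - cand$tss)
      best <- cand[d == min(d), ]
      best <- best[order(best$gene), ][1, ]
      expect_equal(ann$nearest_gene[i], best$gene)
      expected <- summit - best$tss
      if (best$strand == "-") expected <- -expected
      expect_equal(ann$tss_distance[i], expected)
    }
  }
})

test_that("proximal/distal split uses the inclusive 3000-bp boundary", {
  d <- c(0, 2999, 3000, 3001, -5000)
  peaks <- data.frame(id = paste0("p", 1:5), chrom = "c", start = 0,
                      end = 10, tss_distance = d, excluded = FALSE)
  sets <- split_proximal_distal(peaks)
  expect_setequal(sets$proximal$tss_distance, c(0, 2999, 3000))
  expect_setequal(sets$distal$tss_distance, c(3001, -5000))
  expect_equal(nrow(sets$proximal) + nrow(sets$distal), 5)
  all_far <- transform(peaks, tss_distance = tss_distance + 10000)
  expect_equal(nrow(split_proximal_distal(all_far)$proximal), 0)
  expect_error(split_proximal_distal(data.frame(id = "p", chrom = "c",
                                                start = 0, end = 1)),
               "not annotated")
})

test_that("window quantification sums a half-open 1000-bp window", {
  peaks <- data.frame(id = "pk", chrom = "c1", start = 900, end = 1100,
                      summit = 1000)
  uniform <- data.frame(chrom = "c1", pos = 0:2999, s1 = 1, s2 = 2)
  w <- quantify_window(peaks, uniform)
  expect_equal(w["pk", ], c(s1 = 1000, s2 = 2000))
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      s1 = numeric(0))
  expect_equal(unname(quantify_window(peaks, empty)[1, 1]), 0)
  # point signal at summit + 600 falls outside [summit-500, summit+500)
  pt <- data.frame(chrom = "c1", pos = c(1599, 1600, 499, 500), s1 = 1)
  w2 <- quantify_window(peaks, pt)
  expect_equal(unname(w2[1, 1]), 1)  # only pos 500 and... check below
  # boundary accounting: 1500..  pos 1499 in, 1500 out; 500 in, 499 out
  pt2 <- data.frame(chrom = "c1", pos = c(1499, 1500, 500, 499), s1 = 1)
  expect_equal(unname(quantify_window(peaks, pt2)[1, 1]), 2)
  # truncation at chromosome start is flagged
  near0 <- data.frame(id = "p0", chrom = "c1", start = 0, end = 200)
  w3 <- quantify_window(near0, uniform)
  expect_equal(attr(w3, "truncated"), "p0")
})

test_that("differential peaks recover planted 4-fold regions", {
  cfg <- sim_config(n_peaks = 400, seed = 17)
  pk <- simulate_peaks(cfg)
  diff <- differential_peaks(pk$counts, pk$samples, c("KO_IFN", "WT"))
  planted <- pk$truth$is_diff
  rec <- mean(diff$significant[planted] & diff$direction[planted] == "up")
  expect_gte(rec, 0.9)
  expect_lt(mean(diff$significant[!planted]), 0.05)
  # identical normalized counts -> log2fc ~ 0, never significant
  flat <- matrix(50L, 30, 4, dimnames = list(paste0("p", 1:30), NULL))
  flat_samp <- data.frame(condition = rep(c("A", "B"), each = 2))
  dflat <- differential_peaks(flat, flat_samp, c("B", "A"),
                              dispersions = setNames(rep(0.05, 30),
                                                     rownames(flat)))
  expect_equal(dflat$log2fc, rep(0, 30))
  expect_false(any(dflat$significant))
})

test_that("BED round-trips preserve intervals bit-exactly", {
  cfg <- sim_config(n_peaks = 50, seed = 3)
  pk <- simulate_peaks(cfg)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(pk$peaks, path)
  back <- read_bed(path)
  expect_identical(back$start, pk$peaks$start)
  expect_identical(back$end, pk$peaks$end)
  expect_identical(back$id, pk$peaks$id)
  ann <- annotate_tss_distance(back, pk$tss)
  path2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(ann, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("enrichment hand-off keeps foreground within background", {
  cfg <- sim_config(n_peaks = 300, seed = 29)
  pk <- simulate_peaks(cfg)
  diff <- differential_peaks(pk$counts, pk$samples, c("KO_IFN", "WT"))
  reg <- regions_to_enrichment(diff, pk$peaks, pk$sequences, "up")
  expect_true(all(reg$foreground %in% reg$background))
  expect_setequal(reg$background, diff$peak[!is.na(diff$pvalue)])
  expect_equal(sort(names(reg$sequences)), sort(reg$background))
  # no significant peaks in the requested direction -> empty + message
  diff0 <- diff
  diff0$significant <- FALSE
  expect_message(reg0 <- regions_to_enrichment(diff0, pk$peaks,
                                               pk$sequences, "up"),
                 "skipped")
  expect_length(reg0$foreground, 0)
  # chromosome-level sequence extraction
  genome <- c(c1 = "AAACCCGGGTTTAAACCCGGG")
  small <- data.frame(id = c("q1", "q2"), chrom = "c1",
                      start = c(0, 3), end = c(3, 9))
  dsmall <- data.frame(peak = c("q1", "q2"), pvalue = c(0.001, 0.5),
                       padj = c(0.002, 0.5), log2fc = c(2, 0),
                       significant = c(TRUE, FALSE),
                       direction = c("up", "up"))
  regs <- regions_to_enrichment(dsmall, small, genome, "up")
  expect_equal(unname(regs$sequences), c("AAA", "CCCGGG"))
  bad <- data.frame(id = "q3", chrom = "c1", start = 10, end = 99)
  dbad <- data.frame(peak = "q3", pvalue = 0.01, padj = 0.01, log2fc = 2,
                     significant = TRUE, direction = "up")
  expect_error(regions_to_enrichment(dbad, bad, genome, "up"), "bounds")
})
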