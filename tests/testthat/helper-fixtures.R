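# shared fixtures: all synthetic, built in code at test time

# small two-group count matrix with known group means (size factors all 1)
two_group_counts <- function(n_genes, mu0, lfc = 0, n_per = 3, alpha = 0.1,
                             seed = 1) {
  set.seed(seed)
  counts <- cbind(
    matrix(rnbinom(n_genes * n_per, mu = mu0, size = 1 / alpha),
           n_genes, n_per),
    matrix(rnbinom(n_genes * n_per, mu = mu0 * 2^lfc, size = 1 / alpha),
           n_genes, n_per)
  )
  rownames(counts) <- paste0("g", seq_len(n_genes))
  colnames(counts) <- c(paste0("A", seq_len(n_per)),
                        paste0("B", seq_len(n_per)))
  list(counts = counts, condition = rep(c("A", "B"), each = n_per))
}

# truth table over all (C1, C2, C3, C4) boolean patterns
all_call_patterns <- function() {
  g <- expand.grid(C1 = c(FALSE, TRUE), C2 = c(FALSE, TRUE),
                   C3 = c(FALSE, TRUE), C4 = c(FALSE, TRUE))
  data.frame(gene = sprintf("p%02d", seq_len(nrow(g))), g)
}

# independent hypergeometric enumeration oracle (minimum-likelihood rule),
# written from the definition with choose(); kept free of package code
enum_hyper_two_tailed <- function(k, K, N, n) {
  xs <- max(0, n - (N - K)):min(n, K)
  pmass <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  pk <- choose(K, k) * choose(N - K, n - k) / choose(N, n)
  min(1, sum(pmass[pmass <= pk * (1 + 1e-7)]))
}

# independent BH step-up oracle
enum_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

uniform_disp <- function(counts, alpha) {
  setNames(rep(alpha, nrow(counts)), rownames(counts))
}
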