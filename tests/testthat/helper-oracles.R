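# Independent oracles used to check the package's statistics, written from
# definitions rather than sharing any code path with the implementation.

# BH step-up by definition: adjusted_i = min over all j with p_j ranked at or
# above p_i of m * p_(j) / j (double loop, no cummin tricks)
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(vapply(i:m, function(j) min(1, m * ps[j] / j), numeric(1)))
  }, numeric(1))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# exhaustive hypergeometric upper tail: enumerate every size-n draw from a
# background of N genes of which the first K are category members
enum_hyper_upper <- function(N, K, n, k) {
  if (n == 0) return(if (k == 0) 1 else NA_real_)
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Welch two-sided p from the textbook closed form
welch_p <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(abs(tstat), df, lower.tail = FALSE)
}

# tiny expression matrix + design builder for hand examples; rows are genes,
# `groups` maps sample names to conditions
toy_matrix <- function(values, genes, samples, conditions) {
  values <- matrix(values, nrow = length(genes),
                   dimnames = list(NULL, samples))
  expr <- tibble::as_tibble(values)
  expr <- dplyr::bind_cols(tibble::tibble(gene = genes), expr)
  design <- tibble::tibble(sample = samples, condition = conditions)
  attr(expr, "design") <- design
  expr
}

# DE-shaped table for concordance tests without running a test
fake_de <- function(gene, fc, fdr, numerator = "A", denominator = "B") {
  df <- tibble::tibble(gene = gene,
                       mean_a = fc, mean_b = rep(1, length(fc)),
                       fc = fc, log2fc = log2(fc),
                       p = fdr, fdr = fdr,
                       direction = ifelse(fc > 1, "up",
                                          ifelse(fc < 1, "down", "flat")))
  shhconcord:::new_shh_de(df, comparison = paste0(numerator, "_vs_", denominator),
                          numerator = numerator, denominator = denominator,
                          method = "welch_t")
}

printed_top30_path <- function() {
  system.file("extdata", "top30_concordant_printed.tsv", package = "shhconcord")
}
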