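#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' background of `N` of which `K` belong to the category, the probability of
#' observing `k` or more category members. The over-representation
#' convention: the observed overlap is included in the tail.
#'
#' @param N Background size.
#' @param K Category members within the background.
#' @param n Query size (within the background).
#' @param k Observed overlap.
#' @return The p-value in (0, 1].
#' @examples
#' hypergeom_upper(20, 5, 4, 4) # 5 / choose(20, 4)
#' @export
hypergeom_upper <- function(N, K, n, k) {
  check_hyper_bounds(N, K, n, k)
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

check_hyper_bounds <- function(N, K, n, k) {
  ok <- length(N) == 1L && length(K) == 1L && length(n) == 1L && length(k) == 1L &&
    N >= 0 && K >= 0 && K <= N && n >= 0 && n <= N && k >= 0 && k <= min(n, K)
  if (!ok) abort("require 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(n, K)")
  invisible(TRUE)
}

#' Fold enrichment of a category in a query
#'
#' `(k/n) / (K/N)`: the category's share of the query relative to its share
#' of the background. 1 means no enrichment; values above 1 mean
#' over-representation.
#'
#' @inheritParams hypergeom_upper
#' @return Non-negative fold enrichment.
#' @export
fold_enrichment <- function(N, K, n, k) {
  check_hyper_bounds(N, K, n, k)
  if (K == 0) abort("category has no members in the background (K = 0)")
  if (n == 0) abort("empty query (n = 0)")
  (k / n) / (K / N)
}

#' Hypergeometric over-representation of gene categories
#'
#' For each category, members are intersected with the background to give
#' `K`, the overlap with the query gives `k`, and an upper-tail
#' hypergeometric p-value plus fold enrichment are computed. Query genes
#' outside the background are dropped with a warning.
#'
#' @param query Character vector of query gene symbols.
#' @param gene_sets Tidy gene-set tibble (`set`, `source`, `gene`), e.g. from
#'   [read_gene_sets()].
#' @param background Character vector: the gene universe (typically all genes
#'   measured in both experiments).
#' @param adjust `"none"` (default; categories are few and pre-specified) or
#'   `"bh"` for Benjamini-Hochberg across categories.
#' @return A tibble of class `shh_enrichment`, one row per category:
#'   `category`, `N`, `K`, `n`, `k`, `fold_enrichment`, `p` (and `p_adj` when
#'   `adjust = "bh"`), `overlap_genes` (list column). Category order follows
#'   `gene_sets`.
#' @examples
#' sets <- tibble::tibble(set = "OFC", source = "curated",
#'                        gene = c("Gas1", "Foxf2", "Efnb1"))
#' enrich(c("Gas1", "Foxf2", "Gli1"), sets,
#'        background = c(paste0("g", 1:17), "Gas1", "Foxf2", "Efnb1"))
#' @export
enrich <- function(query, gene_sets, background, adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  background <- unique(background)
  if (length(background) == 0L) abort("background must be non-empty")
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside) > 0L) {
    warn(paste0(length(outside), " query gene(s) outside the background dropped"))
    query <- intersect(query, background)
  }
  N <- length(background)
  n <- length(query)
  sets <- attr(gene_sets, "set_order") %||% unique(gene_sets$set)
  rows <- purrr::map(sets, function(s) {
    members <- unique(gene_sets$gene[gene_sets$set == s])
    in_bg <- intersect(members, background)
    K <- length(in_bg)
    overlap <- intersect(query, in_bg)
    k <- length(overlap)
    tibble::tibble(
      category = s, N = N, K = K, n = n, k = k,
      fold_enrichment = if (K > 0L && n > 0L) fold_enrichment(N, K, n, k) else NA_real_,
      p = if (K > 0L) hypergeom_upper(N, K, n, k) else NA_real_,
      overlap_genes = list(sort(overlap)))
  })
  out <- dplyr::bind_rows(rows)
  if (adjust == "bh") {
    out$p_adj <- NA_real_
    ok <- !is.na(out$p)
    out$p_adj[ok] <- adjust_bh(out$p[ok])
    out <- dplyr::relocate(out, "p_adj", .after = "p")
  }
  class(out) <- c("shh_enrichment", class(tibble::tibble()))
  out
}
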