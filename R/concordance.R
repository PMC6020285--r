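#' Re-orient a differential-expression table
#'
#' Flipping replaces every fold change by its reciprocal (log2 fold change by
#' its negative), swaps up/down directions and numerator/denominator labels,
#' and leaves p-values and FDR untouched. Used to express an
#' inhibitor-vs-vehicle comparison as vehicle/inhibitor so that positively
#' pathway-regulated genes appear upregulated in both experiments.
#'
#' @param de An `shh_de` table.
#' @param flip If `FALSE`, the table is returned unchanged.
#' @return An `shh_de` table; `orient(orient(x, TRUE), TRUE)` is `x`.
#' @export
orient <- function(de, flip = TRUE) {
  stopifnot(inherits(de, "shh_de"))
  if (!flip) return(de)
  out <- dplyr::mutate(tibble::as_tibble(de),
    mean_a = de$mean_b, mean_b = de$mean_a,
    fc = 1 / de$fc, log2fc = -de$log2fc,
    direction = dplyr::case_when(de$direction == "up" ~ "down",
                                 de$direction == "down" ~ "up",
                                 TRUE ~ "flat"))
  new_shh_de(out,
             comparison = paste0(attr(de, "denominator"), "_vs_",
                                 attr(de, "numerator")),
             numerator = attr(de, "denominator"),
             denominator = attr(de, "numerator"),
             method = attr(de, "method"))
}

#' Genes significant in both experiments
#'
#' Intersection of two significance gates on gene symbol alone (direction is
#' not compared here; the concordance classification comes after).
#'
#' @param sig_a,sig_b Tibbles with columns `gene`, `direction`
#'   (from [significant()]).
#' @return Character vector of common gene symbols, sorted alphabetically.
#' @export
intersect_common <- function(sig_a, sig_b) {
  sort(intersect(sig_a$gene, sig_b$gene))
}

#' Classify common genes by cross-experiment direction concordance
#'
#' Both tables must be oriented so that positive pathway regulation means
#' fold change above 1 (e.g., treated/vehicle in vitro, vehicle/inhibitor in
#' vivo). A gene is `concordant_positive` when its fold change exceeds 1 in
#' both, `concordant_negative` when below 1 in both, `discordant` otherwise.
#' Discordant genes are retained and flagged, never dropped.
#'
#' @param common Character vector of gene symbols (from
#'   [intersect_common()]).
#' @param de_vitro,de_vivo Oriented `shh_de` tables covering every gene in
#'   `common`.
#' @return A tibble of class `shh_concordance`: `gene`, `fc_vitro`,
#'   `fdr_vitro`, `fc_vivo`, `fdr_vivo`, `klass`. Row order follows sorted
#'   `common` regardless of input order.
#' @examples
#' # Gli1-like gene: up in both arms -> concordant_positive
#' @export
classify_concordance <- function(common, de_vitro, de_vivo) {
  common <- sort(common)
  miss_a <- setdiff(common, de_vitro$gene)
  miss_b <- setdiff(common, de_vivo$gene)
  if (length(miss_a) > 0L || length(miss_b) > 0L) {
    abort(paste0("genes missing from a DE table: ",
                 paste(head(c(miss_a, miss_b), 5L), collapse = ", ")))
  }
  a <- de_vitro[match(common, de_vitro$gene), ]
  b <- de_vivo[match(common, de_vivo$gene), ]
  out <- tibble::tibble(
    gene = common,
    fc_vitro = a$fc, fdr_vitro = a$fdr,
    fc_vivo = b$fc, fdr_vivo = b$fdr,
    klass = dplyr::case_when(
      a$fc > 1 & b$fc > 1 ~ "concordant_positive",
      a$fc < 1 & b$fc < 1 ~ "concordant_negative",
      TRUE ~ "discordant"))
  class(out) <- c("shh_concordance", class(tibble::tibble()))
  out
}

#' Rank one concordance class by fold-change rank sum
#'
#' Within a single sign class, each gene is ranked by fold change
#' independently in each experiment (rank 1 = strongest regulation: largest
#' fold change for the positive class, smallest for the negative class);
#' within-experiment ties receive average ranks. The rank sum is the sum of
#' the two ranks; lower means stronger joint regulation. Output is sorted by
#' ascending rank sum, ties broken by smaller in vitro FDR, then
#' alphabetically.
#'
#' @param genes An `shh_concordance` tibble containing exactly one of
#'   `concordant_positive` or `concordant_negative` (mixed classes error).
#' @param top_k Number of top rows to return; `0` returns all.
#' @return Tibble: input columns plus `rank_vitro`, `rank_vivo`, `rank_sum`,
#'   and final `rank` (1-based position after sorting).
#' @export
rank_concordant <- function(genes, top_k = 0L) {
  klasses <- unique(genes$klass)
  if (length(klasses) != 1L ||
      !klasses %in% c("concordant_positive", "concordant_negative")) {
    abort("rank_concordant needs genes of exactly one concordant sign class")
  }
  sgn <- if (klasses == "concordant_positive") -1 else 1
  out <- dplyr::mutate(tibble::as_tibble(genes),
    rank_vitro = rank(sgn * .data$fc_vitro, ties.method = "average"),
    rank_vivo = rank(sgn * .data$fc_vivo, ties.method = "average"),
    rank_sum = .data$rank_vitro + .data$rank_vivo)
  out <- dplyr::arrange(out, .data$rank_sum, .data$fdr_vitro, .data$gene)
  out <- dplyr::mutate(out, rank = dplyr::row_number())
  if (top_k > 0L) out <- head(out, top_k)
  out
}
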