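#' Per-gene linear fold change between two conditions
#'
#' Fold change is the ratio of arithmetic means of *linear* intensities
#' (numerator condition over denominator condition), the reporting convention
#' of gene-level array signal tables; values below 1 denote downregulation.
#'
#' @param expr Expression tibble (`gene` + sample columns), linear scale.
#' @param design Design tibble (`sample`, `condition`); defaults to the
#'   design attached to `expr`.
#' @param numerator,denominator Condition labels forming the ratio.
#' @return Tibble: `gene`, `mean_a` (numerator mean), `mean_b`, `fc`.
#' @examples
#' sim <- simulate_pair(sim_config(n_genes = 50, seed = 1))
#' fold_change(sim$vitro, numerator = "SHH", denominator = "Veh")
#' @export
fold_change <- function(expr, design = attr(expr, "design"),
                        numerator, denominator) {
  grp <- condition_columns(expr, design, numerator, denominator)
  mean_a <- rowMeans(as.matrix(expr[grp$a]))
  mean_b <- rowMeans(as.matrix(expr[grp$b]))
  tibble::tibble(gene = expr$gene, mean_a = mean_a, mean_b = mean_b,
                 fc = mean_a / mean_b)
}

condition_columns <- function(expr, design, numerator, denominator) {
  if (is.null(design)) abort("no design supplied or attached to the matrix")
  if (numerator == denominator) abort("numerator and denominator must differ")
  sample_ids <- setdiff(names(expr), "gene")
  a <- intersect(sample_ids, design$sample[design$condition == numerator])
  b <- intersect(sample_ids, design$sample[design$condition == denominator])
  if (length(a) == 0L) abort(paste0("condition '", numerator, "' has no samples"))
  if (length(b) == 0L) abort(paste0("condition '", denominator, "' has no samples"))
  list(a = a, b = b)
}

#' Differential expression for one two-condition comparison
#'
#' Two-sided t-test (Welch by default, pooled-variance Student optionally) on
#' log2-transformed intensities, vectorized over genes; linear fold change
#' from [fold_change()]; Benjamini-Hochberg adjusted p-values over all genes
#' in the table.
#'
#' Degenerate variance handling: when both groups have zero variance and
#' equal means the test is uninformative and `p = 1` by convention; with
#' unequal means the evidence is unbounded and the smallest representable
#' positive double is reported (a warning is emitted) — an exact zero p-value
#' is never returned.
#'
#' @param expr Expression tibble, linear intensities.
#' @param design Design tibble; defaults to the attached design.
#' @param numerator,denominator Condition labels (fold change is
#'   numerator/denominator).
#' @param method `"welch_t"` (default) or `"student_t"`.
#' @param comparison Optional comparison name stored in the result.
#' @return A tibble of class `shh_de`, one row per gene: `gene`, `mean_a`,
#'   `mean_b`, `fc`, `log2fc`, `p`, `fdr`, `direction` (`up`/`down`/`flat`).
#'   Attributes `comparison`, `numerator`, `denominator`, `method`.
#' @examples
#' sim <- simulate_pair(sim_config(n_genes = 200, seed = 1))
#' de <- de_test(sim$vitro, numerator = "SHH", denominator = "Veh")
#' dplyr::arrange(de, fdr)
#' @export
de_test <- function(expr, design = attr(expr, "design"),
                    numerator, denominator,
                    method = c("welch_t", "student_t"),
                    comparison = paste0(numerator, "_vs_", denominator)) {
  method <- match.arg(method)
  grp <- condition_columns(expr, design, numerator, denominator)
  if (length(grp$a) < 2L || length(grp$b) < 2L) {
    abort("each condition needs >= 2 replicates for testing")
  }
  fc <- fold_change(expr, design, numerator, denominator)
  xa <- log2(as.matrix(expr[grp$a]))
  xb <- log2(as.matrix(expr[grp$b]))
  p <- row_t_p(xa, xb, pooled = method == "student_t")
  de <- dplyr::mutate(fc,
    log2fc = log2(.data$fc),
    p = p,
    fdr = pmin(pmax(adjust_bh(p), p), 1),
    direction = dplyr::case_when(.data$fc > 1 ~ "up",
                                 .data$fc < 1 ~ "down",
                                 TRUE ~ "flat"))
  new_shh_de(de, comparison = comparison, numerator = numerator,
             denominator = denominator, method = method)
}

new_shh_de <- function(df, comparison, numerator, denominator, method) {
  structure(df, class = c("shh_de", class(tibble::tibble())),
            comparison = comparison, numerator = numerator,
            denominator = denominator, method = method)
}

# vectorized two-sided t-test over matrix rows; cross-checked against
# stats::t.test in the unit tests
row_t_p <- function(xa, xb, pooled = FALSE) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(ma))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / sqrt(se2)
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    same <- degenerate & (ma == mb)
    p[same] <- 1
    hard <- degenerate & (ma != mb)
    if (any(hard)) {
      warn(paste0(sum(hard), " gene(s) with zero within-group variance and ",
                  "unequal means; reporting smallest positive p instead of 0"))
      p[hard] <- .Machine$double.xmin
    }
  }
  unname(p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard BH step-up adjustment returning values in the input order
#' (delegates to [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' adjust_bh(c(0.005, 0.011, 0.02, 0.04))
#' @export
adjust_bh <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(pvalues, method = "BH")
}

#' Significance gating of a differential-expression table
#'
#' Selects genes with `fdr` strictly below `alpha`; genes with fold change
#' exactly 1 have undefined direction and are never returned.
#'
#' @param de An `shh_de` table (or any tibble with `gene`, `fdr`,
#'   `direction`).
#' @param alpha FDR threshold in (0, 1]; the comparison is strict (`fdr <
#'   alpha`).
#' @return Tibble: `gene`, `direction` (`up`/`down`), sorted by gene.
#' @export
significant <- function(de, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    abort("alpha must be a single value in (0, 1]")
  }
  out <- de[de$fdr < alpha & de$direction != "flat", c("gene", "direction")]
  out <- tibble::as_tibble(out)[order(out$gene), ]
  class(out) <- class(tibble::tibble())
  out
}
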