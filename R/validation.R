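#' Relative quantification by the 2^-ddCt (Livak) method
#'
#' Per sample, `dCt = Ct_target - Ct_reference` (reference = housekeeping
#' gene, e.g. Gapdh). The calibrator is the mean control-group dCt; each
#' sample's relative quantity is `RQ = 2^-(dCt - calibrator)`, so the control
#' group averages an RQ near 1. The group fold change is the ratio of mean
#' RQs (treated / control), and a two-sided Welch t-test compares the groups
#' (on the RQ scale by default, matching how such fold changes are usually
#' presented with SEM bars; `scale = "dct"` tests the dCt values instead).
#'
#' @param samples Tibble with columns `sample`, `group` (`"treated"` /
#'   `"control"`), `ct_target`, `ct_reference`; at least two samples per
#'   group.
#' @param scale Scale for the t-test: `"rq"` (default) or `"dct"`.
#' @return A list of class `shh_qpcr`: `samples` (input plus `dct`, `rq`),
#'   `fold_change`, `p_value`, `scale`.
#' @examples
#' ct <- tibble::tibble(
#'   sample = paste0("s", 1:6),
#'   group = rep(c("treated", "control"), each = 3),
#'   ct_target = c(20.1, 19.9, 20.0, 21.0, 21.1, 20.9),
#'   ct_reference = rep(18, 6))
#' ddct_fold(ct)
#' @export
ddct_fold <- function(samples, scale = c("rq", "dct")) {
  scale <- match.arg(scale)
  need <- c("group", "ct_target", "ct_reference")
  if (!all(need %in% names(samples))) {
    abort("samples need columns group, ct_target, ct_reference")
  }
  if (!all(samples$group %in% c("treated", "control"))) {
    abort("group must be 'treated' or 'control'")
  }
  if (any(!is.finite(samples$ct_target)) || any(!is.finite(samples$ct_reference)) ||
      any(samples$ct_target <= 0) || any(samples$ct_reference <= 0)) {
    abort("Ct values must be positive and finite")
  }
  for (g in c("treated", "control")) {
    if (sum(samples$group == g) < 2L) abort(paste0("group '", g, "' needs >= 2 samples"))
  }
  out <- dplyr::mutate(tibble::as_tibble(samples),
                       dct = .data$ct_target - .data$ct_reference)
  calibrator <- mean(out$dct[out$group == "control"])
  out <- dplyr::mutate(out, rq = 2^-(.data$dct - calibrator))
  rq_t <- out$rq[out$group == "treated"]
  rq_c <- out$rq[out$group == "control"]
  fold <- mean(rq_t) / mean(rq_c)
  val <- if (scale == "rq") list(a = rq_t, b = rq_c)
         else list(a = out$dct[out$group == "treated"],
                   b = out$dct[out$group == "control"])
  p <- if (var(val$a) == 0 && var(val$b) == 0) {
    # degenerate replicates: uninformative when the groups coincide,
    # unbounded evidence (smallest positive double) when they differ
    if (mean(val$a) == mean(val$b)) 1 else .Machine$double.xmin
  } else {
    stats::t.test(val$a, val$b)$p.value
  }
  structure(list(samples = out, fold_change = fold, p_value = p, scale = scale),
            class = "shh_qpcr")
}

#' Holm-Sidak step-down multiple-comparison correction
#'
#' Sort p-values ascending; the i-th smallest gets the Sidak factor for the
#' remaining `m - i + 1` hypotheses, `1 - (1 - p)^(m - i + 1)`, made monotone
#' non-decreasing by a running maximum and capped at 1. Rejection is
#' step-down: hypotheses are rejected in order while the adjusted value stays
#' below `alpha`.
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @param alpha Family-wise significance level.
#' @return Tibble in the input order: `p`, `p_adjusted`, `reject`.
#' @examples
#' holm_sidak(c(0.01, 0.04), alpha = 0.05)
#' @export
holm_sidak <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L) {
    return(tibble::tibble(p = numeric(0), p_adjusted = numeric(0),
                          reject = logical(0)))
  }
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  m <- length(pvalues)
  ord <- order(pvalues)
  ps <- pvalues[ord]
  adj_sorted <- pmin(cummax(1 - (1 - ps)^(m - seq_len(m) + 1)), 1)
  # step-down: stop rejecting at the first non-significant hypothesis
  below <- adj_sorted < alpha
  reject_sorted <- below & (cumsum(!below) == 0L)
  adj <- numeric(m); adj[ord] <- adj_sorted
  rej <- logical(m); rej[ord] <- reject_sorted
  tibble::tibble(p = pvalues, p_adjusted = adj, reject = rej)
}

#' Percent expression split between tissue compartments
#'
#' For a gene assayed in two separated compartments (mesenchyme and surface
#' ectoderm), expression per reference gene in each compartment is divided by
#' the total across both compartments and reported as a percentage; the two
#' percentages sum to 100.
#'
#' @param expr_mes,expr_ect Non-negative expression ratios (per reference
#'   gene) for the mesenchymal and ectodermal compartment; vectorized, not
#'   both zero at any position.
#' @return Tibble: `expr_mesenchyme`, `expr_ectoderm`, `pct_mesenchyme`,
#'   `pct_ectoderm`.
#' @examples
#' compartment_percent(0.3, 0.1) # 75% mesenchyme
#' @export
compartment_percent <- function(expr_mes, expr_ect) {
  if (length(expr_mes) != length(expr_ect)) abort("inputs must have equal length")
  if (any(expr_mes < 0) || any(expr_ect < 0)) abort("expression ratios must be >= 0")
  total <- expr_mes + expr_ect
  if (any(total == 0)) abort("both compartments zero: percent split undefined")
  pct_mes <- 100 * expr_mes / total
  tibble::tibble(expr_mesenchyme = expr_mes, expr_ectoderm = expr_ect,
                 pct_mesenchyme = pct_mes, pct_ectoderm = 100 - pct_mes)
}
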