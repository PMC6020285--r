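#' Tidy a differential-expression table
#'
#' @param x An `shh_de` table.
#' @param ... Unused.
#' @return A plain tibble with the per-gene results.
#' @method tidy shh_de
#' @export
tidy.shh_de <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "comparison") <- NULL
  out
}

#' One-row summary of a differential-expression table
#'
#' @param x An `shh_de` table.
#' @param alpha FDR gate used for the significant-gene counts.
#' @param ... Unused.
#' @return One-row tibble: comparison, method, gene and significance counts.
#' @method glance shh_de
#' @export
glance.shh_de <- function(x, alpha = 0.05, ...) {
  sig <- significant(x, alpha)
  tibble::tibble(comparison = attr(x, "comparison"),
                 method = attr(x, "method"),
                 n_genes = nrow(x),
                 alpha = alpha,
                 n_significant = nrow(sig),
                 n_up = sum(sig$direction == "up"),
                 n_down = sum(sig$direction == "down"))
}

#' Tidy a concordance classification
#'
#' @param x An `shh_concordance` table.
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy shh_concordance
#' @export
tidy.shh_concordance <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a concordance classification
#'
#' @param x An `shh_concordance` table.
#' @param ... Unused.
#' @return One-row tibble with the class counts; the three classes always
#'   partition the common genes.
#' @method glance shh_concordance
#' @export
glance.shh_concordance <- function(x, ...) {
  tibble::tibble(n_common = nrow(x),
                 n_concordant = sum(x$klass != "discordant"),
                 n_concordant_up = sum(x$klass == "concordant_positive"),
                 n_concordant_down = sum(x$klass == "concordant_negative"),
                 n_discordant = sum(x$klass == "discordant"))
}

#' Tidy an enrichment result
#'
#' @param x An `shh_enrichment` table.
#' @param ... Unused.
#' @return A plain tibble with `overlap_genes` flattened to a comma-separated
#'   string.
#' @method tidy shh_enrichment
#' @export
tidy.shh_enrichment <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x),
                overlap_genes = purrr::map_chr(.data$overlap_genes,
                                               paste, collapse = ","))
}

#' One-row summary of a pipeline run
#'
#' @param x An `shh_pipeline` result.
#' @param ... Unused.
#' @return One-row tibble of the count cascade (plus recall/precision for
#'   simulated inputs).
#' @method glance shh_pipeline
#' @export
glance.shh_pipeline <- function(x, ...) {
  out <- tibble::as_tibble(x$summary)
  if (!is.null(x$recovery)) {
    out <- dplyr::bind_cols(out, x$recovery[, c("recall", "precision")])
  }
  out
}

#' Tidy a qPCR relative-quantification result
#'
#' @param x An `shh_qpcr` object from [ddct_fold()].
#' @param ... Unused.
#' @return The per-sample tibble (`dct`, `rq` added).
#' @method tidy shh_qpcr
#' @export
tidy.shh_qpcr <- function(x, ...) x$samples

#' One-row summary of a qPCR relative-quantification result
#'
#' @param x An `shh_qpcr` object.
#' @param ... Unused.
#' @return One-row tibble: `fold_change`, `p_value`, `scale`, group sizes.
#' @method glance shh_qpcr
#' @export
glance.shh_qpcr <- function(x, ...) {
  tibble::tibble(fold_change = x$fold_change, p_value = x$p_value,
                 scale = x$scale,
                 n_treated = sum(x$samples$group == "treated"),
                 n_control = sum(x$samples$group == "control"))
}

#' @export
print.shh_pipeline <- function(x, ...) {
  s <- x$summary
  cat("<shh_pipeline>\n")
  cat(sprintf("  significant: %d in vitro (%d up / %d down), %d in vivo (%d up / %d down)\n",
              s$n_sig_vitro, s$n_up_vitro, s$n_down_vitro,
              s$n_sig_vivo, s$n_up_vivo, s$n_down_vivo))
  cat(sprintf("  common: %d; concordant: %d (%d up / %d down); discordant: %d\n",
              s$n_common, s$n_concordant, s$n_concordant_up,
              s$n_concordant_down, s$n_discordant))
  if (!is.null(x$recovery)) {
    cat(sprintf("  recovery vs truth: recall %.3f, precision %.3f\n",
                x$recovery$recall, x$recovery$precision))
  }
  invisible(x)
}

#' @export
print.shh_qpcr <- function(x, ...) {
  cat(sprintf("<shh_qpcr> fold change %.4g (treated/control), p = %.4g (%s scale)\n",
              x$fold_change, x$p_value, x$scale))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes; %.1f%% positive, %.1f%% negative\n", x$n_genes,
              100 * x$frac_positive, 100 * x$frac_negative))
  cat(sprintf("  |log2FC| ~ N+(%g, %g); attenuation %g; sigma %g / %g; reps %d / %d; seed %d\n",
              x$effect_log2_mean, x$effect_log2_sd, x$attenuation,
              x$sigma_vitro, x$sigma_vivo, x$reps_vitro, x$reps_vivo, x$seed))
  invisible(x)
}
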