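#' Configuration for an end-to-end concordance run
#'
#' Inputs are either file paths (two expression matrices with designs) or a
#' [sim_config()] from which a synthetic pair is generated. The default
#' significance gates are asymmetric: a stringent FDR < 0.01 for the robust
#' in vitro arm and a permissive FDR < 0.75 for the attenuated in vivo arm —
#' the permissive in vivo gate limits false negatives while the stringent
#' in vitro gate (and the direction-concordance requirement) limits false
#' positives.
#'
#' @param vitro,vivo Paths to expression TSVs, or `NULL` when `sim` is given.
#' @param design_vitro,design_vivo Paths to the design TSVs.
#' @param sim Optional [sim_config()]; generates the pair instead of reading
#'   files.
#' @param numerator_vitro,denominator_vitro,numerator_vivo,denominator_vivo
#'   Condition labels per arm. The in vivo comparison is computed
#'   inhibitor-vs-vehicle and re-oriented when `flip_vivo` is `TRUE`.
#' @param alpha_vitro,alpha_vivo FDR gates (strict `<`).
#' @param flip_vivo Re-orient the in vivo table to vehicle/inhibitor so that
#'   positive pathway regulation means fold change > 1 in both arms.
#' @param top_k Rows kept in each ranked table (0 = all).
#' @param method Test passed to [de_test()].
#' @param gene_sets Optional path to a GMT file, or a tidy gene-set tibble.
#' @param background `"both"` (default: genes measured in both matrices) or a
#'   character vector of symbols.
#' @param seed Seed used when `sim` is given (overrides `sim$seed` if
#'   non-NULL).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vitro = NULL, vivo = NULL,
                            design_vitro = NULL, design_vivo = NULL,
                            sim = NULL,
                            numerator_vitro = "SHH", denominator_vitro = "Veh",
                            numerator_vivo = "Cyc", denominator_vivo = "Veh",
                            alpha_vitro = 0.01, alpha_vivo = 0.75,
                            flip_vivo = TRUE, top_k = 30L,
                            method = "welch_t",
                            gene_sets = NULL, background = "both",
                            seed = NULL) {
  if (is.null(sim) && (is.null(vitro) || is.null(vivo))) {
    abort("either file paths (vitro, vivo) or a sim config must be given")
  }
  for (a in c(alpha_vitro, alpha_vivo)) {
    if (a <= 0 || a > 1) abort("alpha thresholds must lie in (0, 1]")
  }
  structure(list(vitro = vitro, vivo = vivo,
                 design_vitro = design_vitro, design_vivo = design_vivo,
                 sim = sim,
                 numerator_vitro = numerator_vitro,
                 denominator_vitro = denominator_vitro,
                 numerator_vivo = numerator_vivo,
                 denominator_vivo = denominator_vivo,
                 alpha_vitro = alpha_vitro, alpha_vivo = alpha_vivo,
                 flip_vivo = isTRUE(flip_vivo), top_k = as.integer(top_k),
                 method = method, gene_sets = gene_sets,
                 background = background, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; an optional
#' `sim:` block mirrors [sim_config()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$sim)) sim <- do.call(sim_config, raw$sim)
  raw$sim <- NULL
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, c(raw, list(sim = sim)))
}

#' Run the full cross-experiment concordance pipeline
#'
#' Stages: differential expression per arm, asymmetric FDR gating,
#' orientation of the in vivo table, intersection of significant genes,
#' direction-concordance classification, rank-sum prioritization of each
#' concordant class, and (when gene sets are supplied) hypergeometric
#' enrichment of the concordant genes against the measured background. When
#' the input pair is simulated, recovery against the known truth is scored.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; every intermediate table is written as
#'   TSV with metadata headers and the summary as `report.json`.
#' @return A list of class `shh_pipeline`: `de_vitro`, `de_vivo` (oriented),
#'   `sig_vitro`, `sig_vivo`, `common`, `concordance`, `ranked_up`,
#'   `ranked_down`, `enrichment` (or `NULL`), `recovery` (or `NULL`),
#'   `summary` (named list of integer counts), `config`.
#' @examples
#' res <- run_pipeline(pipeline_config(sim = sim_config(n_genes = 300, seed = 2)))
#' glance(res)
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$sim)) {
    simcfg <- config$sim
    if (!is.null(config$seed)) {
      simcfg$seed <- as.integer(config$seed)
    }
    sim <- simulate_pair(simcfg)
    vitro <- sim$vitro; vivo <- sim$vivo
    design_vitro <- sim$design_vitro; design_vivo <- sim$design_vivo
    truth <- sim$truth
  } else {
    vitro <- stage("read vitro matrix",
                   read_expression_matrix(config$vitro, config$design_vitro))
    vivo <- stage("read vivo matrix",
                  read_expression_matrix(config$vivo, config$design_vivo))
    design_vitro <- attr(vitro, "design")
    design_vivo <- attr(vivo, "design")
  }

  de_vitro <- stage("de_test vitro",
    de_test(vitro, design_vitro, config$numerator_vitro,
            config$denominator_vitro, method = config$method))
  de_vivo_raw <- stage("de_test vivo",
    de_test(vivo, design_vivo, config$numerator_vivo,
            config$denominator_vivo, method = config$method))
  de_vivo <- orient(de_vivo_raw, flip = config$flip_vivo)

  sig_vitro <- significant(de_vitro, config$alpha_vitro)
  sig_vivo <- significant(de_vivo, config$alpha_vivo)
  common <- intersect_common(sig_vitro, sig_vivo)
  concordance <- stage("classify concordance",
                       classify_concordance(common, de_vitro, de_vivo))

  up <- concordance[concordance$klass == "concordant_positive", ]
  down <- concordance[concordance$klass == "concordant_negative", ]
  ranked_up <- if (nrow(up) > 0L) rank_concordant(up, config$top_k) else NULL
  ranked_down <- if (nrow(down) > 0L) rank_concordant(down, config$top_k) else NULL

  enrichment <- NULL
  concordant_genes <- concordance$gene[concordance$klass != "discordant"]
  if (!is.null(config$gene_sets)) {
    gene_sets <- if (is.character(config$gene_sets)) {
      read_gene_sets(config$gene_sets)
    } else config$gene_sets
    background <- if (identical(config$background, "both")) {
      intersect(vitro$gene, vivo$gene)
    } else config$background
    inform(paste0("enrichment background: ", length(unique(background)), " genes"))
    enrichment <- stage("enrichment",
                        enrich(concordant_genes, gene_sets, background))
  }

  recovery <- NULL
  if (!is.null(truth)) {
    detected <- concordance[concordance$klass != "discordant",
                            c("gene", "klass")]
    detected <- tibble::tibble(
      gene = detected$gene,
      direction = ifelse(detected$klass == "concordant_positive",
                         "positive", "negative"))
    recovery <- score_recovery(detected, truth)
  }

  summary <- list(
    n_genes_vitro = nrow(de_vitro), n_genes_vivo = nrow(de_vivo),
    n_sig_vitro = nrow(sig_vitro),
    n_up_vitro = sum(sig_vitro$direction == "up"),
    n_down_vitro = sum(sig_vitro$direction == "down"),
    n_sig_vivo = nrow(sig_vivo),
    n_up_vivo = sum(sig_vivo$direction == "up"),
    n_down_vivo = sum(sig_vivo$direction == "down"),
    n_common = length(common),
    n_concordant = length(concordant_genes),
    n_concordant_up = sum(concordance$klass == "concordant_positive"),
    n_concordant_down = sum(concordance$klass == "concordant_negative"),
    n_discordant = sum(concordance$klass == "discordant"))
  summary <- lapply(summary, as.integer)

  res <- structure(list(de_vitro = de_vitro, de_vivo = de_vivo,
                        sig_vitro = sig_vitro, sig_vivo = sig_vivo,
                        common = common, concordance = concordance,
                        ranked_up = ranked_up, ranked_down = ranked_down,
                        enrichment = enrichment, recovery = recovery,
                        summary = summary, config = config),
                   class = "shh_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Write all pipeline outputs to a directory
#'
#' Emits `de_vitro.tsv`, `de_vivo.tsv`, `concordance.tsv`, `ranked_up.tsv`,
#' `ranked_down.tsv`, `enrichment.tsv` (when computed), and `report.json`
#' (schema-versioned summary with thresholds, seed, and recovery when the
#' run was simulated). Thresholds are recorded in every TSV metadata header
#' so each number is traceable to its gates.
#'
#' @param res A `shh_pipeline` result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(res, out_dir) {
  stopifnot(inherits(res, "shh_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  meta <- list(alpha_vitro = cfg$alpha_vitro, alpha_vivo = cfg$alpha_vivo,
               flip_vivo = cfg$flip_vivo, method = cfg$method,
               seed = cfg$seed %||% cfg$sim$seed %||% "none")
  write_result_table(tibble::as_tibble(res$de_vitro),
                     file.path(out_dir, "de_vitro.tsv"),
                     c(list(comparison = attr(res$de_vitro, "comparison")), meta))
  write_result_table(tibble::as_tibble(res$de_vivo),
                     file.path(out_dir, "de_vivo.tsv"),
                     c(list(comparison = attr(res$de_vivo, "comparison")), meta))
  write_result_table(tibble::as_tibble(res$concordance),
                     file.path(out_dir, "concordance.tsv"), meta)
  if (!is.null(res$ranked_up)) {
    write_result_table(res$ranked_up, file.path(out_dir, "ranked_up.tsv"), meta)
  }
  if (!is.null(res$ranked_down)) {
    write_result_table(res$ranked_down, file.path(out_dir, "ranked_down.tsv"), meta)
  }
  if (!is.null(res$enrichment)) {
    enr <- dplyr::mutate(tibble::as_tibble(res$enrichment),
      overlap_genes = purrr::map_chr(.data$overlap_genes, paste, collapse = ","))
    write_result_table(enr, file.path(out_dir, "enrichment.tsv"), meta)
  }
  report <- list(schema_version = 1L, parameters = meta, counts = res$summary)
  if (!is.null(res$recovery)) report$recovery <- as.list(res$recovery)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Re-derive concordance counts from a common-gene table
#'
#' Takes a table of genes significant in both experiments with both oriented
#' fold-change columns (the layout of a published supplementary
#' "common genes" sheet), re-applies the direction-concordance rule from the
#' fold-change signs alone, and reports the count cascade plus (optionally)
#' the overlap of the concordant genes with a gene category.
#'
#' @param common_table Path to a TSV, or a data frame, with columns `gene`,
#'   `fc_vitro`, `fc_vivo` (both fold changes oriented so positive pathway
#'   regulation is > 1).
#' @param category Optional character vector or single-category tidy tibble
#'   (`set`, `source`, `gene`): category members to intersect with the
#'   concordant genes.
#' @return A list: `n_common`, `n_concordant`, `n_concordant_up`,
#'   `n_concordant_down`, `n_discordant`, `concordant_genes`, and
#'   `n_category_overlap`/`category_overlap` when a category is given.
#' @export
verify_against_supplementary <- function(common_table, category = NULL) {
  tab <- if (is.character(common_table)) read_result_table(common_table)
         else tibble::as_tibble(common_table)
  need <- c("gene", "fc_vitro", "fc_vivo")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    abort(paste0("common-gene table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  klass <- dplyr::case_when(
    tab$fc_vitro > 1 & tab$fc_vivo > 1 ~ "concordant_positive",
    tab$fc_vitro < 1 & tab$fc_vivo < 1 ~ "concordant_negative",
    TRUE ~ "discordant")
  concordant <- sort(tab$gene[klass != "discordant"])
  out <- list(n_common = nrow(tab),
              n_concordant = length(concordant),
              n_concordant_up = sum(klass == "concordant_positive"),
              n_concordant_down = sum(klass == "concordant_negative"),
              n_discordant = sum(klass == "discordant"),
              concordant_genes = concordant)
  if (!is.null(category)) {
    members <- if (is.data.frame(category)) unique(category$gene) else unique(category)
    overlap <- sort(intersect(concordant, members))
    out$n_category_overlap <- length(overlap)
    out$category_overlap <- overlap
  }
  out
}
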