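#' Read a gene-level expression matrix with its sample design
#'
#' Expression values are linear signal intensities (strictly positive), one
#' row per gene, one column per sample. The file is tab-separated with a
#' header row of sample identifiers and a first column named `gene`;
#' lines starting with `#` are ignored. The design file is a two-column TSV
#' (`sample`, `condition`) assigning every sample to exactly one condition.
#'
#' @param path Path to the expression TSV.
#' @param design_path Path to the design TSV, or `NULL` to skip design
#'   validation (the bare matrix is returned).
#' @param canonicalize Gene-symbol canonicalization: `"none"` (exact,
#'   case-sensitive symbols, the default) or `"upper"` (case-fold to upper
#'   case before uniqueness checks). Exposed because different array
#'   annotations may case symbols differently.
#' @return A tibble with column `gene` followed by one numeric column per
#'   sample. When `design_path` is given, the design tibble is attached as
#'   attribute `"design"`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2\ts3\ts4",
#'              "Gli1\t20\t22\t10\t11",
#'              "Gas1\t5\t6\t12\t13"), tf)
#' df <- tempfile(fileext = ".tsv")
#' writeLines(c("sample\tcondition", "s1\tSHH", "s2\tSHH",
#'              "s3\tVeh", "s4\tVeh"), df)
#' read_expression_matrix(tf, df)
#' @export
read_expression_matrix <- function(path, design_path = NULL,
                                   canonicalize = c("none", "upper")) {
  canonicalize <- match.arg(canonicalize)
  # columns come in as text and are converted with base as.numeric: the fast
  # float path can be one ulp off, which would break bit-exact round trips
  expr <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  if (ncol(expr) < 2L || names(expr)[1L] != "gene") {
    abort("expression TSV must have a first column named 'gene' and >= 1 sample column")
  }
  for (s in names(expr)[-1L]) {
    v <- suppressWarnings(as.numeric(expr[[s]]))
    if (anyNA(v) && !all(is.na(expr[[s]]) == is.na(v))) {
      abort(paste0("sample '", s, "' has non-numeric values"))
    }
    expr[[s]] <- v
  }
  if (canonicalize == "upper") expr$gene <- toupper(expr$gene)
  expr$gene <- as.character(expr$gene)
  dup <- unique(expr$gene[duplicated(expr$gene)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate gene symbols in ", path, ": ",
                 paste(head(dup, 5L), collapse = ", ")))
  }
  sample_ids <- names(expr)[-1L]
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids in header")
  for (s in sample_ids) {
    v <- expr[[s]]
    if (!is.numeric(v)) abort(paste0("sample '", s, "' has non-numeric values"))
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0L) {
      abort(paste0("non-positive or missing intensity for gene '",
                   expr$gene[bad[1L]], "' in sample '", s, "'"))
    }
  }
  expr <- tibble::as_tibble(expr)
  if (!is.null(design_path)) {
    design <- read_design(design_path)
    validate_design(expr, design)
    attr(expr, "design") <- design
  }
  expr
}

#' Read a sample design file
#'
#' @param path TSV with columns `sample` and `condition` (lines starting with
#'   `#` ignored).
#' @return A tibble with character columns `sample` and `condition`.
#' @export
read_design <- function(path) {
  design <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                            progress = FALSE)
  if (!all(c("sample", "condition") %in% names(design))) {
    abort("design TSV must have columns 'sample' and 'condition'")
  }
  design <- tibble::tibble(sample = as.character(design$sample),
                           condition = as.character(design$condition))
  if (anyDuplicated(design$sample)) abort("duplicate sample ids in design")
  design
}

#' Validate an expression matrix against a design
#'
#' Checks that every sample column is assigned a condition and that each
#' condition has at least two replicates (required for per-gene testing).
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param design Design tibble (`sample`, `condition`).
#' @return `invisible(TRUE)`; errors otherwise.
#' @export
validate_design <- function(expr, design) {
  sample_ids <- setdiff(names(expr), "gene")
  missing <- setdiff(sample_ids, design$sample)
  if (length(missing) > 0L) {
    abort(paste0("samples absent from design: ", paste(missing, collapse = ", ")))
  }
  used <- design[design$sample %in% sample_ids, ]
  counts <- table(used$condition)
  if (any(counts < 2L)) {
    abort(paste0("condition '", names(counts)[which(counts < 2L)[1L]],
                 "' has fewer than 2 replicates"))
  }
  invisible(TRUE)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; numeric values are written with
#' full double precision so that a read-back reproduces them bit-identically.
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  write_tsv_full(expr, path)
  invisible(path)
}

#' Read gene-set categories from a GMT file
#'
#' GMT: one category per line, `name TAB source TAB member1 TAB member2 ...`.
#' Duplicate members within a line are dropped; file order is preserved.
#'
#' @param path Path to the GMT file.
#' @param canonicalize `"none"` or `"upper"`, as in [read_expression_matrix()].
#' @return A tidy tibble with one row per (category, member): columns `set`,
#'   `source`, `gene`. Category order follows the file.
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines("OFC\tFunato2017\tGas1\tFoxf2\tEfnb1", gmt)
#' read_gene_sets(gmt)
#' @export
read_gene_sets <- function(path, canonicalize = c("none", "upper")) {
  canonicalize <- match.arg(canonicalize)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(paste0("empty GMT file: ", path))
  recs <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      abort(paste0("GMT parse error at line ", i,
                   ": expected name, source and >= 1 member"))
    }
    members <- unique(fields[-(1:2)])
    if (canonicalize == "upper") members <- toupper(members)
    tibble::tibble(set = fields[1L], source = fields[2L], gene = members)
  })
  sets <- vapply(recs, function(r) r$set[1L], character(1L))
  if (anyDuplicated(sets)) abort("duplicate category names in GMT")
  out <- dplyr::bind_rows(recs)
  attr(out, "set_order") <- sets
  out
}

#' Write gene-set categories to a GMT file
#'
#' @param gene_sets Tidy gene-set tibble as returned by [read_gene_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path) {
  sets <- attr(gene_sets, "set_order") %||% unique(gene_sets$set)
  lines <- purrr::map_chr(sets, function(s) {
    rows <- gene_sets[gene_sets$set == s, ]
    paste(c(s, rows$source[1L], rows$gene), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write a result table as TSV with a metadata header
#'
#' Metadata are written as leading `# key: value` comment lines, then a
#' header row, then the data. Floats keep full precision (>= 6 significant
#' digits guaranteed).
#'
#' @param table A data frame.
#' @param path Output path.
#' @param metadata Named list written as `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(table, path, metadata = list()) {
  if (anyDuplicated(names(table))) abort("result table has duplicate column names")
  con <- file(path, open = "w")
  on.exit(close(con))
  if (length(metadata) > 0L) {
    writeLines(paste0("# ", names(metadata), ": ",
                      vapply(metadata, format_meta, character(1L))), con)
  }
  close(con)
  on.exit()
  write_tsv_full(table, path, append = TRUE)
  invisible(path)
}

format_meta <- function(x) paste(format(x, digits = 15L, trim = TRUE), collapse = ",")

#' Read a result table written by [write_result_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble; metadata comment lines are parsed into a named character
#'   vector attached as attribute `"metadata"`.
#' @export
read_result_table <- function(path) {
  lines <- readr::read_lines(path, n_max = 100L, progress = FALSE)
  meta_lines <- lines[startsWith(lines, "# ")]
  meta <- character(0)
  if (length(meta_lines) > 0L) {
    kv <- sub("^# ", "", meta_lines)
    keys <- sub(":.*$", "", kv)
    vals <- trimws(sub("^[^:]*:", "", kv))
    meta <- setNames(vals, keys)
  }
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(out) > 0L) {
    for (j in seq_along(out)) {
      v <- suppressWarnings(as.numeric(out[[j]]))
      if (all(is.na(v) == is.na(out[[j]]))) out[[j]] <- v
    }
  }
  attr(out, "metadata") <- meta
  out
}

# readr drops precision at its default number formatting only for >15
# significant digits; format explicitly so round trips are bit-identical.
write_tsv_full <- function(df, path, append = FALSE) {
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) {
      fmt[[j]] <- vapply(fmt[[j]], function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 17L, trim = TRUE,
                                                scientific = NA)
      }, character(1L))
    }
  }
  readr::write_tsv(fmt, path, append = append, col_names = TRUE,
                   escape = "none", progress = FALSE)
  invisible(path)
}
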