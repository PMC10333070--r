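#' Controlled vocabulary for mutation variant classes
#'
#' Variant classes accepted by [read_mutation_table()] and the mutation
#' analytics. `non_silent_classes()` is the default set counted as
#' protein-altering for tumour mutational burden and the binary mutation
#' matrix; the split is configurable in the downstream functions.
#'
#' @return Character vectors of class names.
#' @export
variant_classes <- function() {
  c("missense", "nonsense", "nonstop", "frameshift_del", "frameshift_ins",
    "in_frame_del", "in_frame_ins", "splice_site", "translation_start_site",
    "silent", "intronic", "utr3", "utr5")
}

#' @rdname variant_classes
#' @export
non_silent_classes <- function() {
  setdiff(variant_classes(), c("silent", "intronic", "utr3", "utr5"))
}

#' Read a genes x samples expression matrix
#'
#' Reads a log-scale expression matrix from TSV (first column = gene ids,
#' remaining columns numeric, one per sample) or GCT v1.2 (two header lines,
#' `NAME` and `Description` columns). Gene symbols are uppercased on
#' ingestion; duplicate gene rows are collapsed by keeping the row with the
#' highest mean expression (the usual microarray probe-collapse convention),
#' with a message reporting how many rows were collapsed.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"gct"`.
#' @return A numeric matrix with gene rownames and sample colnames, rows in
#'   file order (first occurrence for collapsed duplicates).
#' @export
read_expression_matrix <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  if (format == "gct") {
    header <- readLines(path, n = 2L)
    if (length(header) < 2L || !startsWith(header[[1L]], "#1.2")) {
      rlang::abort("Malformed GCT: first line must be the '#1.2' version tag.")
    }
    dims <- suppressWarnings(as.integer(strsplit(header[[2L]], "\t")[[1L]][1:2]))
    if (anyNA(dims)) {
      rlang::abort("Malformed GCT: second line must give row and column counts.")
    }
    df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 3L || !identical(toupper(names(df)[1:2]),
                                    c("NAME", "DESCRIPTION"))) {
      rlang::abort("Malformed GCT: expected NAME and Description columns.")
    }
    if (nrow(df) != dims[[1L]]) {
      rlang::abort(sprintf("Malformed GCT: header declares %d rows, found %d.",
                           dims[[1L]], nrow(df)))
    }
    ids <- as.character(df[[1L]])
    df <- df[, -(1:2), drop = FALSE]
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) rlang::abort("Malformed TSV: need gene ids plus >=1 sample.")
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num) && !all(is.na(v))) {
        bad <- which(is.na(num) & !is.na(v))[1L]
        rlang::abort(sprintf(
          "Non-numeric expression value '%s' at row %d, sample column '%s'.",
          v[bad], bad, names(df)[j]))
      }
      df[[j]] <- num
    }
  }
  mat <- as.matrix(df)
  rownames(mat) <- toupper(ids)
  mat <- collapse_duplicate_genes(mat)
  check_expression_matrix(mat, "expression")
  mat
}

# Keep, per duplicated gene id, the row with the largest mean expression.
collapse_duplicate_genes <- function(mat) {
  ids <- rownames(mat)
  if (!anyDuplicated(ids)) return(mat)
  means <- rowMeans(mat)
  ord <- order(ids, -means)
  keep_first <- !duplicated(ids[ord])
  keep <- sort(ord[keep_first])  # restore file order of first winners
  message(sprintf("Collapsed %d duplicate gene row(s) by max mean expression.",
                  nrow(mat) - length(keep)))
  mat[keep, , drop = FALSE]
}

#' Read and write gene sets in GMT format
#'
#' One gene set per line: name, description, then tab-separated gene
#' symbols. Empty gene fields (trailing tabs) are dropped and symbols are
#' uppercased.
#'
#' @param path Path to a GMT file.
#' @return `read_gene_sets_gmt()`: a named list of character vectors of gene
#'   symbols. `write_gene_sets_gmt()`: the path, invisibly.
#' @export
read_gene_sets_gmt <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      rlang::abort(sprintf(
        "GMT line %d has %d field(s); need name, description and >=1 gene.",
        i, length(fields)))
    }
    genes <- toupper(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      rlang::abort(sprintf("GMT line %d ('%s') has no gene symbols.",
                           i, fields[[1L]]))
    }
    stats::setNames(list(unique(genes)), fields[[1L]])
  })
  do.call(c, sets)
}

#' @rdname read_gene_sets_gmt
#' @param gene_sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gene_sets_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    rlang::abort("`gene_sets` must be a named list.")
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[[i]], descriptions[[i]], gene_sets[[i]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical survival table
#'
#' Expects a TSV with a sample-id column, `time` (follow-up in months) and
#' `event` (0 = censored, 1 = event). Any further columns are kept as
#' covariates. Rows with missing time or event are dropped with a message,
#' mirroring the usual exclusion of patients lacking survival information.
#'
#' @param path Path to the TSV.
#' @param sample_col,time_col,event_col Column names.
#' @return A tibble with columns `sample_id`, `time`, `event`, plus any
#'   covariates.
#' @export
read_clinical_table <- function(path, sample_col = "sample_id",
                                time_col = "time", event_col = "event") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(sample_col, time_col, event_col)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    rlang::abort(sprintf("Clinical table lacks required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(df)
  out <- dplyr::rename(out,
    sample_id = !!rlang::sym(sample_col),
    time      = !!rlang::sym(time_col),
    event     = !!rlang::sym(event_col))
  keep <- !is.na(out$time) & !is.na(out$event)
  if (any(!keep)) {
    message(sprintf("Dropped %d sample(s) with missing survival information.",
                    sum(!keep)))
    out <- out[keep, , drop = FALSE]
  }
  validate_survival_table(out)
  out
}

validate_survival_table <- function(tbl) {
  if (anyDuplicated(tbl$sample_id)) rlang::abort("Duplicated sample ids.")
  if (any(tbl$time < 0)) rlang::abort("Negative survival times.")
  if (!all(tbl$event %in% c(0, 1))) {
    rlang::abort("`event` must be 0 (censored) or 1 (event).")
  }
  invisible(tbl)
}

#' Read a MAF-lite mutation table
#'
#' Expects a TSV with columns `sample_id`, `gene_symbol` and
#' `variant_class`, the last drawn from [variant_classes()]. Exact duplicate
#' records are dropped; unknown variant classes are an error listing the
#' accepted vocabulary.
#'
#' @param path Path to the TSV.
#' @return A tibble with the three columns, gene symbols uppercased.
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_symbol", "variant_class")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    rlang::abort(sprintf("Mutation table lacks required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(df[need])
  out$gene_symbol <- toupper(out$gene_symbol)
  bad <- setdiff(unique(out$variant_class), variant_classes())
  if (length(bad)) {
    rlang::abort(sprintf(
      "Unknown variant_class value(s): %s. Accepted: %s",
      paste(bad, collapse = ", "), paste(variant_classes(), collapse = ", ")))
  }
  dup <- duplicated(out)
  if (any(dup)) {
    message(sprintf("Dropped %d exact duplicate mutation record(s).", sum(dup)))
    out <- out[!dup, , drop = FALSE]
  }
  out
}
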