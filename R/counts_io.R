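#' Read a gene-by-sample count matrix
#'
#' Expects a delimited text file with a header row of sample ids and gene
#' ids in the first column (the layout of an htseq-count table assembled
#' across samples). The delimiter is inferred from the extension
#' (`.csv` = comma, otherwise tab) unless given.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` to infer from the extension.
#' @return integer matrix (genes x samples) with dimnames.
#' @export
read_counts <- function(path, sep = NULL) {
  if (!file.exists(path)) input_error("count file not found: %s", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (ncol(df) < 2) input_error("%s: need a gene-id column plus at least one sample", path)
  gene_ids <- df[[1]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    line <- which(duplicated(gene_ids))[1] + 1L  # +1 for header
    input_error("%s: duplicated gene id '%s' (line %d)", path, dup[1], line)
  }
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids)) {
    input_error("%s: duplicated sample id '%s'", path,
                sample_ids[duplicated(sample_ids)][1])
  }
  mat <- matrix(NA_integer_, nrow = nrow(df), ncol = length(sample_ids),
                dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    x <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(x) | x < 0 | x != floor(x))
    if (length(bad)) {
      input_error("%s: non-integer or negative count '%s' for gene '%s' (line %d)",
                  path, df[[j + 1]][bad[1]], gene_ids[bad[1]], bad[1] + 1L)
    }
    mat[, j] <- as.integer(x)
  }
  validate_counts(mat)
  mat
}

#' Write a count matrix as TSV
#'
#' First column `gene_id`, then one column per sample; round-trips with
#' [read_counts()].
#'
#' @param counts integer matrix with dimnames.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_counts <- function(counts) {
  if (!is.matrix(counts)) input_error("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    input_error("counts must have gene and sample dimnames")
  }
  if (anyDuplicated(rownames(counts))) input_error("duplicated gene ids in counts")
  if (anyDuplicated(colnames(counts))) input_error("duplicated sample ids in counts")
  if (any(counts < 0) || any(counts != floor(counts))) {
    input_error("counts must be nonnegative integers")
  }
  invisible(counts)
}

#' Read a sample sheet
#'
#' Two-column delimited file mapping `sample_id` to `sample_type`.
#'
#' @param path file path.
#' @param sep delimiter; `NULL` to infer from the extension.
#' @return data.frame with columns `sample_id`, `sample_type`.
#' @export
read_sample_sheet <- function(path, sep = NULL) {
  if (!file.exists(path)) input_error("sample sheet not found: %s", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "sample_type") %in% colnames(df))) {
    input_error("%s: expected columns sample_id and sample_type", path)
  }
  if (anyDuplicated(df$sample_id)) {
    input_error("%s: duplicated sample_id '%s'", path,
                df$sample_id[duplicated(df$sample_id)][1])
  }
  df[, c("sample_id", "sample_type")]
}

#' Read gene sets from GMT or two-column TSV
#'
#' GMT lines are `set_name<TAB>description<TAB>gene1<TAB>gene2...`; the
#' two-column format is `set_name<TAB>gene_id` with one gene per row
#' (header optional, detected by the literal column names). Duplicate
#' genes within a set are collapsed with a warning reporting the count.
#'
#' @param path file path; `.gmt` extension selects GMT parsing, otherwise
#'   the line shape decides.
#' @return named list of unique gene-id vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) input_error("gene set file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) input_error("%s: empty gene set file", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  is_gmt <- grepl("\\.gmt$", path, ignore.case = TRUE) ||
    any(lengths(fields) > 2)
  sets <- list()
  if (is_gmt) {
    for (f in fields) {
      if (length(f) < 3) input_error("%s: malformed GMT line for set '%s'", path, f[1])
      sets[[f[1]]] <- c(sets[[f[1]]], f[-(1:2)])
    }
  } else {
    if (any(lengths(fields) != 2)) {
      input_error("%s: expected two tab-separated columns (set_name, gene_id)", path)
    }
    tab <- do.call(rbind, fields)
    if (identical(tolower(tab[1, ]), c("set_name", "gene_id"))) tab <- tab[-1, , drop = FALSE]
    sets <- split(tab[, 2], tab[, 1])
    sets <- sets[unique(tab[, 1])]  # preserve first-appearance order
  }
  for (nm in names(sets)) {
    n_dup <- sum(duplicated(sets[[nm]]))
    if (n_dup > 0) {
      warning(sprintf("set '%s': collapsed %d duplicated gene id(s)", nm, n_dup),
              call. = FALSE)
      sets[[nm]] <- unique(sets[[nm]])
    }
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
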