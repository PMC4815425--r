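#' Expression-study container
#'
#' Holds a genes x samples matrix of log2-scale expression values together
#' with per-sample annotations. Values are expected on the log2 scale as
#' produced by GCRMA-style normalization; missing values are not supported
#' (complete single-platform arrays), so any non-finite cell is an error.
#'
#' @param matrix numeric matrix, rows = genes (unique rownames), columns =
#'   samples (unique colnames), all values finite.
#' @param samples optional data.frame of sample annotations with columns
#'   `sample_id`, `study_id`, `arm` (`treated`/`control`), `part`
#'   (`root`/`shoot`/`seedling`), `method` (`water_withholding`/`mannitol`/
#'   `peg`/`deracination`) and `replicate_index`; one row per matrix column,
#'   in column order.
#' @return An object of class `"expression_study"`.
#' @export
expression_study <- function(matrix, samples = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix))) {
    dup <- unique(rownames(matrix)[duplicated(rownames(matrix))])
    stop("gene identifiers must be unique; duplicated: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(colnames(matrix)) || anyDuplicated(colnames(matrix))) {
    stop("sample identifiers (column names) must be present and unique",
         call. = FALSE)
  }
  if (!all(is.finite(matrix))) {
    bad <- which(!is.finite(matrix), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(matrix)[bad[1]], colnames(matrix)[bad[2]]),
         call. = FALSE)
  }
  obj <- structure(list(matrix = matrix, samples = samples),
                   class = "expression_study")
  if (!is.null(samples)) validate_sample_annotation(obj)
  obj
}

ARM_LEVELS <- c("treated", "control")
PART_LEVELS <- c("root", "shoot", "seedling")
METHOD_LEVELS <- c("water_withholding", "mannitol", "peg", "deracination")
SHEET_COLUMNS <- c("sample_id", "study_id", "arm", "part", "method")

validate_sample_annotation <- function(expr) {
  s <- expr$samples
  missing_cols <- setdiff(SHEET_COLUMNS, names(s))
  if (length(missing_cols) > 0) {
    stop("sample sheet is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_enum <- function(values, allowed, what) {
    bad <- setdiff(unique(values), allowed)
    if (length(bad) > 0) {
      stop(sprintf("invalid %s value(s) %s; allowed: {%s}", what,
                   paste(sQuote(bad), collapse = ", "),
                   paste(allowed, collapse = ", ")), call. = FALSE)
    }
  }
  check_enum(s$arm, ARM_LEVELS, "arm")
  check_enum(s$part, PART_LEVELS, "part")
  check_enum(s$method, METHOD_LEVELS, "method")
  cols <- colnames(expr$matrix)
  orphan <- setdiff(cols, s$sample_id)
  if (length(orphan) > 0) {
    stop("expression column(s) with no sample-sheet row: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(s$sample_id)) {
    stop("duplicated sample_id in sample sheet: ",
         paste(unique(s$sample_id[duplicated(s$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  # align annotation rows to matrix column order; extra sheet rows reported
  extra <- setdiff(s$sample_id, cols)
  if (length(extra) > 0) {
    message("[metaexpr] sample sheet rows without expression columns ",
            "(dropped): ", paste(extra, collapse = ", "))
    s <- s[s$sample_id %in% cols, , drop = FALSE]
  }
  s <- s[match(cols, s$sample_id), , drop = FALSE]
  rownames(s) <- NULL
  if (is.null(s$replicate_index)) {
    s$replicate_index <- stats::ave(seq_len(nrow(s)),
                                    s$study_id, s$part, s$arm,
                                    FUN = seq_along)
  }
  expr$samples <- s
  invisible(expr)
}

#' Read a tab-delimited expression matrix
#'
#' The expected format is plain TSV: a header row of sample identifiers, then
#' one row per gene whose first field is the gene (probe-set) identifier and
#' whose remaining fields are numeric log2 expression values. Duplicate gene
#' identifiers, ragged rows and non-numeric cells are fatal with a message
#' locating the offence.
#'
#' @param path path to the TSV file.
#' @return An [expression_study()] without sample annotations.
#' @seealso [read_sample_sheet()] to attach annotations.
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty expression file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  # header may or may not carry a leading label for the gene-id column
  n_samp <- length(fields[[2]]) - 1L
  sample_ids <- if (length(header) == n_samp) header else header[-1]
  if (length(sample_ids) != n_samp) {
    stop("header has ", length(sample_ids), " sample ids but data rows have ",
         n_samp, " value columns", call. = FALSE)
  }
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != n_samp + 1L)) {
    bad <- which(widths != n_samp + 1L)[1]
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 bad + 1L, n_samp + 1L, widths[bad]), call. = FALSE)
  }
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  cells <- vapply(body, function(f) f[-1], character(n_samp))
  cells <- if (n_samp == 1L) matrix(cells, ncol = 1L) else t(cells)
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-numeric cell '%s' at row %d (gene '%s'), column %d (sample '%s')",
      cells[bad[1], bad[2]], bad[1], gene_ids[bad[1]], bad[2],
      sample_ids[bad[2]]), call. = FALSE)
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  pipeline_log("read_expression_matrix", genes = nrow(vals),
               samples = ncol(vals), path = path)
  expression_study(vals)
}

#' Attach a sample sheet to an expression study
#'
#' The sheet is a TSV with columns `sample_id`, `study_id`, `arm`, `part`,
#' `method` (and optionally `replicate_index`). Every expression column must
#' be matched by exactly one sheet row; enum values outside the allowed
#' vocabularies are fatal with the allowed tokens listed.
#'
#' @param path path to the sample-sheet TSV.
#' @param expr an [expression_study()].
#' @return The annotated `expression_study`.
#' @export
read_sample_sheet <- function(path, expr) {
  stopifnot(inherits(expr, "expression_study"))
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  if (!is.null(sheet$replicate_index)) {
    sheet$replicate_index <- as.integer(sheet$replicate_index)
  }
  expr$samples <- sheet
  out <- validate_sample_annotation(expr)
  pipeline_log("read_sample_sheet", samples = nrow(out$samples),
               studies = length(unique(out$samples$study_id)), path = path)
  out
}

#' Write / read a per-gene result table
#'
#' Tab-delimited output with one row per gene, stable column order and full
#' float precision (values survive a write/read round trip to at least 15
#' significant digits). List columns are dropped with a message.
#'
#' @param table data.frame keyed by a `gene_id` column (or any data.frame).
#' @param path output file path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns a data.frame.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  is_list <- vapply(table, is.list, logical(1))
  if (any(is_list)) {
    message("[metaexpr] dropping list column(s) on write: ",
            paste(names(table)[is_list], collapse = ", "))
    table <- table[!is_list]
  }
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 17, trim = TRUE,
                                                  scientific = NA))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write results to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
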