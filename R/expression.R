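#' Expression matrices
#'
#' An `expression_matrix` is a genes-by-samples numeric matrix with unique
#' row identifiers (genes or probes) and unique sample labels, plus a load
#' report describing how parsing policies were applied. It is the sole data
#' input of the network-inference pipeline; values may be on any monotone
#' expression scale since mutual information is estimated on ranks.
#'
#' @param values numeric matrix, rows = genes/probes, columns = samples.
#' @param ids character vector of row identifiers (defaults to rownames).
#' @param samples character vector of sample labels (defaults to colnames).
#' @param report optional load-report tibble.
#' @return An `expression_matrix` object.
#' @examples
#' m <- expression_matrix(matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4))))
#' dim(m)
#' @export
expression_matrix <- function(values, ids = rownames(values),
                              samples = colnames(values), report = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(ids) || is.null(samples)) {
    abort("row identifiers and sample labels are required.")
  }
  ids <- as.character(ids)
  samples <- as.character(samples)
  if (length(ids) != nrow(values) || length(samples) != ncol(values)) {
    abort("identifier/sample lengths do not match the matrix dimensions.")
  }
  if (anyDuplicated(ids)) abort("row identifiers must be unique.")
  if (anyDuplicated(samples)) abort("sample labels must be unique.")
  if (anyNA(values)) abort("expression values must be complete (no NA).")
  dimnames(values) <- list(ids, samples)
  structure(values,
    class = c("expression_matrix", "matrix", "array"),
    report = report
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d genes x %d samples\n", nrow(x), ncol(x)
  ))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE], 4L))
  invisible(x)
}

#' @export
as_tibble.expression_matrix <- function(x, ...) {
  tibble(
    id = rep(rownames(x), ncol(x)),
    sample = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}

as_expression_matrix <- function(x) {
  if (inherits(x, "expression_matrix")) return(x)
  if (is.matrix(x)) return(expression_matrix(x))
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    vals <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    return(expression_matrix(vals, ids = ids, samples = colnames(x)[-1]))
  }
  abort("cannot interpret input as an expression matrix.")
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample labels and rows that begin with a gene or
#' probe identifier. Files starting with `#1.2` are treated as GCT: the two
#' header lines are skipped and the second (annotation) column is dropped.
#'
#' @param path path to a tab-separated text file.
#' @param missing_values what to do with rows containing missing entries:
#'   `"drop"` (default; dropped rows are counted in the load report) or
#'   `"error"`.
#' @param duplicate_ids policy for duplicated identifiers: `"suffix"`
#'   (default; disambiguate with [make.unique()] and warn) or `"strict"`
#'   (error).
#' @param transpose set `TRUE` when the file is samples-by-genes.
#' @return An [expression_matrix()] with a `report` attribute (tibble with
#'   `rows_read`, `rows_dropped`, `duplicate_ids`, and the policies applied);
#'   retrieve it with `load_report()`.
#' @seealso [write_expression()], [load_report()]
#' @export
read_expression <- function(path,
                            missing_values = c("drop", "error"),
                            duplicate_ids = c("suffix", "strict"),
                            transpose = FALSE) {
  missing_values <- match.arg(missing_values)
  duplicate_ids <- match.arg(duplicate_ids)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))

  first <- readLines(path, n = 1L)
  gct <- startsWith(first, "#1.2")
  raw <- readr::read_tsv(
    path,
    skip = if (gct) 2L else 0L,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (gct && ncol(raw) >= 2L) raw <- raw[, -2L, drop = FALSE]
  if (ncol(raw) < 2L) abort("expression file needs an id column plus data.")

  ids <- as.character(raw[[1L]])
  samples <- colnames(raw)[-1L]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))

  bad <- which(is.na(vals) & !is.na(cells) &
    !(toupper(trimws(cells)) %in% c("NA", "NAN", "")))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(vals))
    abort(sprintf(
      "malformed numeric value '%s' at data row %d, column '%s'.",
      cells[bad[1L]], rc[1L], samples[rc[2L]]
    ))
  }

  incomplete <- !complete.cases(vals)
  if (any(incomplete) && missing_values == "error") {
    abort(sprintf(
      "%d row(s) contain missing values (first: '%s').",
      sum(incomplete), ids[which(incomplete)[1L]]
    ))
  }
  rows_read <- length(ids)
  ids <- ids[!incomplete]
  vals <- vals[!incomplete, , drop = FALSE]

  n_dup <- sum(duplicated(ids))
  if (n_dup > 0L) {
    if (duplicate_ids == "strict") {
      abort(sprintf("%d duplicated identifier(s) under strict policy.", n_dup))
    }
    warn(sprintf("%d duplicated identifier(s) suffix-disambiguated.", n_dup))
    ids <- make.unique(ids, sep = "_")
  }

  rownames(vals) <- ids
  colnames(vals) <- samples
  if (transpose) vals <- t(vals)

  report <- tibble(
    rows_read = rows_read,
    rows_dropped = sum(incomplete),
    duplicate_ids = n_dup,
    missing_policy = missing_values,
    duplicate_policy = duplicate_ids
  )
  expression_matrix(vals, report = report)
}

#' @rdname read_expression
#' @param x an expression matrix (or coercible object).
#' @export
write_expression <- function(x, path) {
  x <- as_expression_matrix(x)
  df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @export
load_report <- function(x) attr(x, "report")

#' Read a gene set (one identifier per line)
#'
#' Blank lines and `#` comments are ignored; duplicates are removed with a
#' warning. A gene set tagged as a transcription-factor list must be
#' non-empty.
#'
#' @param path path to a plain-text file, one identifier per line.
#' @param label free-text role tag, e.g. `"TF list"` or `"ChIP positives"`.
#' @return A `gene_set`: a character vector of unique identifiers with
#'   `label` and `n_duplicates` attributes.
#' @export
read_gene_list <- function(path, label = "gene set") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  ids <- trimws(lines)
  ids <- ids[nzchar(ids)]
  gene_set(ids, label = label)
}

#' @rdname read_gene_list
#' @param ids character vector of identifiers (duplicates tolerated).
#' @export
gene_set <- function(ids, label = "gene set") {
  ids <- as.character(ids)
  n_dup <- sum(duplicated(ids))
  if (n_dup > 0L) {
    warn(sprintf("%d duplicated identifier(s) removed from %s.", n_dup, label))
  }
  ids <- unique(ids)
  if (length(ids) == 0L && grepl("TF", label, ignore.case = TRUE)) {
    abort("a transcription-factor list must not be empty.")
  }
  structure(ids,
    class = c("gene_set", "character"),
    label = label, n_duplicates = n_dup
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf(
    "<gene_set> %s: %d identifiers\n", attr(x, "label"), length(x)
  ))
  invisible(x)
}

#' Collapse probe-level rows to gene level
#'
#' Microarray matrices are often probe-level; given a probe-to-gene mapping
#' this keeps, per gene, either the probe row with the highest mean signal
#' (`"max-mean-row"`, the usual hybridization-quality heuristic) or the
#' arithmetic mean of all its probe rows (`"mean"`). Probes absent from the
#' mapping are dropped and counted in the load report.
#'
#' @param x an expression matrix.
#' @param mapping two-column data frame: probe identifier, gene identifier.
#' @param method `"max-mean-row"` (default) or `"mean"`.
#' @return A gene-level [expression_matrix()].
#' @export
collapse_probes <- function(x, mapping, method = c("max-mean-row", "mean")) {
  x <- as_expression_matrix(x)
  method <- match.arg(method)
  if (ncol(mapping) < 2L) abort("`mapping` needs probe and gene columns.")
  probes <- as.character(mapping[[1L]])
  genes <- as.character(mapping[[2L]])
  keep <- probes %in% rownames(x)
  if (!any(keep)) abort("mapping and matrix identifiers do not intersect.")
  probes <- probes[keep]
  genes <- genes[keep]

  row_mean <- rowMeans(unclass(x))
  out <- vapply(split(probes, genes), function(p) {
    if (method == "max-mean-row") {
      unclass(x)[p[which.max(row_mean[p])], ]
    } else {
      colMeans(unclass(x)[p, , drop = FALSE])
    }
  }, numeric(ncol(x)))
  out <- t(out)

  report <- tibble(
    rows_read = nrow(x),
    rows_dropped = nrow(x) - length(unique(probes)),
    duplicate_ids = 0L,
    missing_policy = NA_character_,
    duplicate_policy = sprintf("collapse:%s", method)
  )
  expression_matrix(out,
    ids = rownames(out), samples = colnames(x),
    report = report
  )
}
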