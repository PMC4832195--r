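#' Construct and validate a sample table
#'
#' A sample table is the basic data container of the package: a samples x
#' variables matrix of non-negative measurements (exchangeable ion
#' concentrations in extract units, or enzyme activities in
#' nmol h\eqn{^{-1}} g\eqn{^{-1}} soil), with ordered unique sample and
#' variable labels and a per-variable category tag.
#'
#' @param values numeric matrix, samples in rows, variables in columns.
#'   Dimnames supply `sample_ids`/`variable_ids` when those are omitted.
#' @param sample_ids character vector of unique sample labels.
#' @param variable_ids character vector of unique variable labels.
#' @param category per-variable category, `"ion"` or `"enzyme"`; recycled
#'   if length one.
#' @return An object of class `sample_table`: the values matrix with
#'   `category` attribute attached and dimnames set.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("B", "Na", "Al")))
#' st <- sample_table(m, category = "ion")
#' dim(st)
#' @export
sample_table <- function(values, sample_ids = rownames(values),
                         variable_ids = colnames(values),
                         category = "ion") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(sample_ids) || is.null(variable_ids))
    stop("sample and variable ids are required (as arguments or dimnames)")
  sample_ids <- as.character(sample_ids)
  variable_ids <- as.character(variable_ids)
  if (length(sample_ids) != nrow(values))
    stop("length of 'sample_ids' must equal the number of rows")
  if (length(variable_ids) != ncol(values))
    stop("length of 'variable_ids' must equal the number of columns")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(variable_ids))
    stop("duplicate variable id: ",
         paste(unique(variable_ids[duplicated(variable_ids)]), collapse = ", "))
  if (any(is.na(sample_ids)) || any(!nzchar(sample_ids)))
    stop("missing or empty sample id")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at sample '%s', variable '%s'",
                 sample_ids[bad[1]], variable_ids[bad[2]]))
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at sample '%s', variable '%s'",
                 sample_ids[bad[1]], variable_ids[bad[2]]))
  }
  category <- match.arg(as.character(category), c("ion", "enzyme"),
                        several.ok = TRUE)
  category <- rep_len(category, ncol(values))
  dimnames(values) <- list(sample_ids, variable_ids)
  structure(values, category = category, class = c("sample_table", "matrix"))
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("Sample table: %d samples x %d variables (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%d %s", table(attr(x, "category")),
                            names(table(attr(x, "category")))),
                    collapse = ", ")))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE]), ...)
  if (nrow(x) > 6L || ncol(x) > 6L) cat("...\n")
  invisible(x)
}

# comma if the header contains more commas than tabs, else tab
detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))) >=
      lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))))
    "," else "\t"
}

#' Read a sample table from delimited text
#'
#' Reads a samples x variables table (first column sample ids, header row
#' variable ids) written as comma- or tab-separated text; the delimiter is
#' auto-detected from the header line unless given. Cells must be finite
#' non-negative numbers; `NA` or non-numeric cells are rejected with the
#' offending row and column named, as the analysis chain has no imputation
#' rule.
#'
#' @param path path to the delimited file.
#' @param delimiter `"auto"` (default), `","` or `"\t"`.
#' @param category per-variable category tag passed to [sample_table()],
#'   or the path of a two-column variables manifest (`variable_id`,
#'   `category`) when categories are mixed.
#' @return A validated [sample_table()].
#' @seealso [write_sample_table()]
#' @export
read_sample_table <- function(path, delimiter = "auto", category = "ion") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (identical(delimiter, "auto")) detect_delimiter(path) else delimiter
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(raw) < 2L) stop("table must have sample ids plus >= 1 variable")
  ids <- raw[[1L]]
  vars <- colnames(raw)[-1L]
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1L)
  bad <- which(is.na(num) & !is.na(as.matrix(raw[-1L])), arr.ind = TRUE)
  na_cells <- which(is.na(as.matrix(raw[-1L])), arr.ind = TRUE)
  bad <- rbind(bad, na_cells)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric or missing cell at row '%s', column '%s'",
                 ids[bad[1, 1]], vars[bad[1, 2]]))
  if (length(category) == 1L && file.exists(category) &&
      !category %in% c("ion", "enzyme")) {
    manifest <- utils::read.csv(category, stringsAsFactors = FALSE)
    if (!all(c("variable_id", "category") %in% names(manifest)))
      stop("variables manifest needs columns 'variable_id' and 'category'")
    idx <- match(vars, manifest$variable_id)
    if (anyNA(idx))
      stop("variable absent from manifest: ",
           paste(vars[is.na(idx)], collapse = ", "))
    category <- manifest$category[idx]
  }
  sample_table(num, sample_ids = ids, variable_ids = vars,
               category = category)
}

#' Write a sample table as delimited text
#'
#' Numeric values are written with 12 significant digits so that a
#' write/read round trip is value-identical at that precision.
#'
#' @param table a [sample_table()].
#' @param path output path.
#' @param delimiter `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path, delimiter = ",") {
  stopifnot(inherits(table, "sample_table"))
  out <- data.frame(sample_id = rownames(table),
                    format(unclass(table), digits = 12, trim = TRUE,
                           scientific = NA),
                    check.names = FALSE)
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Combine sample tables column-wise
#'
#' Binds two sample tables measured on the same samples (e.g. ions and
#' enzymes) into one, preserving per-variable categories; used when
#' correlating across the two variable sets.
#'
#' @param x,y [sample_table()]s with identical sample ids in identical
#'   order.
#' @return A [sample_table()] with the columns of both.
#' @export
combine_tables <- function(x, y) {
  stopifnot(inherits(x, "sample_table"), inherits(y, "sample_table"))
  if (!identical(rownames(x), rownames(y)))
    stop("sample ids of the two tables must match")
  sample_table(cbind(unclass(x), unclass(y)),
               category = c(attr(x, "category"), attr(y, "category")))
}

#' Read and validate a sample metadata table
#'
#' The metadata CSV must carry columns `sample_id`, `site`,
#' `fertilization`, `replicate` and `pH`. Fertilization labels are
#' normalized to upper case and must then be `CF` (chemical fertilizer
#' only) or `COF` (chemical plus organic fertilizer); pH must lie in
#' \[0, 14\]; every (site, fertilization) cell needs at least two
#' replicates because downstream variance estimation requires it.
#'
#' @param path path to the metadata CSV.
#' @param table optional [sample_table()] whose sample ids must all be
#'   present exactly once.
#' @return A data frame of class `sample_metadata`.
#' @export
read_metadata <- function(path, table = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  sample_metadata(md, table = table)
}

#' @rdname read_metadata
#' @param metadata a data frame with the metadata columns, validated in
#'   place (used by [read_metadata()] and the synthetic generator).
#' @export
sample_metadata <- function(metadata, table = NULL) {
  need <- c("sample_id", "site", "fertilization", "replicate", "pH")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0L)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$site <- as.character(metadata$site)
  metadata$fertilization <- toupper(as.character(metadata$fertilization))
  bad <- setdiff(unique(metadata$fertilization), c("CF", "COF"))
  if (length(bad) > 0L)
    stop("unknown fertilization label: ", paste(bad, collapse = ", "))
  metadata$replicate <- as.integer(metadata$replicate)
  if (any(is.na(metadata$replicate) | metadata$replicate < 1L))
    stop("replicate must be a positive integer")
  metadata$pH <- as.numeric(metadata$pH)
  if (any(is.na(metadata$pH) | metadata$pH < 0 | metadata$pH > 14))
    stop("pH outside [0, 14] for sample(s): ",
         paste(metadata$sample_id[is.na(metadata$pH) | metadata$pH < 0 |
                                    metadata$pH > 14], collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  cell_n <- table(metadata$site, metadata$fertilization)
  if (any(cell_n > 0 & cell_n < 2))
    stop("each (site, fertilization) cell needs >= 2 replicates")
  if (!is.null(table)) {
    missing_ids <- setdiff(rownames(table), metadata$sample_id)
    if (length(missing_ids) > 0L)
      stop("sample ids absent from metadata: ",
           paste(missing_ids, collapse = ", "))
  }
  class(metadata) <- c("sample_metadata", "data.frame")
  metadata
}

#' Summarize the experimental design
#'
#' Counts sites, treatments and replicates per (site, fertilization)
#' cell. The design is balanced when every cell holds the same number of
#' replicates, in which case the total sample count equals
#' sites x treatments x replicates.
#'
#' @param metadata a `sample_metadata` data frame.
#' @return A list of class `design_summary` with elements `n_sites`,
#'   `n_treatments`, `n_replicates_per_cell`, `n_samples_total`,
#'   `balanced` and the full `cell_counts` table.
#' @export
summarize_design <- function(metadata) {
  stopifnot(inherits(metadata, "sample_metadata"))
  if (nrow(metadata) == 0L) stop("empty metadata")
  cells <- table(metadata$site, metadata$fertilization)
  counts <- cells[cells > 0]
  balanced <- length(unique(counts)) == 1L &&
    all(cells > 0)  # every site x treatment combination occupied
  structure(list(
    n_sites = length(unique(metadata$site)),
    n_treatments = length(unique(metadata$fertilization)),
    n_replicates_per_cell = if (balanced) unname(counts[1]) else NA_integer_,
    n_samples_total = nrow(metadata),
    balanced = balanced,
    cell_counts = cells), class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat(sprintf("Design: %d site(s) x %d treatment(s), %s replicates/cell, %d samples%s\n",
              x$n_sites, x$n_treatments,
              ifelse(is.na(x$n_replicates_per_cell), "unequal",
                     x$n_replicates_per_cell),
              x$n_samples_total,
              if (x$balanced) " (balanced)" else " (unbalanced)"))
  invisible(x)
}
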