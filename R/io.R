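# Readers and writers for the pipeline's plain-text formats: id-indexed
# TSV/CSV matrices, GMT gene-set collections, and geometry tables. All
# tables are id-indexed, never positional, to prevent silent misalignment.

#' Read an id-indexed matrix from TSV/CSV
#'
#' First column holds row ids (must be unique); remaining columns are
#' numeric. Comment lines starting with `#` are ignored. Ragged rows and
#' duplicated ids are format errors.
#'
#' @param path File path; delimiter inferred from the extension (`.csv` ->
#'   comma, otherwise tab).
#' @return Numeric matrix with row and column names.
#' @export
read_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  nfield <- lengths(strsplit(lines, sep, fixed = TRUE))
  if (length(unique(nfield)) != 1L) {
    stop_ironmap("ragged rows in %s", "ironmap_format_error", path)
  }
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop_ironmap("duplicated row ids in %s", "ironmap_format_error", path)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    stop_ironmap("non-numeric entries in %s", "ironmap_format_error", path)
  }
  rownames(m) <- ids
  m
}

#' Write an id-indexed matrix to TSV/CSV
#'
#' @param x Matrix with row and column names.
#' @param path Output path; delimiter inferred from extension.
#' @param id_name Header for the id column.
#' @param comment Optional character vector written as leading `#` lines
#'   (used by the pipeline to record stage, config hash and seed).
#' @export
write_matrix <- function(x, path, id_name = "id", comment = NULL) {
  assert_that(is.matrix(x) && !is.null(rownames(x)) && !is.null(colnames(x)),
              "x must be a matrix with dimnames")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c(id_name, colnames(x)), collapse = sep), con)
  body <- apply(x, 1L, function(r) {
    paste(format(r, digits = 17, trim = TRUE, scientific = NA),
          collapse = sep)
  })
  writeLines(paste(rownames(x), body, sep = sep), con)
  invisible(path)
}

#' Write a data.frame as TSV with an optional comment header
#' @param x data.frame.
#' @param path Output path.
#' @param comment Optional `#` header lines.
#' @export
write_table <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table, skipping comment lines
#' @param path File path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

as_geneset_list <- function(collection) {
  if (inherits(collection, "ironmap_genesets")) return(collection)
  assert_that(is.list(collection) && !is.null(names(collection)),
              "collection must be a named list or ironmap_genesets")
  structure(list(members = lapply(collection, as.character),
                 names = stats::setNames(as.list(names(collection)),
                                         names(collection))),
            class = "ironmap_genesets")
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one term per line, tab-separated
#' `term_id<TAB>description<TAB>member...`. Duplicate members within a term
#' are deduplicated with a warning; lines with fewer than three fields are
#' format errors.
#'
#' @param path GMT file path.
#' @return An `ironmap_genesets` object: `members` (named list of unique
#'   gene-id vectors) and `names` (named list of descriptions).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    stop_ironmap("GMT line with fewer than 3 fields in %s",
                 "ironmap_format_error", path)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  members <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    if (anyDuplicated(g)) {
      warning(sprintf("duplicated members in term '%s' deduplicated", f[[1]]))
      g <- unique(g)
    }
    g
  })
  descr <- vapply(fields, `[[`, "", 2L)
  structure(list(members = stats::setNames(members, ids),
                 names = stats::setNames(as.list(descr), ids)),
            class = "ironmap_genesets")
}

#' Write a gene-set collection to GMT
#' @param collection An `ironmap_genesets` or named list of gene-id vectors.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  sets <- as_geneset_list(collection)
  lines <- vapply(names(sets$members), function(id) {
    paste(c(id, sets$names[[id]] %||% id, sets$members[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a parcellation geometry as a TSV of centroids
#' @param geometry An `ironmap_geometry`.
#' @param path Output path.
#' @export
write_geometry <- function(geometry, path) {
  df <- data.frame(region_id = geometry$region_id,
                   cx = geometry$centroids[, 1],
                   cy = geometry$centroids[, 2],
                   cz = geometry$centroids[, 3])
  write_table(df, path)
}

#' Read a parcellation geometry from a centroid TSV
#' @param path TSV with region_id, cx, cy, cz.
#' @return An `ironmap_geometry`.
#' @export
read_geometry <- function(path) {
  df <- read_table(path)
  m <- as.matrix(df[, c("cx", "cy", "cz")])
  m <- m / sqrt(rowSums(m^2)) # guard against text-format rounding
  parcellation_geometry(m, df$region_id)
}
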