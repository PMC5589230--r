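#' Read a two-column disease-microbe association table
#'
#' Parses a delimited text file (or literal text) of disease/microbe name
#' pairs into an association record data frame. One record per data row;
#' names are whitespace-trimmed; row order is preserved.
#'
#' Column assignment: when a header is present the reader looks for columns
#' whose names contain "disease" and "microbe"/"organism" (case-insensitive)
#' and uses them in either order; otherwise it falls back to the positions
#' given by `disease_col` / `microbe_col`.
#'
#' @param source path to a readable file, or a character vector of raw lines
#'   (`text = TRUE`).
#' @param delimiter field separator, `"\t"` by default.
#' @param has_header logical; if `NA` (default) the first row is treated as a
#'   header when it contains no digits and matches the keyword columns.
#' @param disease_col,microbe_col 1-based positional fallbacks.
#' @param text logical; treat `source` as literal lines rather than a path.
#' @return data frame with character columns `disease` and `microbe`.
#' @examples
#' read_association_table(c("asthma\tPseudomonas", "IBD\tPrevotella"),
#'                        text = TRUE)
#' @export
read_association_table <- function(source, delimiter = "\t", has_header = NA,
                                   disease_col = 1L, microbe_col = 2L,
                                   text = FALSE) {
  if (text) {
    lines <- as.character(source)
  } else {
    if (!is.character(source) || length(source) != 1L || !file.exists(source))
      stop("cannot read association table: no such file: ",
           paste(source, collapse = " "))
    lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(disease = character(0), microbe = character(0),
                      stringsAsFactors = FALSE))

  fields <- strsplit(lines, delimiter, fixed = TRUE)

  header <- NULL
  first <- tolower(trimws(fields[[1L]]))
  looks_named <- any(grepl("disease", first)) &&
    any(grepl("microbe|organism", first))
  if (isTRUE(has_header) || (is.na(has_header) && looks_named)) {
    header <- first
    fields <- fields[-1L]
    lines <- lines[-1L]
  }
  if (length(fields) == 0L)
    return(data.frame(disease = character(0), microbe = character(0),
                      stringsAsFactors = FALSE))

  if (!is.null(header) && looks_named) {
    disease_col <- which(grepl("disease", header))[1L]
    microbe_col <- which(grepl("microbe|organism", header))[1L]
  }

  need <- max(disease_col, microbe_col)
  short <- which(vapply(fields, length, 1L) < need)
  if (length(short) > 0L)
    stop("association table parse error: line ",
         short[1L] + as.integer(!is.null(header)),
         " has fewer than ", need, " fields")

  disease <- trimws(vapply(fields, `[[`, "", disease_col))
  microbe <- trimws(vapply(fields, `[[`, "", microbe_col))
  bad <- which(!nzchar(disease) | !nzchar(microbe))
  if (length(bad) > 0L)
    stop("association table parse error: line ",
         bad[1L] + as.integer(!is.null(header)), " has an empty name")
  data.frame(disease = disease, microbe = microbe, stringsAsFactors = FALSE)
}

#' Remove duplicate association records
#'
#' Keeps the first occurrence of each (disease, microbe) pair, preserving
#' input order. Matching is exact string match after trimming; set
#' `case_sensitive = FALSE` to fold case before comparing (the kept record
#' retains its original spelling).
#'
#' @param records data frame with columns `disease`, `microbe`.
#' @param case_sensitive logical, default `TRUE`.
#' @return data frame of distinct records.
#' @export
deduplicate <- function(records, case_sensitive = TRUE) {
  records <- as_records(records)
  if (nrow(records) == 0L) return(records)
  d <- records$disease
  m <- records$microbe
  if (!case_sensitive) {
    d <- tolower(d)
    m <- tolower(m)
  }
  keep <- !duplicated(paste0(d, "\r", m))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the binary disease x microbe adjacency matrix
#'
#' Rows are diseases, columns are microbes; `A[i, j] = 1` iff the pair is in
#' `records`. Index order is first-appearance order unless `sort_names`.
#' Records should be deduplicated first so that `sum(A)` equals the number
#' of distinct associations.
#'
#' @param records data frame with columns `disease`, `microbe`; nonempty.
#' @param sort_names logical; lexicographic index order instead of
#'   first-appearance order.
#' @return binary integer matrix with disease rownames and microbe colnames.
#' @export
build_adjacency <- function(records, sort_names = FALSE) {
  records <- as_records(records)
  if (nrow(records) == 0L)
    stop("cannot build adjacency matrix from an empty record list")
  diseases <- unique(records$disease)
  microbes <- unique(records$microbe)
  if (sort_names) {
    diseases <- sort(diseases)
    microbes <- sort(microbes)
  }
  A <- matrix(0L, nrow = length(diseases), ncol = length(microbes),
              dimnames = list(diseases, microbes))
  A[cbind(match(records$disease, diseases),
          match(records$microbe, microbes))] <- 1L
  A
}

#' Recover the association record list from an adjacency matrix
#'
#' Inverse of [build_adjacency()]: one record per 1-entry, in row-major
#' (disease-major) order.
#'
#' @param A binary adjacency matrix with dimnames.
#' @return data frame with columns `disease`, `microbe`.
#' @export
adjacency_to_records <- function(A) {
  check_adjacency(A)
  idx <- which(t(A) == 1, arr.ind = TRUE)  # transpose => disease-major order
  if (nrow(idx) == 0L)
    return(data.frame(disease = character(0), microbe = character(0),
                      stringsAsFactors = FALSE))
  data.frame(disease = rownames(A)[idx[, 2L]],
             microbe = colnames(A)[idx[, 1L]],
             stringsAsFactors = FALSE)
}

#' Degree summary of the bipartite association network
#'
#' @param A binary disease x microbe adjacency matrix.
#' @return list with `microbe_degrees` (named column sums), `disease_degrees`
#'   (named row sums), `mean_microbe_degree` and `mean_disease_degree`.
#' @export
degree_summary <- function(A) {
  check_adjacency(A)
  md <- colSums(A)
  dd <- rowSums(A)
  list(microbe_degrees = md,
       disease_degrees = dd,
       mean_microbe_degree = sum(A) / ncol(A),
       mean_disease_degree = sum(A) / nrow(A))
}

#' Write an adjacency matrix as labeled TSV plus a JSON index sidecar
#'
#' @param A adjacency (or any labeled disease x microbe) matrix.
#' @param path output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(A, path) {
  check_adjacency(A, binary = FALSE)
  utils::write.table(A, path, sep = "\t", quote = FALSE, col.names = NA)
  jsonlite::write_json(
    list(disease_index = rownames(A), microbe_index = colnames(A)),
    paste0(path, ".json"))
  invisible(path)
}

as_records <- function(records) {
  if (is.matrix(records)) records <- as.data.frame(records)
  if (!is.data.frame(records) ||
      !all(c("disease", "microbe") %in% names(records)))
    stop("records must be a data frame with columns 'disease' and 'microbe'")
  records$disease <- trimws(as.character(records$disease))
  records$microbe <- trimws(as.character(records$microbe))
  records
}

check_adjacency <- function(A, binary = TRUE) {
  if (!is.matrix(A) || nrow(A) == 0L || ncol(A) == 0L)
    stop("adjacency must be a nonempty matrix (diseases x microbes)")
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop("adjacency must carry disease rownames and microbe colnames")
  if (anyDuplicated(rownames(A)) || anyDuplicated(colnames(A)))
    stop("adjacency dimnames contain duplicates")
  if (binary && !all(A %in% c(0, 1)))
    stop("adjacency entries must all be 0 or 1")
  invisible(A)
}
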