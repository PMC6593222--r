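# BIOM feature-table I/O.
#
# Reading goes through Bioconductor's biomformat (BIOM 1.0 JSON; HDF5 2.1
# transparently if rhdf5 is available to biomformat). Writing is a
# deterministic BIOM 1.0 JSON ("sparse") writer of our own: given fixed
# inputs and an injected timestamp the bytes are stable, which the export
# manifest relies on.

#' Read a BIOM feature table into a dense count matrix
#'
#' @param path Path to a BIOM 1.0 JSON file (or any file
#'   \code{biomformat::read_biom} accepts).
#' @return Numeric matrix, features as rows, samples as columns.
#' @export
read_biom_table <- function(path) {
  if (!file.exists(path)) stop("BIOM file not found: ", path, call. = FALSE)
  b <- tryCatch(biomformat::read_biom(path), error = function(e) {
    stop("invalid BIOM file '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  m <- as(biomformat::biom_data(b), "matrix")
  storage.mode(m) <- "double"
  validate_feature_matrix(m, path)
  m
}

validate_feature_matrix <- function(m, what = "feature table") {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, ": feature and sample identifiers are required", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop(what, ": duplicate feature identifiers", call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop(what, ": duplicate sample identifiers", call. = FALSE)
  }
  if (anyNA(m)) stop(what, ": NA counts are not allowed", call. = FALSE)
  if (any(m < 0)) stop(what, ": negative counts are not allowed", call. = FALSE)
  invisible(m)
}

json_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

fmt_count <- function(v) {
  ifelse(v == trunc(v),
         format(v, scientific = FALSE, trim = TRUE, nsmall = 0),
         sprintf("%.17g", v))
}

#' Write a count matrix as BIOM 1.0 JSON
#'
#' Sparse representation (only nonzero cells), rows and columns in the
#' caller-given order. Integral counts are serialized as integers, others as
#' decimals. The output is byte-stable for fixed inputs and timestamp, and
#' readable by \code{biomformat::read_biom}.
#'
#' @param m Numeric matrix, features as rows, samples as columns; dimnames
#'   required.
#' @param path Output file path.
#' @param id Optional table id string.
#' @param generated_by Generator tag embedded in the file.
#' @param timestamp Date string embedded in the file; pass a fixed value for
#'   reproducible bytes (default: current time).
#' @return Invisibly, \code{path}.
#' @export
write_biom_json <- function(m, path, id = "No Table ID",
                            generated_by = paste0("biomdex ", biomdex_version()),
                            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  validate_feature_matrix(m)
  storage.mode(m) <- "double"
  nz <- which(m > 0, arr.ind = TRUE)
  # row-major cell order as the BIOM sparse convention expects
  ord <- order(nz[, 1L], nz[, 2L])
  nz <- nz[ord, , drop = FALSE]
  vals <- m[nz]
  elem_type <- if (all(vals == trunc(vals))) "int" else "float"
  cells <- sprintf("[%d,%d,%s]", nz[, 1L] - 1L, nz[, 2L] - 1L, fmt_count(vals))
  row_json <- sprintf("{\"id\":\"%s\",\"metadata\":null}", json_escape(rownames(m)))
  col_json <- sprintf("{\"id\":\"%s\",\"metadata\":null}", json_escape(colnames(m)))
  json <- paste0(
    "{\"id\":\"", json_escape(id), "\",",
    "\"format\":\"Biological Observation Matrix 1.0.0\",",
    "\"format_url\":\"http://biom-format.org\",",
    "\"type\":\"OTU table\",",
    "\"generated_by\":\"", json_escape(generated_by), "\",",
    "\"date\":\"", json_escape(timestamp), "\",",
    "\"matrix_type\":\"sparse\",",
    "\"matrix_element_type\":\"", elem_type, "\",",
    "\"shape\":[", nrow(m), ",", ncol(m), "],",
    "\"rows\":[", paste(row_json, collapse = ","), "],",
    "\"columns\":[", paste(col_json, collapse = ","), "],",
    "\"data\":[", paste(cells, collapse = ","), "]}"
  )
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

biomdex_version <- function() {
  as.character(utils::packageVersion("biomdex"))
}
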