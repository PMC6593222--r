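# Materialize query results back into analysis-ready files: a BIOM feature
# table rebuilt from stored sparse vectors, the matching metadata table, and
# a provenance manifest.

#' Rebuild a feature table for a sample set
#'
#' Columns are the requested samples present in the context, rows the union
#' of features appearing with nonzero count in those samples (both in
#' lexicographic order); integer feature ids are translated back to the
#' original identifier strings. A freshly loaded table fetched over all its
#' samples reproduces the input exactly up to row/column order.
#'
#' @inheritParams map_identifiers
#' @param samples Character vector of sample ids (or a \code{biomdex_hits}).
#' @param features Optional feature restriction: rows are intersected with
#'   this set.
#' @return Numeric count matrix (features x samples). Wrap with
#'   \code{\link{write_biom_json}} to serialize.
#' @export
fetch_table <- function(store, context, samples, features = NULL) {
  assert_store(store)
  assert_context(store, context)
  if (inherits(samples, "biomdex_hits")) samples <- samples$samples
  samples <- sort(unique(as.character(samples)), method = "radix")
  if (!length(samples)) stop("no samples requested", call. = FALSE)
  rep_set <- kv_set_members(store, kv_key(context, "registry", "samples"))
  present <- samples[samples %in% rep_set]
  if (!length(present)) {
    stop("none of the ", length(samples),
         " requested sample(s) are present in context '", context, "'",
         call. = FALSE)
  }
  vecs <- lapply(present, function(s) sample_vector(store, context, s))
  names(vecs) <- present
  all_ints <- sort(unique(unlist(lapply(vecs, `[[`, "ints"), use.names = FALSE)))
  all_fids <- unmap_identifiers(store, context, all_ints, "feature")
  keep <- rep(TRUE, length(all_fids))
  if (!is.null(features)) keep <- all_fids %in% as.character(features)
  if (!any(keep)) {
    stop("no features with nonzero counts remain after the restriction",
         call. = FALSE)
  }
  rows <- sort(all_fids[keep], method = "radix")
  int_of <- setNames(all_ints, all_fids)
  row_of_int <- setNames(match(names(int_of), rows), as.character(int_of))
  m <- matrix(0, nrow = length(rows), ncol = length(present),
              dimnames = list(rows, present))
  for (j in seq_along(present)) {
    v <- vecs[[j]]
    ri <- row_of_int[as.character(v$ints)]
    ok <- which(!is.na(ri))
    if (length(ok)) {
      m[cbind(ri[ok], rep.int(j, length(ok)))] <- v$counts[ok]
    }
  }
  m
}

#' Emit the metadata table for a sample set
#'
#' One row per requested sample that has any metadata (lexicographic);
#' columns are the requested variables, or the union of variables observed
#' among those samples. Cells with no stored value carry a single
#' configurable missing marker. Requested samples with no metadata at all
#' are omitted and reported via the \code{"omitted"} attribute.
#'
#' @inheritParams fetch_table
#' @param variables Optional character vector of variables (column order
#'   preserved as given); default: union of observed variables, sorted.
#' @param missing Marker written for absent cells (default empty string).
#' @return data.frame, first column \code{"#SampleID"}; attribute
#'   \code{"omitted"} lists requested samples without metadata.
#' @export
fetch_metadata <- function(store, samples, variables = NULL, missing = "") {
  assert_store(store)
  if (inherits(samples, "biomdex_hits")) samples <- samples$samples
  samples <- sort(unique(as.character(samples)), method = "radix")
  has_md <- vapply(samples, function(s) {
    length(kv_record_fields(store, md_record_key(s))) > 0L
  }, logical(1L))
  kept <- samples[has_md]
  omitted <- samples[!has_md]
  if (is.null(variables)) {
    obs <- unique(unlist(lapply(kept, function(s) {
      kv_record_fields(store, md_record_key(s))
    }), use.names = FALSE))
    variables <- sort(obs, method = "radix")
  }
  cols <- lapply(variables, function(v) {
    vals <- vapply(kept, function(s) {
      kv_record_get(store, md_record_key(s), v)[[1L]]
    }, character(1L))
    ifelse(is.na(vals), missing, vals)
  })
  df <- data.frame(kept, cols, stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c("#SampleID", variables)
  rownames(df) <- NULL
  attr(df, "omitted") <- omitted
  df
}

#' Write a metadata table as tab-delimited text
#'
#' @param df data.frame as returned by \code{\link{fetch_metadata}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_metadata_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a query result as a self-contained bundle
#'
#' Writes the fetched feature table (BIOM 1.0 JSON), the matching metadata
#' TSV and a provenance manifest (query provenance, context, counts,
#' timestamp, tool version and per-file checksums) into a directory. With a
#' fixed \code{timestamp} the bundle is byte-identical across runs.
#'
#' @inheritParams fetch_table
#' @param hits A \code{biomdex_hits} from \code{\link{select_samples}} or
#'   \code{\link{search_features}}; must be context-bound.
#' @param output_dir Destination directory (created if needed).
#' @param variables Optional metadata variable restriction.
#' @param timestamp Timestamp string recorded in the manifest and BIOM file;
#'   inject a fixed value for reproducible bytes.
#' @return The manifest, invisibly (also written as \code{manifest.json}).
#' @export
export_hits <- function(store, hits, output_dir, variables = NULL,
                        features = NULL,
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  assert_store(store)
  if (!inherits(hits, "biomdex_hits")) {
    stop("`hits` must be a biomdex_hits object", call. = FALSE)
  }
  if (is.null(hits$context)) {
    stop("export needs a context-bound hit set", call. = FALSE)
  }
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", output_dir, call. = FALSE)
  }
  table_path <- file.path(output_dir, "table.biom")
  md_path <- file.path(output_dir, "metadata.tsv")
  manifest_path <- file.path(output_dir, "manifest.json")

  m <- fetch_table(store, hits$context, hits$samples, features = features)
  write_biom_json(m, table_path, timestamp = timestamp)
  md <- fetch_metadata(store, hits$samples, variables = variables)
  write_metadata_tsv(md, md_path)

  describe_prov <- function(p) {
    if (is.list(p)) lapply(p, describe_prov)
    else as.character(p)
  }
  manifest <- list(
    tool = "biomdex",
    version = biomdex_version(),
    timestamp = timestamp,
    context = hits$context,
    n_samples = length(hits$samples),
    n_features = nrow(m),
    samples = as.list(hits$samples),
    query = list(constraints = names(hits$provenance)),
    files = list(
      table = list(name = "table.biom",
                   md5 = unname(tools::md5sum(table_path))),
      metadata = list(name = "metadata.tsv",
                      md5 = unname(tools::md5sum(md_path)))
    )
  )
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, manifest_path, useBytes = TRUE)
  invisible(manifest)
}
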