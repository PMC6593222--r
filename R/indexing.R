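# Context lifecycle and table ingest.
#
# A context is a named partition of the store holding data produced under
# one sequencing + bioinformatics protocol (e.g. a Deblur 16S V4 90-nt
# context vs. a closed-reference OTU context). Counts within a context are
# comparable; across contexts only sample identities are. Each context owns:
#   <ctx>:registry:samples / <ctx>:registry:features   membership registries
#   <ctx>:map-forward|map-reverse|map-next:<space>     id <-> integer maps
#   <ctx>:data:<sample>                                sparse count vector
#   <ctx>:feature:<feature-id>                         inverted index (samples)
#   <ctx>:sample-features:<sample>                     feature membership
#   <ctx>:taxon:<label> / <ctx>:lineage:<feature-id>   taxonomy index

RESERVED_NAMESPACES <- c("state", "metadata")

ctx_registry_key <- function() kv_key("state", "registry", "contexts")

assert_context_name <- function(name) {
  if (length(name) != 1L || is.na(name) || !nzchar(name)) {
    stop("context name must be a single non-empty string", call. = FALSE)
  }
  if (grepl(KEY_SEP, name, fixed = TRUE)) {
    stop("context name may not contain '", KEY_SEP, "': ", name, call. = FALSE)
  }
  if (name %in% RESERVED_NAMESPACES) {
    stop("context name '", name, "' is reserved", call. = FALSE)
  }
  name
}

assert_context <- function(store, context) {
  assert_context_name(context)
  if (!context %in% kv_set_members(store, ctx_registry_key())) {
    stop("unknown context: ", context, call. = FALSE)
  }
  context
}

#' Create a named processing context
#'
#' @param store A \code{biomdex_store}.
#' @param name Context name; unique, no \code{":"}.
#' @param description Free-text description of the protocol the context
#'   partitions (e.g. \code{"Deblur 16S V4 90nt"}).
#' @return Invisibly, the context summary (see \code{\link{context_info}}).
#' @export
#' @examples
#' st <- store_create()
#' create_context(st, "deblur-90nt", "Deblur 16S V4 90nt")
#' list_contexts(st)
create_context <- function(store, name, description = "") {
  assert_store(store)
  assert_context_name(name)
  if (name %in% kv_set_members(store, ctx_registry_key())) {
    stop("context already exists: ", name, call. = FALSE)
  }
  kv_set_add(store, ctx_registry_key(), name)
  kv_put(store, kv_key("state", "about", name), as.character(description))
  invisible(context_info(store, name))
}

#' @rdname create_context
#' @return \code{list_contexts}: character vector of context names, sorted.
#' @export
list_contexts <- function(store) {
  assert_store(store)
  kv_set_members(store, ctx_registry_key())
}

#' Summary of one context
#'
#' @inheritParams create_context
#' @return List with \code{name}, \code{description}, \code{n_samples},
#'   \code{n_features}; counts reflect the registries at call time.
#' @export
context_info <- function(store, name) {
  assert_store(store)
  assert_context(store, name)
  out <- list(
    name = name,
    description = kv_get(store, kv_key("state", "about", name)),
    n_samples = length(kv_set_members(store, kv_key(name, "registry", "samples"))),
    n_features = length(kv_set_members(store, kv_key(name, "registry", "features")))
  )
  class(out) <- "biomdex_context"
  out
}

#' @export
print.biomdex_context <- function(x, ...) {
  cat(sprintf("<context> %s: %d samples, %d features\n  %s\n",
              x$name, x$n_samples, x$n_features, x$description))
  invisible(x)
}

#' Map string identifiers to dense per-context integers
#'
#' Inside a context every feature and sample identifier is remapped to a
#' small integer (dense from 0, first-seen order) so stored vectors carry
#' integers instead of long identifier strings. The forward and reverse maps
#' are a bijection; integers are never reassigned.
#'
#' @inheritParams create_context
#' @param context Context name.
#' @param ids Character vector of identifiers; unknown ids are assigned the
#'   next integers in first-occurrence order.
#' @param space Identifier space, \code{"feature"} or \code{"sample"}.
#' @return Integer vector aligned with \code{ids}.
#' @export
map_identifiers <- function(store, context, ids, space = c("feature", "sample")) {
  assert_store(store)
  space <- match.arg(space)
  assert_context(store, context)
  ids <- as.character(ids)
  if (!length(ids)) return(integer())
  fwd_key <- kv_key(context, "map-forward", space)
  cur <- suppressWarnings(as.integer(kv_record_get(store, fwd_key, ids)))
  if (anyNA(cur)) {
    next_key <- kv_key(context, "map-next", space)
    nxt <- kv_get(store, next_key)
    nxt <- if (is.null(nxt)) 0L else as.integer(nxt)
    new_ids <- unique(ids[is.na(cur)])
    new_ints <- seq.int(nxt, length.out = length(new_ids))
    kv_record_put(store, fwd_key, setNames(as.character(new_ints), new_ids))
    kv_record_put(store, kv_key(context, "map-reverse", space),
                  setNames(new_ids, as.character(new_ints)))
    kv_put(store, next_key, as.character(nxt + length(new_ids)))
    cur[is.na(cur)] <- new_ints[match(ids[is.na(cur)], new_ids)]
  }
  cur
}

#' @rdname map_identifiers
#' @param integers Integer vector to translate back to identifier strings.
#' @return \code{unmap_identifiers}: character vector; \code{NA} for
#'   integers never assigned.
#' @export
unmap_identifiers <- function(store, context, integers, space = c("feature", "sample")) {
  assert_store(store)
  space <- match.arg(space)
  assert_context(store, context)
  unname(kv_record_get(store, kv_key(context, "map-reverse", space),
                       as.character(as.integer(integers))))
}

encode_pairs <- function(ints, counts) {
  paste(ints, fmt_count(counts), sep = ":", collapse = ";")
}

decode_pairs <- function(encoded) {
  if (is.null(encoded) || !nzchar(encoded)) {
    return(list(ints = integer(), counts = numeric()))
  }
  parts <- strsplit(strsplit(encoded, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  list(ints = vapply(parts, function(p) as.integer(p[[1L]]), integer(1L)),
       counts = vapply(parts, function(p) as.numeric(p[[2L]]), numeric(1L)))
}

# one sample's stored sparse vector: feature integers + counts
sample_vector <- function(store, context, sample) {
  decode_pairs(kv_get(store, kv_key(context, "data", sample)))
}

#' Load a feature table into a context
#'
#' Each sample's nonzero counts become a sparse vector stored under the
#' composite (context, sample) key with feature identifiers remapped to
#' integers; the per-feature inverted index and per-sample feature
#' membership sets are updated alongside. Zero counts are dropped; samples
#' already present in the context are skipped in full (idempotent ingest —
#' merging would silently double data).
#'
#' @inheritParams map_identifiers
#' @param table A path to a BIOM 1.0 JSON file, a \code{biomformat::biom}
#'   object, or a numeric matrix (features x samples, dimnames required).
#' @return List of class \code{biomdex_load_summary}:
#'   \code{samples_loaded}, \code{samples_skipped}, \code{features_new}.
#' @export
load_table <- function(store, context, table) {
  assert_store(store)
  assert_context(store, context)
  m <- resolve_table(table)
  bad <- grep(KEY_SEP, colnames(m), fixed = TRUE, value = TRUE)
  if (length(bad)) {
    stop("sample id may not contain '", KEY_SEP, "': ", bad[[1L]], call. = FALSE)
  }
  bad <- grep(KEY_SEP, rownames(m), fixed = TRUE, value = TRUE)
  if (length(bad)) {
    stop("feature id may not contain '", KEY_SEP, "': ", bad[[1L]], call. = FALSE)
  }

  samp_reg <- kv_key(context, "registry", "samples")
  feat_reg <- kv_key(context, "registry", "features")
  present <- kv_set_members(store, samp_reg)
  todo <- setdiff(colnames(m), present)
  skipped <- ncol(m) - length(todo)

  features_new <- 0L
  if (length(todo)) {
    mm <- m[, todo, drop = FALSE]
    keep_feat <- rownames(mm)[rowSums(mm > 0) > 0]
    map_identifiers(store, context, keep_feat, "feature")
    map_identifiers(store, context, todo, "sample")
    for (s in todo) {
      nz <- which(mm[, s] > 0)
      fids <- rownames(mm)[nz]
      fints <- map_identifiers(store, context, fids, "feature")
      kv_put(store, kv_key(context, "data", s), encode_pairs(fints, mm[nz, s]))
      kv_set_add(store, kv_key(context, "sample-features", s), fids)
    }
    for (f in keep_feat) {
      hit <- todo[mm[f, ] > 0]
      kv_set_add(store, kv_key(context, "feature", f), hit)
    }
    kv_set_add(store, samp_reg, todo)
    features_new <- kv_set_add(store, feat_reg, keep_feat)
  }
  out <- list(samples_loaded = length(todo), samples_skipped = skipped,
              features_new = features_new)
  class(out) <- "biomdex_load_summary"
  out
}

#' @export
print.biomdex_load_summary <- function(x, ...) {
  cat(sprintf("loaded %d sample(s) (%d skipped as already present), %d new feature(s)\n",
              x$samples_loaded, x$samples_skipped, x$features_new))
  invisible(x)
}

resolve_table <- function(table) {
  if (is.character(table) && length(table) == 1L) {
    m <- read_biom_table(table)
  } else if (methods::is(table, "biom")) {
    m <- as(biomformat::biom_data(table), "matrix")
    storage.mode(m) <- "double"
    validate_feature_matrix(m)
  } else if (is.matrix(table)) {
    m <- table
    storage.mode(m) <- "double"
    validate_feature_matrix(m)
  } else {
    stop("`table` must be a file path, biom object or matrix", call. = FALSE)
  }
  m
}

#' Load per-feature taxonomy into a context
#'
#' Expects two tab-separated columns: feature identifier and a
#' semicolon-delimited lineage (e.g.
#' \code{"k__Bacteria; p__Firmicutes; g__Clostridium"}). Every rank label of
#' the lineage indexes the feature, so a genus label retrieves the same
#' features whether or not the caller knows the full lineage. Labels are
#' stored verbatim after whitespace trimming; matching is exact and
#' case-sensitive. Features not (yet) present in the context are still
#' indexed — they simply retrieve no samples.
#'
#' @inheritParams map_identifiers
#' @param table Path to a 2-column TSV, or a 2-column data.frame
#'   (feature id, lineage).
#' @return Number of features indexed, invisibly.
#' @export
load_taxonomy <- function(store, context, table) {
  assert_store(store)
  assert_context(store, context)
  if (is.character(table) && length(table) == 1L) {
    lines <- readLines(table, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nfld <- lengths(parts)
    if (any(nfld != 2L)) {
      stop("taxonomy line ", which(nfld != 2L)[[1L]],
           " does not have 2 tab-separated columns", call. = FALSE)
    }
    fids <- vapply(parts, `[[`, character(1L), 1L)
    lineages <- vapply(parts, `[[`, character(1L), 2L)
  } else if (is.data.frame(table) && ncol(table) == 2L) {
    fids <- as.character(table[[1L]])
    lineages <- as.character(table[[2L]])
  } else {
    stop("`table` must be a TSV path or 2-column data.frame", call. = FALSE)
  }
  bad <- grep(KEY_SEP, fids, fixed = TRUE, value = TRUE)
  if (length(bad)) {
    stop("feature id may not contain '", KEY_SEP, "': ", bad[[1L]], call. = FALSE)
  }
  for (i in seq_along(fids)) {
    labels <- trimws(strsplit(lineages[[i]], ";", fixed = TRUE)[[1L]])
    labels <- labels[nzchar(labels)]
    for (lab in labels) {
      kv_set_add(store, kv_key(context, "taxon", lab), fids[[i]])
    }
    kv_put(store, kv_key(context, "lineage", fids[[i]]), lineages[[i]])
  }
  kv_set_add(store, kv_key(context, "registry", "taxonomy"), fids)
  kv_put(store, kv_key(context, "flag", "taxonomy"), "1")
  invisible(length(unique(fids)))
}

taxonomy_loaded <- function(store, context) {
  identical(kv_get(store, kv_key(context, "flag", "taxonomy")), "1")
}

#' Lineage string recorded for a feature
#'
#' @inheritParams map_identifiers
#' @param feature Feature identifier.
#' @return Lineage string, or \code{NULL} if none recorded.
#' @export
feature_lineage <- function(store, context, feature) {
  assert_store(store)
  assert_context(store, context)
  kv_get(store, kv_key(context, "lineage", feature))
}
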