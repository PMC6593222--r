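# User-facing search surface. Every constraint evaluates to a sample set;
# combinations are plain set intersections, so constraint order never
# matters. Results are sets of unique sample ids, with per-constraint
# provenance retained for reporting.

new_hitset <- function(samples, context = NULL, provenance = list()) {
  out <- list(context = context,
              samples = sort(unique(as.character(samples)), method = "radix"),
              provenance = provenance)
  class(out) <- "biomdex_hits"
  out
}

#' @export
print.biomdex_hits <- function(x, ...) {
  cat(sprintf("<hits> %d sample(s)%s\n", length(x$samples),
              if (is.null(x$context)) "" else paste0(" in context '", x$context, "'")))
  if (length(x$provenance)) {
    cat("  constraints:", paste(names(x$provenance), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Samples containing given features
#'
#' Looks features up in the context's inverted index. With
#' \code{reduce = "any"} a sample qualifies if it contains at least one of
#' the features (the union); with \code{"all"} it must contain every one
#' (the intersection). Features absent from the context contribute the
#' empty set.
#'
#' @inheritParams map_identifiers
#' @param features Character vector of feature identifiers (exact match —
#'   the index stores exact sequences).
#' @param reduce \code{"any"} (union) or \code{"all"} (intersection).
#' @return A \code{biomdex_hits} object; \code{$samples} holds the ids.
#' @export
search_features <- function(store, context, features, reduce = c("any", "all")) {
  assert_store(store)
  reduce <- match.arg(reduce)
  assert_context(store, context)
  features <- as.character(features)
  if (!length(features)) {
    stop("`features` must name at least one feature", call. = FALSE)
  }
  per_feature <- lapply(features, function(f) {
    kv_set_members(store, kv_key(context, "feature", f))
  })
  names(per_feature) <- features
  samples <- Reduce(if (reduce == "any") union else intersect, per_feature)
  new_hitset(samples, context,
             provenance = list(features = per_feature, reduce = reduce))
}

#' Features carrying a taxon label
#'
#' Exact-label lookup in the context's taxonomy index; compose with
#' \code{\link{search_features}} to reach samples. Rank prefixes are not
#' normalized: \code{"g__Clostridium"} and \code{"Clostridium"} are
#' different labels.
#'
#' @inheritParams map_identifiers
#' @param label Taxon label as it appears in the loaded lineages.
#' @return Character vector of feature identifiers, sorted.
#' @export
search_taxon <- function(store, context, label) {
  assert_store(store)
  assert_context(store, context)
  if (!taxonomy_loaded(store, context)) {
    stop("no taxonomy loaded for context: ", context, call. = FALSE)
  }
  kv_set_members(store, kv_key(context, "taxon", label))
}

#' Select samples by combined constraints
#'
#' The general entry point: any combination of a feature constraint
#' (context-bound), a where clause and a full-text expression (both
#' metadata-bound) is intersected on sample id. If a context is given the
#' result is additionally intersected with the context's
#' samples-represented set, so a metadata-only query can still be confined
#' to one processing protocol.
#'
#' @inheritParams search_features
#' @param context Optional context name; required when \code{features} is
#'   given.
#' @param features Optional feature identifiers.
#' @param where Optional where clause (text or parsed tree), see
#'   \code{\link{evaluate_where}}.
#' @param fulltext Optional full-text expression, see
#'   \code{\link{search_fulltext}}.
#' @param fulltext_variable Optional variable restriction for
#'   \code{fulltext}.
#' @return A \code{biomdex_hits} object.
#' @export
#' @examples
#' \dontrun{
#' select_samples(st, context = "deblur-90nt", features = sotus,
#'                where = "empo_3=='Soil (non-saline)' and ph > 0")
#' }
select_samples <- function(store, context = NULL, features = NULL,
                           reduce = c("any", "all"), where = NULL,
                           fulltext = NULL, fulltext_variable = NULL) {
  assert_store(store)
  reduce <- match.arg(reduce)
  if (is.null(features) && is.null(where) && is.null(fulltext) &&
      is.null(context)) {
    stop("select_samples needs at least one constraint", call. = FALSE)
  }
  if (!is.null(features) && is.null(context)) {
    stop("a feature constraint requires a context", call. = FALSE)
  }
  if (!is.null(context)) assert_context(store, context)

  prov <- list()
  parts <- list()
  if (!is.null(features)) {
    hs <- search_features(store, context, features, reduce)
    parts <- c(parts, list(hs$samples))
    prov$features <- hs$provenance$features
    prov$reduce <- reduce
  }
  if (!is.null(where)) {
    w <- evaluate_where(store, where)
    parts <- c(parts, list(w))
    prov$where <- if (is.character(where)) where else "parsed clause"
  }
  if (!is.null(fulltext)) {
    ft <- search_fulltext(store, fulltext, fulltext_variable)
    parts <- c(parts, list(ft))
    prov$fulltext <- fulltext
  }
  if (!length(parts) && is.null(context)) {
    stop("select_samples needs at least one constraint", call. = FALSE)
  }
  if (!is.null(context)) {
    parts <- c(parts, list(kv_set_members(store, kv_key(context, "registry", "samples"))))
  }
  samples <- Reduce(intersect, parts)
  new_hitset(samples, context, provenance = prov)
}

#' Partition a sample set by membership in a context
#'
#' Supports the cross-protocol workflow: identify samples in one context
#' (say, by the presence of specific Deblur sOTUs) and then see which of
#' them carry data in another (say, closed-reference OTUs) before fetching
#' from it.
#'
#' @inheritParams map_identifiers
#' @param samples Character vector of sample ids (or a \code{biomdex_hits}).
#' @param target_context Context whose membership partitions the set.
#' @return List with \code{present} and \code{absent}, disjoint and jointly
#'   covering the input.
#' @export
partition_by_context <- function(store, samples, target_context) {
  assert_store(store)
  assert_context(store, target_context)
  if (inherits(samples, "biomdex_hits")) samples <- samples$samples
  samples <- sort(unique(as.character(samples)), method = "radix")
  rep_set <- kv_set_members(store, kv_key(target_context, "registry", "samples"))
  list(present = samples[samples %in% rep_set],
       absent = samples[!samples %in% rep_set])
}

#' Tabulate a metadata variable over a sample set
#'
#' Counts raw stored values among the given samples; samples lacking the
#' variable are counted as missing. Counts plus the missing count always
#' sum to the number of samples, which makes this a quick sanity check
#' before fetching a large result.
#'
#' @inheritParams partition_by_context
#' @param variable Variable name (matched exactly).
#' @return List of class \code{biomdex_variable_summary}: \code{variable},
#'   \code{counts} (named integer vector, values sorted), \code{n_missing},
#'   \code{n_samples}.
#' @export
summarize_variable <- function(store, samples, variable) {
  assert_store(store)
  if (inherits(samples, "biomdex_hits")) samples <- samples$samples
  samples <- unique(as.character(samples))
  vals <- vapply(samples, function(s) {
    kv_record_get(store, md_record_key(s), variable)[[1L]]
  }, character(1L))
  present <- vals[!is.na(vals)]
  counts <- if (length(present)) {
    tb <- table(present)
    setNames(as.integer(tb), names(tb))
  } else {
    setNames(integer(), character())
  }
  counts <- counts[sort(names(counts), method = "radix")]
  out <- list(variable = variable, counts = counts,
              n_missing = sum(is.na(vals)), n_samples = length(samples))
  class(out) <- "biomdex_variable_summary"
  out
}

#' @export
print.biomdex_variable_summary <- function(x, ...) {
  cat(sprintf("<summary> %s over %d sample(s)\n", x$variable, x$n_samples))
  for (v in names(x$counts)) cat(sprintf("  %-30s %d\n", v, x$counts[[v]]))
  if (x$n_missing) cat(sprintf("  %-30s %d\n", "<missing>", x$n_missing))
  invisible(x)
}
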