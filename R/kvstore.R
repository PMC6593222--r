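KEY_SEP <- ":"
SNAPSHOT_MAGIC <- "biomdex-snapshot"
SNAPSHOT_VERSION <- 1L

#' Create an empty in-memory key-value store
#'
#' The store is the substrate every index in biomdex is built on. It holds
#' three kinds of state under composite string keys of the form
#' \code{namespace:category:item}: plain string values, string sets with
#' set algebra, and field/value records. It is an in-process reference
#' implementation of a backend contract deliberately small enough to sit on
#' any key-value engine; persistence is an explicit whole-store snapshot
#' (\code{\link{store_save}} / \code{\link{store_load}}).
#'
#' Environments give the store reference semantics: all loading and indexing
#' functions mutate the store they are handed, as a database handle would.
#'
#' @return An object of class \code{biomdex_store}.
#' @seealso \code{\link{kv_put}}, \code{\link{kv_set_add}},
#'   \code{\link{kv_record_put}}, \code{\link{store_save}}
#' @export
#' @examples
#' st <- store_create()
#' kv_put(st, kv_key("ctx", "data", "S1"), "payload")
#' kv_get(st, kv_key("ctx", "data", "S1"))
store_create <- function() {
  st <- new.env(parent = emptyenv())
  st$values  <- new.env(parent = emptyenv(), hash = TRUE)
  st$sets    <- new.env(parent = emptyenv(), hash = TRUE)
  st$records <- new.env(parent = emptyenv(), hash = TRUE)
  class(st) <- "biomdex_store"
  st
}

#' @export
print.biomdex_store <- function(x, ...) {
  cat("<biomdex_store>\n")
  cat("  values: ", length(ls(x$values, sorted = FALSE)), "\n", sep = "")
  cat("  sets:   ", length(ls(x$sets, sorted = FALSE)), "\n", sep = "")
  cat("  records:", length(ls(x$records, sorted = FALSE)), "\n", sep = "")
  ctxs <- tryCatch(list_contexts(x), error = function(e) character())
  if (length(ctxs)) cat("  contexts:", paste(ctxs, collapse = ", "), "\n")
  invisible(x)
}

assert_store <- function(store) {
  if (!inherits(store, "biomdex_store")) {
    stop("`store` must be a biomdex_store (see store_create())", call. = FALSE)
  }
}

#' Render a composite store key
#'
#' Keys are \code{namespace:category:item}. Components are compared bytewise
#' and may not contain the separator \code{":"}, which keeps the rendering
#' injective; a violation is rejected naming the offending component.
#'
#' @param namespace Short label, e.g. a context name or \code{"metadata"}.
#' @param category Label such as \code{"data"}, \code{"feature"}, \code{"stem"}.
#' @param item Identifier string.
#' @return A single key string.
#' @export
kv_key <- function(namespace, category, item) {
  for (nm in c("namespace", "category", "item")) {
    v <- switch(nm, namespace = namespace, category = category, item = item)
    if (length(v) != 1L || is.na(v) || !nzchar(v)) {
      stop("key ", nm, " must be a single non-empty string", call. = FALSE)
    }
    if (grepl(KEY_SEP, v, fixed = TRUE)) {
      stop("key ", nm, " may not contain '", KEY_SEP, "': ", v, call. = FALSE)
    }
  }
  paste(namespace, category, item, sep = KEY_SEP)
}

# keys built by kv_key are always valid; raw strings passed by callers are
# re-checked so a bad component cannot slip into the store
assert_key <- function(key) {
  if (length(key) != 1L || is.na(key) || !is.character(key)) {
    stop("key must be a single string", call. = FALSE)
  }
  parts <- strsplit(key, KEY_SEP, fixed = TRUE)[[1L]]
  if (length(parts) != 3L || !all(nzchar(parts))) {
    stop("malformed key (want namespace:category:item): ", key, call. = FALSE)
  }
  key
}

#' Low-level key-value operations
#'
#' The backend contract: string put/get, set add/members/combine, record
#' put/get. All collection-valued returns are in bytewise lexicographic
#' order so that behaviour is deterministic across platforms.
#'
#' @param store A \code{biomdex_store}.
#' @param key,keys Key string(s) built with \code{\link{kv_key}}.
#' @param value Single string to store.
#' @name kvstore-ops
NULL

#' @rdname kvstore-ops
#' @return \code{kv_put} invisibly returns the store; \code{kv_get} the
#'   stored string or \code{NULL} when absent.
#' @export
kv_put <- function(store, key, value) {
  assert_store(store); assert_key(key)
  if (length(value) != 1L || is.na(value)) {
    stop("value must be a single non-NA string", call. = FALSE)
  }
  assign(key, as.character(value), envir = store$values)
  invisible(store)
}

#' @rdname kvstore-ops
#' @export
kv_get <- function(store, key) {
  assert_store(store); assert_key(key)
  if (!exists(key, envir = store$values, inherits = FALSE)) return(NULL)
  get(key, envir = store$values, inherits = FALSE)
}

#' @rdname kvstore-ops
#' @param members Character vector of members to add (duplicates collapse).
#' @return \code{kv_set_add} returns the number of members newly added.
#' @export
kv_set_add <- function(store, key, members) {
  assert_store(store); assert_key(key)
  members <- unique(as.character(members))
  if (anyNA(members)) stop("set members may not be NA", call. = FALSE)
  if (length(members) == 0L) return(0L)
  cur <- if (exists(key, envir = store$sets, inherits = FALSE)) {
    get(key, envir = store$sets, inherits = FALSE)
  } else character()
  new <- setdiff(members, cur)
  if (length(new)) {
    assign(key, sort(c(cur, new), method = "radix"), envir = store$sets)
  }
  length(new)
}

#' @rdname kvstore-ops
#' @return \code{kv_set_members} returns the member set, sorted; empty
#'   character vector for an absent key.
#' @export
kv_set_members <- function(store, key) {
  assert_store(store); assert_key(key)
  if (!exists(key, envir = store$sets, inherits = FALSE)) return(character())
  get(key, envir = store$sets, inherits = FALSE)
}

# internal: needed so re-indexing can retract stale memberships
kv_set_remove <- function(store, key, members) {
  assert_store(store); assert_key(key)
  if (!exists(key, envir = store$sets, inherits = FALSE)) return(0L)
  cur <- get(key, envir = store$sets, inherits = FALSE)
  keep <- setdiff(cur, members)
  n_removed <- length(cur) - length(keep)
  if (length(keep)) {
    assign(key, keep, envir = store$sets)
  } else {
    rm(list = key, envir = store$sets)
  }
  n_removed
}

#' @rdname kvstore-ops
#' @param mode One of \code{"intersection"}, \code{"union"},
#'   \code{"difference"}. Difference is a left fold: the first key's set
#'   minus the members of all the rest.
#' @return \code{kv_set_combine} returns the combined set, sorted.
#' @export
kv_set_combine <- function(store, keys,
                           mode = c("intersection", "union", "difference")) {
  assert_store(store)
  mode <- match.arg(mode)
  if (length(keys) < 1L) stop("kv_set_combine needs at least one key", call. = FALSE)
  sets <- lapply(keys, function(k) kv_set_members(store, k))
  acc <- sets[[1L]]
  if (length(sets) > 1L) {
    for (s in sets[-1L]) {
      acc <- switch(mode,
        intersection = intersect(acc, s),
        union        = union(acc, s),
        difference   = setdiff(acc, s))
    }
  }
  sort(unique(acc), method = "radix")
}

#' @rdname kvstore-ops
#' @param fields For \code{kv_record_put}, a named character vector of
#'   field/value pairs to merge into the record; for \code{kv_record_get},
#'   the field names to fetch.
#' @return \code{kv_record_put} invisibly returns the store.
#' @export
kv_record_put <- function(store, key, fields) {
  assert_store(store); assert_key(key)
  fields <- unlist(fields)
  if (length(fields) == 0L) return(invisible(store))
  nm <- names(fields)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("record fields must have unique non-empty names", call. = FALSE)
  }
  cur <- if (exists(key, envir = store$records, inherits = FALSE)) {
    get(key, envir = store$records, inherits = FALSE)
  } else character()
  cur[nm] <- as.character(fields)
  assign(key, cur, envir = store$records)
  invisible(store)
}

#' @rdname kvstore-ops
#' @return \code{kv_record_get} returns a named character vector over the
#'   requested fields, \code{NA} marking each absent field.
#' @export
kv_record_get <- function(store, key, fields) {
  assert_store(store); assert_key(key)
  fields <- as.character(fields)
  out <- rep(NA_character_, length(fields))
  names(out) <- fields
  if (exists(key, envir = store$records, inherits = FALSE)) {
    cur <- get(key, envir = store$records, inherits = FALSE)
    hit <- fields %in% names(cur)
    out[hit] <- cur[fields[hit]]
  }
  out
}

# internal: field names of one record key, sorted
kv_record_fields <- function(store, key) {
  assert_store(store); assert_key(key)
  if (!exists(key, envir = store$records, inherits = FALSE)) return(character())
  sort(names(get(key, envir = store$records, inherits = FALSE)), method = "radix")
}

#' Snapshot a store to disk and restore it
#'
#' The snapshot is a single self-describing JSON file with a magic header
#' and format version; it round-trips the full store state so every query
#' answer is preserved bit-for-bit across a save/load cycle.
#'
#' @param store A \code{biomdex_store}.
#' @param path File path for the snapshot.
#' @return \code{store_save} invisibly returns \code{path};
#'   \code{store_load} returns a fresh \code{biomdex_store}.
#' @export
store_save <- function(store, path) {
  assert_store(store)
  dump_env <- function(e) {
    keys <- sort(ls(e, sorted = FALSE), method = "radix")
    setNames(lapply(keys, function(k) {
      v <- get(k, envir = e, inherits = FALSE)
      if (!is.null(names(v))) as.list(v) else as.list(unname(v))
    }), keys)
  }
  payload <- list(
    magic = SNAPSHOT_MAGIC,
    version = SNAPSHOT_VERSION,
    values = dump_env(store$values),
    sets = dump_env(store$sets),
    records = dump_env(store$records)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname store_save
#' @export
store_load <- function(path) {
  if (!file.exists(path)) stop("snapshot not found: ", path, call. = FALSE)
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                                simplifyVector = FALSE)
  if (!identical(payload$magic, SNAPSHOT_MAGIC)) {
    stop("not a biomdex snapshot (bad magic header): ", path, call. = FALSE)
  }
  if (!identical(as.integer(payload$version), SNAPSHOT_VERSION)) {
    stop("unsupported snapshot version: ", payload$version, call. = FALSE)
  }
  st <- store_create()
  for (k in names(payload$values)) {
    assign(k, as.character(payload$values[[k]][[1L]]), envir = st$values)
  }
  for (k in names(payload$sets)) {
    assign(k, sort(unlist(payload$sets[[k]], use.names = FALSE),
                   method = "radix"), envir = st$sets)
  }
  for (k in names(payload$records)) {
    rec <- payload$records[[k]]
    assign(k, setNames(as.character(unlist(rec, use.names = FALSE)),
                       names(rec)), envir = st$records)
  }
  st
}
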