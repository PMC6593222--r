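# Sample metadata: ingest, Porter-stem full-text index, where-clauses.
#
# Metadata lives in a single shared namespace ("metadata"): queries over it
# are context-free and intersect with context-bound constraints on sample id.
# Values are kept as raw strings; typing happens per comparison at query
# time, because deposited metadata columns routinely mix numbers, text and
# missing markers.

# QIIME-style missing markers, compared case-insensitively; values with a
# "missing:" prefix (e.g. "Missing: Not provided") are also dropped.
MISSING_MARKERS <- c("", "na", "n/a", "nan", "none", "unknown",
                     "not applicable")

is_missing_value <- function(x) {
  lx <- tolower(trimws(x))
  lx %in% MISSING_MARKERS | startsWith(lx, "missing:")
}

md_samples_key <- function() kv_key("metadata", "registry", "samples")
md_vars_key <- function() kv_key("metadata", "registry", "variables")
md_record_key <- function(sample) kv_key("metadata", "sample", sample)
md_stem_key <- function(stem) kv_key("metadata", "stem", stem)
md_varstem_key <- function(variable, stem) {
  kv_key("metadata", "varstem", paste(variable, stem, sep = "\t"))
}

#' Tokenize and stem a metadata value
#'
#' Lowercases, splits on runs of non-alphanumeric characters, drops tokens
#' shorter than 2 characters and purely numeric tokens, Porter-stems each
#' survivor, and deduplicates preserving first-occurrence order. The
#' minimum length of 2 keeps domain terms like \code{"ph"} searchable while
#' bare numerals never pollute the index.
#'
#' @param value Character vector of raw values.
#' @return Character vector of stems (for vector input, stems of all values
#'   concatenated, deduplicated in order).
#' @export
#' @examples
#' stem_text("Soil (non-saline)")   # "soil" "non" "salin"
#' stem_text("pH 7")                # "ph"
stem_text <- function(value) {
  value <- as.character(value)
  value <- value[!is.na(value)]
  if (!length(value)) return(character())
  tokens <- unlist(strsplit(tolower(value), "[^a-z0-9]+"), use.names = FALSE)
  tokens <- tokens[nzchar(tokens)]
  tokens <- tokens[nchar(tokens) >= 2L & !grepl("^[0-9]+$", tokens)]
  if (!length(tokens)) return(character())
  unique(porter_stem(tokens))
}

#' Ingest a sample-metadata table
#'
#' The table is QIIME-mapping-file style: tab-delimited, header row, first
#' column the sample identifier (any column name, \code{"#SampleID"}
#' included), remaining columns variables; values are taken verbatim.
#' Missing markers are dropped at ingest, so a stored record contains only
#' real values. Every kept categorical value is stemmed into the full-text
#' index, globally and per variable. Re-ingesting a sample first retracts
#' its previous stem memberships, so the index always reflects exactly the
#' stored values.
#'
#' @inheritParams create_context
#' @param table Path to a metadata TSV, or a data.frame whose first column
#'   is the sample identifier.
#' @return List of class \code{biomdex_ingest_summary}: \code{samples},
#'   \code{variables}, \code{values_dropped_missing}.
#' @export
ingest_metadata <- function(store, table) {
  assert_store(store)
  if (is.character(table) && length(table) == 1L) {
    df <- read_metadata_tsv(table)
  } else if (is.data.frame(table)) {
    df <- table
    df[] <- lapply(df, as.character)
  } else {
    stop("`table` must be a TSV path or data.frame", call. = FALSE)
  }
  if (ncol(df) < 1L) stop("metadata table has no columns", call. = FALSE)
  samples <- as.character(df[[1L]])
  if (anyDuplicated(samples)) {
    stop("duplicate sample id in metadata: ",
         samples[duplicated(samples)][[1L]], call. = FALSE)
  }
  bad <- grep(KEY_SEP, samples, fixed = TRUE, value = TRUE)
  if (length(bad)) {
    stop("sample id may not contain '", KEY_SEP, "': ", bad[[1L]], call. = FALSE)
  }
  vars <- colnames(df)[-1L]
  bad <- grep(KEY_SEP, vars, fixed = TRUE, value = TRUE)
  if (length(bad)) {
    stop("variable name may not contain '", KEY_SEP, "': ", bad[[1L]],
         call. = FALSE)
  }

  dropped <- 0L
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    vals <- vapply(vars, function(v) df[[v]][[i]], character(1L))
    miss <- is.na(vals) | is_missing_value(vals)
    dropped <- dropped + sum(miss)
    retract_sample_stems(store, s)
    keep <- vals[!miss]
    if (length(keep)) {
      kv_record_put(store, md_record_key(s), keep)
      for (v in names(keep)) {
        for (stem in stem_text(keep[[v]])) {
          kv_set_add(store, md_stem_key(stem), s)
          kv_set_add(store, md_varstem_key(v, stem), s)
        }
      }
    }
    kv_set_add(store, md_samples_key(), s)
    kv_set_add(store, md_vars_key(), names(keep))
  }
  out <- list(samples = length(samples), variables = length(vars),
              values_dropped_missing = dropped)
  class(out) <- "biomdex_ingest_summary"
  out
}

#' @export
print.biomdex_ingest_summary <- function(x, ...) {
  cat(sprintf("ingested %d sample(s) x %d variable(s); %d missing value(s) dropped\n",
              x$samples, x$variables, x$values_dropped_missing))
  invisible(x)
}

# drop a sample from every stem set derived from its currently stored values
retract_sample_stems <- function(store, sample) {
  rec_key <- md_record_key(sample)
  flds <- kv_record_fields(store, rec_key)
  if (!length(flds)) return(invisible())
  old <- kv_record_get(store, rec_key, flds)
  for (v in flds) {
    for (stem in stem_text(old[[v]])) {
      kv_set_remove(store, md_stem_key(stem), sample)
      kv_set_remove(store, md_varstem_key(v, stem), sample)
    }
  }
  rm(list = rec_key, envir = store$records)
  invisible()
}

# strict TSV reader: verbatim values, ragged rows rejected with line number
read_metadata_tsv <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines)) stop("metadata file is empty: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  # a trailing empty field is dropped by strsplit; pad to header width
  width <- length(parts[[1L]])
  nfld <- lengths(parts)
  short_by_one <- which(nfld == width - 1L & endsWith(lines, "\t"))
  for (i in short_by_one) parts[[i]] <- c(parts[[i]], "")
  nfld <- lengths(parts)
  bad <- which(nfld != width)
  if (length(bad)) {
    stop("metadata line ", bad[[1L]], " has ", nfld[bad[[1L]]],
         " fields, expected ", width, call. = FALSE)
  }
  header <- parts[[1L]]
  body <- parts[-1L]
  df <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  colnames(df) <- header
  df
}

#' Retrieve stored metadata values for one sample
#'
#' @inheritParams create_context
#' @param sample Sample identifier.
#' @param variables Variables to fetch; default all observed variables.
#' @return Named character vector; \code{NA} marks a variable with no
#'   stored (non-missing) value for the sample.
#' @export
get_sample_metadata <- function(store, sample, variables = NULL) {
  assert_store(store)
  if (is.null(variables)) variables <- kv_set_members(store, md_vars_key())
  if (!length(variables)) return(setNames(character(), character()))
  kv_record_get(store, md_record_key(sample), variables)
}

## ---- full-text search -----------------------------------------------------

# grammar:  expr   := term (('|' | '-') term)*
#           term   := factor ('&' factor)*
#           factor := WORD | "phrase" | '(' expr ')'
# '&' binds tighter than '|' and '-'; '-' is a left-fold difference.
ft_tokenize <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("&", "|", "(", ")") || ch == "-" || ch == "−") {
      op <- if (ch == "−") "-" else ch
      tokens[[length(tokens) + 1L]] <- list(type = op, pos = i)
      i <- i + 1L
    } else if (ch %in% c("\"", "'")) {
      close <- regexpr(ch, substr(text, i + 1L, n), fixed = TRUE)
      if (close < 0L) {
        stop("full-text syntax error at position ", i,
             ": unterminated quote", call. = FALSE)
      }
      tokens[[length(tokens) + 1L]] <-
        list(type = "phrase", value = substr(text, i + 1L, i + close - 1L), pos = i)
      i <- i + close + 1L
    } else {
      mt <- regexpr("^[^\\s&|()\"'−-]+", substr(text, i, n), perl = TRUE)
      len <- attr(mt, "match.length")
      if (len < 1L) {
        stop("full-text syntax error at position ", i, ": unexpected '",
             ch, "'", call. = FALSE)
      }
      tokens[[length(tokens) + 1L]] <-
        list(type = "word", value = substr(text, i, i + len - 1L), pos = i)
      i <- i + len
    }
  }
  tokens
}

ft_parse <- function(text) {
  tokens <- ft_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tk <- tokens[[pos]]; pos <<- pos + 1L; tk }
  expect_more <- function(what) {
    tk <- peek()
    if (is.null(tk)) {
      stop("full-text syntax error at position ", nchar(text) + 1L,
           ": expected ", what, call. = FALSE)
    }
    tk
  }
  parse_factor <- function() {
    tk <- expect_more("a term")
    if (tk$type == "(") {
      advance()
      node <- parse_expr()
      tk2 <- expect_more("')'")
      if (tk2$type != ")") {
        stop("full-text syntax error at position ", tk2$pos,
             ": expected ')'", call. = FALSE)
      }
      advance()
      return(node)
    }
    if (tk$type %in% c("word", "phrase")) {
      advance()
      return(list(type = tk$type, value = tk$value))
    }
    stop("full-text syntax error at position ", tk$pos,
         ": unexpected '", tk$type, "'", call. = FALSE)
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.null(peek()) && peek()$type == "&") {
      advance()
      node <- list(type = "and", lhs = node, rhs = parse_factor())
    }
    node
  }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.null(peek()) && peek()$type %in% c("|", "-")) {
      op <- advance()$type
      node <- list(type = if (op == "|") "or" else "diff",
                   lhs = node, rhs = parse_term())
    }
    node
  }
  node <- parse_expr()
  tk <- peek()
  if (!is.null(tk)) {
    stop("full-text syntax error at position ", tk$pos,
         ": unexpected trailing input", call. = FALSE)
  }
  node
}

ft_lookup_stem <- function(store, stem, variable) {
  if (is.null(variable)) {
    kv_set_members(store, md_stem_key(stem))
  } else {
    kv_set_members(store, md_varstem_key(variable, stem))
  }
}

ft_eval <- function(store, node, variable) {
  switch(node$type,
    word = ,
    phrase = {
      stems <- stem_text(node$value)
      if (!length(stems)) return(character())
      sets <- lapply(stems, ft_lookup_stem, store = store, variable = variable)
      Reduce(intersect, sets)
    },
    and = intersect(ft_eval(store, node$lhs, variable),
                    ft_eval(store, node$rhs, variable)),
    or = union(ft_eval(store, node$lhs, variable),
               ft_eval(store, node$rhs, variable)),
    diff = setdiff(ft_eval(store, node$lhs, variable),
                   ft_eval(store, node$rhs, variable)),
    stop("internal: unknown full-text node ", node$type)
  )
}

#' Full-text search over the stemmed metadata index
#'
#' Terms are words (stemmed before lookup, so \code{"antibiotics"} and
#' \code{"antibiotic"} hit the same key) or quoted phrases (every stem of
#' the phrase intersected). Operators: \code{&} intersection, \code{|}
#' union, \code{-} difference (left fold), parentheses; \code{&} binds
#' tightest. Unknown stems evaluate to the empty set.
#'
#' @inheritParams create_context
#' @param expression Search expression, e.g.
#'   \code{"soil & (saline | antibiotics)"}.
#' @param variable If given, restrict lookups to stems observed in that
#'   variable's values only.
#' @return Character vector of matching sample ids, sorted.
#' @export
search_fulltext <- function(store, expression, variable = NULL) {
  assert_store(store)
  if (length(expression) != 1L || !nzchar(trimws(expression))) {
    stop("full-text expression must be a single non-empty string", call. = FALSE)
  }
  node <- ft_parse(expression)
  sort(unique(ft_eval(store, node, variable)), method = "radix")
}

## ---- where clauses --------------------------------------------------------

WHERE_OPS <- c("==", "!=", "<=", ">=", "<", ">", "in", "notin")

wc_tokenize <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value = NULL, pos = i) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    two <- substr(text, i, i + 1L)
    if (two %in% c("==", "!=", "<=", ">=")) { push("op", two); i <- i + 2L; next }
    if (ch %in% c("<", ">")) { push("op", ch); i <- i + 1L; next }
    if (ch %in% c("(", ")", "{", "}", ",")) { push(ch); i <- i + 1L; next }
    if (ch %in% c("'", "\"")) {
      close <- regexpr(ch, substr(text, i + 1L, n), fixed = TRUE)
      if (close < 0L) {
        stop("where-clause syntax error at position ", i,
             ": unterminated string", call. = FALSE)
      }
      push("string", substr(text, i + 1L, i + close - 1L))
      i <- i + close + 1L
      next
    }
    mt <- regexpr("^[A-Za-z0-9_.+-]+", substr(text, i, n), perl = TRUE)
    len <- attr(mt, "match.length")
    if (len < 1L) {
      stop("where-clause syntax error at position ", i, ": unexpected '",
           ch, "'", call. = FALSE)
    }
    word <- substr(text, i, i + len - 1L)
    lw <- tolower(word)
    if (lw %in% c("and", "or")) {
      push("bool", lw)
    } else if (lw == "in") {
      push("op", "in")
    } else if (lw == "notin") {
      push("op", "notin")
    } else if (lw == "not") {
      push("not", "not")
    } else if (grepl("^[+-]?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", word)) {
      push("number", word)
    } else {
      push("ident", word)
    }
    i <- i + len
  }
  tokens
}

#' Parse a where clause over metadata variables
#'
#' Grammar: single comparisons \code{variable op literal} joined by
#' \code{and} / \code{or} with parentheses. Operators: \code{==}, \code{!=},
#' \code{<}, \code{<=}, \code{>}, \code{>=}, \code{in}, \code{notin} (also
#' written \code{not in}); literals are numbers, quoted strings, or for the
#' membership operators a parenthesized or braced comma-separated list.
#' \code{and} binds tighter than \code{or}.
#'
#' @param text Clause text, e.g.
#'   \code{"empo_3=='Soil (non-saline)' and ph > 0"}.
#' @return An expression tree of class \code{biomdex_where}, for
#'   \code{\link{evaluate_where}}.
#' @export
parse_where <- function(text) {
  if (length(text) != 1L || !nzchar(trimws(text))) {
    stop("where clause must be a single non-empty string", call. = FALSE)
  }
  tokens <- wc_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tk <- tokens[[pos]]; pos <<- pos + 1L; tk }
  fail <- function(tk, what) {
    p <- if (is.null(tk)) nchar(text) + 1L else tk$pos
    stop("where-clause syntax error at position ", p, ": expected ", what,
         call. = FALSE)
  }
  parse_literal_list <- function() {
    tk <- peek()
    if (is.null(tk) || !tk$type %in% c("(", "{")) fail(tk, "a literal list")
    closer <- if (tk$type == "(") ")" else "}"
    advance()
    vals <- character()
    num <- logical()
    repeat {
      tk <- peek()
      if (is.null(tk)) fail(tk, paste0("'", closer, "'"))
      if (tk$type == closer) { advance(); break }
      if (tk$type == ",") { advance(); next }
      if (!tk$type %in% c("string", "number")) fail(tk, "a literal")
      vals <- c(vals, tk$value)
      num <- c(num, tk$type == "number")
      advance()
    }
    list(values = vals, numeric = num)
  }
  parse_comparison <- function() {
    tk <- peek()
    if (is.null(tk)) fail(tk, "a comparison")
    if (tk$type == "(") {
      advance()
      node <- parse_or()
      tk2 <- peek()
      if (is.null(tk2) || tk2$type != ")") fail(tk2, "')'")
      advance()
      return(node)
    }
    if (!tk$type %in% c("ident", "number")) fail(tk, "a variable name")
    var <- advance()$value
    tk <- peek()
    op <- NULL
    if (!is.null(tk) && tk$type == "not") {
      advance()
      tk <- peek()
      if (is.null(tk) || !identical(tk$value, "in")) fail(tk, "'in' after 'not'")
      advance()
      op <- "notin"
    } else {
      if (is.null(tk) || tk$type != "op") fail(tk, "a comparison operator")
      op <- advance()$value
    }
    if (op %in% c("in", "notin")) {
      lit <- parse_literal_list()
      node <- list(type = "cmp", variable = var, op = op,
                   value = lit$values, value_numeric = lit$numeric)
    } else {
      tk <- peek()
      if (is.null(tk) || !tk$type %in% c("string", "number", "ident")) {
        fail(tk, "a literal")
      }
      advance()
      node <- list(type = "cmp", variable = var, op = op,
                   value = tk$value, value_numeric = tk$type == "number")
    }
    node
  }
  parse_and <- function() {
    node <- parse_comparison()
    repeat {
      tk <- peek()
      if (is.null(tk) || tk$type != "bool" || tk$value != "and") break
      advance()
      node <- list(type = "and", lhs = node, rhs = parse_comparison())
    }
    node
  }
  parse_or <- function() {
    node <- parse_and()
    repeat {
      tk <- peek()
      if (is.null(tk) || tk$type != "bool" || tk$value != "or") break
      advance()
      node <- list(type = "or", lhs = node, rhs = parse_and())
    }
    node
  }
  node <- parse_or()
  tk <- peek()
  if (!is.null(tk)) {
    stop("where-clause syntax error at position ", tk$pos,
         ": unexpected trailing input", call. = FALSE)
  }
  class(node) <- c("biomdex_where", "list")
  node
}

# equality under query-time typing: numeric when both sides coerce, else
# exact string
wc_equal <- function(stored, literal, literal_numeric) {
  sn <- suppressWarnings(as.numeric(stored))
  ln <- suppressWarnings(as.numeric(literal))
  if (literal_numeric && !is.na(sn) && !is.na(ln)) sn == ln else stored == literal
}

wc_eval_cmp <- function(store, node, universe) {
  vals <- vapply(universe, function(s) {
    kv_record_get(store, md_record_key(s), node$variable)[[1L]]
  }, character(1L))
  present <- !is.na(vals)
  keep <- logical(length(universe))
  if (node$op %in% c("<", "<=", ">", ">=")) {
    num <- suppressWarnings(as.numeric(vals))
    lit <- suppressWarnings(as.numeric(node$value))
    if (is.na(lit)) {
      stop("numeric comparison against non-numeric literal: ",
           node$value, call. = FALSE)
    }
    ok <- present & !is.na(num)
    keep[ok] <- switch(node$op,
      "<"  = num[ok] <  lit,
      "<=" = num[ok] <= lit,
      ">"  = num[ok] >  lit,
      ">=" = num[ok] >= lit)
  } else if (node$op %in% c("==", "!=")) {
    for (i in which(present)) {
      eq <- wc_equal(vals[[i]], node$value, node$value_numeric)
      keep[i] <- if (node$op == "==") eq else !eq
    }
  } else if (node$op %in% c("in", "notin")) {
    for (i in which(present)) {
      hit <- any(vapply(seq_along(node$value), function(j) {
        wc_equal(vals[[i]], node$value[[j]], node$value_numeric[[j]])
      }, logical(1L)))
      keep[i] <- if (node$op == "in") hit else !hit
    }
  } else {
    stop("unknown where-clause operator: ", node$op, call. = FALSE)
  }
  universe[keep]
}

#' Evaluate a where clause to a sample set
#'
#' Typing happens per comparison: ordering operators coerce the stored
#' string to a number and exclude the sample when the value is missing or
#' non-coercible (so \code{ph > 0} doubles as a has-valid-pH filter);
#' \code{==} / \code{!=} / \code{in} / \code{notin} compare as exact strings
#' unless both sides coerce numerically, in which case numeric equality is
#' used. Samples with no stored value for the variable are always excluded.
#'
#' @inheritParams create_context
#' @param clause Clause text or a parsed \code{biomdex_where} tree.
#' @param universe Sample ids to evaluate over; default all samples with
#'   metadata.
#' @return Character vector of matching sample ids, sorted.
#' @export
#' @examples
#' st <- store_create()
#' ingest_metadata(st, data.frame(sample = c("S1", "S2", "S3"),
#'                                ph = c("6.5", "NA", "8.1")))
#' evaluate_where(st, "ph < 7")
evaluate_where <- function(store, clause, universe = NULL) {
  assert_store(store)
  if (is.character(clause)) clause <- parse_where(clause)
  if (!inherits(clause, "biomdex_where") && !is.list(clause)) {
    stop("`clause` must be a string or parsed where clause", call. = FALSE)
  }
  if (is.null(universe)) universe <- kv_set_members(store, md_samples_key())
  universe <- sort(unique(as.character(universe)), method = "radix")
  eval_node <- function(node, uni) {
    switch(node$type,
      cmp = wc_eval_cmp(store, node, uni),
      and = { l <- eval_node(node$lhs, uni); eval_node(node$rhs, l) },
      or = sort(union(eval_node(node$lhs, uni), eval_node(node$rhs, uni)),
                method = "radix"),
      stop("malformed where clause node: ", node$type, call. = FALSE))
  }
  eval_node(clause, universe)
}
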