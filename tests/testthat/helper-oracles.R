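# Brute-force oracles: every one recomputes a query answer by direct scan
# over the raw inputs (dense matrix / metadata data.frame), independent of
# the store's indices.

sorted <- function(x) sort(unique(as.character(x)), method = "radix")

# canonical byte serialization of a store, for state-unchanged assertions
store_snapshot_bytes <- function(st) {
  p <- tempfile(fileext = ".json")
  on.exit(unlink(p))
  store_save(st, p)
  readBin(p, "raw", file.size(p))
}

oracle_feature_samples <- function(m, feature) {
  if (!feature %in% rownames(m)) return(character())
  sorted(colnames(m)[m[feature, ] > 0])
}

oracle_search_features <- function(m, features, reduce) {
  sets <- lapply(features, oracle_feature_samples, m = m)
  sorted(Reduce(if (reduce == "any") union else intersect, sets))
}

oracle_inverted_index <- function(m) {
  feats <- rownames(m)[rowSums(m > 0) > 0]
  setNames(lapply(feats, oracle_feature_samples, m = m), feats)
}

oracle_taxon_features <- function(tax_df, label) {
  hit <- vapply(seq_len(nrow(tax_df)), function(i) {
    labels <- trimws(strsplit(tax_df[[2L]][[i]], ";", fixed = TRUE)[[1L]])
    label %in% labels
  }, logical(1L))
  sorted(tax_df[[1L]][hit])
}

# per-sample stem sets recomputed from the raw metadata values
oracle_stem_sets <- function(md_df, variable = NULL) {
  vars <- setdiff(colnames(md_df), colnames(md_df)[1L])
  if (!is.null(variable)) vars <- intersect(vars, variable)
  out <- list()
  for (i in seq_len(nrow(md_df))) {
    s <- md_df[[1L]][[i]]
    stems <- character()
    for (v in vars) {
      val <- md_df[[v]][[i]]
      if (!is.na(val) && !biomdex:::is_missing_value(val)) {
        stems <- c(stems, stem_text(val))
      }
    }
    out[[s]] <- unique(stems)
  }
  out
}

oracle_fulltext <- function(md_df, expression, variable = NULL) {
  node <- biomdex:::ft_parse(expression)
  stem_sets <- oracle_stem_sets(md_df, variable)
  samples_with <- function(stem) {
    sorted(names(stem_sets)[vapply(stem_sets, function(ss) stem %in% ss,
                                   logical(1L))])
  }
  eval_node <- function(n) {
    switch(n$type,
      word = ,
      phrase = {
        stems <- stem_text(n$value)
        if (!length(stems)) return(character())
        Reduce(intersect, lapply(stems, samples_with))
      },
      and = intersect(eval_node(n$lhs), eval_node(n$rhs)),
      or = union(eval_node(n$lhs), eval_node(n$rhs)),
      diff = setdiff(eval_node(n$lhs), eval_node(n$rhs)))
  }
  sorted(eval_node(node))
}

# row-scan evaluation of a where clause over the raw metadata table, with
# its own coercion logic
oracle_where <- function(md_df, clause, universe = NULL) {
  node <- if (is.character(clause)) parse_where(clause) else clause
  samples <- md_df[[1L]]
  if (is.null(universe)) universe <- samples
  value_of <- function(s, var) {
    i <- match(s, samples)
    if (is.na(i) || !var %in% colnames(md_df)) return(NA_character_)
    v <- md_df[[var]][[i]]
    if (is.na(v) || biomdex:::is_missing_value(v)) NA_character_ else v
  }
  cmp_one <- function(s, n) {
    v <- value_of(s, n$variable)
    if (is.na(v)) return(FALSE)
    if (n$op %in% c("<", "<=", ">", ">=")) {
      num <- suppressWarnings(as.numeric(v))
      lit <- as.numeric(n$value)
      if (is.na(num)) return(FALSE)
      return(switch(n$op, "<" = num < lit, "<=" = num <= lit,
                    ">" = num > lit, ">=" = num >= lit))
    }
    eq_one <- function(lit, lit_num) {
      nv <- suppressWarnings(as.numeric(v))
      nl <- suppressWarnings(as.numeric(lit))
      if (lit_num && !is.na(nv) && !is.na(nl)) nv == nl else v == lit
    }
    if (n$op == "==") return(eq_one(n$value, n$value_numeric))
    if (n$op == "!=") return(!eq_one(n$value, n$value_numeric))
    hits <- any(vapply(seq_along(n$value), function(j) {
      eq_one(n$value[[j]], n$value_numeric[[j]])
    }, logical(1L)))
    if (n$op == "in") hits else !hits
  }
  eval_node <- function(n, uni) {
    switch(n$type,
      cmp = uni[vapply(uni, cmp_one, logical(1L), n = n)],
      and = intersect(eval_node(n$lhs, uni), eval_node(n$rhs, uni)),
      or = union(eval_node(n$lhs, uni), eval_node(n$rhs, uni)))
  }
  sorted(eval_node(node, unique(as.character(universe))))
}

# (sample, feature, count) multiset of a dense matrix, for table equality
count_triples <- function(m) {
  nz <- which(m > 0, arr.ind = TRUE)
  df <- data.frame(sample = colnames(m)[nz[, 2L]],
                   feature = rownames(m)[nz[, 1L]],
                   count = m[nz], stringsAsFactors = FALSE)
  df[order(df$sample, df$feature), , drop = FALSE]
}

expect_same_triples <- function(a, b) {
  ta <- count_triples(a); tb <- count_triples(b)
  rownames(ta) <- NULL; rownames(tb) <- NULL
  expect_equal(ta, tb)
}
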