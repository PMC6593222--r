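# Random fixture builders for property-style tests. All draws come from the
# caller's RNG state; tests set a seed at the top of each block.

rand_feature_matrix <- function(n_samples = sample(5:25, 1L),
                                n_features = sample(10:60, 1L),
                                density = runif(1L, 0.05, 0.3),
                                prefix = "f") {
  feats <- sprintf("%s%03d", prefix, seq_len(n_features))
  samps <- sprintf("S%03d", sample.int(500L, n_samples))
  m <- matrix(0, n_features, n_samples, dimnames = list(feats, samps))
  nz <- runif(length(m)) < density
  m[nz] <- rpois(sum(nz), 8) + 1
  m
}

MD_CATEGORIES <- c("Soil (non-saline)", "soil dry", "Saline lake water",
                   "Animal distal gut", "control")
MD_WORDS <- c("soil", "saline", "antibiotics", "fermented", "grassland",
              "forest", "sediment", "treated", "samples", "compost")

rand_metadata <- function(samples) {
  n <- length(samples)
  ph <- sprintf("%.2f", runif(n, 3, 10))
  miss <- runif(n) < 0.15
  ph[miss] <- sample(c("", "NA", "not applicable", "Missing: no pH"),
                     sum(miss), replace = TRUE)
  junk <- !miss & runif(n) < 0.1
  ph[junk] <- "seven-ish"
  desc <- vapply(seq_len(n), function(i) {
    paste(sample(MD_WORDS, sample(1:3, 1L)), collapse = " ")
  }, character(1L))
  data.frame(
    "#SampleID" = samples,
    ph = ph,
    empo_3 = sample(MD_CATEGORIES, n, replace = TRUE),
    description = desc,
    depth_cm = as.character(sample(c("5", "10", "30", "NA"), n, replace = TRUE)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

rand_where_clause <- function() {
  cmp <- function() {
    pick <- sample(4L, 1L)
    if (pick == 1L) {
      sprintf("ph %s %.1f", sample(c("<", "<=", ">", ">="), 1L), runif(1, 3, 10))
    } else if (pick == 2L) {
      sprintf("empo_3 %s '%s'", sample(c("==", "!="), 1L),
              sample(MD_CATEGORIES, 1L))
    } else if (pick == 3L) {
      vals <- sample(MD_CATEGORIES, sample(1:3, 1L))
      sprintf("empo_3 %s (%s)", sample(c("in", "notin"), 1L),
              paste(sprintf("'%s'", vals), collapse = ", "))
    } else {
      sprintf("depth_cm %s %s", sample(c("==", "!=", "<", ">"), 1L),
              sample(c("5", "10", "30"), 1L))
    }
  }
  n <- sample(1:3, 1L)
  parts <- vapply(seq_len(n), function(i) cmp(), character(1L))
  ops <- sample(c("and", "or"), max(n - 1L, 0L), replace = TRUE)
  out <- parts[[1L]]
  for (i in seq_along(ops)) out <- paste(out, ops[[i]], parts[[i + 1L]])
  if (n > 1L && runif(1) < 0.3) out <- sprintf("(%s)", out)
  out
}

rand_fulltext_expr <- function() {
  term <- function() {
    w <- sample(c(MD_WORDS, "unseenword"), 1L)
    if (runif(1) < 0.2) sprintf("\"%s %s\"", w, sample(MD_WORDS, 1L)) else w
  }
  n <- sample(1:3, 1L)
  out <- term()
  if (n >= 2L) out <- paste(out, sample(c("&", "|", "-"), 1L), term())
  if (n >= 3L) out <- sprintf("(%s) %s %s", out, sample(c("&", "|", "-"), 1L),
                              term())
  out
}

# load a matrix + metadata into a fresh store under one context
build_store <- function(m, md = NULL, context = "ctx", tax = NULL) {
  st <- store_create()
  create_context(st, context, "test context")
  load_table(st, context, m)
  if (!is.null(md)) ingest_metadata(st, md)
  if (!is.null(tax)) load_taxonomy(st, context, tax)
  st
}

rand_taxonomy <- function(features) {
  genus <- sample(c("g__Bacillus", "g__Clostridium", "g__Nitrospira"),
                  length(features), replace = TRUE)
  phylum <- sample(c("p__Firmicutes", "p__Proteobacteria"),
                   length(features), replace = TRUE)
  data.frame(feature = features,
             lineage = paste("k__Bacteria;", phylum, ";", genus),
             stringsAsFactors = FALSE)
}
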