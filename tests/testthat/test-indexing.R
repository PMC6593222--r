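toy_matrix <- function() {
  matrix(c(1, 0, 2,
           0, 5, 0), nrow = 3,
         dimnames = list(c("f_a", "f_b", "f_c"), c("S1", "S2")))
}

test_that("contexts register, reject duplicates and invalid names, and coexist", {
  st <- store_create()
  create_context(st, "deblur-90nt", "Deblur 16S V4 90nt")
  create_context(st, "closed-ref", "closed reference OTUs")
  expect_identical(list_contexts(st), c("closed-ref", "deblur-90nt"))
  expect_error(create_context(st, "deblur-90nt", "again"), "already exists")
  expect_error(create_context(st, "bad:name", ""), "may not contain")
  expect_error(create_context(st, "", ""), "non-empty")
  expect_error(create_context(st, "metadata", ""), "reserved")
  # loading into one context leaves the other untouched
  load_table(st, "deblur-90nt", toy_matrix())
  expect_identical(context_info(st, "closed-ref")$n_samples, 0L)
  expect_identical(context_info(st, "deblur-90nt")$n_samples, 2L)
})

test_that("identifier maps assign dense integers in first-seen order, stably", {
  st <- store_create()
  create_context(st, "c", "")
  expect_identical(map_identifiers(st, "c", c("f1", "f2", "f1"), "feature"),
                   c(0L, 1L, 0L))
  expect_identical(map_identifiers(st, "c", c("f3", "f2"), "feature"),
                   c(2L, 1L))
  expect_identical(unmap_identifiers(st, "c", 1L, "feature"), "f2")
  # sample space is independent of feature space
  expect_identical(map_identifiers(st, "c", "f1", "sample"), 0L)
  # bijection: forward then reverse is the identity on all assigned ids
  ids <- c("f1", "f2", "f3")
  expect_identical(unmap_identifiers(st, "c", map_identifiers(st, "c", ids, "feature"),
                                     "feature"), ids)
})

test_that("loading a toy table stores sparse vectors and the inverted index", {
  st <- store_create()
  create_context(st, "c", "")
  smry <- load_table(st, "c", toy_matrix())
  expect_identical(smry$samples_loaded, 2L)
  expect_identical(smry$features_new, 3L)
  v1 <- biomdex:::sample_vector(st, "c", "S1")
  fids1 <- unmap_identifiers(st, "c", v1$ints, "feature")
  expect_identical(setNames(v1$counts, fids1)[c("f_a", "f_c")],
                   c(f_a = 1, f_c = 2))
  expect_identical(search_features(st, "c", "f_a", "any")$samples, "S1")
  expect_identical(search_features(st, "c", "f_b", "any")$samples, "S2")
  expect_identical(search_features(st, "c", "f_c", "any")$samples, "S1")
})

test_that("reloading the same table skips all samples and changes nothing", {
  st <- store_create()
  create_context(st, "c", "")
  load_table(st, "c", toy_matrix())
  before <- store_snapshot_bytes(st)
  smry <- load_table(st, "c", toy_matrix())
  expect_identical(smry$samples_loaded, 0L)
  expect_identical(smry$samples_skipped, 2L)
  expect_identical(store_snapshot_bytes(st), before)
})

test_that("invalid tables are rejected naming the defect", {
  st <- store_create()
  create_context(st, "c", "")
  m <- toy_matrix()
  colnames(m) <- c("S:1", "S2")
  expect_error(load_table(st, "c", m), "may not contain")
  m <- toy_matrix(); m[1, 1] <- -1
  expect_error(load_table(st, "c", m), "negative")
  m <- toy_matrix(); rownames(m) <- c("f", "f", "g")
  expect_error(load_table(st, "c", m), "duplicate feature")
  expect_error(load_table(st, "c", withr::local_tempfile(lines = "not biom")),
               "invalid BIOM")
  expect_error(load_table(st, "missing-ctx", toy_matrix()), "unknown context")
})

test_that("BIOM JSON files written by the package load identically to matrices", {
  set.seed(31)
  m <- rand_feature_matrix()
  path <- withr::local_tempfile(fileext = ".biom")
  write_biom_json(m, path, timestamp = "1970-01-01T00:00:00")
  m2 <- read_biom_table(path)
  expect_same_triples(m, m2)
  # and through an independent reader
  b <- biomformat::read_biom(path)
  m3 <- as(biomformat::biom_data(b), "matrix")
  expect_same_triples(m, m3)
})

test_that("inverted index matches a brute-force rebuild on a 50x200 fixture", {
  set.seed(99)
  m <- rand_feature_matrix(n_samples = 50, n_features = 200)
  st <- build_store(m)
  idx <- oracle_inverted_index(m)
  for (f in names(idx)) {
    expect_identical(kv_set_members(st, kv_key("ctx", "feature", f)), idx[[f]])
  }
  # membership sets are the transpose of the inverted index
  for (s in colnames(m)) {
    expect_identical(kv_set_members(st, kv_key("ctx", "sample-features", s)),
                     sorted(rownames(m)[m[, s] > 0]))
  }
})

test_that("count mass is conserved through load", {
  set.seed(17)
  m <- rand_feature_matrix()
  st <- build_store(m)
  total <- sum(vapply(colnames(m), function(s) {
    sum(biomdex:::sample_vector(st, "ctx", s)$counts)
  }, numeric(1L)))
  expect_equal(total, sum(m))
})

test_that("load order does not affect observable query answers", {
  set.seed(23)
  m <- rand_feature_matrix(n_samples = 12, n_features = 30)
  st1 <- build_store(m)
  perm <- sample(ncol(m))
  st2 <- store_create()
  create_context(st2, "ctx", "test context")
  for (j in perm) load_table(st2, "ctx", m[, j, drop = FALSE])
  for (f in rownames(m)) {
    expect_identical(search_features(st1, "ctx", f, "any")$samples,
                     search_features(st2, "ctx", f, "any")$samples)
  }
  expect_same_triples(fetch_table(st1, "ctx", colnames(m)),
                      fetch_table(st2, "ctx", colnames(m)))
})

test_that("taxonomy fan-out indexes every rank label verbatim", {
  st <- store_create()
  create_context(st, "c", "")
  tax <- data.frame(
    f = c("f_a", "f_b"),
    lineage = c("k__Bacteria; p__Firmicutes; g__Clostridium",
                "k__Bacteria; p__Firmicutes"),
    stringsAsFactors = FALSE)
  load_taxonomy(st, "c", tax)
  expect_identical(search_taxon(st, "c", "g__Clostridium"), "f_a")
  expect_identical(search_taxon(st, "c", "p__Firmicutes"), c("f_a", "f_b"))
  expect_identical(search_taxon(st, "c", "g__NeverSeen"), character())
  expect_identical(feature_lineage(st, "c", "f_a"),
                   "k__Bacteria; p__Firmicutes; g__Clostridium")
})

test_that("malformed taxonomy lines are rejected with their line number", {
  st <- store_create()
  create_context(st, "c", "")
  bad <- withr::local_tempfile(lines = c("f_a\tk__Bacteria", "f_b only one col"))
  expect_error(load_taxonomy(st, "c", bad), "line 2")
})
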