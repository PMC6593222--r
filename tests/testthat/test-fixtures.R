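small_spec <- function(seed = 7L, ...) {
  corpus_spec(n_studies = 2L, samples_per_study = 20L,
              n_background_features = 40L, sequencing_depth = 500,
              seed = seed, ...)
}

test_that("identical spec and seed give byte-identical corpus files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_corpus(small_spec(), d1)
  generate_corpus(small_spec(), d2)
  files <- list.files(d1)
  expect_identical(sort(files), sort(list.files(d2)))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("the generated corpus is readable by the ingest side", {
  d <- withr::local_tempdir()
  g <- generate_corpus(small_spec(seed = 9L), d)
  st <- store_create()
  create_context(st, "c", "")
  for (p in g$tables) load_table(st, "c", p)
  ingest_metadata(st, g$metadata)
  load_taxonomy(st, "c", g$taxonomy)
  ci <- context_info(st, "c")
  expect_identical(ci$n_samples, 40L)
  # truth/ingest agreement: samples with any low feature per the truth file
  want <- sorted(g$truth$samples[g$truth$has_low])
  got <- search_features(st, "c", g$truth$low_features, "any")$samples
  expect_identical(got, want)
  # taxonomy search reaches the differential features
  expect_identical(search_taxon(st, "c", "g__Acidipila"),
                   sorted(g$truth$low_features))
})

test_that("null association leaves low and high prevalences statistically equal", {
  lows <- 0L; highs <- 0L; n <- 0L
  for (seed in 1:10) {
    d <- withr::local_tempdir()
    g <- generate_corpus(small_spec(seed = seed, association_strength = 0), d)
    lows <- lows + sum(g$truth$has_low)
    highs <- highs + sum(g$truth$has_high)
    n <- n + length(g$truth$samples)
  }
  pt <- prop.test(c(lows, highs), c(n, n))
  expect_gt(pt$p.value, 0.001)
})

test_that("with the default association, retrieval groups separate on pH", {
  ok <- 0L
  for (seed in 1:20) {
    d <- withr::local_tempdir()
    g <- generate_corpus(corpus_spec(n_studies = 2L, samples_per_study = 100L,
                                     n_background_features = 40L,
                                     sequencing_depth = 500, seed = seed), d)
    med_low <- median(g$truth$ph[g$truth$has_low])
    med_high <- median(g$truth$ph[g$truth$has_high])
    if (med_low < med_high) ok <- ok + 1L
  }
  expect_identical(ok, 20L)
})

test_that("pH is uniform over its range (moment check at large n)", {
  d <- withr::local_tempdir()
  g <- generate_corpus(corpus_spec(n_studies = 5L, samples_per_study = 200L,
                                   n_background_features = 20L,
                                   sequencing_depth = 100, seed = 2L), d)
  ph <- g$truth$ph
  mu <- mean(c(3.5, 9.0))
  se <- sqrt(diff(c(3.5, 9.0))^2 / 12 / length(ph))
  expect_lt(abs(mean(ph) - mu), 3 * se)
})

test_that("every differential feature occurs somewhere at default-ish sizes", {
  d <- withr::local_tempdir()
  g <- generate_corpus(corpus_spec(n_studies = 2L, samples_per_study = 100L,
                                   n_background_features = 60L,
                                   sequencing_depth = 1000, seed = 3L), d)
  counts <- lapply(g$tables, read_biom_table)
  observed <- sorted(unlist(lapply(counts, rownames)))
  expect_true(all(g$truth$low_features %in% observed))
  expect_true(all(g$truth$high_features %in% observed))
})

test_that("invalid corpus specs are rejected", {
  expect_error(corpus_spec(n_studies = 0), "positive")
  expect_error(corpus_spec(ph_range = c(9, 3.5)), "increasing")
  expect_error(corpus_spec(decoy_fraction = 2), "\\[0, 1\\]")
})

test_that("two-context corpora honor the overlap fraction and truth mapping", {
  d <- withr::local_tempdir()
  spec <- small_spec(seed = 21L)
  g <- generate_two_context_corpus(spec, d, overlap_fraction = 0.6)
  st <- store_create()
  create_context(st, "deblur", "")
  create_context(st, "closedref", "")
  for (p in g$tables) load_table(st, "deblur", p)
  for (p in g$tables2) load_table(st, "closedref", p)
  ingest_metadata(st, g$metadata)
  part <- partition_by_context(st, g$truth$samples, "closedref")
  expect_identical(part$present, g$overlap)
  expect_identical(sorted(c(part$present, part$absent)), sorted(g$truth$samples))

  d2 <- withr::local_tempdir()
  g1 <- generate_two_context_corpus(small_spec(seed = 22L), d2, 1.0)
  samples2 <- sorted(unlist(lapply(g1$tables2, function(p) colnames(read_biom_table(p)))))
  expect_identical(samples2, sorted(g1$truth$samples))
  d3 <- withr::local_tempdir()
  g0 <- generate_two_context_corpus(small_spec(seed = 23L), d3, 0)
  expect_length(g0$tables2, 0L)
  expect_error(generate_two_context_corpus(small_spec(), d3, 1.5), "\\[0, 1\\]")
})
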