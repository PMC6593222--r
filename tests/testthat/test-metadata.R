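md_toy <- function() {
  data.frame(
    "#SampleID" = c("S1", "S2", "S3"),
    ph = c("6.5", "", "8.1"),
    description = c("soil with antibiotics", "Saline lake", "forest soil"),
    check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("ingest drops missing markers and stores values verbatim", {
  st <- store_create()
  smry <- ingest_metadata(st, md_toy())
  expect_identical(smry$samples, 3L)
  expect_identical(smry$variables, 2L)
  expect_identical(smry$values_dropped_missing, 1L)
  expect_identical(unname(get_sample_metadata(st, "S2", "ph")), NA_character_)
  expect_identical(unname(get_sample_metadata(st, "S1", "ph")), "6.5")
  # all documented missing markers drop, case-insensitively
  st2 <- store_create()
  df <- data.frame(s = sprintf("S%d", 1:7),
                   v = c("NA", "n/a", "NaN", "None", "UNKNOWN",
                         "not applicable", "Missing: not collected"))
  smry2 <- ingest_metadata(st2, df)
  expect_identical(smry2$values_dropped_missing, 7L)
})

test_that("re-ingesting an identical table leaves the store unchanged", {
  st <- store_create()
  ingest_metadata(st, md_toy())
  before <- store_snapshot_bytes(st)
  ingest_metadata(st, md_toy())
  expect_identical(store_snapshot_bytes(st), before)
})

test_that("re-ingesting changed values retracts stale stems", {
  st <- store_create()
  ingest_metadata(st, md_toy())
  expect_identical(search_fulltext(st, "antibiotics"), "S1")
  changed <- md_toy()
  changed$description[[1L]] <- "compost trial"
  ingest_metadata(st, changed)
  expect_identical(search_fulltext(st, "antibiotics"), character())
  expect_identical(search_fulltext(st, "compost"), "S1")
})

test_that("duplicate ids and ragged rows are rejected informatively", {
  st <- store_create()
  df <- md_toy(); df[[1L]][2L] <- "S1"
  expect_error(ingest_metadata(st, df), "duplicate sample id")
  path <- withr::local_tempfile(lines = c("id\tph", "S1\t6.5", "S2\t6.5\textra"))
  expect_error(ingest_metadata(st, path), "line 3")
})

test_that("metadata TSV files round trip through ingest (header name free)", {
  st <- store_create()
  path <- withr::local_tempfile(
    lines = c("#SampleID\tph\tempo_3",
              "S1\t6.5\tSoil (non-saline)",
              "S2\t\tAnimal distal gut"))
  smry <- ingest_metadata(st, path)
  expect_identical(smry$samples, 2L)
  expect_identical(unname(get_sample_metadata(st, "S1", "empo_3")),
                   "Soil (non-saline)")
  expect_identical(unname(get_sample_metadata(st, "S2", "ph")), NA_character_)
})

test_that("full-text single terms, difference and variable restriction work", {
  st <- store_create()
  ingest_metadata(st, md_toy())
  expect_identical(search_fulltext(st, "soil"), c("S1", "S3"))
  expect_identical(search_fulltext(st, "antibiotic"), "S1")  # stem match
  expect_identical(search_fulltext(st, "soil - forest"), "S1")
  expect_identical(search_fulltext(st, "soil | saline"), c("S1", "S2", "S3"))
  expect_identical(search_fulltext(st, "\"forest soil\""), "S3")
  expect_identical(search_fulltext(st, "neverseen"), character())
  expect_identical(search_fulltext(st, "saline", variable = "ph"), character())
  expect_identical(search_fulltext(st, "saline", variable = "description"), "S2")
  expect_error(search_fulltext(st, "soil & ("), "position")
  expect_error(search_fulltext(st, "soil )"), "position")
})

test_that("where clauses type per comparison and exclude missing values", {
  st <- store_create()
  ingest_metadata(st, md_toy())
  expect_identical(evaluate_where(st, "ph < 7"), "S1")
  expect_identical(evaluate_where(st, "ph > 0"), c("S1", "S3"))  # S2 missing
  expect_identical(evaluate_where(st, "ph < 7 and ph > 7"), character())
  expect_identical(evaluate_where(st, "ph == 6.50"), "S1")  # numeric equality
  expect_identical(evaluate_where(st, "description == 'Saline lake'"), "S2")
  expect_identical(evaluate_where(st, "ph < 7 or ph >= 8"), c("S1", "S3"))
  expect_identical(
    evaluate_where(st, "description in ('Saline lake', 'forest soil')"),
    c("S2", "S3"))
  expect_identical(evaluate_where(st, "description not in ('Saline lake')"),
                   c("S1", "S3"))
  expect_identical(evaluate_where(st, "ph < 7", universe = c("S3")), character())
  expect_error(parse_where("ph <> 7"), "position")
  expect_error(parse_where(""), "non-empty")
})

test_that("stem index equals a brute-force rebuild from stored values", {
  set.seed(12)
  samples <- sprintf("S%03d", 1:50)
  md <- rand_metadata(samples)
  st <- store_create()
  ingest_metadata(st, md)
  want <- oracle_stem_sets(md)
  all_stems <- sorted(unlist(want, use.names = FALSE))
  for (stem in all_stems) {
    expect_identical(
      kv_set_members(st, kv_key("metadata", "stem", stem)),
      sorted(names(want)[vapply(want, function(ss) stem %in% ss, logical(1L))]))
  }
  # the global index equals the union over variables of the sub-index
  for (stem in all_stems) {
    per_var <- lapply(setdiff(colnames(md), "#SampleID"), function(v) {
      kv_set_members(st, biomdex:::md_varstem_key(v, stem))
    })
    expect_identical(kv_set_members(st, kv_key("metadata", "stem", stem)),
                     sorted(unlist(per_var)))
  }
})

test_that("where and fulltext agree with brute-force row scans on random fixtures", {
  set.seed(2024)
  for (rep in 1:25) {
    samples <- sprintf("S%03d", sample.int(400, sample(10:40, 1L)))
    md <- rand_metadata(samples)
    st <- store_create()
    ingest_metadata(st, md)
    for (q in 1:8) {
      clause <- rand_where_clause()
      expect_identical(evaluate_where(st, clause), oracle_where(md, clause),
                       info = clause)
      expr <- rand_fulltext_expr()
      expect_identical(search_fulltext(st, expr), oracle_fulltext(md, expr),
                       info = expr)
    }
  }
})

test_that("where-clause results are monotone in universe and conjuncts", {
  set.seed(5)
  samples <- sprintf("S%03d", 1:30)
  md <- rand_metadata(samples)
  st <- store_create()
  ingest_metadata(st, md)
  for (rep in 1:20) {
    clause <- rand_where_clause()
    big <- evaluate_where(st, clause)
    small_uni <- sample(samples, 10L)
    small <- evaluate_where(st, clause, universe = small_uni)
    expect_true(all(small %in% big))
    conj <- sprintf("(%s) and (%s)", clause, rand_where_clause())
    expect_true(all(evaluate_where(st, conj) %in% big))
  }
})
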