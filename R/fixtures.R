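# Seeded synthetic corpus generator.
#
# Emulates the structure of a multi-study soil survey in which a handful of
# exact sequence variants associate strongly with low- or high-pH soils:
# per sample, pH is uniform over ph_range; each differential feature is
# present with logistic probability in its favoured direction
# (log-odds `association_strength` per pH unit around pH 6.5); counts for
# the features present in a sample are multinomial over a Poisson
# sequencing depth, with background feature proportions drawn once per
# corpus from a Dirichlet. The generator writes exactly the formats the
# ingest side reads (BIOM 1.0 JSON per study, metadata TSV, taxonomy TSV)
# plus a machine-readable truth file, so it doubles as a format-conformance
# exerciser.

#' Specification of a synthetic multi-study corpus
#'
#' @param n_studies Number of studies (each written as its own BIOM table).
#' @param samples_per_study Samples per study.
#' @param n_background_features Background (non-differential) features.
#' @param n_low_ph_features,n_high_ph_features Differential features
#'   associated with low / high pH.
#' @param ph_range Uniform sampling range for per-sample pH.
#' @param association_strength Log-odds of differential-feature presence per
#'   pH unit away from 6.5 (in the favoured direction).
#' @param sequencing_depth Poisson mean of per-sample total counts.
#' @param decoy_fraction Fraction of samples given the decoy \code{empo_3}
#'   category instead of \code{"Soil (non-saline)"}.
#' @param missing_ph_fraction Fraction of samples whose metadata pH is
#'   replaced by a missing marker (their true pH stays in the truth file).
#' @param feature_id_length Length of the synthetic DNA-sequence feature
#'   ids, mimicking exact sub-OTU sequence identifiers.
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   corpus files.
#' @return List of class \code{biomdex_corpus_spec}.
#' @export
corpus_spec <- function(n_studies = 5L,
                        samples_per_study = 80L,
                        n_background_features = 190L,
                        n_low_ph_features = 5L,
                        n_high_ph_features = 5L,
                        ph_range = c(3.5, 9.0),
                        association_strength = 1.5,
                        sequencing_depth = 5000,
                        decoy_fraction = 0.1,
                        missing_ph_fraction = 0.05,
                        feature_id_length = 90L,
                        seed = 1L) {
  spec <- list(n_studies = as.integer(n_studies),
               samples_per_study = as.integer(samples_per_study),
               n_background_features = as.integer(n_background_features),
               n_low_ph_features = as.integer(n_low_ph_features),
               n_high_ph_features = as.integer(n_high_ph_features),
               ph_range = as.numeric(ph_range),
               association_strength = as.numeric(association_strength),
               sequencing_depth = as.numeric(sequencing_depth),
               decoy_fraction = as.numeric(decoy_fraction),
               missing_ph_fraction = as.numeric(missing_ph_fraction),
               feature_id_length = as.integer(feature_id_length),
               seed = as.integer(seed))
  counts <- c("n_studies", "samples_per_study", "n_background_features",
              "sequencing_depth", "feature_id_length")
  for (nm in counts) {
    if (is.na(spec[[nm]]) || spec[[nm]] <= 0) {
      stop("corpus spec field '", nm, "' must be positive", call. = FALSE)
    }
  }
  for (nm in c("n_low_ph_features", "n_high_ph_features")) {
    if (is.na(spec[[nm]]) || spec[[nm]] < 0) {
      stop("corpus spec field '", nm, "' must be non-negative", call. = FALSE)
    }
  }
  if (length(spec$ph_range) != 2L || diff(spec$ph_range) <= 0) {
    stop("ph_range must be an increasing pair", call. = FALSE)
  }
  for (nm in c("decoy_fraction", "missing_ph_fraction")) {
    if (spec[[nm]] < 0 || spec[[nm]] > 1) {
      stop("corpus spec field '", nm, "' must be in [0, 1]", call. = FALSE)
    }
  }
  class(spec) <- "biomdex_corpus_spec"
  spec
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

# description phrase pools; seeded words exercise the stem index
DESC_SOIL <- c("topsoil core from temperate grassland",
               "agricultural soil under long term fertilization",
               "forest soil sampled after rainfall",
               "arid soil crust near saline lake",
               "rhizosphere soil of cultivated wheat",
               "composted soil amendment trial plot")
DESC_DECOY <- c("fecal sample collected after antibiotics course",
                "gut community from captive rodent",
                "oral swab following antibiotics treatment",
                "freshwater sediment reference sample")

GENUS_POOL <- c("g__Bacillus", "g__Clostridium", "g__Pseudomonas",
                "g__Streptomyces", "g__Nitrospira", "g__Bradyrhizobium")
PHYLUM_POOL <- c("p__Firmicutes", "p__Proteobacteria", "p__Actinobacteria",
                 "p__Acidobacteria", "p__Nitrospirae")

#' Generate a synthetic corpus on disk
#'
#' @param spec A \code{\link{corpus_spec}}.
#' @param dir Output directory (created if needed).
#' @return Invisible list: \code{tables} (per-study BIOM paths),
#'   \code{metadata} (TSV path), \code{taxonomy} (TSV path), \code{truth}
#'   (JSON path), and the in-memory \code{truth} list.
#' @export
generate_corpus <- function(spec, dir) {
  if (!inherits(spec, "biomdex_corpus_spec")) {
    stop("`spec` must come from corpus_spec()", call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(spec$seed)

  n_feat <- spec$n_background_features + spec$n_low_ph_features +
    spec$n_high_ph_features
  feat_ids <- unique(random_dna(n_feat, spec$feature_id_length))
  while (length(feat_ids) < n_feat) {
    feat_ids <- unique(c(feat_ids, random_dna(n_feat - length(feat_ids),
                                              spec$feature_id_length)))
  }
  low_idx <- seq_len(spec$n_low_ph_features)
  high_idx <- spec$n_low_ph_features + seq_len(spec$n_high_ph_features)
  bg_idx <- setdiff(seq_len(n_feat), c(low_idx, high_idx))
  low_features <- feat_ids[low_idx]
  high_features <- feat_ids[high_idx]

  # background community profile for the whole corpus
  bg_alpha <- stats::rgamma(length(bg_idx), shape = 1, rate = 1)
  bg_prop <- bg_alpha / sum(bg_alpha)
  diff_weight <- 3 / max(length(bg_idx), 1L)

  n_total <- spec$n_studies * spec$samples_per_study
  study_of <- rep(seq_len(spec$n_studies), each = spec$samples_per_study)
  sample_ids <- sprintf("study%02d.S%04d", study_of,
                        stats::ave(seq_len(n_total), study_of, FUN = seq_along))
  ph <- stats::runif(n_total, spec$ph_range[[1L]], spec$ph_range[[2L]])
  decoy <- stats::runif(n_total) < spec$decoy_fraction
  miss_ph <- stats::runif(n_total) < spec$missing_ph_fraction

  beta <- spec$association_strength
  counts <- matrix(0, nrow = n_feat, ncol = n_total,
                   dimnames = list(feat_ids, sample_ids))
  present_low <- matrix(FALSE, length(low_idx), n_total)
  present_high <- matrix(FALSE, length(high_idx), n_total)
  for (i in seq_len(n_total)) {
    p_low <- stats::plogis(beta * (6.5 - ph[[i]]))
    p_high <- stats::plogis(beta * (ph[[i]] - 6.5))
    pres_l <- stats::runif(length(low_idx)) < p_low
    pres_h <- stats::runif(length(high_idx)) < p_high
    present_low[, i] <- pres_l
    present_high[, i] <- pres_h
    w <- c(ifelse(pres_l, diff_weight, 0),
           ifelse(pres_h, diff_weight, 0),
           bg_prop)
    depth <- stats::rpois(1L, spec$sequencing_depth)
    if (depth > 0 && sum(w) > 0) {
      counts[, i] <- stats::rmultinom(1L, depth, w / sum(w))[, 1L]
    }
  }
  # presence in the truth sense means sampled reads, not just Bernoulli draw
  obs_low <- counts[low_idx, , drop = FALSE] > 0
  obs_high <- counts[high_idx, , drop = FALSE] > 0

  table_paths <- character(spec$n_studies)
  for (k in seq_len(spec$n_studies)) {
    cols <- which(study_of == k)
    sub <- counts[, cols, drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    table_paths[[k]] <- file.path(dir, sprintf("table_study%02d.biom", k))
    write_biom_json(sub, table_paths[[k]],
                    id = sprintf("synthetic study %02d", k),
                    generated_by = "biomdex synthetic corpus",
                    timestamp = "1970-01-01T00:00:00")
  }

  ph_str <- sprintf("%.3f", ph)
  ph_str[miss_ph] <- "NA"
  empo <- ifelse(decoy, "Animal distal gut", "Soil (non-saline)")
  desc_pool_idx <- ifelse(decoy,
                          sample.int(length(DESC_DECOY), n_total, replace = TRUE),
                          sample.int(length(DESC_SOIL), n_total, replace = TRUE))
  description <- ifelse(decoy, DESC_DECOY[desc_pool_idx],
                        DESC_SOIL[desc_pool_idx])
  md <- data.frame(
    "#SampleID" = sample_ids,
    study_id = sprintf("study%02d", study_of),
    ph = ph_str,
    empo_3 = empo,
    description = description,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  md_path <- file.path(dir, "metadata.tsv")
  write_metadata_tsv(md, md_path)

  lineage <- character(n_feat)
  lineage[low_idx] <- "k__Bacteria; p__Acidobacteria; g__Acidipila"
  lineage[high_idx] <- "k__Bacteria; p__Bacteroidetes; g__Alkalitalea"
  if (length(bg_idx)) {
    lineage[bg_idx] <- paste0("k__Bacteria; ",
                              sample(PHYLUM_POOL, length(bg_idx), replace = TRUE),
                              "; ",
                              sample(GENUS_POOL, length(bg_idx), replace = TRUE))
  }
  tax_path <- file.path(dir, "taxonomy.tsv")
  writeLines(paste(feat_ids, lineage, sep = "\t"), tax_path, useBytes = TRUE)

  truth <- list(
    low_features = low_features,
    high_features = high_features,
    samples = sample_ids,
    study = sprintf("study%02d", study_of),
    ph = round(ph, 6),
    decoy = decoy,
    ph_missing_in_metadata = miss_ph,
    has_low = as.logical(colSums(obs_low) > 0),
    has_high = as.logical(colSums(obs_high) > 0)
  )
  truth_path <- file.path(dir, "truth.json")
  writeLines(jsonlite::toJSON(truth, auto_unbox = FALSE, digits = NA),
             truth_path, useBytes = TRUE)

  invisible(list(tables = table_paths, metadata = md_path,
                 taxonomy = tax_path, truth_path = truth_path, truth = truth))
}

#' Generate paired tables for two overlapping contexts
#'
#' Writes the primary corpus, then a second set of per-study tables covering
#' a configurable fraction of the samples with a smaller, remapped
#' (closed-reference-like) feature space: each exact-sequence feature is
#' deterministically assigned to one of a reduced set of reference OTU ids
#' and counts are aggregated. The truth file gains the overlap sample list
#' and the feature mapping.
#'
#' @inheritParams generate_corpus
#' @param overlap_fraction Fraction of corpus samples also covered by the
#'   second context.
#' @param n_reference_otus Size of the reduced feature space (default: a
#'   third of the primary feature count).
#' @return Invisible list as \code{\link{generate_corpus}} plus
#'   \code{tables2} (second context's BIOM paths) and \code{overlap}
#'   (sample ids in both contexts).
#' @export
generate_two_context_corpus <- function(spec, dir, overlap_fraction = 0.6,
                                        n_reference_otus = NULL) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must be in [0, 1]", call. = FALSE)
  }
  out <- generate_corpus(spec, dir)
  truth <- out$truth
  n_total <- length(truth$samples)
  n_feat <- spec$n_background_features + spec$n_low_ph_features +
    spec$n_high_ph_features
  if (is.null(n_reference_otus)) n_reference_otus <- max(1L, n_feat %/% 3L)

  n_overlap <- round(overlap_fraction * n_total)
  overlap <- sort(sample(truth$samples, n_overlap), method = "radix")

  # full feature list, in the taxonomy file's (generation) order
  tax <- read.delim(out$taxonomy, header = FALSE, colClasses = "character")
  feat_ids <- tax[[1L]]
  otu_of <- sprintf("ref%05d",
                    sample.int(n_reference_otus, length(feat_ids), replace = TRUE))
  names(otu_of) <- feat_ids

  tables2 <- character(0)
  dir2 <- file.path(dir, "context2")
  if (!dir.exists(dir2)) dir.create(dir2)
  for (k in seq_along(out$tables)) {
    m <- read_biom_table(out$tables[[k]])
    cols <- intersect(colnames(m), overlap)
    if (!length(cols)) next
    m <- m[, cols, drop = FALSE]
    agg <- rowsum(m, group = otu_of[rownames(m)])
    agg <- agg[rowSums(agg) > 0, , drop = FALSE]
    if (!nrow(agg)) next
    p <- file.path(dir2, sprintf("table_study%02d.biom", k))
    write_biom_json(agg, p, id = sprintf("closed-reference study %02d", k),
                    generated_by = "biomdex synthetic corpus",
                    timestamp = "1970-01-01T00:00:00")
    tables2 <- c(tables2, p)
  }
  truth$overlap <- overlap
  truth$otu_of <- as.list(otu_of)
  writeLines(jsonlite::toJSON(truth, auto_unbox = FALSE, digits = NA),
             out$truth_path, useBytes = TRUE)
  out$truth <- truth
  out$tables2 <- tables2
  out$overlap <- overlap
  invisible(out)
}
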