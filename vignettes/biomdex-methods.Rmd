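---
title: "biomdex: data model, indexing and query semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{biomdex: data model, indexing and query semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

biomdex answers sample-discovery questions over collections of microbiome
feature tables: which samples contain an exact sequence feature, carry a
taxon label, or satisfy a metadata constraint — and it hands the answer
back as an analysis-ready feature table plus metadata file. This vignette
documents the data model, the semantics every query is guaranteed to obey,
the knobs that matter, and the design decisions that were genuinely open.

## The storage contract

Everything is built on a deliberately small key-value contract
(`store_create()`, `kv_*`): string values, string sets with
intersection/union/difference, and field→value records, under composite
keys `namespace:category:item`. Two properties of the contract do real
work:

- **Set algebra is the query engine.** An inverted index entry *is* a set;
  feature searches, stem lookups and constraint composition are set
  operations, so the whole query layer inherits commutativity and
  associativity from set theory, and the test suite checks those laws
  directly rather than trusting the implementation.
- **No key scanning.** Every enumerable collection (contexts,
  samples-represented, features-represented, indexed variables) is
  maintained as an explicit registry set. This keeps the contract
  implementable on any key-value engine, including ones where key
  enumeration is expensive or unavailable, and it is why `n_samples` in
  `context_info()` is always a registry cardinality rather than a scan.

The separator `:` is reserved; any identifier containing it is rejected at
write time, which keeps key rendering injective. Two namespaces are
reserved: `state` (context registry) and `metadata` (shared sample
metadata). Where an ordering is observable — set members, table rows and
columns, CLI output — it is bytewise lexicographic (radix sort), so equal
stores produce byte-equal answers on every platform.

The in-memory reference backend adds two internal operations beyond the
public contract: enumerating the fields of a single record and removing
members from a single set. The first supports metadata export; the second
lets re-ingest retract stale stem memberships (below). Both touch exactly
one key, so the no-scanning property stands.

Persistence is an explicit whole-store snapshot: one self-describing JSON
file with a magic header and format version. A save/load cycle reproduces
every query answer bit-for-bit (asserted in the acceptance suite). There is
no networked service, replication, eviction or transaction support, by
design: the data model, not the server, is the point. The command-line
layer adds a single-writer lock file around mutating commands, which is the
only concurrency control the snapshot model needs.

## Contexts and the feature index

A *context* partitions the store by processing protocol (sequencing
preparation + bioinformatics pipeline). Counts produced by different
protocols are not comparable, so each context owns its identifier maps,
sparse vectors and indices; the only thing shared across contexts is the
sample identifier. `partition_by_context()` exploits that: find samples in
one context (e.g. by presence of exact Deblur sub-OTU sequences), then
split the result by membership in another (e.g. closed-reference OTUs)
before fetching from it.

Within a context, every feature and sample identifier is remapped to a
dense integer, assigned from 0 in first-seen order and never reused.
Feature identifiers in amplicon work are often the exact sequences
themselves (90+ characters), so stored vectors carry integers instead;
the forward and reverse maps are maintained together and are a bijection
at all times (property-tested). Load-order affects the integer assignment
but never any observable string-level answer — also property-tested, by
loading permuted tables and comparing query results.

`load_table()` accepts BIOM 1.0 JSON (through Bioconductor's `biomformat`),
a `biom` object, or a plain matrix. Per sample it stores the nonzero
(feature-integer, count) pairs and updates the per-feature inverted index
and the per-sample feature-membership set. Three ingest rules matter:

- **Zeros are dropped, negative counts are rejected.** BIOM permits float
  counts, so counts are stored as given (integral counts serialize as
  integers); a zero carries no occurrence information and a negative count
  is a corrupt table.
- **Skip, don't merge.** A sample already present in the context is skipped
  in full and reported in the load summary. Re-ingesting a table is
  therefore idempotent; merging counts would silently double data.
- **Exact identifiers.** The index stores exact strings. Harmonizing
  sequence lengths across preparations (e.g. trimming queries to 90 nt) is
  the caller's preprocessing; the CLI offers `--trim-length` as a
  convenience that truncates *query* identifiers only, never stored ones.

Taxonomy, when provided as a feature→lineage table, fans out: a feature is
indexed under every rank label of its lineage, trimmed but otherwise
verbatim. Matching is exact and case-sensitive; normalizing rank prefixes
(`g__Clostridium` vs `Clostridium`) is left to callers, because silently
rewriting labels at ingest would make the index lossy.

## Metadata: records, stems, where-clauses

Metadata rows are stored as verbatim string records, one per sample, in a
single shared namespace — sample information is protocol-independent, so
metadata queries are context-free and intersect with context-bound
constraints on sample id.

**Missing values** are dropped at ingest, so a stored record contains only
real values. The marker vocabulary — empty string, `NA`, `N/A`, `NaN`,
`None`, `Unknown`, `not applicable`, and any `Missing:`-prefixed value,
case-insensitively — follows common QIIME-style metadata practice; the
format itself does not standardize one.

**The full-text index** maps the Porter stem of every word in every kept
categorical value to the set of samples carrying it, globally and per
variable. The tokenizer lowercases, splits on runs of non-alphanumeric
characters, drops tokens shorter than 2 characters and purely numeric
tokens, and stems the rest. The length-2 floor is deliberate: it keeps
`ph` searchable while excluding single letters; dropping bare numerals
keeps values like `"pH 7"` from polluting the index with `7`. There is no
stop-word list — stems are cheap, and a stop list would make results
depend on a curated vocabulary. The stemmer itself is implemented in the
package from the classic 1980 rule tables (no stemming library exists in
this package's dependency footprint) and is locked by test to a frozen
1000-word reference produced by an independent transcription of the
algorithm, including the canonical published example transformations.

Because the index must always equal what the stored values imply (a
biconditional the tests rebuild and check), re-ingesting a sample first
retracts the stem memberships derived from its previous values. Without
that retraction, an updated record would leave phantom hits behind.

**Where-clauses** (`ph > 0 and empo_3=='Soil (non-saline)'`) are parsed by
a small recursive-descent parser: comparisons (`==`, `!=`, `<`, `<=`, `>`,
`>=`, `in`, `notin`/`not in`) joined by `and`/`or` with parentheses, `and`
binding tighter. Values stay raw strings; typing happens per comparison at
query time, because deposited metadata columns routinely mix numbers,
text and annotations:

- Ordering operators coerce the stored string to a number and *exclude*
  the sample when the value is missing or non-coercible. This is why
  `ph > 0` doubles as a has-valid-pH filter rather than an error.
- Equality and membership compare as exact strings unless both sides
  coerce numerically, in which case numeric equality is used (so
  `ph == 6.50` matches a stored `"6.5"`).

Evaluation is a linear scan over the candidate universe. At the intended
desk scale (thousands to tens of thousands of samples) this is
milliseconds; no numeric-range index structure is maintained.

## Query composition and extraction

`select_samples()` intersects whatever constraints are supplied — feature
presence (union or intersection over the feature list), a where-clause, a
full-text expression — and, when a context is given, the context's
samples-represented set. Since every constraint is a set, composition is
order-independent; the master property test checks every path, alone and
combined, against brute-force scans of the raw inputs on randomized
corpora.

`fetch_table()` rebuilds a count matrix from the stored vectors: columns
are the requested samples present in the context, rows the union of their
nonzero features, both lexicographic; a fetched table never contains an
all-zero row. Requesting samples none of which are in the context is a
distinct, named error — silence there would make an empty cross-context
fetch look like a real empty result. The BIOM writer is the package's own
deterministic JSON serializer (sparse representation, injectable timestamp
and generator tag), because byte-stable output given fixed inputs is what
makes export bundles verifiable by checksum; files it writes are re-read
by `biomformat` in the tests as a format-conformance check. HDF5 BIOM 2.1
is not written; reading works wherever `biomformat`'s HDF5 support is
available.

## The synthetic corpus generator

`generate_corpus()` emulates the structure this system is built to query:
a multi-study soil survey in which a few exact sequence variants associate
strongly with low- or high-pH samples. Per sample:

- pH ~ Uniform(3.5, 9.0) — a realistic span for surveyed soils;
- each low-pH differential feature is present with probability
  `plogis(β·(6.5 − pH))`, high-pH features mirrored; β defaults to 1.5
  log-odds per pH unit ("strong" association: presence odds change ~4.5×
  per pH unit);
- counts for the features present are multinomial over a Poisson(5000)
  sequencing depth, with background feature proportions drawn once per
  corpus from a Dirichlet, and differential features given a weight of
  three times the mean background weight so that presence usually survives
  sampling;
- metadata records study id, pH (3 decimals; 5% replaced by a missing
  marker to exercise the `ph > 0` filter), an `empo_3` column that is
  `"Soil (non-saline)"` except for a 10% decoy category, and a free-text
  description seeded with searchable words.

Default sizes are 5 studies × 80 samples, 5 + 5 differential features and
190 background features. All randomness flows from one integer seed, and
identical spec + seed yields byte-identical files (fixed embedded
timestamps); the generator writes exactly the formats the ingest side
reads, so it doubles as an end-to-end format test.
`generate_two_context_corpus()` additionally writes a
closed-reference-like second context: a seeded fraction (default 0.6) of
samples re-expressed in a reduced feature space by deterministically
aggregating exact sequences into reference OTU ids.

What the generator does *not* emulate: ecological covariance between taxa,
batch and primer effects, chimeras, uneven study sizes, or the biased
study composition of real repositories. Passing tests on this corpus
demonstrate that the indexing and query machinery is exact and that the
retrieval workflow recovers a planted covariate association; they say
nothing about biological effect sizes in real deposited data.

## The demonstration pipeline

`demo_ph_replication()` runs the full workflow: generate a corpus, load
every study into one Deblur-like context, ingest metadata and taxonomy,
retrieve samples containing *any* low-pH (resp. high-pH) differential
feature under the constraint `ph > 0 and empo_3=='Soil (non-saline)'`, and
compare the two groups' metadata pH with a two-sided Mann-Whitney
(Wilcoxon rank-sum) test, normal approximation (group sizes are in the
hundreds, where the exact null is both unavailable with ties and
unnecessary). A sample containing features from both sets appears in both
groups, as retrieval-based grouping implies. The acceptance suite runs
this across 20 seeds and requires p < 10⁻⁶ in at least 19 and the low-pH
group to have the lower median in all 20; at the default conditions the
observed p-values are typically below 10⁻¹⁵.

## Problem sizes and test design

The property suites run on randomized corpora of 5–50 samples × 10–200
features (up to two contexts) — 200 corpora for the master
oracle-equivalence property, with every query path compared against
brute-force scans; metadata properties use ~200 random clauses and
expressions over 50-sample tables. These sizes keep the full suite under
two minutes on one CPU while exercising every code path at sizes where
brute force is still exact and cheap. The demonstration uses the
generator's default 400-sample corpus. Scale-out behaviour (hundreds of
thousands of samples) is an explicit non-goal of the reference backend,
though nothing in the contract precludes a server-backed implementation.

## Known limitations

- Single-writer, in-process store; no concurrent mutation.
- Where-clause evaluation is a linear scan (no range indices).
- Exact-match feature and taxon search only; no k-mer or alignment-based
  approximate search, no hit ranking, and no prevalence statistics —
  repository composition biases make naive prevalence misleading.
- Full-text search covers ASCII alphanumeric tokens; the Porter stemmer is
  an English-language algorithm.
- HDF5 BIOM output is not implemented; JSON BIOM 1.0 is the interchange
  format.
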