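---
title: "rolhs: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rolhs: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem this package models

Radiotherapy departments accumulate patient data across electronic health
records, treatment-planning systems and delivery systems, each with its
own relational schema and local vocabulary. A learning health system
needs those data findable and queryable by *meaning* rather than by
table layout. The established pattern is: validate and clean the
relational exports, map every coded cell to a class of a shared ontology
(the radiation-oncology ontology extended with NCI Thesaurus concepts),
publish the result as an RDF knowledge graph, and answer cohort
questions by terminology-aware graph search. `rolhs` implements that
pattern end-to-end at desk scale, with a synthetic cohort standing in
for the (private) clinical warehouse, so that every step can be tested
against an independent oracle.

# The synthetic world

`generate_cohort()` emits seven relational tables (all-character
columns, as a CSV ingest would produce) for five diagnosis groups:
prostate, NSCLC, SCLC, breast, and head & neck. Group-conditional
vocabularies drive the attributes a real cohort would show — histology
and T/N/M distributions differ per group, Gleason grade group and a PSA
category exist only for prostate, toxicity types are organ-appropriate
(cystitis for prostate, esophagitis/pneumonitis for lung, dermatitis for
breast, xerostomia for head & neck; fatigue and nausea shared) — while
smoking status, ECOG performance status, race/ethnicity and treatment
intent are drawn from shared distributions so the groups overlap
realistically. Each patient carries 18–25 categorical attributes in
total (6 demographic, 3 diagnosis, 4–6 staging, 4 treatment, 2–4 graded
toxicities, 2 lab flags); the generator's tests assert that range
exactly. Dates are `YYYYMMDD`, the diagnosis date never follows the RT
start date, and prescription dose/fraction counts are consistent with
the sampled fractionation scheme — the cohort is *clean by
construction*, which is what makes the downstream validation oracles
sharp.

Choices not dictated by the source material, made once: vocabulary sizes
(4–9 values per attribute), one treatment course per patient, two lab
tests, 2–4 toxicities with grades 1–3 (grade weights 0.5/0.35/0.15), and
8×8×8 per-patient dose grids whose DVH summaries populate the
`dose_grid` table (the full grid is regenerable via
`cohort_dose_grid()`). These are documented constants of the fixture
world, not claims about any real registry.

What a green test does *not* establish: the synthetic cohort has no
longitudinal structure, no missingness beyond what is injected, no
free-text, and vocabularies far smaller than NCIT; results here
demonstrate correctness of the machinery, not clinical performance.

# ETL validation

Five checks: data type (integer/decimal parse), cross-field consistency
(RT start not before diagnosis; dependent elements — a recorded T stage
requires N and M, a prescription dose requires a fraction count),
mandatory keys, numeric range (marital status 1–9, ECOG 0–4, grades
1–5), and date format (`YYYYMMDD`). Guard semantics make check ownership
unambiguous: empty cells are skipped by everything except the mandatory
check, unparseable values belong to type/format, and the date comparison
runs only when both dates parse. This is why the error-injection oracle
can demand precision = recall = 1: each injected fault violates exactly
one named check, and injection avoids interactions (cross-field
corruption skips patients whose diagnosis date was format-corrupted).

The drop policy blanks the violating cell and keeps the row; mandatory
failures instead flag the row, whose blank key already prevents the
mapping compiler from minting a subject URI. Consequently cleaned tables
re-validate with zero violations for all cell-local checks, while
mandatory flags persist by design. For dependent-element violations the
*antecedent* cell is dropped (T stage recorded but N missing → drop T),
which preserves the fixed-point property.

Mapping completeness is `100·mapped/source` over value-bearing cells
(cells under literal or value-to-class bridges); structural triples
(rdf:type, relationships) are deliberately outside the denominator since
they are minted per row, not per source element.

# Relational → RDF mapping

The mapping spec is a JSON mirror of the D2RQ triad: class maps mint one
subject URI per row from a template (`{base}/patient/{patient_id}`;
deterministic, no UUIDs, so runs diff cleanly), property bridges attach
literals (with explicit datatypes; dates converted to ISO-8601) or
ontology classes via value lookups, and reference bridges link class
maps through their shared template columns. Two class maps may share a
URI template — the staging table writes onto the diagnosis node — which
stands in for a relational join without join machinery. Unknown lookup
values are skipped and logged, never invented; unresolvable class
*codes* in a spec are a hard error before compilation.

The triple store is an ordered, deduplicated data frame with three
positional indexes. Turtle output is deterministic (sorted prefixes,
one triple per line, sorted) and the bundled parser reads exactly that
line-oriented subset, reporting the offending line on failure. The BGP
engine implements textbook conjunctive-pattern join semantics by
successive merges; numeric range filtering is intentionally *not* part
of the pattern language (it would exceed BGP), and full SPARQL is a
non-goal.

# Ontology search

Term matching is case-insensitive, whitespace-normalized exact matching
against labels and synonyms — no stemming or fuzzy matching, since the
modelled behaviour is synonym lookup in a terminology, not information
retrieval. Expansion adds descendants up to `child_levels` (level 0
means the matched class only; "include children up to one level" on a
graded toxicity class pulls in exactly the grade-1/2/3 children) and,
optionally, ancestors up to `parent_levels` (default 1; transitive
closure to the root is configurable but not the default, as nothing
pins that behaviour). A patient matches when an expanded class URI
appears in object position anywhere in the patient's forward subgraph
within 3 hops — enough to reach attribute-node types
(patient → diagnosis → toxicity node → CTCAE class) without crossing
into other patients' nodes, which forward edges cannot do. Multiple
q-terms intersect (cohort-definition semantics); a union mode is a flag.

# Patient similarity

Each patient's individual knowledge graph (the same 3-hop forward
subgraph) yields `n = 10` sentences of at most `L = 20` tokens:
traversal is breadth-first from the patient node with the outgoing-edge
order of each node shuffled under a seeded RNG. This resolves the
tension in "breadth-first random walks" — the visit discipline is BFS,
the randomness is in neighbor order — and makes every sentence of a
small subgraph cover the same token *set* while varying order, which is
what windowed embedding models need. Tokens are class CURIEs, instance
IDs and normalized literals.

Four model kinds, all single-threaded and deterministic given a seed
(own xorshift RNG in compiled code): skip-gram with negative sampling
(window 5, 5 negatives, linearly decaying learning rate from 0.025);
the same trainer with character 3–5-gram subword composition (mean of
word + n-gram vectors) for the fasttext kind; PV-DBOW document vectors
for the doc2vec kind; and AdaGrad factorization of the 1/distance-
weighted co-occurrence matrix under the weighted least-squares objective
(x_max 10, exponent 0.75, eta 0.05) for the glove kind. Training runs
100 epochs by default. As a stand-in for pre-training on a full
terminology scrape (out of scope), one background sentence per ontology
class (code, label and synonym words, parent codes) is prepended to the
training corpus.

A patient vector is the mean of the patient's *distinct* token vectors
(mean rather than sum so that 18-attribute and 25-attribute patients are
comparable; distinct so walk repetition does not re-weight hub tokens),
or the trained document vector for doc2vec. Ranking uses cosine
(descending) or Euclidean/Manhattan/Minkowski distance (ascending;
Minkowski order defaults to 3 because orders 1 and 2 duplicate the other
two metrics), ties broken by patient ID. Cluster evaluation reports
mean pairwise cosine within each of the five diagnosis groups, the
pooled within-group mean, the between-group mean, and overall mean
pairwise distances — both the within-cluster and all-pairs cosine are
reported since the source material does not disambiguate; within-cluster
is treated as primary. The tested stochastic property is qualitative:
with equal group weights at n = 250, mean intra-group cosine exceeds
mean inter-group cosine for the word2vec kind across three seeds.

# DVH

The cumulative DVH uses uniform bin edges `0, w, 2w, …` spanning the
structure's maximum dose plus one bin; the value at each edge is the
exact fraction of masked voxels with dose ≥ edge (so refinement never
changes shared edges). `Vx` interpolates linearly between edges. `Dx`
is pinned as the minimum dose received by the hottest x% of the volume —
the exact voxel quantile when voxel doses are available, the
interpolated curve inverse otherwise; the two agree within one bin.
The quantile reading is the one consistent with "D95 of a uniform
6000 cGy structure is exactly 6000". Units are cGy end-to-end; Gy input
is converted explicitly at construction.

# Numerical and degenerate-input choices

* Ontology files are validated on load: unique non-empty codes,
  resolvable acyclic parents (cycle members are named), self-parenting
  rejected; traversal is level-bounded BFS with deduplication, so
  diamonds count ancestors once.
* Empty query results, empty expansions and empty stores are ordinary
  values, not errors; zero-vector cosine and empty-mask DVH are errors.
* All randomness flows from explicit integer seeds; derived seeds stay
  below 2^31. Reruns of the pipeline with the same config are
  byte-identical in Turtle, corpus and manifest.
* The `(N−k)/N` completeness identity is exercised with cell-local
  faults only; mandatory-key faults remove a whole row's elements at
  once and are covered by the ledger-recovery oracle instead.

# Known limitations

No OWL reasoning, no live terminology service, no SPARQL beyond BGP, no
DICOM parsing, no FHIR emission, no temporal similarity. Embedding
quality claims are limited to the separation property on the synthetic
world; absolute similarity values depend on the fixture vocabulary and
should not be compared to numbers obtained on clinical data.
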