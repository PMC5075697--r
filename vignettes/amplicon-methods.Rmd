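---
title: "Methods: amplicon search, clustering, dereplication, chimera detection and read merging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon search, clustering, dereplication, chimera detection and read merging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliconr)
```

ampliconr reimplements, in R with a compiled alignment core, the command
set that dominates marker-gene (16S/18S/ITS amplicon) preprocessing:
heuristic global-alignment search, greedy centroid clustering, full-length
and prefix dereplication, UCHIME-style chimera detection, DUST masking,
quality-aware merging of paired-end reads, FASTQ utilities, and
abundance-aware sorting, shuffling and subsampling. This vignette explains
the models and algorithms, the parameters that matter, the numerical
choices taken where the design was open, and what the synthetic fixtures
used in the test suite do and do not demonstrate about real data.

## Sequence comparison: the two-phase search

Every similarity-driven command (`usearch_global`, clustering, chimera
parent search) compares a query against a database in two phases.

**Phase 1 — shared words.** All overlapping words of length *k* (default
`wordlength = 8`) consisting solely of A/C/G/T are extracted from the
query, duplicates collapsed; a sequence of length *n* has at most
*n* − *k* + 1 unique words. An inverted index over the database maps each
of the 4^*k* word codes to the set of targets containing it, each target
counted at most once per word. Candidates must share at least
`minwordmatches` words (default 10, automatically lowered to the query's
unique word count when that is smaller, floored at one) and are visited in
the order: shared-word count descending, target length ascending, target
ordinal ascending. The final ordinal tie-break is our own choice, made so
the ranking is a total order independent of index construction order. The
index stores postings as plain integer vectors in a hashed environment;
representation (the classical bitmap-versus-list switch for very frequent
words) is behaviour-invisible, so a single representation is used.

**Phase 2 — optimal global alignment.** Each candidate is aligned with a
full dynamic program (Gotoh three-state recurrences) under affine gap
penalties in which *terminal* gap runs — runs touching either end of the
alignment — are priced separately from interior runs. A run of length *L*
costs `open + L × extend`. Defaults: match +2, mismatch −4, interior
open 20 / extend 2, terminal open 2 / extend 1, chosen for drop-in
compatibility with the wider tool family; every value is an argument of
`align_params()`. A gap run in the query sits at a single query position
*i* and is terminal exactly when *i* = 0 or *i* = *m*; this lets the DP
price terminal runs by making the penalty a function of the boundary
index, with no post-processing. When the product of the two lengths
exceeds 25 × 10⁶ (two 5,000 bp sequences), the aligner switches
automatically to a divide-and-conquer variant (Myers–Miller style: the
optimal path's crossing point on the middle row is found from a forward
and a mirrored backward linear-memory pass; only vertical gap runs can
cross a row split, so the combine step considers a free crossing and an
in-gap crossing per column) with identical scores and linear memory; a
`method` argument forces either path for testing.

Ambiguity codes: N against anything scores 0 and never counts as an
identity match; other IUPAC codes whose base sets intersect score as a
match but count toward identity only when textually equal after
normalisation (U→T, case folded). Traceback ties prefer diagonal, then
gap-in-query, then gap-in-target, giving one canonical optimal alignment.

Identity definitions (`iddef` 0–4) follow the classical menu: matches over
the shorter length (0), over all columns (1 and 4), over columns excluding
terminal gaps (2, the default), or over matches + mismatches + internal
gap *runs* (3). The exact historical semantics of definition 3 are not
fixed anywhere authoritative; the formula above is this package's
documented choice.

Two properties worth flagging because they are *not* theorems under this
scoring model: (i) appending an identical suffix to both sequences can
*decrease* the optimal score, because a cheap terminal gap in the shorter
problem becomes an expensive interior gap; the classical monotonicity
property holds only under uniform gap pricing, and the test suite asserts
it there. (ii) The score-only reference implementation used by the tests
(`.align_score_oracle_cpp`) shares the scoring model but none of the code
paths — full matrices, no traceback, a different state formulation — and
both are validated against exhaustive enumeration of all alignments on
tiny instances.

**The accept/reject loop.** Candidates are pre-filtered (`self`,
`minqsize`), aligned, post-filtered (`maxgaps` on internal gap columns,
`maxsubs` on mismatches), and accepted iff identity ≥ `id`. The loop ends
after `maxaccepts` acceptances (default 1) or `maxrejects` rejections
(default 32); zero means unlimited. A candidate failing any post-alignment
filter consumes one rejection; candidates excluded before alignment do
not. With `strand = "both"` the reverse complement is searched as well and
the better orientation per target is reported, ties resolved in favour of
plus. Hits are sorted by identity descending, target ordinal ascending.

## Greedy centroid clustering

`cluster_records()` processes sequences in input order (`smallmem`), by
length descending (`fast`) or abundance descending (`size`; ties by the
other key, then ordinal) and searches each against the current centroid
database. If at least one centroid is accepted, the query joins the
most similar accepted centroid (distance-based greedy clustering, DGC) or,
with `sizeorder = TRUE`, the most abundant accepted one (abundance-based,
AGC; among accepted candidates only, so `maxaccepts` bounds what AGC can
see); otherwise it becomes a new centroid. Clustering is sequential by
design; a `threads` argument is accepted for interface compatibility and
the result is identical for any value, which is the only behavioural
contract parallelism would have to honour anyway.

Per cluster, `center_star_msa()` merges the member↔centroid pairwise
alignments on the centroid coordinate ("once a gap, always a gap"):
insertion slots between centroid positions are widened to the longest
insertion observed, all rows padded to equal length. The consensus is the
abundance-weighted majority symbol per column, ties resolved by the fixed
order A < C < G < T < other letters < gap; gap columns are removed from
the consensus output.

## Dereplication and rereplication

Full-length dereplication collapses identical normalised sequences (U→T,
case-insensitive) with summed abundances, first-seen record as
representative, output sorted by abundance. The classical implementation
detail — an open-addressing CityHash table — is representation, not
behaviour; R environments keyed by the normalised sequence give identical
results, with equality always decided by full string comparison.

Prefix dereplication follows the published algorithm exactly: sort by
length, process shortest first, look up the full sequence and then every
shorter prefix down to the shortest input length; on a match, delete the
matched entry and insert the longer sequence with accumulated abundance.
Lookups use 64-bit FNV-1a hashes computed incrementally (every prefix of a
length-*n* sequence in O(*n*) total; `fnv1a64_prefixes()`), with hash
collisions resolved by comparison — a collision can slow a lookup, never
change a result. The documented ambiguity — a sequence that is a prefix
of several candidates — resolves to the shortest candidate, then the most
abundant, the lexicographically smaller label, the earliest input
position. Processing order realises this chain directly: within a length
class, records are processed by abundance descending, label ascending,
ordinal ascending. (Processing strictly by input order within a length
class, an alternative reading, would break the chain; the tie-break rules
are the substance, so the order serves them.)

`rereplicate()` expands abundance *n* into *n* unit records; original
labels are unrecoverable, so each copy keeps its representative's label.

## Chimera detection

Candidate parents for a query are found by splitting it into four
near-equal segments and searching each against the parent set with
`maxaccepts` 4, `maxrejects` 16 and identity threshold 0.55. De novo mode
(`uchime_denovo`) processes records by abundance descending and uses the
previously seen records as potential parents, requiring parent abundance
≥ `abskew` (default 2) times the query's.

Each parent pair (A, B) is evaluated on a three-way alignment built by
merging the query↔A and query↔B pairwise alignments on query coordinates.
Per column, with the chimeric model being one parent up to a crossover
column and the other after it: the query votes **yes** when it matches the
model and differs from the other parent, **no** when it differs from the
model where the parents differ, and abstains otherwise. The score is

\[ h = \frac{Y}{\beta\,(N + d_n)} \]

with β (`xn`) = 8 and pseudo-count `dn` = 1.4, maximised exhaustively over
all crossover columns and both parent orders (queries are amplicon-length;
no windowing is needed). A crossover only counts when each side
contributes at least one yes vote — otherwise the "model" degenerates to a
single parent and a query identical to one parent would score as its own
chimera. Votes are aggregated over the whole three-way alignment at the
best crossover; per-segment aggregation variants of the original
heuristic would differ at most in candidate generation, which the
four-segment search already covers.

Divergence is 100 × (identity of query to the model − identity to the
best single parent), identities computed over non-double-gap columns of
the three-way alignment. Classification: *chimeric* when `h ≥ minh`
(default 0.28) and divergence ≥ `mindiv` (default 0.8%); *borderline*
when the score passes but divergence does not; *non-chimeric* otherwise.
The four scoring constants are exposed as options so the formula is
auditable.

## DUST low-complexity masking

Windows of length 64 step 32 slide over the sequence; within a window,
every subinterval ending at each cursor position is scored as
Σ c_t(c_t−1)/2 over its triplet counts divided by (triplets − 1),
maintained incrementally. The window's maximal-scoring subinterval is
masked when 10 × score > `level` (default 20); triplets containing
non-ACGT symbols are skipped; intervals merge. Soft masking lowercases
(losslessly — uppercase recovers the input), hard masking writes N.
Search, clustering and chimera commands soft-mask with DUST by default
(`qmask`/`dbmask` ∈ none/dust/soft); masked (lowercase) positions are
excluded from word indexing and counting but alignment always uses the
full sequence, so masking only affects candidate generation.

## Merging of paired-end reads

The merger scans every ungapped placement of the reverse-complemented
reverse read against the forward read with overlap ≥ `minovlen` (default
10), including staggered placements. Per overlapped column with error
probabilities p₁, p₂, an observed-equal column contributes
α·P + β·(1−P) with P = (1−p₁)(1−p₂) + p₁p₂/3 — the probability the
true bases match under uniform 0.25 backgrounds — and an
observed-different column contributes β·P′ + α·(1−P′) with
P′ = 1 − [(1−p₁)p₂/3 + (1−p₂)p₁/3 + 2p₁p₂/9], the probability the true
bases differ given the observation (one read in error toward the other's
base, or both in error onto a common third base). α = +4 and β = −5 are
attained exactly at perfect quality. Per-quality terms are precomputed as
lookup tables. The best-scoring placement wins; score ties go to the
smaller overlap (documented choice). The pair is rejected when the best
placement is staggered without `allow_stagger` (staggered placements are
scanned regardless, because ignoring them would let a spurious
non-staggered placement win), when observed mismatches exceed `maxdiffs`
(default 5), or when the merged length leaves
[`minmergelen`, `maxmergelen`]. Stagger overhangs are trimmed before
scoring, so only genuinely paired columns contribute.

Merged overlap columns take the consensus base — the higher-quality base
on disagreement, the forward base on exact quality ties — with posterior
qualities: on agreement p = (p₁p₂/3)/(1 − p₁ − p₂ + 4p₁p₂/3), on
disagreement (keeping the base with smaller p₁)
p = p₁(1 − p₂/3)/(p₁ + p₂ − 4p₁p₂/3), reported as round(−10·log₁₀p)
capped at `qmax_out` (default 41). A caveat the formulas imply: a read
with quality < 2 has error probability above 3/4, i.e. it is worse than
uninformative under a uniform background, so agreement with it can
*lower* the posterior below max(q₁,q₂) and disagreement can raise it.
The monotonicity properties are therefore stated, and tested, for
qualities ≥ 2; the formulas themselves hold everywhere.

## FASTQ utilities

`fastq_chars()` reports the quality character range and guesses the
offset: any code below 59 forces Phred+33; all codes ≥ 64 suggest
Phred+64 (flagged ambiguous, with both interpretations reported, since
high-quality +33 files occupy the same range); anything else is reported
as +33. Expected errors EE = Σ 10^(−q/10). `fastq_filter()` applies its
criteria in a fixed documented order: strip ends → truncate at the first
quality below `truncqual` → truncate to `trunclen` (discarding shorter
reads) → length bounds → N count → EE thresholds on the final read.
`fastq_stats()` tabulates per-position quartiles and EE-versus-truncation
tables; the exact column layout is this package's own. Encoding
conversion re-encodes the same quality values under the other offset,
clamping to `[qmin_out, qmax_out]`.

## Sorting, shuffling, subsampling

Sorting is a stable descending sort by length or abundance. Randomised
commands take an explicit integer seed (`0` = time-derived) and use R's
Mersenne–Twister with rejection sampling — a named, platform-stable
generator, so `randseed` reproduces byte-identical output everywhere;
shuffling is Fisher–Yates via `sample.int`. Abundance-aware subsampling
draws reads without replacement as if the records had been rereplicated,
sampled and dereplicated, without materialising the expansion: each
record's kept count is drawn from the sequential (conditional)
hypergeometric via `stats::rhyper`, giving exactly the multivariate
hypergeometric marginals — unbiased for abundant and rare amplicons
alike. Percentages convert to unit counts by rounding half up.

## Synthetic data and what the tests show

The fixture generators are first-class, seeded, pure functions:

* `make_families()` — independent random templates (mutual identity
  ≈ 25%, far below any clustering threshold) with members mutated at an
  exact substitution count (`round(n × rate)`), so stated divergence
  bounds hold by construction rather than on average; templates get the
  highest abundance in their family so abundance-ordered clustering seeds
  on them, making the member-to-centroid identity bound exact.
* `make_chimeras()` — parent pairs at controlled mutual identity with
  mid-sequence breakpoints and abskew-respecting abundances.
* `make_read_pairs()` — random templates with exact overlap lengths,
  constant or linearly decaying qualities, and optionally planted
  substitutions at recorded overlap columns.

These fixtures emulate clean, substitution-dominated amplicon data. They
do not emulate indel-rich platforms, position-dependent or motif-dependent
error profiles, PCR abundance skews correlated with sequence content, or
reference databases with taxonomic structure. Passing tests therefore
demonstrate algorithmic correctness (agreement with oracles, exact
recovery under constructions whose ground truth is guaranteed), not
field performance on any particular instrument's data.

Problem sizes in the default test run were chosen to keep the full suite
under a minute of compute while still exercising every code path at
non-trivial scale: 500 oracle-checked alignments up to 300 bp, a 100×100
word-count instance, 50-sequence search fixtures, 2–20 families for
clustering, 100 chimera constructions, 10,000 merged pairs, 10,000
subsampling draws.

## Known limitations

* Single-threaded; `threads` is interface plumbing only.
* Gap penalties are integer-valued (scores are exact integers).
* bzip2 transport is not supported (gzip is); SAM output, UDB databases,
  local alignment and protein alphabets are out of scope.
* De novo chimera detection tests each record against all previously
  processed records, regardless of their own classification — detected
  chimeras are not removed from the parent pool.
* The DUST subinterval enumeration considers all subintervals ending at
  the window cursor (the canonical recurrence); masked output near window
  boundaries can shift by up to one window step relative to
  implementations that enumerate differently.
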