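---
title: "Methods: rank-threshold deconvolution of 3-D pooled insertion libraries"
author: "poolcube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-threshold deconvolution of 3-D pooled insertion libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolcube)
```

## The experimental design and its deconvolution problem

A sequence-indexed insertion resource places one sample per well of a
plate × row × column cube and sequences one target-enriched library per
pool: `P + R + C` libraries for `P × R × C` samples. Each sample's insertion
flank is PCR-enriched with a primer anchored in the inserted element, so the
reads of a genuine flank are abundant in exactly the three pools containing
its well and (ideally) absent elsewhere. Deconvolution is the inverse
problem: given per-pool read sets, recover each flank's well.

The method is deliberately non-probabilistic: it relies on *coverage ranks*
within each pool, not on absolute read counts or a noise model. The premise
is that targeted sequences are amplified and sequenced far more deeply than
noise, so whatever the library sizes and amplification biases are, genuine
elements populate the top of each pool's coverage ranking.

## Read filtering model

Every genuine read starts with a technical prefix:
`barcode + primer + identifier`, where the identifier is a short piece of
the element terminus that guards against mispriming (a misprimed product
carries the primer but not the element terminus). Filtering is
substitution-only (Hamming): an indel in the prefix would shift the trim
offset and corrupt the index slice, so indel-tolerant matching buys little
and costs determinism. The barcode is matched exactly, because it is the
demultiplexing key; primer and identifier each carry a configurable
mismatch allowance (defaults used in the tests: 2 and 1). An `N` never
matches. After trimming, the first `index_length` bases are sliced off as
the read's sequence index. `index_length` defaults to 8, the target-site
duplication length of Ds-family transposons; it is a config parameter
because different element families duplicate different lengths.

Reads shorter than `prefix + index_length` and reads whose index is a known
endogenous element are dropped and *counted*, never fatal: the filter
statistics obey two conservation laws
(`total = matched + dropped_no_match`,
`matched = retained + dropped_endogenous + dropped_short`) that the test
suite asserts on every simulated library.

## Coverage and ranking

Within one library, the coverage of an index is its read count divided by
the library's total retained reads. Normalisation by library size removes
between-pool depth differences; any monotone rescaling (e.g. per-million)
would yield identical ranks and therefore identical assignments. Ties are
broken by descending raw count, then lexicographic index — an arbitrary but
deterministic and platform-independent rule, so a re-run is byte-identical.
Each index also keeps a representative full-length read (the modal trimmed
sequence, lexicographically smallest on ties) so reports and the
downstream FASTA contain a real read, not an 8-mer.

The store behind this is a single-file embedded SQLite database with one
table per (element end × library) — `N × L` tables of
(index_seq, trimmed_seq, read_id) — with all SQL generated internally.

## Candidate bounds and the two grades

A plate pool is expected to contain `R × C` genuine elements, so its
Grade-1 candidate set is the top `floor(TH_G1 × R × C)` effective ranks
(`TH_G1` default 1.5; analogous bounds in the other dimensions). The factor
1.5 admits 50% headroom for rank jitter; it is exposed because noisier read
sets warrant a larger factor. `floor()` is used because fractional
thresholds times expected counts are generally non-integral and a candidate
bound must be a rank.

* **Grade-1**: candidate in exactly one pool of each dimension → assigned
  to the intersection well.
* **Grade-2**: exactly two dimensions with unique Grade-1 candidacy, and in
  the third dimension no Grade-1 pool but exactly one pool within the
  relaxed bound `floor(TH_G2 × expected)` (`TH_G2` default 3, constrained
  `TH_G2 ≥ TH_G1`). The relaxed bound is constructed in strict parallel to
  the Grade-1 bound — the minimal reading consistent with "beyond Grade-1
  range but high enough for Grade-2". If the weak dimension offers two or
  more relaxed pools the element is reported ambiguous and never assigned;
  the intent behind a forced choice would be unverifiable.
* **Multi-well**: candidacy in several pools of some dimension (with at
  least one everywhere) yields the full cross-product of implied wells.
  This is the expected signature of a premeiotic transposition inherited by
  several progeny, so it is reported, flagged, and the implied wells are
  not treated as unresolved. Beyond 8 implied wells the pattern is far more
  likely background than a premeiotic event, and the index is reclassified
  "suspected endogenous" (the cap is a pragmatic guard, config-exposed).
* Two indices landing in one well are both kept and flagged ambiguous —
  arbitration by rank would hide a real collision signal.

Assignments are emitted in deterministic (plate, row, column, index) order.

## Endogenous inference

Host-genome relatives of the target element amplify in most or all pools,
not three. An index *prominent* in strictly more than 50% of all pools is
inferred endogenous. "Prominent" is not defined independently in the
source method; here it reuses the Grade-1 candidacy bound (rank within
`floor(f × expected)`, `f` defaulting to `TH_G1`), giving one coherent
notion of "high coverage" throughout; the fraction is separately
configurable. The strict inequality matters at the boundary: in a 30-pool
design, 16 prominent pools is endogenous, 15 is not — asserted exactly in
the tests. Inference runs *before* candidate ranking and the inferred
indices are excluded from it, with ranks recomputed among the remaining
indices ("top N after exclusion"): endogenous reads are precisely the reads
that would otherwise crowd genuine elements out of the candidate bounds.
Inferred indices can be fed back to the read filter as `known_endogenous`.

## Element mapping

No aligner is run: BLAST 12-column tabular or SAM output for the assigned
flank FASTA is parsed, coordinates normalised to 1-based inclusive
forward-strand intervals. Per query, hits below 95% identity or 80% of the
query length are discarded (both config-exposed; the source method states
no thresholds, so these are defaults, not claims); zero survivors =
unmapped, one = unique, and a runner-up within 90% of the best score =
multiple (repetitive region). The insertion point is the flank-proximal hit
coordinate — the trimmed read begins with the TSD at the element junction,
so this approximates the insertion site to within the TSD length. Gene
context against a GFF3 gene model: `exon(k of n)` with exons numbered in
transcription order, `intron`, `within_1kb_upstream` / `downstream`
measured from the gene span (strand-aware), else `intergenic`. The ±1 kb
window is the conventional promoter/terminator-proximal band for calling a
likely knockout. A well whose 5′ and 3′ flanks both map uniquely to the
same chromosome within `2 × index_length` bp (one TSD span) is flagged
paired — the strongest internal evidence that both sequences are genuine.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults define the reference study conditions used by the
test suite: a 4 × 4 × 6 cube (96 wells, 14 pools), 10,000 reads per pool,
lognormal per-element amplification weights with `sigma = 0.5`
(multiplicative PCR bias — the simplest generative model consistent with
deep-but-variable target coverage), 10% noise reads and 0.5% i.i.d.
substitution error. Problem sizes throughout the suite (3×3×3 unit cubes,
the 4×4×6 acceptance cube, 10⁵-read coverage oracles, 100 random oracle
instances, 1,000 random annotation cases) were chosen as the smallest sizes
at which each property is meaningfully exercised.

Noise is split half-and-half:

* **Misprimed** reads carry the correct prefix but an off-target genomic
  fragment. They are drawn from a per-pool set of `n_noise_loci` (default
  40) random loci with lognormal weights, not as i.i.d. random sequence:
  misprimed PCR products are clonal amplicons, and it is precisely their
  coverage continuum between genuine elements and singletons that makes
  the Grade-2 band non-empty in practice. Off-target loci whose leading
  k-mer collides with a genuine truth index are resampled, keeping the
  ground-truth ledger exact.
* **Junk** reads are uniform random sequence without the primer, so the
  reject branch of the filter is exercised too.

Per-pool attenuation divides the genuine elements' weights in one pool
while the noise keeps its unattenuated scale, shifting that pool's
genuine:noise balance — the mechanism by which real pools go "not-so-good".
Under the default conditions a 20× attenuation demotes the weakest few
elements of that pool past the Grade-1 bound into the Grade-2 band; the
acceptance suite asserts that every such well is still recovered, that all
Grade-2 wells lie in the attenuated pool, and that nothing is misassigned.
Endogenous spike-ins appear in every pool at a copy multiplier; duplicate
wells share one insertion (premeiotic mimic). Each pool's RNG stream is
keyed by `(seed, pool, end)`, so outputs are independent of generation
order and byte-identical across re-runs.

The 5′ read is modelled as the reverse complement of
`(upstream flank + TSD)`, so both ends share one underlying TSD while each
end's trimmed read aligns contiguously to the reference (the 5′ index is
`revcomp(TSD)`); truth-derived idealised alignments (`truth_alignments()`)
let the mapping stage be tested without an aligner.

Deliberately not modelled: PCR chimeras, indel errors, realistic quality
strings (constant qualities are emitted), barcode cross-talk, and
uneven well occupancy. Consequently, passing tests demonstrate the
*algorithmic* correctness of filtering, ranking, grading and annotation
under controlled violations (noise, attenuation, endogenous background,
duplicates) — they do not certify recovery rates on real libraries, whose
noise structure is richer.

## Numerical and degenerate-input choices

* Candidate bounds use `floor()`; pools with fewer indices than a bound
  contribute all of them.
* All sequence comparison is upper-cased; filtering is order-preserving
  and two runs yield byte-identical output.
* Empty inputs are empty outputs, not errors: an empty library gives an
  empty coverage table; a deconvolution with no assignments still writes
  valid (empty) FASTA/TSV/HTML reports.
* Malformed FASTQ (line count not a multiple of 4, parse failures) is a
  hard error naming the record offset; malformed BLAST lines name the line
  number. Bad *reads* are counted, not fatal.
* A hit on a chromosome absent from the annotation classifies as
  intergenic with a warning, signalling an annotation/genome mismatch
  rather than failing the run; GFF3 `##sequence-region` pragmas are
  honoured so feature-less chromosomes count as covered.
* Raising `TH_G1` can only grow candidate sets; an assignment unique at a
  lower threshold is either reproduced or flagged (multi-well/ambiguous) at
  a higher one, never silently moved — asserted as a property test.

## Known limitations

* Only 3-D designs are validated; the data model would extend to more
  dimensions but no logic beyond three is tested.
* Exons must carry `Parent` attributes referring directly to gene IDs;
  transcript-level GFF3 hierarchies (gene → mRNA → exon) are not resolved.
* The unique-locus criterion (identity/length/score-margin) is a
  configurable operationalisation, not a calibrated claim about any
  particular genome.
* No statistical confidence accompanies assignments; the method is
  rank-threshold based by design.
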