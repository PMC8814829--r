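---
title: "Methods: exosomal versus whole-milk small RNA-seq analysis with exomir"
author: "exomir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exosomal versus whole-milk small RNA-seq analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`exomir` implements a complete small RNA-seq comparison of miRNA content
between milk exosomes and whole milk: read cleaning with explicit
composition filters, mature-miRNA quantification on pre-miRNA hairpins
via a positional counting window, differential abundance with a
conditional negative-binomial exact test and a two-tier fold-change
classification, genomic clustering and seed-family annotation of the
upregulated set, and miRNA target prediction in 3' UTRs by seed
matching with nearest-neighbor duplex free-energy scoring.

Because the original raw libraries, the reference miRNA catalogue, and
the pig transcriptome are not bundled, the package ships a first-class
synthetic-data generator that emulates the two-condition design
(three biological replicates per condition) with known per-miRNA ground truth.
Every pipeline stage is tested against that truth and against
independent brute-force oracles. The `analysis/` scripts in the source
repository run the whole workflow on one synthetic study.

# Read cleaning

Reads are processed through a fixed cascade; each read is removed at
the first failing stage and the accounting identity
`input = surviving + sum(removed)` is exact:

1. **3' adapter trimming.** The suffix starting at the leftmost
   position where an adapter *prefix* of at least `min_overlap = 5`
   bases matches exactly (0 mismatches) is removed. Either the full
   adapter occurs at that position or the remainder of the read equals
   an adapter prefix. Exact prefix matching with a 5-nt minimum
   overlap is the simplest fully testable trimming rule, and the default adapter is
   the TruSeq small-RNA 3' adapter used by the library kit.
2. **Length bounds.** Reads shorter than 18 nt are discarded
   (`too_short`); reads longer than 34 nt (`too_long`), the upper end
   of the observed miRNA length range, are likewise removed. Both
   bounds are inclusive.
3. **Composition filters.** `mono_composition` fires when any single
   base makes up at least 80% of the read (the threshold is read as
   inclusive); `ac_only` / `gt_only` when the read alphabet is a subset
   of {A,C} / {G,T}; `dimer_repeat` / `trimer_repeat` when the read is
   a tandem repeat of a 2-mer / 3-mer, allowing one trailing partial
   unit. "Continuous nucleotide dimers or trimers" is interpreted as
   whole-read tandem repeats — the standard low-complexity filter for
   small-RNA data — because homopolymer runs are already caught by the
   80% rule. Reads containing N are removed (`ambiguous_base`); the
   protocol is silent on ambiguous bases. Flags are computed
   independently and may co-occur; removal is attributed by a fixed
   priority (mono, ac, gt, dimer, trimer, ambiguous) so that accounting
   is deterministic.
4. **Contaminant subtraction.** A read is a contaminant iff it occurs
   as an exact substring of any sequence in the user-supplied
   rRNA/tRNA/snRNA/repeat (and optionally mRNA) set, on either strand.
   This folds the database-comparison step into a single exact-match
   filter against whatever contaminant catalogue the user provides.

The ordering of the composition rules relative to each other is not
fixed by the protocol being reproduced; the cascade above is explicit
and logged, and the per-reason counts are emitted per library.

# Quantification: the positional counting window

Clean reads are matched exactly (0 mismatches) as substrings of the
hairpin sequences. A read matching several hairpins or positions is
assigned deterministically to the lexicographically lowest hairpin
name, then the leftmost position; fractional multi-mapping assignment
was rejected for the sake of reproducibility and testability.

A mature miRNA annotated at `[x, y]` on its hairpin accumulates a read
aligned at `[s, e]` on the same hairpin iff

    s >= x - 2   and   e <= y + 5,

i.e. the read span is fully contained in the tolerance window
`[x-2, y+5]`. The window absorbs the 5'/3' isomiR end variation typical
of miRNA processing. Containment of the full span (rather than a
start-only condition) is chosen because simulated isomiR offsets of
−2…0 at the 5' end and 0…+5 at the 3' end then reproduce the rule
exactly. A read eligible for several matures on one hairpin counts
toward the mature with the smallest `|s - x|`, ties to the lower `x`;
each read counts at most once.

Per sample, the library size is the number of aligned reads and the
unique count is the number of distinct aligned sequences; the mapping
census (pre-miRNAs hit, matures hit, unique mapped, total mapped) is
emitted as a standard census table.

# Differential abundance

Counts are normalized as counts per million mapped reads (CPM) using
total mapped reads as the library size. No trimmed-mean normalization
is applied — total-count scaling is the simplest defensible choice and
is stated here explicitly.

**Dispersion.** A single negative-binomial dispersion `phi`
(`variance = mu + phi * mu^2`) is estimated by pooled method of
moments on counts scaled to the geometric-mean library size: per
miRNA and condition, the moment relation `v - m = phi * m^2` is pooled
as `phi = sum(v - m) / sum(m^2 - v/n)`, with the denominator the
unbiased estimator of `mu^2`, floored at zero. With 2000 features this
recovers simulated dispersions well (see the test suite) and is fully
deterministic.

**Exact test.** For each miRNA, per-condition counts are scaled to the
common effective library size, rounded, and summed into `(sumA, sumB)`.
Conditional on `s = sumA + sumB`, the null split follows

    P(a) ∝ C(a + rA - 1, a) * C(s - a + rB - 1, s - a),
    rA = nA / phi,  rB = nB / phi,

which is free of the unknown mean because both condition sums share
the negative-binomial probability parameter; at `phi = 0` it reduces to
`Binomial(s, nA / (nA + nB))`. The two-sided p-value sums the
probabilities of all splits no more likely than the observed one (so
`p = 1` when the observed split is the conditional mode). The
implementation enumerates all `s + 1` splits in log space; the test
suite checks it against an independent enumeration built from
`dnbinom` products for every total up to 200.

**Ratios and marks.** The linear fold change is
`(meanCpmB + pseudo) / (meanCpmA + pseudo)` with a pseudocount equal to
the CPM value of 0.5 reads at the smallest library. The pseudocount is
required because a miRNA can be entirely absent from one condition
(a miRNA detected only in exosomes, with zero whole-milk counts, must
still get a finite ratio). Classification is two-tier and symmetric: at
significance `p < 0.05`, a ratio above 2 (below 1/2) is marked
UP (DOWN) at the first tier ("different") and above 10 (below 1/10) at
the second ("significantly different"). Enrichment tables of this kind conventionally list only UP marks;
the implementation is directional both ways.

Published enrichment ratios are often not reconstructible from the
raw counts printed beside them, because the normalization behind them
is rarely stated; `exomir` therefore defines its ratio explicitly as
above and makes no claim to match any externally printed ratio from
its raw counts.

**Compositional closure.** Because CPM are relative, enriching some
miRNAs necessarily deflates the apparent abundance of all others: if
the truth multiplies baseline relative abundances `b_i` by folds
`f_i`, the recoverable CPM-scale effect is `f_i / sum(b * f)`, not
`f_i`. The simulator records this `effective_fold` alongside the
nominal one, and the analysis scripts evaluate recovery against it.
This mirrors the real data, where the most enriched miRNA makes up a
large share of the exosome library.

# Annotation of the upregulated set

**Genomic clusters.** Pre-miRNAs on the same chromosome are chained by
single linkage: sorted by start, an interval joins the current chain
when the gap to the running end (next start − max end so far − 1,
floored at 0 for overlaps) is at most `max_gap = 10000` bp. Chains
with at least two members are reported. Design choices where the rule
"within 10 kb" is ambiguous: the gap is measured end-to-start (both
published example clusters, with gaps 0 and 671 bp, satisfy it);
strand is ignored for linking and reported per member; singletons are
not clusters. Single-linkage chaining with a running maximum is
provably identical to the transitive closure of the pairwise
gap ≤ max_gap relation, and the tests verify this equivalence on random
interval sets. The published locus strings
(`name (chrom_start_end_strand)`) are parsed directly.

**Seed families.** The seed is mature positions 2–8 (1-based), a 7-mer
under the TargetScan convention; matures sharing an identical seed form
one family. Family names come from an optional seed-to-name lookup
table; otherwise names are synthesized as `seed:<7-mer>`.

# Target prediction

**Site scan.** For each mature and UTR, all occurrences of the reverse
complement of the seed are located: `7mer-m8` (match to positions
2–8), `8mer` (the same followed by an A opposite position 1), and
`7mer-A1` (match to positions 2–7 followed by an A). Overlapping sites
are all reported; each span is reported once with its strongest class.
The site taxonomy is the canonical one; the energy threshold, not a
particular external prediction tool, defines the method.

**Duplex energy.** Each site, extended by 15 nt of upstream UTR
context (where the miRNA 3' region can pair), is scored against the
full mature sequence by dynamic programming over an intermolecular
duplex: nearest-neighbor stacks for Watson–Crick and G·U wobble pairs,
length-dependent bulge and interior-loop initiation with a capped
asymmetry (NINIO) term, a duplex-initiation term, and terminal AU/GU
penalties at both helix ends; no intramolecular structure and no
target-accessibility model. The parameter set is the Turner 2004 RNA
table (Xia et al. 1998 Watson–Crick stacks; Mathews et al. 1999 wobble
stacks) embedded as versioned data and exposed via `nn_parameters()` so
tests can recompute energies by direct table summation. The loop model
is deliberately simple (no terminal-mismatch or special small-loop
tables); for the deep, near-perfect duplexes that matter at the
threshold this underestimates stability only mildly and identically
across candidates. Loops are capped at 10 unpaired bases per strand.
Sites with `dG < -20` kcal/mol are retained; a gene is a predicted
target of a miRNA iff at least one retained site exists in any of its
transcripts. Gene-level summaries count distinct (miRNA, gene) pairs.

With these choices, a planted perfect 22-mer complement scores around
−35 to −40 kcal/mol (retained), while an isolated 7-mer seed match in
an otherwise non-complementary context scores far above −20
(rejected): the threshold separates full-length complementarity from
seed-only matches, which is the qualitative behavior the −20 kcal/mol
default encodes.

# The synthetic-data generator

`make_reference()` builds hairpins of 60–120 nt, each embedding one
mature of 18–24 nt (length distribution peaked at 22 nt, as in real
mature catalogues), placed so that the counting window and the wider
straggler offsets stay inside the hairpin. Hairpin sequences are
re-drawn until no achievable read trips a composition filter or embeds
the adapter prefix — without this, a skewed window would silently
remove genuine reads and break truth accounting. Genomic placements
put hairpins 1 and 2 within 500 bp on one chromosome (to exercise
clustering) and space all others at least 50 kb apart (isolated).
UTRs of 200–2000 nt carry planted, non-overlapping perfect
reverse-complement sites for at least three matures. Contaminant
surrogates stand in for rRNA/tRNA/snRNA/repeat catalogues.

`make_truth()` fixes the simulated study conditions: three replicates per
condition, 1e5 reads per replicate (the real clean-read totals are
~1e7; the default is scaled down two orders of magnitude to keep the
full round trip fast at identical statistical structure), log-normal
baseline abundances (sdlog 1.5) weighted toward 22-nt matures so
aggregate libraries peak at 22 nt as real milk libraries do,
per-replicate gamma scaling of the multinomial means with dispersion
0.05 (with three biological replicates per group and no stated noise
model, gamma-Poisson is the field's standard choice), per-class junk-read
fractions (1% each of mono/AC/GT/dimer/trimer reads, 2% contaminant
fragments), and a 2% "straggler" fraction of genuine reads drawn with
5' offsets {−4,−3} outside the counting window to test exclusion.

`simulate_libraries()` draws genuine reads from the mature windows with
5' offsets in {−2..0} and 3' offsets in {0..+5} — exactly the spans the
counting rule accepts — with offsets weighted half toward the canonical
form and half toward total length 22. Every read has the 3' adapter
appended and is truncated to the 36-nt instrument read length; genuine
spans are at most 31 nt, so at least 5 adapter bases always remain and
trimming is unambiguous. Junk reads are constructed per class to fail
exactly their own filter (e.g. the mono class is ≥80% one base with
the remainder drawn from the opposite alphabet group so no other flag
fires first; contaminant fragments are re-drawn until they pass the
composition stage). Quality strings are constant 'I' (Phred 40):
qualities play no role in any filter. The truth table records, per
miRNA/condition/replicate, the realized (post-gamma) expected count,
the expected in-window count, the simulated count, and the nominal and
effective fold changes. Identical inputs and seed yield byte-identical
FASTQ output.

What the generator does *not* emulate: sequencing errors, quality-score
variation, PCR duplicates, cross-mapping between homologous hairpins,
and real secondary-structure constraints on hairpin sequence. Passing
round-trip tests therefore demonstrates correctness of the pipeline's
logic under the stated read model, not robustness to base-call noise.

# Numerical and interface conventions

* DNA alphabet everywhere in memory; U→T on every ingest point.
* Hairpin-relative coordinates are 1-based inclusive in memory and in
  GFF3; BED on disk is 0-based half-open, converted only in the
  reader/writer pair.
* Tie-breaks are deterministic throughout (lexicographic hairpin,
  leftmost position, lower `x`, fixed composition-flag priority), so
  every stage is invariant to read order.
* p-value ties in the exact test are compared with a relative
  tolerance of 1e-10 to keep the discrete tail sum stable against
  floating-point rounding.
* The pipeline driver (`run_pipeline()`) validates formats first
  (FASTQ 4-line structure, FASTA headers, GFF3 spans within hairpins,
  BED sanity), halts at the first failing stage with a stage-named
  error, and records an md5 manifest of every emitted table; reruns
  with the same config are byte-identical.
* Single-threaded by design; no output depends on parallel scheduling.

# Problem sizes used in the shipped studies

The bundled analysis uses 60 hairpins, 30 UTRs, and 3+3 libraries of
1e5 reads; the test suite's end-to-end round trip uses 40 hairpins and
the same depth, and its statistical calibration uses 2000 features at
3 versus 3 replicates. These sizes were chosen so that the complete
workflow and test suite run comfortably on a laptop while keeping
every statistical check well-powered.

# Known limitations

* The exact test uses a common dispersion; no per-miRNA (tagwise)
  shrinkage, and no multiple-testing correction (the reproduced
  analysis applies none).
* Target prediction has no conservation filter, no accessibility
  model, and scores one site at a time; absolute energies from the
  simplified loop model should be read as a ranking device around the
  −20 kcal/mol threshold, not as physical free energies to the last
  decimal.
* Contaminant subtraction is exact-match only; diverged contaminant
  copies will not be caught.
* Novel-miRNA discovery and pathway mapping are out of scope.
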