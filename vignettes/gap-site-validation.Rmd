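---
title: "Validating splice-junction gap-sites with gqs and wgis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating splice-junction gap-sites with gqs and wgis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapsites)
library(data.table)
```

## The problem

Spliced aligners report gapped alignments wherever a read spans an
exon-exon junction of the mRNA it was sequenced from. The genomic location
of such an alignment gap — keyed by `(seqid, lend, rstart)`, where `lend`
is the last aligned base left of the gap and `rstart` the first aligned
base right of it — is a *gap-site*, a candidate splice junction. Aligners
report gap-sites with a substantial false-discovery rate, and because
standard RNA-seq protocols lose strand information, even a correct
junction cannot immediately be assigned to a strand. This package
validates gap-sites with two scores and infers the strand from the genomic
sequence.

## Evidence accumulation

Evidence arrives sequentially — alignment by alignment, sample by sample —
which dictates two properties of any per-site statistic:

* **Monotonicity.** Adding alignments must never decrease a score, so
  means or medians are unusable. We therefore keep only order statistics
  and saturating counters: the count of supporting alignments (`nAligns`),
  the set of *distinct left alignment start positions* saturating at a
  capacity `n` (its size is `nlstart`), the four largest values of `mcl`
  (the smaller of the two matched-segment lengths flanking a gap) whose
  sum is the quartet sum `qsm`, and the sample multiplicity `nProbes`.
* **An informational limit.** Once a junction is sufficiently confirmed,
  further evidence carries no information, so per-site storage is bounded:
  at most `n` starts, at most four `mcl` values (each capped at 255, a
  byte-packing convention inherited from compact integer containers).

The capacity is fixed at `n = 8` everywhere rather than tied to the host
word size, so results are identical across machines; `n = 4` remains
available as an argument for compatibility with the smaller-capacity
variant.

Within a CIGAR string, the matched-segment length on each side of an `N`
operation sums all `M`/`=`/`X` runs of the adjacent segment (segments
delimited by read ends or neighbouring `N`s). Deletions consume reference
but are not matches, so they contribute span, not support. A gap whose
flank contains no match at all is biologically meaningless and is rejected
into a diagnostics tally rather than silently kept.

Merging records is defined so that split-and-merge equals single-pass
accumulation. One subtlety: past saturation, *which* `n` distinct starts
are kept depends on encounter order. Accumulation keeps the first `n`
(insertion order, the streaming behaviour); merging keeps the `n`
smallest of the union, which makes merge commutative and associative.
The two conventions coincide whenever a site has at most `n` distinct
starts — the only regime where the set contents matter beyond their count.

## The gap quality score (gqs)

From alignment evidence alone,

$$\mathrm{gqs} = \left\lfloor 10 \cdot \frac{2\,\min(\mathrm{nlstart},\,n)}{n}
\cdot \frac{\mathrm{qsm}}{4} \right\rfloor,$$

computed in exact integer arithmetic. At read length 100 the score ranges
over 0–1000: the maximum needs a saturated `nlstart` (8 distinct starts)
*and* `qsm = 200` (four gaps each flanked by at least 50 matching bases).
Sites with `gqs >= 1000` are *gqs-validated*; the predicate is `>=` rather
than `==` so that longer reads, which can push `qsm` beyond 200, cannot
un-validate a site.

```{r}
gqs(8, 200)
gqs(4, 200)
```

## The weighted gap information score (wgis)

`gqs` is insensitive for sites supported by few alignments. `wgis`
augments the alignment evidence with splice-site sequence scores:

$$\mathrm{wgis} = f_{nls} \times f_{qsm} \times f_{s5} \times f_{s3}
\times s_{str}$$

with `fnls = log2(log2(nlstart) + 1) + 1` (range (0, 3] after
saturation), `fqsm = log2(log2(max(qsm - 13, 2)))` (0 for `qsm <= 15`,
about 2.916 at `qsm = 200`), and `fs5`/`fs3 = log2(max(score, 1))` for the
donor and acceptor scores of the *selected strand*. Because the last three
factors clamp at zero, `wgis = 0` exactly when `qsm <= 15` or either
selected score is at most 1; every nonzero site is *wgis-validated*. With
the largest acceptor/donor scores observed on annotated human splice
sites (11.8 and 16.1), the factors bound `|wgis|` by about 124.9.

```{r}
round(wgis(8, 200, 11.8, 16.1, 0, 0)$wgis, 1)
```

### Strand inference

Donor (5') sites are scored on 9-mers covering positions −3..+6 around
the boundary, acceptor (3') sites on 23-mers covering −20..+3. For an
unstranded gap-site both hypotheses are evaluated: on the plus strand the
acceptor sits at `rstart` (window read forward), on the minus strand at
`lend` (window read in reverse complement). The strand sign compares the
two acceptor scores — whichever boundary looks more like an acceptor wins,
with ties assigned to plus — and signs the product, so `sign(wgis)`
carries the inferred strand. The factor magnitudes are evaluated on the
selected strand's score pair, not on a maximum over strands, keeping the
magnitude and the sign mutually coherent.

Windows that run past a chromosome end or contain non-ACGT characters are
*unscorable*: the site gets `wgis = 0` with a recorded reason rather than
a guessed score. Aligners do emit junctions whose flanking sequence
contains `N`; treating those as below threshold is deliberate policy.

### Quality levels

`|wgis|` partitions into four levels (`gql`): 0 (not validated),
(0, 30] → 1, (30, 80] → 2, > 80 → 3. The interior cut points correspond
to empirical minima in the joint distribution of site counts and distance
to annotation; here they are fixed constants of the method.

## Splice-site scoring models

Scoring is pluggable behind `score5()`/`score3()`:

* **Maximum-entropy tables** (`load_maxent_tables()`): pre-computed odds
  tables in a documented plain-text layout — a full 4^9 donor table, and
  for the acceptor an inclusion-exclusion decomposition into five 7-mer
  marginal tables and four 3-mer overlap tables,
  `score3 = log2(prod(marginals)/prod(overlaps))`. Estimating such tables
  is a separate modelling exercise and out of scope; they are consumed,
  not fitted.
* **A log-odds position weight matrix** (`train_wmm()` /
  `wmm_from_profile()`): per-position frequencies with pseudocount
  smoothing against a uniform (or supplied) background,
  `score = sum(log2(p_signal/p_background))`. This is the self-contained
  alternative: the synthetic-data tests train it on the generator's own
  sampling profiles. Increasing the pseudocount shrinks every weight
  monotonically toward zero.

## Annotation by sod minimisation

Ensembl-dialect GTF files list exons as independent rows tied together
only by `transcript_id` and `exon_number`, so intron-connected exon pairs
are reconstructed first (adjacent exons per transcript, deduplicated
across transcripts with id lists preserved). A gap-site overlaps a pair
when its supported range `[range_start, range_end]` (the extremes of
aligned bases among its supporting alignments) intersects the pair's span;
among overlapping pairs the reported one minimises

$$\mathrm{sod} = |\mathrm{lend} - \mathrm{left\_exon\_end}| +
|\mathrm{rstart} - \mathrm{right\_exon\_start}|.$$

`sod = 0` is an exact annotated junction; small positive values cover
alternative donors/acceptors and technical jitter. Ties are broken on the
lexicographically smallest `(transcript_id, left_exon_end)` purely for
determinism. Matching deliberately ignores the reference strand — a
gap-site has no strand before wgis — and reports the matched pair's strand
alongside for comparison. The overlap search itself runs on interval
trees (`GenomicRanges::findOverlaps`); tests verify it against a
brute-force scan.

## IDIN statistics and logos

The intronic dinucleotides (IDIN) adjacent to the boundaries — left IDIN
after `lend`, right IDIN before `rstart` — classify junctions: canonical
major-spliceosome introns read `GT..AG` in strand-corrected orientation,
minor-spliceosome ones `AT..AC`. On the minus strand the 5' dinucleotide
is the reverse complement of the right IDIN and vice versa; applying the
same transform twice restores the raw orientation. Without strand
information, a minus-strand `GT-AG` appears as `CT-AG` read from the
genome, so the summed raw proportions of `GT-AG` and `CT-AG` bound the
true canonical fraction from above (`gtag_upper_bound()`). Sites count by
occurrence, not by alignment abundance, so merged multi-sample tables
inflate rare classes — a known property of occurrence counting, not a bug.

Logo matrices are per-position relative frequencies over strand-corrected
windows, with per-position orderings (ties alphabetical). The default
extents are 3 exonic + 6 intronic bases at the donor and 8 intronic +
4 exonic at the acceptor — the junction-centred views used for visual
inspection; both are configurable, and rendering is left to the caller.
Introns shorter than 4 bases are flagged and excluded from dinucleotide
tables rather than producing overlapping slices.

## The synthetic universe

`generate_universe()` builds the entire test world from one seeded stream:
random chromosomes, genes of 150-base exons joined by 300-base introns,
donor/acceptor windows sampled from sharp consensus profiles (the
invariant GT/AG dinucleotides have probability 1) and written into the
genome in strand orientation, plus an Ensembl-dialect GTF and reads
emitted directly as aligned `M-N-M` SAM records — no aligner involved, by
design, since exact coordinates are the ground truth being tested.

Default conditions: read length 100, 12 supporting reads per true
junction, noise junctions at 30% of the true count with coverage 1–3 and
random boundaries at least 50 bases from any true plant. The coverage
default follows from arithmetic, not tuning: at fixed read length 100 a
flanking match of exactly 50 pins the read start, so `qsm = 200` and
8 distinct starts together require at least 11 reads (4 centred + 7
off-centre); 12 leaves one to spare. The generator emulates coordinates,
coverage and splice-site sequence composition; it does not emulate
sequencing error, quality strings, paired ends, or expression structure —
so passing recovery tests demonstrate correctness of extraction, scoring,
strand inference and annotation on clean data, not robustness to
alignment artefacts.

Test problem sizes (2 chromosomes of 20 kb, 4 genes, 8 true junctions)
were chosen as the smallest universe that exercises both strands, multiple
chromosomes and noise placement.

## Numerical and degenerate-input choices

* `gqs` uses exact integer arithmetic (`(20 * nlstart * qsm) %/% (4n)`),
  so truncation can never be perturbed by floating-point representation.
* Scores keep full double precision internally; output tables round
  `wgis` to 3 decimals.
* Acceptor-score ties in strand inference resolve to plus strand.
* Empty inputs propagate as empty tables with intact schemas; an empty
  IDIN table is an error for `gtag_upper_bound` (a proportion of nothing).
* Unsorted inputs to the annotation sweep raise an error instead of
  silently producing wrong matches.

## Known limitations

* The shipped WMM is a first-order model; it cannot represent the
  position dependencies a maximum-entropy model captures, so its absolute
  scores are not comparable to published maximum-entropy scores (only the
  thresholds at 1 are structural).
* Scores for minor-spliceosome (`AT-AC`) junctions are systematically low
  under donor/acceptor models trained on major-spliceosome consensus;
  validated sets will under-represent them.
* The GT-AG upper bound is exactly that — an upper bound; it counts
  minus-strand canonical sites via their CT-AG mirror image and therefore
  also absorbs genuine antisense CT-AG artefacts.
* Multiplicity (`nProbes`) is additive under merge, which assumes each
  input table represents a distinct sample.
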