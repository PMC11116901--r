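---
title: "Detecting and modelling reciprocal chromosomal translocations with translocatr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and modelling reciprocal chromosomal translocations with translocatr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(translocatr)
```

## The problem

Balanced reciprocal translocations exchange terminal segments between two
nonhomologous chromosomes. A plant homozygous for the exchange is fully
fertile, but a heterozygote pairs the four involved chromosomes as a
quadrivalent at diakinesis; adjacent disjunction then produces unbalanced,
abortive gametes, so heterozygotes are semi-sterile. In watermelon this
semi-sterility is exploited to breed less-seed diploid varieties: crossing a
homozygous translocation line with a wild type gives F1 fruit with strongly
reduced seed set. Making this usable in a breeding programme requires (i)
locating the translocation breakpoints by comparing whole-genome assemblies
of the wild-type and translocated lines, (ii) characterizing the junction
sequences, (iii) deriving codominant PCR markers that distinguish all three
genotype classes, and (iv) a meiotic model predicting sterility and F2
segregation ratios that the marker data can be tested against.

`translocatr` implements this chain as a tested pipeline on synthetic data:
a genome simulator with exactly known truth stands in for sequencing and
assembly, and every downstream component (aligner, breakpoint caller,
junction analyzer, marker designer, meiosis model, segregation statistics)
is validated against that truth.

## The synthetic genome generator

`generate_wt_genome()` draws i.i.d. bases at a target GC fraction. The
default study conditions are a desk-scale analogue of a watermelon
assembly: 11 chromosomes of 200 kb at GC 0.35. The real ~370 Mb scale adds
nothing to the correctness questions the package answers and is out of test
scope; all sizes are configurable.

`apply_reciprocal_translocation()` and `apply_complex_translocation()`
derive mutant genomes through an explicit segment map, so the truth record
knows, for every derived chromosome, the ordered wild-type segments it is
built from and the exact junction coordinates. Junction edits follow the
non-homologous end joining (NHEJ) repertoire seen in sequenced breakpoints:

* **deletions** of 0-25 bp, taken from the junction-proximal side of each
  retained segment (end resection);
* **insertions** of arbitrary sequence (rare; off by default);
* a **micro-homology motif** (e.g. the 5 nt `TTTAT`): both wild-type flanks
  are rewritten so the motif abuts the break on each donor, and the derived
  junction retains exactly one copy spanning the join. Whether a repaired
  junction keeps one or two copies is not observable from the mutant alone;
  the generator fixes one copy, and the analyzer makes no assumption either
  way (it reports whatever overlap the sequences support).

The three bundled presets (`preset_event_specs()`) reproduce the
configurations of three watermelon translocation lines at desk scale: a
single Chr6-Chr10 reciprocal with 3 bp deletions and the `TTTAT` motif; two
independent reciprocals (Chr1-Chr5 with 25/24 bp deletions, Chr4-Chr8 with
4/4 bp); and a chained complex Chr1-Chr5-Chr11 event with deletions 25, 24,
1 and 4 bp across its four junctions. Breakpoint positions are the published
coordinates scaled by the ratio of desk to real chromosome length (about
1/168).

### Junction sanitization

An exact-match breakpoint is only defined up to chance homology: if the
first base beyond a break happens to match the other donor's continuation,
the same mutant sequence is produced by a junction one base over — exactly
the ambiguity that makes indel left-alignment necessary in variant calling.
About 40% of random junctions are ambiguous by at least one base. The
generator therefore *sanitizes* junctions by default: wherever a single
wild-type base adjacent to a break would extend an exact match past the
designed breakpoint, that base is rewritten (the edit is recorded in the
truth record). Designed truth is then exactly recoverable, deletions and
micro-homology included. Real junctions are not sanitized, of course; on
real data the caller's leftmost-placement convention (below) makes reported
coordinates deterministic, but a deletion size can be under-estimated by the
length of chance flank homology. `sanitize = FALSE` disables the rewrites.

### What the simulator does not model

No repeats, centromeres, or low-complexity sequence (unique 21-mers are
denser than in a real genome, so anchor coverage is optimistic); no SNPs or
small indels between the compared assemblies (near-isogenic lines justify
this, but assemblies of more distant material would fragment the blocks);
no assembly errors or read-level noise; no inversions (minus-strand blocks
are reported and flagged, never interpreted). Passing tests therefore
demonstrate algorithmic correctness on clean colinear assemblies, not
robustness to assembly artifacts.

## Anchor alignment

`build_anchor_index()` indexes every k-mer that occurs exactly once on the
forward strand of the wild-type genome (k odd, default 21, so no k-mer is
its own reverse complement). `chain_anchors()` matches the mutant's unique
k-mers against the index — forward matches as plus-strand anchors,
reverse-complement matches flagged as minus-strand — and chains co-oriented
anchors into synteny blocks. A chain breaks when the wild-type chromosome or
strand changes, when consecutive anchors are more than `max_gap` apart on
either genome (default 2,000 bp), or when the alignment diagonal shifts by
more than `indel_slack` (default 50 bp). Blocks need `min_anchors` (default
10) anchors; on random 200 kb sequence unique-anchor density is ~100%, so
breakpoints are localized to within ~k of the junction, far below
`max_gap`. Because anchors are processed in mutant order, an anchor that
could extend two chains joins the nearer one on the mutant genome.

## Breakpoint calling and refinement

`call_translocations()` emits a candidate junction wherever two adjacent
blocks on one mutant chromosome derive from different wild-type chromosomes
(blocks shorter than 1 kb are dropped first; same-chromosome discontinuities
are logged as intra-chromosomal anomalies, never called). Candidates are
grouped by the connected components of the wild-type adjacency graph: a
2-cycle is a reciprocal event, a component spanning three or more wild-type
chromosomes a chained complex event.

`refine_breakpoints()` extends exact sequence matches from the anchored
block edges: rightward along the left donor, leftward along the right
donor. Three outcomes:

* extensions **abut**: the junction is unambiguous, `ci_width` 0;
* extensions **overlap** by h bases: the overlap is the junction
  micro-homology. The junction placement is ambiguous over an interval of
  h + 1 positions; the *leftmost* placement on the mutant chromosome is the
  canonical coordinate (deterministic, documented in the output). The truth
  record canonicalizes the same way, so comparison is exact;
* extensions leave a **gap**: the intervening mutant bases are reported as
  an insertion and `ci_width` is the residual gap.

## Junction characterization

Deletion sizes are not junction-locally identifiable: only each donor
chromosome's total coverage gap is observable, and the published
per-recombinant-chromosome deletion sizes correspond exactly to that gap
attributed to the junction where the donor contributes the proximal
segment. `characterize_junctions()` therefore reports `deletion_left` as
the left donor's coverage gap at the break (its last matched base here to
its resumption at the partner junction) and `deletion_right` as the right
donor's gap. Micro-homology is the maximal exact overlap of the two
extensions (present at both donors' flanks by construction, capped at 50
bp); a junction is classed `microhomology_mediated` at >= 2 bp of overlap
(1 bp is uninformative), `blunt` otherwise. The threshold is a parameter
because published descriptions class junctions as blunt-joined while still
reporting a motif; the package reports both quantities and leaves the
dichotomy to the configured threshold.

## Marker design and in-silico genotyping

For each refined breakpoint, `design_breakpoint_markers()` builds a
nonrecombinant pair (WT-F/R spanning the wild-type breakpoint position) and
a recombinant pair (MT-F/R spanning the derived junction). Rules (all
configurable): primer length 20, GC 40-60%, Wallace-rule Tm (2 °C per A/T,
4 °C per G/C) within 55-65 °C, amplicons 150-1,000 bp, WT/MT product sizes
at least 100 bp apart. A primer may occur at most once per genome (both
strands); note a junction-flank primer necessarily occurs in *both* genomes
because the flank is retained, so pair specificity comes from convergent
same-chromosome geometry, which the designer verifies by in-silico PCR
before returning. `insilico_pcr()` is an exact-match, full-length annealing
model: one mismatch means no product, and multiplexing is the union of
independent pairs (no primer-dimer model). Amplicon presence maps
bijectively to the three genotype classes (WT only, both, MT only), making
the panel codominant; `genotype_population()` applies the map and flags
individuals whose two markers of one reciprocal event disagree.

## The meiosis model

Each heterozygous reciprocal event forms one quadrivalent consuming two of
the 11 chromosome pairs (`predict_diakinesis_configuration()`); homozygotes
pair as 11 bivalents. Alternate (balanced) disjunction occurs with
frequency *a* per quadrivalent; adjacent-1 and adjacent-2 are lumped into a
single unbalanced mass because only balanced-vs-unbalanced is identifiable
from sterility and seed-set data. Gametes are N or T with probability a/2
each and unbalanced with probability 1 - a; independent events multiply.
Under balanced-only viability the surviving gametes are N and T at 1/2
each per event, so selfing a heterozygote gives per-event genotypes
NN:NT:TT = 1:2:1, a fully homozygous (fertile) fraction of (1/2)^k for k
independent events — normal : semi-sterile of 1:1 at k = 1 and 1:3 at
k = 2 — and predicted pollen sterility 1 - prod(a_i) (0.5 per event at the
classical a = 0.5). Seed reduction uses the same fraction on the ovule side
(symmetric gametophyte model); observed seed reductions need not match
pollen sterility, so both knobs (`a`, `ovule_factor`) are exposed rather
than fitted.

Chained complex events have no closed-form ratio. A heterozygous chain over
c chromosomes is modelled as one multivalent of 2c chromosomes; gamete
enumeration requires an explicit balanced fraction, with a documented
default (uniform 3:3 disjunction of a hexavalent: 10 equiprobable splits of
six chromosomes, one of which is balanced, giving 1/10) available by
opting in via `use_default_chain_table = TRUE`. Chain predictions are
model-dependent and flagged as such. Cytologically a shared-chromosome
chain can also resolve as two quadrivalents rather than one hexavalent —
the configuration actually observed for the chained watermelon line — and
that situation is represented as two quadrivalent-forming events in
`karyotype_config()`.

`estimate_alternate_frequency()` inverts the sterility model,
a_hat = (1 - s)^(1/k), with the confidence interval obtained by
transforming an exact Clopper-Pearson binomial interval on s (from the
number of pollen grains scored). The transform is monotone, so coverage is
inherited from the binomial interval.

## Segregation statistics

`chisq_gof()` is the plain Pearson statistic against expected counts
total x ratio/sum(ratio), with **no** Yates continuity correction — the
bundled published tables back-compute to the printed three-decimal values
only without it (112:125 vs 1:1 gives 0.713). `conforms` uses an inclusive
boundary (chi2 equal to the critical value still conforms).
`segregation_report()` prints percentages at one decimal (half-up) and chi2
at three decimals, mirroring the published table layout. The bundled
fixtures (`f2_example_counts()`) carry the published F2 pollen counts
(237/182/173 plants) and the ten codominant marker rows.

## Numerical choices and problem sizes

All stochastic operations take explicit seeds; nothing reads or leaves
hidden RNG state. The test suite exercises the desk-scale conditions
directly: 50 randomized reciprocal events (deletions 0-25 bp, breakpoints
>= 10 kb from chromosome ends so that flanking blocks always exceed the
1 kb minimum) plus 20 wild-type self-comparisons on the 11 x 200 kb
karyotype; marker codominance over 20 random designs and 100 replicate F2
genotyping simulations of n = 237; meiosis simulation at n = 10^5 compared
to theory within three binomial standard errors; estimator coverage over
200 replicates at n = 10^4 pollen grains. Unit tests run the same code
paths on a 4 x 30 kb karyotype.

## Known limitations

* Exact-match refinement: any SNP within the extension window truncates the
  extension; on non-isogenic material breakpoint precision degrades to the
  local variant density.
* Deletions spanning an entire retained segment, terminal-segment losses
  and inversions are out of scope; minus-strand blocks are flagged only.
* The PCR model has no mismatch tolerance, thermodynamic Tm, or
  primer-dimer screening; designed primers are optimal only under these
  simplified rules.
* The meiosis model treats events as independent and lumps adjacent modes;
  3:1 ratios from adjacent-2 disjunction with crossover, certation, or
  gametophytic selection are representable only through the viability
  hooks.
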