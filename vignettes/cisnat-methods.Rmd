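---
title: "Methods: cis-NAT detection, nat-siRNA profiling and expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-NAT detection, nat-siRNA profiling and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological question

Cis-natural antisense transcripts (cis-NATs) are pairs of RNAs transcribed
from opposite strands of the same genomic locus whose exonic sequences
overlap. The overlap makes perfect sense/antisense duplexes possible, and the
small interfering RNAs processed from such duplexes — nat-siRNAs — are one
route by which plants regulate transcripts post-transcriptionally, notably
under abiotic stress (salt, cold, drought). Given strand-resolved transcript
models (from strand-specific RNA-seq assembly), mapped small-RNA libraries
and per-condition FPKM tables, this package answers, at each stage with an
explicit, testable rule:

1. which transcript pairs overlap antisense, in what geometry, and between
   which biotypes (detection);
2. which transcripts participate in networks with several antisense partners
   (grouping);
3. which overlaps actually spawn small RNAs, from which strand, and whether
   production concentrates in the overlap (profiling);
4. which pairs are expressed where, how the sense/antisense balance moves
   under stress, and which members are differentially expressed (expression).

## Detection model

**Overlap is exonic; orientation is genomic.** The overlap of two transcripts
is the merged union of all pairwise exon-by-exon intersections, measured in
bases counted once regardless of how many exon pairs cover them
("non-redundant" overlap). A candidate pair must overlap by strictly more
than `min_overlap = 25` nt. Orientation, by contrast, is decided on the
genomic spans: *enclosed* when one span contains the other (equal spans are
containment in both directions, hence enclosed), otherwise *convergent*
(3′–3′; the plus-strand member lies upstream so both 3′ termini fall in the
overlap) or *divergent* (5′–5′). Separating the two notions is deliberate:
overlap length is a hybridisation quantity and lives on exons; orientation is
a promoter-geometry quantity and lives on spans.

All internal coordinates are 0-based half-open; GFF3 converts at the I/O
boundary and BED is native. Half-open abutment (`[0,50)` vs `[50,80)`) is not
overlap.

**Biotype exclusions.** Pairs where either member is a transposon, rRNA,
tRNA, snRNA, snoRNA or miRNA are removed *after* enumeration, so both the
pre- and post-exclusion counts are reported (the run log records every such
in/out count). The biotype vocabulary is closed; unknown strings are
validation errors rather than silent pass-throughs, because the exclusion
filter depends on exact labels.

**Representative pairs.** Isoform combinations of the same unordered locus
pair collapse to the combination with the longest exonic overlap; ties break
to the lexicographically smallest transcript-id pair so output is
deterministic. The >25 nt rule is applied at enumeration, before
representative selection.

## Network grouping

Transcripts are vertices, representative pairs are edges; connected
components with two members are one-to-one pairs, larger components are
many-to-many groups. Groups are typed by strand-wise member counts
(`one-to-two`, `two-to-two`, …, numeric beyond four) rather than by maximum
degree — the strand-wise bipartition reproduces every label in common use and
generalises. One-to-two groups additionally carry the unordered combination
of their two pairs' orientations (`enclosed+convergent`, …);
`divergent+divergent` is in the vocabulary even though it is rarely observed,
since absence is data, not a type constraint.

## nat-siRNA profiling

Reads arrive pre-collapsed (one record per unique sequence-position, copy
count in the BED score); "unique" statistics count records, "total"
statistics sum copies. Filtering keeps lengths 18–34 nt inclusive and drops
reads overlapping rRNA/tRNA/sn/snoRNA features or organelle chromosomes.

A read is a nat-siRNA of a pair iff it lies *wholly inside a single* merged
overlap interval; a read straddling an overlap boundary, or bridging the gap
between two overlap intervals, is not assigned. Either genome strand
qualifies — the strand only decides which member the read is attributed to.

Per pair and condition the package reports:

- **strand bias** on unique counts: `one-strand-{plus,minus}` when one strand
  is silent, `{plus,minus}-biased` when max/min ≥ fold (5 primary, 2
  secondary screen), else `balanced`. Unique rather than copy-summed counts
  are used; copy-summed totals are reported alongside so the choice is
  auditable.
- **density enrichment**: unique reads per kb inside the overlap versus
  inside the flank (union of both members' exons minus the overlap); ratio
  strictly above 5 flags enrichment, an empty or silent flank with a
  populated overlap reports an infinite ratio and counts as enriched, and a
  fully silent pair reports `NA` and does not.
- **overlap exclusivity**: every read touching either member's exons lies
  inside the overlap *and* more than five unique nat-siRNAs exist (strict
  `> 5`, i.e. at least six).

Descriptive statistics (length histogram over 18–34 nt, 5′-first-nucleotide
frequencies with `N` excluded from the denominator) and a genomic-context
classifier (precedence transposon > exon > intron > upstream > downstream >
intergenic, with strand-aware 1 kb flank windows by default) round out the
module.

## Expression analysis

A pair is **expressed** in a condition iff both members have FPKM > 0 and at
least one unique nat-siRNA maps to the overlap in the same condition's
small-RNA library. Per-condition expressed sets yield the co-expression
intersection and union. Expression analysis is restricted to one-to-one
pairs; groups are summarised separately with the evidence threshold exposed
as a parameter.

**Ratio subgroups.** For a control/stress contrast, with
`ds = log2((FPKM_sense,stress + eps) / (FPKM_sense,control + eps))`, `da`
likewise for the antisense member, and `t = log2(2)`: subgroup 2 is sense-up
antisense-down (`ds ≥ t`, `da ≤ −t`), subgroup 3 the mirror image, subgroup 4
both up, subgroup 5 both down, subgroup 1 both moves below threshold, and
anything mixed is an outlier. Subgroups 1–3 formalise the classic prose
descriptions (unchanged; sense up / antisense down; sense down / antisense
up); assigning the remaining coherent patterns (both-up, both-down) to 4 and
5 was a genuinely open design point — the field describes those subgroups
only by their protein families — and is our reading, stated here rather than
hidden. The pseudocount `eps = 0.1` FPKM guards ratios against the zeros
that "not expressed" produces by definition.

**Differential expression.** Significance is computed on raw fragment counts
with a two-sided Fisher exact test on
`[count_stress, lib_stress − count_stress; count_control, lib_control −
count_control]`, implemented by hypergeometric enumeration (the sum of all
table probabilities not exceeding the observed one, with the conventional
`1 + 1e-7` tie tolerance); the fold change is computed on FPKM with the same
pseudocount. A transcript is a DEG when |log2 fold| ≥ 1 and p < 0.001. Tests
verify the enumeration against an independent log-binomial-coefficient oracle
and against `stats::fisher.test` to 1e-12 for margins up to 200.

**Stress-preferential pairs** are expressed under a stress but not under
control — exclusivity, not magnitude; magnitude screening is available
through the DEG flags. **Domain-term enrichment** is a per-term Fisher exact
test of a target transcript set against the background-minus-target set, with
direction by rate comparison and significance at p < 0.001.

`pearson_r2()` is the squared Pearson product-moment correlation, used to
summarise how tightly per-pair sense/antisense log-ratios agree between
conditions.

## The synthetic-data generator

The generator is truth-first: it decides every label (orientation, partner
class, network topology, strand-bias class, exclusivity, enrichment,
subgroup, DEG status, stress-exclusivity), then constructs coordinates,
reads and FPKM tables that realise those labels by construction, and emits
the labels as a ground-truth manifest next to the files. This makes recovery
tests exact for the deterministic stages and sharply calibrated for the
stochastic ones.

What it emulates: opposite-strand overlapping transcripts of every
orientation class with exact planted exonic overlap lengths (overlap windows
always inside single exons; members optionally spliced); many-to-many
cassettes (one-to-two of every subtype, one-to-three, two-to-two,
one-to-four); decoys that the pipeline must reject (same-strand overlaps,
exactly-25-nt overlaps, transposon partners); standalone rRNA-class and
transposon features; four-condition small-RNA libraries with planted strand
bias, overlap/flank density ratios and background reads; and four-condition
FPKM/count tables with planted subgroup, DEG and stress-exclusive structure.

Default study conditions, and why:

- **60 overlap reads per pair per condition** with bias fraction 0.9 for
  biased pairs: at these sizes a binomial draw crosses the 5-fold threshold
  for ≈97% of biased pairs, which is what the ≥95% recovery requirement
  budgets for.
- **overlap/flank density ratio 3** for ordinary pairs and **10** for
  enriched ones: both sit far from the 5-fold flag (Poisson noise moves them
  by far less than the 2–3× margin), so enrichment recovery is effectively
  deterministic.
- **log-normal FPKM baselines** (meanlog 1.5, sdlog 1 — median ≈ 4.5 FPKM)
  with multiplicative noise sdlog 0.15: subgroup effects of 4-fold (twice
  the 2-fold calling threshold) then sit ≈3σ from the decision boundary.
- **DEG carriers** take an 8-fold shift on a baseline floored at 30 FPKM.
  The floor exists because short antisense members (an enclosed partner may
  have only ~150 exonic nt) would otherwise carry so few fragments that an
  8-fold shift is statistically invisible at p < 0.001 — planted truth
  should be detectable truth.
- **library size 2×10⁶ fragments** per condition keeps Fisher tables small
  enough for exact enumeration while giving per-kilobase counts in a
  realistic range.

Each output file draws from its own sub-seed derived from (master seed,
file role), so regenerating any file is independent of generation order and
the whole bundle is byte-identical under a fixed seed.

What the fixtures do *not* emulate — and hence what passing tests do not
show about real data: read sequences in the BED name field are synthetic
(their 5′ nucleotide follows the configured weights but they are not
substrings of the random genome FASTA; nothing downstream re-aligns them);
there is no mapping ambiguity, sequencing error, positional bias or isoform
mis-assembly; FPKM noise is i.i.d. log-normal with no mean–variance
relationship; and planted classes are cleanly separated where real pairs
form continua. Recovery rates on these fixtures certify the *rules*, not the
difficulty of real libraries.

## Numerical and degenerate-input choices

- Strict inequalities follow the stated rules exactly: overlap `> 25`,
  enrichment ratio `> 5`, exclusivity uniques `> 5`, DEG `p < 0.001`.
- Zero flank density with a populated overlap → `Inf` ratio, enriched; fully
  silent pair → `NA` ratio, not enriched.
- Both-zero strand counts → balanced; equal spans → enclosed; representative
  ties → smallest id pair.
- Empty read sets give zero histograms and zero frequencies rather than NaN.
- Report ordering uses radix (byte-wise) sorting throughout so output is
  locale-independent and byte-reproducible.
- `fisher_exact_p()` clamps to 1 and enumerates only the hypergeometric
  support, so library-scale margins cost only as much as the observed count
  range.

## Problem sizes

The default fixture plants 45 one-to-one pairs (plus isoform cases and nine
network cassettes, ~150 transcripts, ~60k reads across four conditions); the
whole pipeline runs in well under a minute on one core. Stochastic recovery
is assessed over 20 replicates of a 15-pair two-condition configuration,
chosen so the full replicate loop stays in the low minutes while still
aggregating several hundred planted labels per statistic.

## Known limitations

- Trans-NAT detection (complementarity between distinct loci) is out of
  scope; only positional antisense overlap is considered.
- FPKM estimation, read alignment and transcript assembly are consumed, not
  performed; garbage in upstream quantification propagates.
- Whether "unique" small RNAs are unique by sequence or by
  (sequence, position) is a convention; this package treats each BED record
  as one unique read and documents the dual reporting.
- The group-level expression screen exposes its nat-siRNA threshold as a
  parameter (default > 1) because per-pair and per-group conventions differ
  in the literature.

## A worked call

```{r example}
library(cisnat)

cfg <- simulation_config(seed = 1)
fx <- write_fixture(cfg, "fixture")
beds <- setNames(file.path("fixture", paste0("smallrna_", cfg$conditions, ".bed")),
                 cfg$conditions)
res <- run_pipeline(fx$gff3, beds, fx$expression, fx$domain_map,
                    control = "control", subgroup_stress = "cold",
                    out_dir = "reports")
glance(res)
autoplot(res)
```
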