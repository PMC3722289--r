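---
title: "Exon-assembly HLA typing from capture sequencing reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon-assembly HLA typing from capture sequencing reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlacall)
```

## The problem

The HLA genes of the human MHC are the most polymorphic loci in the
genome: thousands of alleles per classical gene, differing by dense SNP
and indel variation concentrated in the peptide-binding exons.  Targeted
capture sequencing of the whole MHC yields short paired-end reads covering
every exon of every HLA gene, and `hlacall` turns those reads into allele
calls ("types") against an allele reference panel with exon segmentation
(an IMGT/HLA-style database), in one pass, together with zygosity, a
confidence score, and candidate novel variants.

The pipeline has four stages:

1. **Read preparation** — for each gene, harvest read pairs with either
   end mapped inside the gene's genomic region, plus fully-unmapped pairs
   of high base quality.  Unmapped pairs cannot be assigned to a gene
   positionally, so they ride along as a rescue pool and are resolved by
   the next stage's database matching.
2. **Error correction** — match every read (and its reverse complement)
   to its most similar reference sequence in the panel.  Reads with more
   than two discordances are discarded; retained reads are snapped to the
   reference over their aligned span, and each discordance is recorded in
   a per-gene variant ledger with its supporting read count.  A
   *discordance* is one event: a mismatched base or an indel run of any
   length.
3. **Exon haplotype assembly** — corrected reads are chained into per-exon
   haplotype sequences wherever consecutive reads share a perfect overlap
   of at least 10 bp.  Assemblies not present in the panel (chimeras of
   the two true haplotypes, typically) are filtered out; survivors are
   scored (below).  Exons broken by low-depth regions are re-joined by
   bridging fragments across gaps, but only through a database exon
   consistent with all fragments.
4. **Typing** — exon haplotypes are combined into candidate full-gene
   types, ranked by TScore; zygosity follows the supporting-read ratio
   rule; the final call carries an AScore confidence, and the correction
   ledger is screened for novel variants.

## Scores

Three scores drive the calls.  For one assembled exon haplotype with
per-base depths $X_i$ ($i = 1..L$, mean $\bar X$):

$$D = \frac{1}{L-1} \sum_{i=1}^{L} \frac{(X_i - \bar X)^2}{\bar X},
  \qquad R = \frac{1}{1 + D}$$

$R \in (0, 1]$ is the **depth-reliability**: 1 exactly when coverage is
uniform, shrinking as the depth profile grows more dispersed (a
variance-to-mean dispersion index per degree of freedom).  Profiles of
length < 2 are degenerate and score 1.  With coverage fraction $C$
(assembled length over the exon reference length) and read count $N$, the
**HScore** of the haplotype is

$$S = C \cdot R \cdot \ln(1 + N),$$

bounded factors times a diminishing-returns function of read support.  A
candidate type (one database allele) collects, per exon, the best-HScore
assembly consistent with it, and is ranked by the **TScore**

$$\mathrm{TScore} = \sum_{e} N_e S_e$$

over its supported exons.  The two top-ranked candidates become the best
and sub-optimal type; reads supporting both count in both support totals
but in neither *unique* count.  The gene is a **homozygote** when

$$\mathrm{ratio} = \frac{\text{unique support of sub-optimal type}}
                        {\text{support of best type}} < 0.1,$$

otherwise a heterozygote calling both types; a ratio of exactly 0.1 is a
heterozygote (the homozygote is defined strictly below threshold).
Finally the call's confidence is

$$\mathrm{AScore} = \frac{S_2 - S_1}{S_0} \in [0, 1],$$

where $S_2$ is the final type's TScore, $S_1$ the best TScore among
candidates outside the final call (its nearest competitor), and $S_0$ the
full score $\sum S \cdot N$ of all surviving assemblies of the gene.  The
algebraic forms of $R$, HScore, TScore and AScore are the package's own
reconstruction from the published symbol definitions (the source formulas
are not available in machine-readable form); they honor every stated
variable and bound, and they are kept in single pluggable functions
(`depth_reliability()`, `hscore()`, `tscore()`, `ascore()`) so an
alternative algebra can be swapped without touching callers.

## Matching and correction

The reference matcher replaces an external BLAST dependency with an
in-package seed-and-extend design: 30-mer seeds at the read positions
$\{0, 30, \ge 60\}$ guarantee, by pigeonhole, that any placement of a
91 bp read with at most two substitutions shares at least one exact seed
with the reference.  Candidate diagonals from seed hits are verified by
direct mismatch counting; reads for which no ungapped placement is within
the two-event budget fall back to a fitting alignment (dynamic program
with event costs: mismatch 1, gap open 1, gap extension free) over a
window of $\pm 8$ bp around each candidate diagonal, which recovers
indel-containing reads with indels up to the window half-width.  The DP
aligns the read end to end with interior gaps only — a read may not shed
its flanks as gap events, so clustered sequencing errors can never be
re-explained as a cheap "trim" — and among equal-cost alignments it
prefers the one with the most aligned columns.  Because the gapped rescue
runs only when no ungapped placement exists, a read with both a
two-mismatch placement and a one-indel placement is reported with the
ungapped one; the two placements are equally acceptable under the
two-event contract, and this keeps the rescue cost proportional to the
reads that need it.

Alleles with full (exon + intron) sequences are matched as whole
templates, and the alignment is then projected onto the exon it overlaps
most; reads straddling an exon boundary are trimmed to their exonic part,
kept only if at least 30 bp (`min_span`) remain.  Exon-only databases are
matched per exon directly; reads straddling an exon boundary cannot be
placed in that dialect and are discarded, which is why the full-sequence
manifest dialect is preferred.  Ties between equally
close references are broken deterministically: larger aligned span, then
lexicographically smaller allele name, then lower exon number.  The
corrected read is the reference substring over the aligned exonic span —
correction is reference-snapping, deliberately ignoring base qualities.

## Assembly: enumeration and the database-guided path

`assemble_exon()` enumerates *all* maximal perfect-overlap chains:
although reads could be chained in any order, every maximal consistent
assembly is produced deterministically, so the result set cannot depend on
input order (a safety cap of 10,000 chains guards pathological inputs).
The pipeline itself uses an equivalent, faster formulation: since only
assemblies present in the database survive the filter, reads are placed
(by exact occurrence) on each distinct database exon sequence and chained
along it; maximal chained segments of a database exon are exactly the
maximal chain sequences that pass the filter.  The equivalence of the two
routes is asserted by a test that runs both on random read sets.

Depth profiles count every read lying on an assembly, at its first
occurrence.  When two assemblies share content — the usual case for the
two haplotypes of a heterozygote — a shared read legitimately contributes
depth to both; depth totals across assemblies therefore equal total read
bases only when assemblies are read-disjoint, and the conservation test
uses such fixtures.  The coverage fraction $C$ is computed against the
longest compatible database exon, so partial assemblies score $C < 1$ and
full-length assemblies exactly 1.

A "low-depth break" is any base with zero corrected-read coverage:
fragments on either side of a gap are bridged through a database exon
(gap bases take depth 0, which the reliability score penalizes), one
bridged candidate per consistent exon variant.

## Novel variants

Every discordance recorded during correction is re-judged after typing: a
record is reported as novel when its read support reaches 4 (the
pipeline's variant-calling depth floor), and the edited sequence context
(variant applied to its matched exon, ±10 bp) occurs in *no* allele of
the gene at that exon — a discordance whose alternate state matches
another extant allele is evidence for that allele, not a novel variant.
Surviving records are attached to the called allele sharing the matched
exon sequence (or the first called allele otherwise).

## The simulator and what it does (not) emulate

`generate_synthetic_db()` builds a panel of 3 genes × 8 alleles × 8 exons
by default: per gene an ancestral template (270 bp exons separated by
140 bp introns, 150 bp flanks) is mutated independently per allele at 1%
per base, giving ~2% pairwise divergence — the order of divergence between
classical HLA allele groups — with a constructive guarantee that every
allele pair differs exonically.  Two protein variants share each allele
group in the naming (`G1*01:01`, `G1*01:02`, ...), so two-field and
one-field resolutions genuinely differ.  Intron length exceeds the read
length so no read spans two exons; exon-boundary reads exist and exercise
the trimming path.

`simulate_diploid()` draws fragments uniformly from two chosen haplotype
templates (equal expectation), insert length Normal(500, 10) truncated at
the read length, 2 × 91 bp ends, independent per-base substitution errors
— the regime of standard whole-genome read simulators.  Defaults mirror
the capture design the pipeline targets.  What it does *not* model:
capture/GC bias, indel sequencing errors (a flag-less deliberate
simplification; the matcher's indel path is exercised by constructed
fixtures instead), quality-score structure, and contamination.  Passing
simulation tests therefore demonstrate the *algorithm's* correctness
under its stated assumptions, not robustness to real capture artifacts.

Study sizes: the accuracy grid runs depths {20, 50, 100}× by error rates
{0, 1, 2}% with 36 diploid samples per condition (9 × 36 samples, three
genes each); exact-recovery uses 10 diploids at 100×/0%, and homozygote
recovery 40 single-gene samples at 50×/1%.  These sizes give binomial
standard errors below 2 percentage points per condition while keeping the
default test run desk-sized.

## Numerical and design choices

* **Half-open intervals** internally everywhere; file formats and reports
  use the 1-based inclusive conventions of their ecosystems (samtools
  regions, VCF-like positions).
* **Heterozygote boundary**: ratio exactly 0.1 calls a heterozygote.
* **"Unique" support** is defined against the best candidate (reads
  consistent with the sub-optimal but not the best type), pooled across
  exons; this is the reading under which the ratio discriminates true
  heterozygotes from assembly shadows.
* **Nearest competitor** for the AScore is the best-scoring candidate
  outside the final call (the runner-up for homozygotes, the third
  candidate for heterozygotes).
* **Unmapped-pair quality** is the mean base Phred score of the pair,
  floor 20 by default — the notion of "high quality" is otherwise
  unspecified, and a mean floor is simple, monotone and tunable.
* **Genes with no surviving assembly** return a structured `untypeable`
  result, never an error, so multi-gene runs always complete.
* **Determinism**: every tie in matching, assembly and candidate ranking
  is broken lexicographically; all simulation randomness flows from one
  seeded stream.

## Known limitations

* The seed-and-extend guarantee holds for reads of ~90 bp and the
  two-event budget; shorter reads with early errors can evade the seeds
  and be discarded rather than matched.
* Indels longer than the rescue window (8 bp) are not recovered.
* Read pairing is not used as a constraint during matching or assembly;
  mates are matched independently (insert-size information is unused
  beyond the simulator).
* The exon-only database dialect cannot place reads across exon
  boundaries; full-sequence databases are preferred when available.
* Typing resolution is bounded by the panel: alleles identical over all
  exons covered by reads are indistinguishable in principle, and near-
  identical alleles (one or two exonic differences) can push a true
  heterozygote's ratio below 0.1 at low depth.

## A worked example

```{r example, eval = FALSE}
db <- generate_synthetic_db(seed = 1)
sim <- simulate_diploid(db, simulation_config(depth = 50, seed = 2))
results <- type_sample(sim$reads, db)
typing_report(results, sample = "demo")
evaluate_typing(typing_report(results, sample = "sim1"), sim$truth,
                n_fields = 2)
```
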