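# hlacall — one-step HLA typing from targeted MHC capture sequencing

The HLA genes of the human major histocompatibility complex (MHC) decide
tissue compatibility, and typing them — naming the two alleles a sample
carries per gene, at "4-digit" (two-field) resolution — normally needs
dedicated assays per gene. Whole-MHC capture sequencing covers every exon
of every HLA gene in one experiment; `hlacall` implements an analysis
pipeline that types all genes of an allele reference panel (IMGT/HLA
style) directly from those short paired-end reads, and flags putative
novel variants along the way.

The pipeline: (1) harvest each gene's read pairs from a SAM/BAM file
(either end in the gene region, plus high-quality fully-unmapped pairs);
(2) match every read to its most similar panel sequence, discard reads
with more than two SNP/indel discordances, snap the rest to the
reference and ledger each discordance; (3) assemble corrected reads into
per-exon haplotype sequences by perfect-overlap chaining (minimum 10 bp,
no mismatch in the overlap), drop assemblies absent from the panel, and
score survivors with

    R = 1 / (1 + D),   D = Σ (Xi − X̄)² / X̄ / (L − 1)      (depth reliability)
    S = C · R · ln(1 + N)                                   (HScore)

where `C` is the exon coverage fraction, `N` the supporting read count
and `Xi` the per-base depths; (4) rank candidate full-gene types by
`TScore = Σ Ne·Se` over supported exons, call zygosity from the
supporting-read ratio (sub-optimal type's unique reads over best type's
reads, heterozygote at ratio ≥ 0.1), and attach the confidence
`AScore = (S2 − S1)/S0`. A built-in synthetic panel generator and a
wgsim-style diploid read simulator (2×91 bp, insert 500 ± 10 bp,
0–2 % base error, 20–100× depth) make the whole pipeline testable at
desk scale, with an accuracy evaluator at 2- and 4-digit resolution.

See `vignettes/hla-typing-methods.Rmd` for the model, the score
reconstructions, design decisions and limitations.

## Worked example

```r
library(hlacall)

db  <- generate_synthetic_db(seed = 1)        # 3 genes x 8 alleles x 8 exons
sim <- simulate_diploid(db, simulation_config(depth = 50, seed = 2))
results <- type_sample(sim$reads, db)
typing_report(results, sample = "demo")
```

```
 sample gene  allele1  allele2     zygosity     ratio  tscore1  tscore2    ascore n_novel status
   demo   G1 G1*03:01 G1*04:01 heterozygote 0.6112412 2057.328 1572.999 0.5340488       0     ok
   demo   G2 G2*02:01 G2*01:01 heterozygote 0.8058124 2022.065 1804.487 0.4462332       0     ok
   demo   G3 G3*01:01 G3*02:01 heterozygote 0.5472127 1572.853 1434.581 0.4777475       0     ok
```

Each row is one gene's call: the two alleles, the zygosity decision with
its supporting-read ratio (all well above the 0.1 homozygote threshold
here), the TScores of the called types, and the AScore confidence.
Checking against the simulation's known truth:

```r
evaluate_typing(typing_report(results, sample = "sim1"), sim$truth, n_fields = 2)
#   resolution n_alleles n_correct accuracy
# 1          2         6         6        1
```

All six alleles (two per gene) are recovered at full resolution. A thin
command-line front end for shell use ships in `inst/scripts/hlacall`
(`extract`, `type`, `simulate`, `evaluate` subcommands).

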