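---
title: "Error-aware single-cell genotyping and clonal analysis with ampliclone"
author: "ampliclone maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-aware single-cell genotyping and clonal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliclone)
```

## The measurement problem

Targeted single-cell genotyping amplifies a handful of somatic mutation
loci — from genomic DNA and, where expression allows, from mRNA-derived
cDNA — in thousands of individually sorted cells, and counts reference and
variant reads per cell and amplicon. Three error processes stand between
those counts and a genotype:

* **PCR allelic skew.** A single cell contributes two template molecules.
  Whichever is amplified first dominates the library, so the single-cell
  variant allele frequency (scVAF = variant reads / coverage) of a true
  heterozygote ranges from roughly 0.01 to 0.99 rather than sitting at 0.5.
* **Allelic dropout (ADO).** One allele may fail to amplify at all.
  Dropout of the mutant allele makes a mutant cell look wild type; dropout
  of the wild-type allele makes a heterozygote look homozygous mutant.
* **Polymerase and sequencing error.** Wild-type cells show a small but
  locus-specific background of variant reads.

`ampliclone` implements a calling scheme built around cells from a
wild-type control sample co-sorted onto every plate (about 10% of wells).
Because their genotype is known in advance, their scVAF distribution
measures the per-locus noise floor directly.

## Threshold calling

For each amplicon, with control scVAFs $x_1,\dots,x_n$ (cells passing the
coverage filter only; sample SD with $n-1$ denominator):

$$\theta_{WT} = \bar x + k\,s, \qquad
  \theta_{MUT} = \theta_{WT} + m, \qquad
  \theta_{HOM} = 1 - \theta_{MUT},$$

with defaults $k = 3$ (`sd_multiplier`) and $m = 0.01$ (`mutant_margin`).
A cell is WT when its scVAF falls strictly below $\theta_{WT}$ and mutant
at or above $\theta_{MUT}$, provided it also has at least
`min_mutant_reads` (10) variant reads; everything in between — and every
mutant-side call short on variant reads — is *undetermined*. Coverage
minima are 50 reads for gDNA and 30 for cDNA amplicons; below them the
amplicon is *undetected*. The boundary conventions (strict at the WT
cutoff, inclusive at the mutant cutoff) push exact-boundary cells toward
undetermined, the conservative direction; the published description does
not fix them.

Per-mutation consensus across analytes is asymmetric because cDNA
amplicons drop out far more often than gDNA ones: a mutant call in either
analyte wins; WT requires a WT gDNA call (a WT cDNA call with
non-informative gDNA stays undetermined).

Threshold quality is validated by parametric bootstrap: control scVAFs
are resampled, each resample fitted to a beta distribution by the method
of moments (zeros replaced by half the smallest positive value, since
beta support is open), and the upper-tail mass beyond $\theta_{MUT}$
recorded — the probability of calling a truly WT cell mutant. On
published control moments for a representative gDNA amplicon
(mean 0.000719, SD 0.000472) this tail probability is on the order of
$10^{-15}$, far below the $6\times10^{-3}$ bound reported for the worst
locus.

An alternative strategy derives cutoffs from the scVAF distribution of
*all* cells at a heterozygous locus: a Gaussian-kernel density estimate
(Silverman bandwidth, 1001-point grid on $[0,1]$) is trimodal —
homozygous-reference, heterozygous, homozygous-alternate — and its two
interior minima are the calling cutoffs. This is deliberately stricter:
cells between the control-derived mutant threshold and the lower minimum
are reassigned to undetermined, never to WT, trading sensitivity for
specificity. When fewer than three peaks separate, the function refuses
and directs the caller back to control-derived thresholds.

## Allelic dropout

Where a germline heterozygous SNP sits on the same gDNA amplicon as the
mutation, dropout is directly observable. The allele seen in the WT
control sample defines "Ref"; thresholds for detecting the Alt allele
parallel the mutation thresholds (control mean + 3 SD + 0.01, mirrored
for Hom-Alt). Phase — whether the SNP Alt allele rides on the mutant
haplotype — is inferred from the Pearson correlation of mutation and SNP
scVAFs across cells: allelic skew is shared by loci on the same molecule,
so in-phase pairs correlate positively. We require at least 20 paired
cells and two-sided $p < 0.05$; non-significant loci are reported
ambiguous and excluded from rescue rather than guessed. Rescue then moves
apparently-WT cells whose SNP genotype shows the mutant haplotype was
never sampled to undetermined; it never creates or destroys a mutant
call. Per-allele ADO rates are the fractions of SNP-genotyped cells
called Hom-Ref (Alt dropout) or Hom-Alt (Ref dropout).

Loci without a linked SNP use the homozygous-frequency estimator: under a
heterozygous mutation with symmetric per-allele dropout, apparent
homozygotes arise from WT-allele loss, giving

$$\widehat{ADO}_{WT} = \frac{n_{hom}}{n_{het} + 2\,n_{hom}}.$$

Both estimators measure dropout *among detected cells*: cells losing both
alleles leave the denominator, so with true per-allele rate $a$ the
observable rate is $a/(1+a)$, while extreme amplification skew adds a
small false-homozygote excess in the opposite direction. In simulations
at $a = 0.10$ the two effects nearly cancel and both estimators land
within $\pm 0.02$ of $a$, and within 0.02 of each other — the agreement
we require of them in the tests. For dual-analyte loci a homozygous call
requires homozygous appearance in both the gDNA and cDNA readouts.

## Clonal structure

With several mutations per sample, co-occurrence determines the clonal
hierarchy. Each candidate tree places every mutation at one node under a
wild-type root; a clone is the mutation set on the path from the root.
The likelihood of the observed cells-by-mutations matrix treats entries
as independent given the cell's clone: a spurious mutant observation
occurs at the false-positive rate (default 0.01), a missed mutation at
the dropout rate (default 0.02), and missing entries contribute
likelihood 1; each cell's likelihood averages over attachment to every
clone. Because targeted panels here carry at most six mutations, the tree
space (at most $7^5$ rooted trees, enumerated via Prüfer sequences) is
searched exhaustively, so the reported tree is the global
maximum-likelihood solution — no MCMC is needed at this scale, and tests
verify the score against a brute-force per-cell summation. Ties break
toward fewer branches, then lexicographic order, and are reported.

Cells attach to the clone whose mutation set matches their detected
mutations; a cell whose detected set matches no clone may be rescued into
the deepest consistent clone by assuming up to `max_ancestral_ado`
(default 1) *ancestral* mutations went undetected — dropout of an
ancestor is the observed failure mode, while dropout of a detected
descendant is impossible. Cells with no unique consistent clone are
unassignable and excluded downstream. One consequence worth knowing:
dropout of a clone's *deepest* mutation is observationally silent (the
cell exactly matches the parent clone), so assignment accuracy is bounded
by roughly $1 - a \cdot P(\text{non-root clone})$ at call-level dropout
rate $a$.

## Clone abundance across cell states

To quantify expansion along differentiation, each cluster's clone
representation is the mutant:WT odds — the cell-count analogue of a
density ratio — and the *normalized likelihood* divides by the odds in a
reference population (HSC/MPP by default), so the reference is exactly 1
and values above 1 mean the clone is over-represented in that cell state
relative to the stem/progenitor compartment. Computation is per sample
first, then averaged across samples. Uncertainty comes from a percentile
bootstrap over cells resampled within sample (default 1000 replicates,
seeded); clusters whose interval excludes 1 are flagged. Graph-diffusion
density smoothing and Bayesian compositional testing are deliberately out
of scope: the normalization formulas are implemented at cluster level on
hard counts, which keeps every number auditable from the genotype table.
The bulk-sequencing counterpart is the $2\times\mathrm{VAF}$ rule for the
mutant cell fraction of an autosomal heterozygous mutation (VAF itself
for hemizygous loci; diploid VAFs above 0.5 are flagged and capped).

## Bulk driver annotation

The `driver_rules` module reproduces a bulk variant post-processing
scheme as a transparent rule engine: caller-specific read-support and
quality filters (VarDict: 5 variant reads for SNVs with 2 per strand, 10
with 4 per strand for indels, base quality ≥ 30, mapping quality ≥ 40
except in the duplicated U2AF1/U2AF1L5 region, strand-bias Fisher
$p \geq 10^{-4}$, no positional bias; Mutect2: all default filters pass or
only `clustered_events`, plus the same read-support rule), germline and
artefact flags (population allele frequency above 0.001 without hotspot
rescue, the 0.4–0.6 or >0.9 germline VAF band, panel-of-normals hits,
cohort recurrence), and eight pathogenicity rules (truncating variants in
a 25-gene list, hotspot residues, DNMT3A/TET2/NOTCH1 domain windows, CALR
exon 9, FLT3-ITD, and COSMIC/InterPro evidence with VAF conditions). All
external evidence (COSMIC counts, population frequencies, InterPro
membership) enters as input columns so the package runs offline; the
compiled list of recurrent clonal-hematopoiesis variants ships as an
empty, user-replaceable table. Every classification records the rule IDs
that produced it, and the tests replay classifications from the trace
alone. A sample is CH-positive when at least one pathogenic driver
reaches the VAF cutoff, reported at both the 0.01 and 0.02 bands.

## The simulator, and what it does and does not show

`simulate_cells()` generates the full data triplet (counts, manifest,
metadata) plus ground truth. Defaults encode the study conditions the
calling scheme assumes: allele-sampling fractions from a symmetric
Beta(1.2, 1.2), which reproduces the 0.01–0.99 heterozygote scVAF spread;
per-allele pre-amplification dropout, independent between alleles and
between analytes (gDNA 0.10 per allele, matching the ~9–10% per-allele
rates the control-threshold strategy measures; cDNA 0.30, reflecting the
much higher cDNA dropout that motivates the asymmetric consensus rules);
locus noise 0.001 (the order of the published control moments); negative
binomial coverage (gDNA mean 500, cDNA mean 150, dispersion 2, chosen so
default coverage filters retain roughly 95% of cells); empty wells
emitting at most 2 reads; 10% WT-control wells. A linked SNP shares the
cell's haplotype-sampling fraction and dropout events with its mutation
amplicon, which is exactly why phase correlations arise. Output is
bit-reproducible from (config, seed).

The simulator does *not* model doublets, cross-well contamination,
UMI/read duplication structure, expression-dependent cDNA detection, or
correlated dropout between alleles — so passing tests demonstrate that
the estimators recover their own generative parameters under the stated
noise model, not that the model captures every artefact of real plates.
The label-perturbation utility (`perturb_labels()`) supports the
sensitivity analysis pattern: relabel a random 10% of mutant cells as WT
and confirm that cluster-level enrichment conclusions survive with
attenuated effect sizes.

## Numerical choices and degenerate inputs

* Thresholds need at least 30 control cells per locus (stable SD); fewer
  is an error naming the amplicon.
* All-zero control distributions give a WT threshold of 0 and a
  false-positive probability of 0 with the beta fit skipped (logged).
* Beta moment fits are refused (NA shapes) when the variance is
  incompatible with a beta distribution.
* Phase inference with a zero-variance margin returns ambiguous rather
  than a division-by-zero correlation.
* The tree search refuses more than 6 mutations (directing users to MCMC
  tools) and all-missing matrices.
* Undetermined and unassignable cells are excluded from genotype-stratified
  results everywhere, never imputed.

## Problem sizes used in the test suite

The bundled tests run the whole pipeline at 400–4000 cells per dataset,
estimate ADO at 1000–2000 cells, and verify clone-tree recovery over 100
replicate simulations of 500 cells with three mutations — sizes at which
the binomial error bands quoted in the tests are meaningful for the
properties being checked, while a full run stays in the minutes range on
one CPU.
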