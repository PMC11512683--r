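# ampliclone

Single-cell targeted amplicon genotyping and clonal analysis for studies
of somatic mosaicism — in particular clonal hematopoiesis (CH), where
blood-cell clones carrying driver mutations (most often in *DNMT3A* and
*TET2*) expand with age in people without hematologic disease. Plate-based
targeted genotyping reads out each mutation from independent gDNA and cDNA
amplicons in thousands of FACS-sorted cells; `ampliclone` turns the
resulting per-cell allelic read counts into genotypes, dropout estimates,
clonal hierarchies, and clone-size comparisons across hematopoietic cell
states, and applies rule-based driver annotation to bulk variant tables.

## The method in brief

For each amplicon, scVAF = variant reads / coverage. Wild-type control
cells co-sorted on every plate measure the locus noise floor, giving

    θ_WT  = mean(scVAF_ctrl) + 3·SD(scVAF_ctrl)
    θ_MUT = θ_WT + 0.01          θ_HOM = 1 − θ_MUT

A cell is WT below θ_WT, mutant at or above θ_MUT with ≥ 10 mutant reads
(homozygous-appearing beyond θ_HOM), undetermined in between; amplicons
under 50 (gDNA) / 30 (cDNA) reads are undetected. gDNA/cDNA calls merge by
asymmetric consensus rules, thresholds are validated by bootstrap
beta-fit false-positive analysis, allelic dropout is measured via linked
germline SNPs (with haplotype phase from the scVAF correlation) or from
homozygous-mutant frequencies (n_hom / (n_het + 2·n_hom)), clonal
hierarchies come from exhaustive maximum-likelihood mutation-tree search,
and clone abundance per cell cluster is the mutant:WT odds normalized to
the HSC/MPP reference (bulk counterpart: mutant cell fraction = 2×VAF).
A built-in simulator (PCR allelic skew, per-allele dropout, sequencing
error, coverage dispersion, empty wells, WT-control wells) provides
ground truth for every stage. See the vignette in `vignettes/` for the
full model.

## Worked example

```r
library(ampliclone)

tree <- clone_tree(c(0L, 1L), c("TET2_pQ726X", "TET2_pR1261C"))
cfg <- sim_config(
  n_cells = 800,
  clusters = list(`HSC/MPP` = c(TET2_pQ726X = 0.10,
                                `TET2_pQ726X+TET2_pR1261C` = 0.05),
                  GMP = c(TET2_pQ726X = 0.25,
                          `TET2_pQ726X+TET2_pR1261C` = 0.10)),
  tree = tree,
  loci = data.frame(mutation_id = c("TET2_pQ726X", "TET2_pR1261C"),
                    linked_snp = c(TRUE, FALSE)))
sim <- simulate_cells(cfg, seed = 42)
res <- run_pipeline(sim$dataset)

res$thresholds[, c("amplicon_id", "wt_threshold", "mutant_threshold")]
#>         amplicon_id wt_threshold mutant_threshold
#> 1  TET2_pQ726X_gDNA      0.00541           0.0154
#> 2  TET2_pQ726X_cDNA      0.01766           0.0277
#> 3   TET2_pQ726X_SNP      0.00477           0.0148
#> 4 TET2_pR1261C_gDNA      0.00525           0.0153
#> 5 TET2_pR1261C_cDNA      0.01165           0.0217
```

Locus-specific thresholds derived from the WT-control wells: cDNA
amplicons are noisier (higher cutoffs) than gDNA amplicons, as expected
from their lower coverage. Consensus genotypes and dropout estimates:

```r
table(consensus = res$calls$consensus, mutation = res$calls$mutation_id)
#>               mutation
#> consensus      TET2_pQ726X TET2_pR1261C
#>   MUT                  187           58
#>   UNDETERMINED         106           58
#>   WT                   507          684

res$ado_report[res$ado_report$method == "snp",
               c("locus_id", "phase", "correlation",
                 "ado_rate_ref", "ado_rate_alt")]
#>      locus_id    phase correlation ado_rate_ref ado_rate_alt
#> 1 TET2_pQ726X in_phase         0.3        0.094        0.098
```

The linked SNP is correctly phased onto the mutant haplotype and the
per-allele dropout estimates (~9–10%) recover the simulated 10% rate.
The inferred clonal hierarchy is the linear tree
WT → *TET2* p.Q726X → p.Q726X + p.R1261C, and clone abundance across
cell states shows the expansion built into the simulation:

```r
clone_fraction_by_cluster(res$assignments, sim$dataset$meta,
                          res$tree_fit$tree, "TET2_pQ726X",
                          reference_cluster = "HSC/MPP")
#>   cluster_label n_mut n_wt clone_fraction normalized_likelihood
#> 1           GMP   129  233          0.356                   3.1
#> 2       HSC/MPP    49  274          0.152                   1.0
```

The normalized likelihood of 3.1 in granulocyte-monocyte progenitors
(reference ≡ 1 in HSC/MPP) says the mutant clone is ~3-fold
over-represented downstream of the stem-cell compartment — the signature
of a clone expanding with myeloid differentiation.

Bulk variant tables go through `annotate_variants()` (caller post-filters,
germline/artefact flags, the eight driver rules) and
`classify_sample_ch()`; a thin command-line wrapper with subcommands
`genotype`, `ado`, `clones`, `abundance`, `driver` and `simulate` is
installed at `inst/cli/ampliclone`.

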