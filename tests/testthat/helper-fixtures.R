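# Shared fixture builders; everything is generated in code.

# non-negative numeric sample of length n with exact sample mean m and
# sample SD s (right-skewed base keeps small-mean samples above zero,
# like real control-noise scVAFs)
moments_sample <- function(m, s, n = 100) {
  z <- as.numeric(scale(qexp(ppoints(n))))  # mean 0, sample sd 1
  x <- m + s * z
  stopifnot(all(x >= 0), all(x <= 1))
  x
}

toy_counts <- function() {
  data.frame(cell_id = c("c1", "c2", "c3"),
             amplicon_id = "ampA",
             ref_reads = c(100L, 60L, 0L),
             alt_reads = c(0L, 40L, 120L),
             stringsAsFactors = FALSE)
}

toy_manifest <- function() {
  data.frame(amplicon_id = "ampA", mutation_id = "GENE1_pX1Y",
             analyte = "gDNA", linked_snp_id = NA_character_,
             ploidy = "diploid", stringsAsFactors = FALSE)
}

toy_meta <- function(ctrl = TRUE) {
  data.frame(cell_id = c("c1", "c2", "c3"),
             sample_id = c("S1", "S1", "S1"),
             is_wt_control = c(ctrl, FALSE, FALSE),
             cluster_label = c(NA, "HSC/MPP", "GMP"),
             sort_gate = NA_character_, stringsAsFactors = FALSE)
}

write_toy_files <- function(dir, counts = toy_counts(),
                            manifest = toy_manifest(), meta = toy_meta()) {
  paths <- c(counts = file.path(dir, "counts.tsv"),
             manifest = file.path(dir, "manifest.tsv"),
             meta = file.path(dir, "meta.tsv"))
  write.table(counts, paths[["counts"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(manifest, paths[["manifest"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(meta, paths[["meta"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

# two-mutation linear-tree simulation used across modules
linear_sim_config <- function(n_cells = 600, ado = 0.10, snp = TRUE,
                              error = 0.001) {
  tree <- clone_tree(c(0L, 1L), c("A", "B"))
  sim_config(
    n_cells = n_cells,
    clusters = list(`HSC/MPP` = c(A = 0.10, `A+B` = 0.05),
                    GMP = c(A = 0.25, `A+B` = 0.08)),
    tree = tree,
    loci = data.frame(mutation_id = c("A", "B"),
                      error_rate = error,
                      ado_prob_gdna = ado,
                      ado_prob_cdna = 0.30,
                      linked_snp = c(snp, FALSE),
                      stringsAsFactors = FALSE))
}

# genotype matrix simulated directly at the call level (per-entry errors),
# used by the clone-tree recovery checks
simulate_genotype_matrix <- function(tree, clone_probs, n_cells,
                                     fp = 0.01, ado = 0.02) {
  ids <- tree$clone_ids
  pr <- clone_probs[ids]
  clone <- sample(seq_along(ids), n_cells, replace = TRUE, prob = pr)
  m <- length(tree$mutations)
  truth <- matrix(0L, nrow = n_cells, ncol = m,
                  dimnames = list(NULL, tree$mutations))
  for (i in seq_len(n_cells)) truth[i, tree$clones[[clone[i]]]] <- 1L
  obs <- truth
  flip_up <- truth == 0 & matrix(runif(n_cells * m) < fp, n_cells)
  flip_dn <- truth == 1 & matrix(runif(n_cells * m) < ado, n_cells)
  obs[flip_up] <- 1L
  obs[flip_dn] <- 0L
  list(obs = obs, truth = truth, clone = ids[clone])
}
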