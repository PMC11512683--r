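#' @keywords internal
#' Mutant/WT labels for a clone of interest: mutant = assigned to the clone
#' or any of its descendants; WT = assigned to the root clone. Other clones
#' (e.g. sister branches) and unassignable cells are excluded.
clone_labels <- function(assignments, tree, clone_of_interest) {
  ci <- match(clone_of_interest, tree$clone_ids)
  if (is.na(ci)) stop("unknown clone: ", clone_of_interest, call. = FALSE)
  target <- tree$clones[[ci]]
  in_subtree <- vapply(tree$clone_ids, function(id) {
    s <- tree$clones[[match(id, tree$clone_ids)]]
    length(target) > 0 && all(target %in% s)
  }, logical(1))
  lab <- rep(NA_character_, nrow(assignments))
  lab[assignments$clone_id %in% tree$clone_ids[in_subtree]] <- "MUT"
  lab[assignments$clone_id == "WT"] <- "WT"
  lab
}

#' @keywords internal
#' Normalized mutant:WT likelihood per cluster for one sample's label table.
norm_lik_one_sample <- function(df, reference_cluster) {
  tab <- table(factor(df$cluster_label), factor(df$label,
                                                levels = c("MUT", "WT")))
  n_mut <- tab[, "MUT"]
  n_wt <- tab[, "WT"]
  ref <- reference_cluster
  if (!(ref %in% rownames(tab)) || n_mut[ref] == 0 || n_wt[ref] == 0) {
    stop("reference cluster '", ref, "' needs at least one mutant and one ",
         "WT cell", call. = FALSE)
  }
  odds <- ifelse(n_wt > 0, n_mut / n_wt, NA_real_)
  data.frame(cluster_label = rownames(tab),
             n_mut = as.vector(n_mut), n_wt = as.vector(n_wt),
             clone_fraction = as.vector(n_mut / pmax(n_mut + n_wt, 1)),
             relative_likelihood = as.vector(odds),
             normalized_likelihood = as.vector(odds / odds[ref]),
             stringsAsFactors = FALSE)
}

#' Clone abundance across cell states, normalized to a reference population
#'
#' Quantifies the expansion or contraction of a mutant clone along
#' differentiation. Per cluster, the clone's representation is the
#' mutant:WT odds (cell-count ratio, the discrete analogue of a density
#' ratio); the normalized likelihood divides by the odds in the reference
#' cluster (HSC/MPP), so the reference is 1 by construction and values > 1
#' mean the clone is over-represented in that cell state relative to the
#' stem/progenitor compartment. Computed per sample, then averaged across
#' samples.
#'
#' @param assignments data.frame from [assign_cells()].
#' @param meta Cell metadata with cell_id, sample_id, cluster_label.
#' @param tree The [clone_tree()] used for the assignments.
#' @param clone_of_interest clone_id whose subtree counts as mutant.
#' @param reference_cluster Cluster label used as the normalization
#'   reference.
#' @return data.frame with one row per cluster: n_mut, n_wt,
#'   clone_fraction, relative_likelihood, normalized_likelihood (averaged
#'   across samples), n_samples.
#' @export
clone_fraction_by_cluster <- function(assignments, meta, tree,
                                      clone_of_interest,
                                      reference_cluster = "HSC/MPP") {
  df <- merge(assignments, meta[, c("cell_id", "sample_id",
                                    "cluster_label")], by = "cell_id")
  df$label <- clone_labels(df, tree, clone_of_interest)
  df <- df[!is.na(df$label) & !is.na(df$cluster_label), , drop = FALSE]
  # samples lacking both genotypes in the reference cluster cannot be
  # normalized and are dropped from the cross-sample average
  per_sample <- lapply(split(df, df$sample_id), function(s) {
    tryCatch(norm_lik_one_sample(s, reference_cluster),
             error = function(e) NULL)
  })
  per_sample <- Filter(Negate(is.null), per_sample)
  pooled <- norm_lik_one_sample(df, reference_cluster)
  if (!length(per_sample)) per_sample <- list(pooled)
  nl <- sapply(per_sample, function(s) {
    s$normalized_likelihood[match(pooled$cluster_label, s$cluster_label)]
  })
  nl <- matrix(nl, nrow = nrow(pooled))
  pooled$normalized_likelihood <- rowMeans(nl, na.rm = TRUE)
  pooled$n_samples <- rowSums(!is.na(nl))
  pooled
}

#' Bootstrap confidence intervals for normalized clone likelihoods
#'
#' Percentile intervals over cell-level resampling (within sample), with
#' clusters whose interval excludes 1 flagged as credibly shifted.
#'
#' @inheritParams clone_fraction_by_cluster
#' @param reps Bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return The [clone_fraction_by_cluster()] table with columns ci_lower,
#'   ci_upper, excludes_one.
#' @export
bootstrap_abundance_ci <- function(assignments, meta, tree,
                                   clone_of_interest,
                                   reference_cluster = "HSC/MPP",
                                   reps = 1000, seed = NULL,
                                   conf = 0.95) {
  if (reps < 100) stop("reps must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  point <- clone_fraction_by_cluster(assignments, meta, tree,
                                     clone_of_interest, reference_cluster)
  boot <- replicate(reps, {
    idx <- unlist(lapply(split(seq_len(nrow(assignments)),
                               meta$sample_id[match(assignments$cell_id,
                                                    meta$cell_id)]),
                         function(i) sample(i, length(i), replace = TRUE)))
    a <- assignments[idx, , drop = FALSE]
    a$cell_id_orig <- a$cell_id
    a$cell_id <- paste0("bs", seq_len(nrow(a)))
    m <- meta[match(a$cell_id_orig, meta$cell_id), , drop = FALSE]
    m$cell_id <- a$cell_id
    res <- tryCatch(
      clone_fraction_by_cluster(a, m, tree, clone_of_interest,
                                reference_cluster),
      error = function(e) NULL)
    if (is.null(res)) return(rep(NA_real_, nrow(point)))
    res$normalized_likelihood[match(point$cluster_label,
                                    res$cluster_label)]
  })
  boot <- matrix(boot, nrow = nrow(point))
  alpha <- (1 - conf) / 2
  qs <- t(apply(boot, 1, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE))
  point$ci_lower <- qs[, 1]
  point$ci_upper <- qs[, 2]
  point$excludes_one <- point$ci_lower > 1 | point$ci_upper < 1
  point
}

#' Clonal cell fraction from a bulk variant allele frequency
#'
#' For an autosomal heterozygous mutation every clonal cell carries one
#' mutant allele out of two, so the mutant cell fraction is 2 x VAF. For
#' hemizygous loci the VAF already equals the cell fraction. Diploid VAFs
#' above 0.5 are inconsistent with the heterozygous assumption; they are
#' flagged and the fraction capped at 1.
#'
#' @param vaf Bulk variant allele frequency in \[0, 1\].
#' @param ploidy "diploid" or "hemizygous" (vectorized).
#' @return Clonal cell fraction(s) in \[0, 1\].
#' @export
#' @examples
#' bulk_clone_fraction(0.10)  # 0.20
bulk_clone_fraction <- function(vaf, ploidy = "diploid") {
  stopifnot(all(vaf >= 0), all(vaf <= 1))
  n <- max(length(vaf), length(ploidy))
  vaf <- rep_len(vaf, n)
  ploidy <- rep_len(ploidy, n)
  out <- ifelse(ploidy == "hemizygous", vaf, 2 * vaf)
  high <- ploidy != "hemizygous" & vaf > 0.5
  if (any(high)) {
    warning(sum(high), " diploid VAF(s) > 0.5 are inconsistent with a ",
            "heterozygous mutation; cell fraction capped at 1")
    out[high] <- 1
  }
  out
}
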