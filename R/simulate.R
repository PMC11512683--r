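#' Simulation configuration
#'
#' Describes a synthetic targeted single-cell genotyping experiment with
#' known ground truth. The generative model mirrors plate-based targeted
#' amplicon genotyping:
#' \itemize{
#'   \item each cell belongs to a cluster (cell state) and, within it, to a
#'     clone of the supplied tree with cluster-specific probabilities (the
#'     remainder is the WT clone);
#'   \item per locus, coverage is negative-binomial (gDNA deeper than
#'     cDNA); in heterozygous mutant cells a per-cell allele-sampling
#'     fraction drawn from a symmetric beta produces the PCR allelic skew
#'     that spreads heterozygote scVAFs over roughly 0.01-0.99;
#'   \item each allele drops out independently before amplification
#'     (mutant-allele dropout makes the cell look WT, WT-allele dropout
#'     makes it look homozygous mutant; both lost leaves an empty-well
#'     signal of at most a couple of reads);
#'   \item WT alleles yield variant reads at the locus sequencing-error
#'     rate;
#'   \item a linked germline SNP on the same gDNA amplicon shares the
#'     cell's haplotype sampling, so phase correlations arise naturally;
#'   \item roughly 10\% of wells carry WT-control cells (wild type at all
#'     somatic loci, homozygous reference at all SNPs).
#' }
#'
#' @param n_cells Cells from the sample of interest.
#' @param clusters Named list: per cluster, a named numeric vector of clone
#'   probabilities (names are clone_ids of \code{tree}; remainder = WT).
#'   A single unnamed vector may be given for a one-cluster design.
#' @param tree A [clone_tree()] over the simulated mutations.
#' @param loci data.frame describing each mutation locus: mutation_id,
#'   error_rate, ado_prob_gdna, ado_prob_cdna, has_cdna (logical),
#'   linked_snp (logical), snp_in_phase (logical), ploidy. Defaults are
#'   filled for omitted columns.
#' @param skew_shape Beta shape (symmetric) of the allele-sampling fraction.
#' @param coverage_gdna,coverage_cdna Negative-binomial means per analyte.
#' @param coverage_dispersion Negative-binomial size parameter.
#' @param wt_control_fraction Fraction of extra wells with WT-control cells.
#' @param empty_well_read_max Maximum reads emitted by an empty well.
#' @param cluster_weights Named probabilities of each cluster (uniform when
#'   NULL).
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_cells = 500,
                       clusters = list(`HSC/MPP` = c()),
                       tree = clone_tree(0L, "GENE1_pX1Y"),
                       loci = NULL,
                       skew_shape = 1.2,
                       coverage_gdna = 500,
                       coverage_cdna = 150,
                       coverage_dispersion = 2,
                       wt_control_fraction = 0.10,
                       empty_well_read_max = 2,
                       cluster_weights = NULL) {
  muts <- tree$mutations
  defaults <- data.frame(mutation_id = muts,
                         error_rate = 0.001,
                         ado_prob_gdna = 0.10,
                         ado_prob_cdna = 0.30,
                         has_cdna = TRUE,
                         linked_snp = FALSE,
                         snp_in_phase = TRUE,
                         ploidy = "diploid",
                         stringsAsFactors = FALSE)
  if (!is.null(loci)) {
    for (col in names(loci)) {
      defaults[[col]][match(loci$mutation_id, muts)] <- loci[[col]]
    }
  }
  for (cl in names(clusters)) {
    p <- clusters[[cl]]
    if (length(p) && (any(p < 0) || sum(p) > 1)) {
      stop("clone probabilities in cluster '", cl,
           "' must be non-negative and sum to at most 1", call. = FALSE)
    }
    if (length(p) && !all(names(p) %in% tree$clone_ids)) {
      stop("unknown clone id(s) in cluster '", cl, "'", call. = FALSE)
    }
  }
  if (is.null(cluster_weights)) {
    cluster_weights <- stats::setNames(rep(1 / length(clusters),
                                           length(clusters)),
                                       names(clusters))
  }
  structure(list(n_cells = n_cells, clusters = clusters, tree = tree,
                 loci = defaults, skew_shape = skew_shape,
                 coverage_gdna = coverage_gdna,
                 coverage_cdna = coverage_cdna,
                 coverage_dispersion = coverage_dispersion,
                 wt_control_fraction = wt_control_fraction,
                 empty_well_read_max = empty_well_read_max,
                 cluster_weights = cluster_weights),
            class = "sim_config")
}

#' @keywords internal
#' Reads for one amplicon given per-haplotype sampling fractions and
#' dropout indicators. hap_frac is the pre-dropout sampling share of the
#' allele carrying the variant (mutation or SNP Alt).
amplicon_reads <- function(coverage, carries_variant, hap_frac,
                           drop_var_allele, drop_other_allele, error_rate,
                           empty_max, exact = FALSE) {
  if (drop_var_allele && drop_other_allele) {
    cov <- sample.int(empty_max + 1L, 1L) - 1L  # 0..empty_max reads
    alt <- if (cov > 0) stats::rbinom(1, cov, 0.5) else 0L
    return(c(ref = cov - alt, alt = alt))
  }
  if (!carries_variant) {
    # both sampled alleles are WT at this position
    alt <- stats::rbinom(1, coverage, error_rate)
    return(c(ref = coverage - alt, alt = alt))
  }
  p_alt <- if (drop_var_allele) error_rate
           else if (drop_other_allele) 1 - error_rate
           else hap_frac * (1 - error_rate) + (1 - hap_frac) * error_rate
  # degenerate skew with no sequencing error: alleles amplify perfectly
  # evenly, so reads reflect the exact allele balance
  alt <- if (exact && error_rate == 0) round(coverage * p_alt)
         else stats::rbinom(1, coverage, p_alt)
  c(ref = coverage - alt, alt = alt)
}

#' Simulate a targeted single-cell genotyping dataset
#'
#' Generates allelic counts, manifest and metadata tables plus the ground
#' truth, for the design described by [sim_config()]. Reproducible
#' bit-for-bit from (config, seed).
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @param sample_id Label of the simulated sample of interest.
#' @return List of class \code{sim_dataset}: \code{dataset} (a
#'   \code{genotyping_dataset}), \code{truth} (per-cell data.frame with
#'   clone, cluster, per-locus genotype and dropout events).
#' @export
simulate_cells <- function(config, seed = 1L, sample_id = "SIM1") {
  set.seed(as.integer(seed))
  tree <- config$tree
  loci <- config$loci
  m <- nrow(loci)
  n_smp <- config$n_cells
  n_ctrl <- round(n_smp * config$wt_control_fraction /
                    max(1 - config$wt_control_fraction, 1e-9))
  cl_names <- names(config$clusters)

  cells <- data.frame(
    cell_id = sprintf("C%05d", seq_len(n_smp + n_ctrl)),
    is_wt_control = rep(c(FALSE, TRUE), c(n_smp, n_ctrl)),
    stringsAsFactors = FALSE)
  cells$sample_id <- ifelse(cells$is_wt_control, "WT_CTRL", sample_id)
  cells$cluster_label <- sample(cl_names, nrow(cells), replace = TRUE,
                                prob = config$cluster_weights[cl_names])
  cells$cluster_label[cells$is_wt_control] <- NA_character_

  # clone per cell (WT-control cells are always the WT clone)
  draw_clone <- function(cluster) {
    p <- config$clusters[[cluster]]
    ids <- names(p)
    pr <- c(as.numeric(p), 1 - sum(p))
    sample(c(ids, "WT"), 1, prob = pr)
  }
  cells$clone_id <- "WT"
  smp <- !cells$is_wt_control
  cells$clone_id[smp] <- vapply(cells$cluster_label[smp], draw_clone,
                                character(1))

  # truth genotype matrix: does this cell carry mutation j?
  carry <- matrix(FALSE, nrow = nrow(cells), ncol = m,
                  dimnames = list(cells$cell_id, loci$mutation_id))
  for (i in which(smp)) {
    ci <- match(cells$clone_id[i], tree$clone_ids)
    carry[i, tree$clones[[ci]]] <- TRUE
  }

  # manifest
  man <- list()
  for (j in seq_len(m)) {
    mut <- loci$mutation_id[j]
    snp_id <- if (loci$linked_snp[j]) paste0(mut, "_SNP") else NA_character_
    man[[length(man) + 1]] <- data.frame(
      amplicon_id = paste0(mut, "_gDNA"), mutation_id = mut,
      analyte = "gDNA", linked_snp_id = snp_id, ploidy = loci$ploidy[j],
      stringsAsFactors = FALSE)
    if (loci$has_cdna[j]) {
      man[[length(man) + 1]] <- data.frame(
        amplicon_id = paste0(mut, "_cDNA"), mutation_id = mut,
        analyte = "cDNA", linked_snp_id = NA_character_,
        ploidy = loci$ploidy[j], stringsAsFactors = FALSE)
    }
    if (loci$linked_snp[j]) {
      man[[length(man) + 1]] <- data.frame(
        amplicon_id = snp_id, mutation_id = snp_id,
        analyte = "gDNA", linked_snp_id = NA_character_,
        ploidy = "diploid", stringsAsFactors = FALSE)
    }
  }
  man <- do.call(rbind, man)

  n_slots <- nrow(cells) * nrow(man)
  cc_cell <- character(n_slots)
  cc_amp <- character(n_slots)
  cc_ref <- integer(n_slots)
  cc_alt <- integer(n_slots)
  emit <- function(cell, amp, r) {
    k <<- k + 1L
    cc_cell[k] <<- cell
    cc_amp[k] <<- amp
    cc_ref[k] <<- r[["ref"]]
    cc_alt[k] <<- r[["alt"]]
  }
  truth_events <- vector("list", nrow(cells))
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    is_ctrl <- cells$is_wt_control[i]
    ev <- character(0)
    for (j in seq_len(m)) {
      mut <- loci$mutation_id[j]
      has_mut <- !is_ctrl && carry[i, j]
      # shared pre-amplification state of the gDNA molecule:
      # haplotype A carries the mutation (and the SNP Alt if in-phase);
      # infinite skew shape = no amplification skew (exact 50:50 sampling)
      exact <- is.infinite(config$skew_shape)
      fracA <- if (exact) 0.5
               else stats::rbeta(1, config$skew_shape, config$skew_shape)
      dropA_g <- stats::runif(1) < loci$ado_prob_gdna[j]
      dropB_g <- stats::runif(1) < loci$ado_prob_gdna[j]
      cov_g <- stats::rnbinom(1, mu = config$coverage_gdna,
                              size = config$coverage_dispersion)
      r <- amplicon_reads(cov_g, has_mut, fracA, dropA_g, dropB_g,
                          loci$error_rate[j], config$empty_well_read_max, exact)
      emit(cells$cell_id[i], paste0(mut, "_gDNA"), r)
      if (has_mut && dropA_g) ev <- c(ev, paste0(mut, ":gDNA_mut_ADO"))
      if (has_mut && dropB_g) ev <- c(ev, paste0(mut, ":gDNA_wt_ADO"))

      if (loci$has_cdna[j]) {
        dropA_c <- stats::runif(1) < loci$ado_prob_cdna[j]
        dropB_c <- stats::runif(1) < loci$ado_prob_cdna[j]
        frac_c <- stats::rbeta(1, config$skew_shape, config$skew_shape)
        cov_c <- stats::rnbinom(1, mu = config$coverage_cdna,
                                size = config$coverage_dispersion)
        r <- amplicon_reads(cov_c, has_mut, frac_c, dropA_c, dropB_c,
                            loci$error_rate[j], config$empty_well_read_max, exact)
        emit(cells$cell_id[i], paste0(mut, "_cDNA"), r)
      }
      if (loci$linked_snp[j]) {
        # SNP sits on the same gDNA amplicon: same haplotype sampling and
        # the same allele-dropout events as the mutation readout.
        # WT-control cells are homozygous Ref; sample cells are het.
        snp_het <- !is_ctrl
        alt_on_A <- loci$snp_in_phase[j]
        frac_alt <- if (alt_on_A) fracA else 1 - fracA
        drop_alt <- if (alt_on_A) dropA_g else dropB_g
        drop_ref <- if (alt_on_A) dropB_g else dropA_g
        r <- amplicon_reads(cov_g, snp_het, frac_alt, drop_alt, drop_ref,
                            loci$error_rate[j], config$empty_well_read_max, exact)
        emit(cells$cell_id[i], paste0(mut, "_SNP"), r)
      }
    }
    truth_events[[i]] <- paste(ev, collapse = ";")
  }
  counts <- data.frame(cell_id = cc_cell[seq_len(k)],
                       amplicon_id = cc_amp[seq_len(k)],
                       ref_reads = cc_ref[seq_len(k)],
                       alt_reads = cc_alt[seq_len(k)],
                       stringsAsFactors = FALSE)

  meta <- data.frame(cell_id = cells$cell_id,
                     sample_id = cells$sample_id,
                     is_wt_control = cells$is_wt_control,
                     cluster_label = cells$cluster_label,
                     sort_gate = NA_character_,
                     stringsAsFactors = FALSE)
  truth <- data.frame(cell_id = cells$cell_id,
                      clone_id = cells$clone_id,
                      cluster_label = cells$cluster_label,
                      ado_events = unlist(truth_events),
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(carry))

  structure(list(dataset = build_dataset(counts, man, meta),
                 truth = truth, config = config, seed = seed),
            class = "sim_dataset")
}

#' Simulate WT-control cells only
#'
#' Control cells wild type at every locus, in per-plate blocks, for
#' threshold derivation and false-positive validation.
#'
#' @param config A [sim_config()].
#' @param n_cells Control cells per plate.
#' @param n_plates Number of plates.
#' @param seed Integer seed; per-plate seeds are derived from it.
#' @return data.frame of counts with a \code{plate} column.
#' @export
simulate_wt_controls <- function(config, n_cells = 50, n_plates = 1,
                                 seed = 1L) {
  loci <- config$loci
  out <- list()
  for (p in seq_len(n_plates)) {
    set.seed(as.integer(seed) + p - 1L)
    for (i in seq_len(n_cells)) {
      for (j in seq_len(nrow(loci))) {
        cov <- stats::rnbinom(1, mu = config$coverage_gdna,
                              size = config$coverage_dispersion)
        alt <- stats::rbinom(1, cov, loci$error_rate[j])
        out[[length(out) + 1]] <- data.frame(
          plate = p,
          cell_id = sprintf("P%dCTRL%04d", p, i),
          amplicon_id = paste0(loci$mutation_id[j], "_gDNA"),
          ref_reads = cov - alt, alt_reads = alt,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Randomly relabel a fraction of mutant cells as WT
#'
#' Sensitivity utility: deliberately mis-classifies a simple random sample
#' of the MUT-labeled cells as WT, to measure how robust downstream
#' comparisons are to genotyping error.
#'
#' @param labels Character vector of "MUT"/"WT" labels.
#' @param fraction Fraction of MUT labels to flip.
#' @param seed Integer seed.
#' @return List: \code{labels} (perturbed), \code{flipped} (indices).
#' @export
perturb_labels <- function(labels, fraction = 0.10, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  set.seed(as.integer(seed))
  mut_idx <- which(labels == "MUT")
  n_flip <- round(length(mut_idx) * fraction)
  if (n_flip >= length(mut_idx) && fraction < 1) {
    warning("requested fraction flips every MUT label")
  }
  flip <- if (n_flip > 0) sample(mut_idx, n_flip) else integer(0)
  labels[flip] <- "WT"
  list(labels = labels, flipped = sort(flip))
}
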