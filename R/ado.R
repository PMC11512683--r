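#' Call a germline SNP genotype from its scVAF
#'
#' The reference (Ref) allele is by convention the allele observed in the
#' WT-control sample; the alternate (Alt) allele is seen only in the sample
#' of interest, where the SNP is heterozygous. Thresholds come from the
#' WT-control (homozygous-Ref) scVAF distribution:
#' \code{alt_detection_threshold = mean + sd_multiplier*SD + mutant_margin},
#' \code{hom_alt_threshold = 1 - alt_detection_threshold}. Calls:
#' HomRef below the lower threshold (Alt-allele dropout), HomAlt above the
#' upper threshold (Ref-allele dropout), Het in between (biallelic
#' detection), Undetected when gDNA coverage is below the minimum.
#'
#' @param snp_scvaf SNP scVAF value(s) (\code{NA} allowed for undetected).
#' @param coverage Total reads at the SNP locus.
#' @param thresholds One-row threshold set for the SNP amplicon; its
#'   \code{mutant_threshold} column is the Alt-detection threshold and
#'   \code{hom_mutant_threshold} the HomAlt threshold.
#' @param config A [run_config()]; supplies the gDNA coverage minimum.
#' @return Character vector: HomRef, Het, HomAlt or Undetected.
#' @export
call_snp_genotype <- function(snp_scvaf, coverage, thresholds,
                              config = run_config()) {
  if (is.null(thresholds) || !nrow(thresholds)) {
    stop("no thresholds supplied for SNP genotype calling", call. = FALSE)
  }
  lo <- thresholds$mutant_threshold
  hi <- thresholds$hom_mutant_threshold
  n <- max(length(snp_scvaf), length(coverage))
  snp_scvaf <- rep_len(snp_scvaf, n)
  coverage <- rep_len(coverage, n)
  out <- rep("Het", n)
  out[snp_scvaf < lo] <- "HomRef"
  out[snp_scvaf > hi] <- "HomAlt"
  out[is.na(snp_scvaf) | coverage < config$min_coverage_gdna] <- "Undetected"
  out
}

#' Infer the phase of a germline SNP relative to a somatic mutation
#'
#' PCR allelic skew is shared by all loci on the same amplified allele, so
#' across cells the mutation scVAF and the SNP scVAF are positively
#' correlated when the SNP Alt allele sits on the mutant haplotype
#' (in-phase) and negatively correlated when it sits on the other haplotype
#' (out-of-phase). Pearson correlation with a two-sided significance test;
#' non-significant correlations are reported as ambiguous and excluded from
#' rescue.
#'
#' @param mutation_scvaf,snp_scvaf Paired per-cell scVAFs over cells with
#'   both amplicons detected.
#' @param config A [run_config()]; \code{min_phase_cells} and
#'   \code{phase_alpha} are used.
#' @return List: \code{phase} ("in_phase", "out_of_phase" or "ambiguous"),
#'   \code{correlation}, \code{p_value}, \code{n_cells_used}.
#' @export
infer_phase <- function(mutation_scvaf, snp_scvaf, config = run_config()) {
  keep <- !is.na(mutation_scvaf) & !is.na(snp_scvaf)
  x <- mutation_scvaf[keep]
  y <- snp_scvaf[keep]
  if (length(x) < config$min_phase_cells) {
    stop("only ", length(x), " paired cells; at least ",
         config$min_phase_cells, " required for phase inference",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(phase = "ambiguous", correlation = NA_real_,
                p_value = NA_real_, n_cells_used = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
  r <- unname(ct$estimate)
  p <- ct$p.value
  if (is.na(p)) p <- 0  # exact collinearity
  phase <- if (p < config$phase_alpha && r > 0) "in_phase"
           else if (p < config$phase_alpha && r < 0) "out_of_phase"
           else "ambiguous"
  list(phase = phase, correlation = r, p_value = p,
       n_cells_used = length(x))
}

#' Reassign WT consensus calls using linked-SNP dropout evidence
#'
#' A cell that appears WT for the mutation may have simply failed to sample
#' the mutant allele. The linked SNP reveals which alleles were sampled:
#' \itemize{
#'   \item MUT cells are never touched (the mutant allele was seen).
#'   \item in-phase: WT + SNP HomRef -> UNDETERMINED (mutant-allele
#'     dropout); WT + SNP Het/HomAlt -> WT confirmed.
#'   \item out-of-phase: WT + SNP HomAlt -> UNDETERMINED; WT + SNP
#'     Het/HomRef -> WT confirmed.
#'   \item SNP Undetected -> consensus unchanged.
#' }
#'
#' @param consensus Character vector of consensus genotypes.
#' @param snp_call Character vector of SNP genotypes from
#'   [call_snp_genotype()].
#' @param phase A phase string or the list returned by [infer_phase()].
#' @return List: \code{consensus} (possibly reassigned), \code{ado_flag}
#'   (\code{"mutant_allele_ADO"} where reassigned, else \code{NA}),
#'   \code{confirmed_wt} logical.
#' @export
apply_snp_ado_rescue <- function(consensus, snp_call, phase) {
  if (is.list(phase)) phase <- phase$phase
  if (!phase %in% c("in_phase", "out_of_phase")) {
    warning("ambiguous phase; SNP ADO rescue skipped")
    return(list(consensus = consensus,
                ado_flag = rep(NA_character_, length(consensus)),
                confirmed_wt = rep(FALSE, length(consensus))))
  }
  dropout_geno <- if (phase == "in_phase") "HomRef" else "HomAlt"
  n <- max(length(consensus), length(snp_call))
  consensus <- rep_len(consensus, n)
  snp_call <- rep_len(snp_call, n)
  ado_flag <- rep(NA_character_, n)
  confirmed <- rep(FALSE, n)

  wt <- consensus == "WT"
  hit <- wt & snp_call == dropout_geno
  consensus[hit] <- "UNDETERMINED"
  ado_flag[hit] <- "mutant_allele_ADO"
  confirmed[wt & !hit & snp_call %in% c("HomRef", "Het", "HomAlt")] <- TRUE
  list(consensus = consensus, ado_flag = ado_flag, confirmed_wt = confirmed)
}

#' Per-allele ADO rates from linked-SNP genotypes
#'
#' In sample-of-interest cells the SNP is germline heterozygous, so every
#' homozygous SNP call is a dropout event: HomRef means the Alt allele
#' dropped, HomAlt means the Ref allele dropped. Rates are dropout events
#' over all cells with a genotyped SNP.
#'
#' @param snp_calls Character vector of SNP genotypes over QC-passing cells
#'   of the sample of interest ("Undetected" entries are ignored).
#' @return List: \code{ado_rate_alt_allele}, \code{ado_rate_ref_allele},
#'   \code{n_cells}, \code{method = "snp"}.
#' @export
ado_rate_from_snp <- function(snp_calls) {
  calls <- snp_calls[snp_calls %in% c("HomRef", "Het", "HomAlt")]
  n <- length(calls)
  if (n == 0) {
    stop("no genotyped cells; cannot estimate ADO from SNP calls",
         call. = FALSE)
  }
  list(ado_rate_alt_allele = sum(calls == "HomRef") / n,
       ado_rate_ref_allele = sum(calls == "HomAlt") / n,
       n_cells = n, method = "snp")
}

#' WT-allele ADO rate from homozygous-mutant frequencies
#'
#' For heterozygous somatic mutations without a linked SNP, apparent
#' homozygous-mutant cells arise from dropout of the WT allele. Among truly
#' heterozygous mutant cells, each allele drops independently with rate
#' \eqn{a}; observed het calls require neither allele dropped while
#' hom-appearing calls had the WT allele dropped, giving the estimator
#' \deqn{\hat a = n_{hom} / (n_{het} + 2 n_{hom}).}
#'
#' @param n_het_mut Number of heterozygous-appearing mutant cells.
#' @param n_hom_mut Number of homozygous-appearing mutant cells (for
#'   dual-analyte loci, homozygous in both gDNA and cDNA readouts).
#' @return List: \code{wt_ado_rate}, \code{n_cells},
#'   \code{method = "hom_frequency"}.
#' @export
#' @examples
#' ado_rate_from_hom(90, 10)  # 10/110
ado_rate_from_hom <- function(n_het_mut, n_hom_mut) {
  if (n_het_mut + n_hom_mut == 0) {
    stop("no mutant cells; cannot estimate ADO from homozygous frequencies",
         call. = FALSE)
  }
  list(wt_ado_rate = n_hom_mut / (n_het_mut + 2 * n_hom_mut),
       n_cells = n_het_mut + n_hom_mut, method = "hom_frequency")
}

#' SNP-based ADO analysis for every linked SNP of a dataset
#'
#' For each manifest amplicon declaring a linked germline SNP: derives SNP
#' thresholds from WT-control cells, calls SNP genotypes, infers phase
#' against the mutation scVAF, rescues WT consensus calls, and estimates
#' per-allele ADO rates. Loci with ambiguous phase are reported but not
#' rescued.
#'
#' @param dataset A \code{genotyping_dataset}.
#' @param calls Consensus call table from [call_genotypes()].
#' @param config A [run_config()].
#' @return List with \code{calls} (rescued table) and \code{report}
#'   (one row per locus: locus_id, snp_id, method, phase, correlation,
#'   ado_rate_ref, ado_rate_alt, wt_ado_rate, n_cells).
#' @export
ado_analysis <- function(dataset, calls, config = run_config()) {
  man <- dataset$manifest
  counts <- dataset$counts
  meta <- dataset$meta
  ctrl_cells <- meta$cell_id[meta$is_wt_control]
  linked <- man[!is.na(man$linked_snp_id), , drop = FALSE]
  report <- list()

  scvaf_table <- function(amp) {
    rows <- counts[counts$amplicon_id == amp, , drop = FALSE]
    cov <- rows$ref_reads + rows$alt_reads
    data.frame(cell_id = rows$cell_id, coverage = cov,
               scvaf = ifelse(cov > 0, rows$alt_reads / cov, NA_real_),
               stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(linked))) {
    snp <- linked$linked_snp_id[i]
    mut_amp <- linked$amplicon_id[i]
    mutation <- linked$mutation_id[i]
    snp_tab <- scvaf_table(snp)
    mut_tab <- scvaf_table(mut_amp)
    detected_snp <- snp_tab$coverage >= config$min_coverage_gdna

    # thresholds from WT-control (Hom-Ref) cells passing coverage
    ctrl <- snp_tab[detected_snp & snp_tab$cell_id %in% ctrl_cells, ]
    thr <- derive_thresholds(ctrl$scvaf, amplicon_id = snp, config = config)

    # sample-of-interest cells
    smp <- snp_tab[!(snp_tab$cell_id %in% ctrl_cells), , drop = FALSE]
    smp$snp_call <- call_snp_genotype(smp$scvaf, smp$coverage, thr, config)

    # phase: cells with both amplicons detected
    both <- merge(smp[, c("cell_id", "scvaf")],
                  mut_tab[mut_tab$coverage >= min_coverage_for(
                    linked$analyte[i], config),
                    c("cell_id", "scvaf")],
                  by = "cell_id", suffixes = c("_snp", "_mut"))
    both <- both[!(both$cell_id %in% ctrl_cells), , drop = FALSE]
    ph <- tryCatch(
      infer_phase(both$scvaf_mut, both$scvaf_snp, config),
      error = function(e) list(phase = "ambiguous",
                               correlation = NA_real_,
                               p_value = NA_real_,
                               n_cells_used = nrow(both)))

    # rescue consensus calls for this mutation
    if (ph$phase %in% c("in_phase", "out_of_phase")) {
      idx <- which(calls$mutation_id == mutation)
      m <- match(calls$cell_id[idx], smp$cell_id)
      snp_for_cell <- ifelse(is.na(m), "Undetected", smp$snp_call[m])
      res <- apply_snp_ado_rescue(calls$consensus[idx], snp_for_cell,
                                  ph$phase)
      calls$consensus[idx] <- res$consensus
      keep_flag <- is.na(calls$ado_flag[idx])
      calls$ado_flag[idx][keep_flag] <- res$ado_flag[keep_flag]
    }

    est <- tryCatch(ado_rate_from_snp(smp$snp_call),
                    error = function(e) list(ado_rate_alt_allele = NA_real_,
                                             ado_rate_ref_allele = NA_real_,
                                             n_cells = 0L, method = "snp"))
    report[[length(report) + 1]] <- data.frame(
      locus_id = mutation, snp_id = snp, method = "snp",
      phase = ph$phase, correlation = ph$correlation,
      ado_rate_ref = est$ado_rate_ref_allele,
      ado_rate_alt = est$ado_rate_alt_allele,
      wt_ado_rate = NA_real_, n_cells = est$n_cells,
      stringsAsFactors = FALSE)
  }

  # hom-frequency estimates per mutation
  for (mutation in unique(calls$mutation_id)) {
    sub <- calls[calls$mutation_id == mutation &
                   calls$consensus == "MUT", , drop = FALSE]
    dual <- any(!is.na(sub$gdna_call)) && any(!is.na(sub$cdna_call))
    hom <- if (dual) sub$is_hom_gdna & sub$is_hom_cdna
           else sub$is_hom_gdna | sub$is_hom_cdna
    est <- tryCatch(ado_rate_from_hom(sum(!hom), sum(hom)),
                    error = function(e) list(wt_ado_rate = NA_real_,
                                             n_cells = 0L))
    report[[length(report) + 1]] <- data.frame(
      locus_id = mutation, snp_id = NA_character_,
      method = "hom_frequency", phase = NA_character_,
      correlation = NA_real_, ado_rate_ref = NA_real_,
      ado_rate_alt = NA_real_, wt_ado_rate = est$wt_ado_rate,
      n_cells = est$n_cells, stringsAsFactors = FALSE)
  }

  list(calls = calls, report = do.call(rbind, report))
}
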