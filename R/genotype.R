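#' Single-cell variant allele frequency
#'
#' scVAF = variant reads / coverage, where coverage is the total read count
#' at the locus in that cell. Exact ratio, no rounding. Cells with zero
#' coverage must be called UNDETECTED upstream; the ratio is undefined there.
#'
#' @param variant_reads Variant-supporting read count(s).
#' @param coverage Total read count(s) at the locus; must be positive.
#' @return scVAF value(s) in \[0, 1\].
#' @export
#' @examples
#' compute_scvaf(3, 60)   # 0.05
compute_scvaf <- function(variant_reads, coverage) {
  if (any(coverage <= 0)) {
    stop("coverage must be positive; zero-coverage cells are UNDETECTED",
         call. = FALSE)
  }
  if (any(variant_reads < 0) || any(variant_reads > coverage)) {
    stop("variant_reads must lie in [0, coverage]", call. = FALSE)
  }
  variant_reads / coverage
}

#' Build a threshold set from a WT-calling threshold
#'
#' Completes a locus threshold set from a stated (or externally derived)
#' WT-calling scVAF cutoff: the mutant-calling threshold adds the
#' configured \code{mutant_margin} and the homozygous-mutant threshold is
#' its mirror image \code{1 - mutant_threshold}.
#'
#' @param amplicon_id Identifier recorded in the output.
#' @param wt_threshold WT-calling scVAF cutoff.
#' @param control_mean,control_sd,n_control_cells Optional provenance of
#'   the cutoff.
#' @param config A [run_config()].
#' @param strategy Strategy tag recorded in the output.
#' @return One-row data.frame (see [derive_thresholds()]).
#' @export
#' @examples
#' threshold_set("TET2_pR1261C_gDNA", wt_threshold = 0.002136)
threshold_set <- function(amplicon_id, wt_threshold,
                          control_mean = NA_real_, control_sd = NA_real_,
                          n_control_cells = NA_integer_,
                          config = run_config(),
                          strategy = "control_thresholds") {
  mutant <- wt_threshold + config$mutant_margin
  data.frame(amplicon_id = amplicon_id,
             control_mean = control_mean,
             control_sd = control_sd,
             wt_threshold = wt_threshold,
             mutant_threshold = mutant,
             hom_mutant_threshold = 1 - mutant,
             n_control_cells = n_control_cells,
             strategy = strategy,
             stringsAsFactors = FALSE)
}

#' Derive locus-specific scVAF thresholds from WT-control cells
#'
#' WT-control cells are wild type at every targeted locus, so their scVAFs
#' measure the locus-specific noise floor (polymerase and sequencing error).
#' The WT-calling threshold is \code{mean + sd_multiplier * SD} of the
#' control scVAFs; the mutant-calling threshold adds the fixed
#' \code{mutant_margin}; the homozygous-mutant threshold is the mirror image
#' \code{1 - mutant_threshold}. SD is the sample standard deviation (n - 1).
#'
#' @param scvafs Numeric vector of control-cell scVAFs for one amplicon,
#'   computed only from cells passing the coverage filter.
#' @param amplicon_id Identifier recorded in the output.
#' @param config A [run_config()].
#' @return One-row data.frame: amplicon_id, control_mean, control_sd,
#'   wt_threshold, mutant_threshold, hom_mutant_threshold, n_control_cells,
#'   strategy.
#' @export
#' @examples
#' set.seed(1)
#' derive_thresholds(rbeta(100, 2, 2000), "TET2_gDNA")
derive_thresholds <- function(scvafs, amplicon_id = NA_character_,
                              config = run_config()) {
  scvafs <- scvafs[!is.na(scvafs)]
  if (length(scvafs) < config$min_control_cells) {
    stop("too few WT-control cells (", length(scvafs), " < ",
         config$min_control_cells, ") to derive thresholds for amplicon ",
         amplicon_id, call. = FALSE)
  }
  if (any(scvafs < 0) || any(scvafs > 1)) {
    stop("control scVAFs must lie in [0, 1]", call. = FALSE)
  }
  m <- mean(scvafs)
  s <- stats::sd(scvafs)
  threshold_set(amplicon_id,
                wt_threshold = m + config$sd_multiplier * s,
                control_mean = m, control_sd = s,
                n_control_cells = length(scvafs), config = config)
}

#' @keywords internal
min_coverage_for <- function(analyte, config) {
  ifelse(analyte == "gDNA", config$min_coverage_gdna,
         config$min_coverage_cdna)
}

#' Call a per-amplicon genotype from allelic counts
#'
#' Decision rules, applied in order:
#' \enumerate{
#'   \item coverage below the analyte minimum (gDNA/cDNA) -> UNDETECTED;
#'   \item scVAF < wt_threshold -> WT;
#'   \item scVAF >= mutant_threshold with >= min_mutant_reads mutant reads
#'     -> MUT, upgraded to HOM_MUT when scVAF >= hom_mutant_threshold
#'     (diploid loci only; HOM_MUT counts as MUT downstream);
#'   \item otherwise (borderline scVAF, or enough scVAF but too few mutant
#'     reads) -> UNDETERMINED.
#' }
#'
#' @param ref_reads,alt_reads Integer read counts (vectorized).
#' @param analyte "gDNA" or "cDNA" (scalar or vector).
#' @param thresholds One-row threshold set for this amplicon (from
#'   [derive_thresholds()] or [minima_thresholds()]).
#' @param config A [run_config()].
#' @param ploidy "diploid" or "hemizygous"; hemizygous loci never receive
#'   the homozygous distinction.
#' @return data.frame: scvaf, coverage, mutant_reads, call, reason.
#' @export
call_amplicon <- function(ref_reads, alt_reads, analyte, thresholds,
                          config = run_config(), ploidy = "diploid") {
  coverage <- ref_reads + alt_reads
  n <- length(coverage)
  scvaf <- ifelse(coverage > 0, alt_reads / coverage, NA_real_)
  min_cov <- rep_len(min_coverage_for(analyte, config), n)
  ploidy <- rep_len(ploidy, n)

  call <- rep("UNDETERMINED", n)
  reason <- rep("borderline_scvaf", n)

  und <- coverage < min_cov
  call[und] <- "UNDETECTED"
  reason[und] <- "low_coverage"

  wt <- !und & scvaf < thresholds$wt_threshold
  call[wt] <- "WT"
  reason[wt] <- "below_wt_threshold"

  enough_vaf <- !und & !wt & scvaf >= thresholds$mutant_threshold
  mut <- enough_vaf & alt_reads >= config$min_mutant_reads
  call[mut] <- "MUT"
  reason[mut] <- "above_mutant_threshold"
  reason[enough_vaf & !mut] <- "insufficient_mutant_reads"

  hom <- mut & ploidy == "diploid" &
    scvaf >= thresholds$hom_mutant_threshold
  call[hom] <- "HOM_MUT"
  reason[hom] <- "above_hom_threshold"

  data.frame(scvaf = scvaf, coverage = coverage, mutant_reads = alt_reads,
             call = call, reason = reason, stringsAsFactors = FALSE)
}

#' Consensus genotype from gDNA and cDNA amplicon calls
#'
#' Independent amplicons genotype the same mutation from genomic DNA and
#' from mRNA-derived cDNA. The consensus rules are asymmetric because cDNA
#' amplicons drop out far more often than gDNA amplicons:
#' \enumerate{
#'   \item MUT (or HOM_MUT) in either analyte -> MUT;
#'   \item both WT -> WT;
#'   \item gDNA WT, cDNA undetected/undetermined/absent -> WT;
#'   \item cDNA WT, gDNA undetected/undetermined/absent -> UNDETERMINED;
#'   \item both non-informative -> UNDETERMINED.
#' }
#'
#' @param gdna_call,cdna_call Character vectors of per-amplicon calls (one
#'   of WT, MUT, HOM_MUT, UNDETERMINED, UNDETECTED) or \code{NA} where the
#'   amplicon does not exist for this mutation.
#' @return Character vector of consensus genotypes: WT, MUT or UNDETERMINED.
#' @export
consensus_call <- function(gdna_call, cdna_call = NA_character_) {
  n <- max(length(gdna_call), length(cdna_call))
  g <- rep_len(as.character(gdna_call), n)
  c_ <- rep_len(as.character(cdna_call), n)
  valid <- c("WT", "MUT", "HOM_MUT", "UNDETERMINED", "UNDETECTED",
             NA_character_)
  bad <- !(g %in% valid) | !(c_ %in% valid)
  if (any(bad)) {
    stop("invalid amplicon call state(s): ",
         paste(unique(c(g[bad], c_[bad])), collapse = ", "), call. = FALSE)
  }
  is_mut <- function(x) !is.na(x) & x %in% c("MUT", "HOM_MUT")
  is_wt <- function(x) !is.na(x) & x == "WT"
  noninf <- function(x) is.na(x) | x %in% c("UNDETECTED", "UNDETERMINED")

  out <- rep("UNDETERMINED", n)
  out[is_mut(g) | is_mut(c_)] <- "MUT"                 # rule 1
  out[is_wt(g) & is_wt(c_)] <- "WT"                    # rule 2
  out[is_wt(g) & noninf(c_)] <- "WT"                   # rule 3
  # rule 4 and both-non-informative stay UNDETERMINED
  out
}

#' Validate thresholds by bootstrap beta-fit false-positive analysis
#'
#' Quantifies the probability that a genuinely WT cell exceeds the
#' mutant-calling threshold under the locus noise model. Each bootstrap
#' replicate resamples the control scVAFs with replacement, fits a beta
#' distribution by the method of moments (zeros replaced by half the
#' smallest positive control scVAF, since beta support is open), and records
#' the upper-tail probability beyond the mutant threshold. The point
#' estimate is the fit on the full sample. Degenerate all-zero controls have
#' no noise to model; their false-positive probability is 0 by construction.
#'
#' @param scvafs Control-cell scVAFs for the amplicon.
#' @param thresholds One-row threshold set for the amplicon.
#' @param config A [run_config()]; \code{bootstrap_reps} and \code{rng_seed}
#'   are used.
#' @return List: \code{fp_probability} (point estimate),
#'   \code{fp_range} (min/max over replicates), \code{shape1}, \code{shape2}
#'   (full-sample fit), \code{replicates} (per-replicate tail
#'   probabilities).
#' @export
validate_fp_probability <- function(scvafs, thresholds,
                                    config = run_config()) {
  scvafs <- scvafs[!is.na(scvafs)]
  thr <- thresholds$mutant_threshold
  if (all(scvafs == 0)) {
    message("all-zero control distribution; beta fit skipped, ",
            "fp_probability = 0")
    return(list(fp_probability = 0,
                fp_range = c(0, 0), shape1 = NA_real_, shape2 = NA_real_,
                replicates = rep(0, config$bootstrap_reps)))
  }
  eps <- min(scvafs[scvafs > 0]) / 2
  x <- ifelse(scvafs == 0, eps, scvafs)
  tail_prob <- function(v) {
    fit <- fit_beta_moments(mean(v), stats::sd(v))
    if (is.na(fit[["shape1"]])) return(0)
    stats::pbeta(thr, fit[["shape1"]], fit[["shape2"]], lower.tail = FALSE)
  }
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  reps <- replicate(config$bootstrap_reps,
                    tail_prob(sample(x, length(x), replace = TRUE)))
  fit <- fit_beta_moments(mean(x), stats::sd(x))
  list(fp_probability = tail_prob(x),
       fp_range = range(reps),
       shape1 = fit[["shape1"]], shape2 = fit[["shape2"]],
       replicates = reps)
}

#' Method-of-moments beta fit
#'
#' Solves shape parameters of a beta distribution from a mean and standard
#' deviation. Returns NA shapes when the variance is incompatible with a
#' beta distribution (v >= m(1-m)) or degenerate (v = 0).
#'
#' @param m Mean in (0, 1).
#' @param s Standard deviation.
#' @return Named numeric vector \code{c(shape1, shape2)}.
#' @export
#' @examples
#' fit_beta_moments(0.000719, 0.000472)
fit_beta_moments <- function(m, s) {
  v <- s^2
  if (is.na(v) || v <= 0 || v >= m * (1 - m)) {
    return(c(shape1 = NA_real_, shape2 = NA_real_))
  }
  k <- m * (1 - m) / v - 1
  c(shape1 = m * k, shape2 = (1 - m) * k)
}

#' Thresholds from the minima of the all-cell scVAF distribution
#'
#' Alternative calling strategy: across all genotyped cells at a
#' heterozygous locus, the scVAF histogram is trimodal (homozygous-reference
#' near 0, heterozygous near 0.5, homozygous-alternate near 1). The two
#' interior minima of a kernel density estimate maximally separate the three
#' peaks: the lower minimum is the mutant-calling cutoff and the upper one
#' the homozygous cutoff. Gaussian kernel, Silverman bandwidth, 1001-point
#' grid over \[0, 1\].
#'
#' @param scvafs All-cell scVAFs at the locus.
#' @param amplicon_id Identifier recorded in the output.
#' @param wt_threshold Optional WT-calling cutoff (typically the
#'   control-derived one); cells between it and the lower minimum are
#'   undetermined rather than WT. Defaults to the lower minimum itself,
#'   which leaves no undetermined band.
#' @return One-row data.frame like [derive_thresholds()] with
#'   \code{strategy = "distribution_minima"}: \code{mutant_threshold} is
#'   the lower minimum and \code{hom_mutant_threshold} the upper minimum.
#' @export
minima_thresholds <- function(scvafs, amplicon_id = NA_character_,
                              wt_threshold = NULL) {
  scvafs <- scvafs[!is.na(scvafs)]
  if (length(scvafs) < 10) {
    stop("too few cells for a density estimate", call. = FALSE)
  }
  d <- stats::density(scvafs, kernel = "gaussian", bw = "nrd0",
                      from = 0, to = 1, n = 1001)
  y <- d$y
  i <- 2:(length(y) - 1)
  is_max <- y[i] > y[i - 1] & y[i] >= y[i + 1]
  is_min <- y[i] < y[i - 1] & y[i] <= y[i + 1]
  peaks <- i[is_max]
  mins <- i[is_min]
  if (length(peaks) < 3 || length(mins) < 2) {
    stop("scVAF distribution does not show three separated peaks; ",
         "fall back to the control_thresholds strategy", call. = FALSE)
  }
  # the three tallest peaks, in scVAF order, and the deepest minimum
  # between each consecutive pair
  top3 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:3])
  cut_between <- function(a, b) {
    seg <- mins[mins > a & mins < b]
    if (!length(seg)) {
      stop("no density minimum between peaks at scVAF ",
           signif(d$x[a], 3), " and ", signif(d$x[b], 3),
           "; fall back to the control_thresholds strategy", call. = FALSE)
    }
    seg[which.min(y[seg])]
  }
  lower <- d$x[cut_between(top3[1], top3[2])]
  upper <- d$x[cut_between(top3[2], top3[3])]
  if (is.null(wt_threshold)) wt_threshold <- lower
  if (wt_threshold > lower) {
    stop("wt_threshold exceeds the lower density minimum", call. = FALSE)
  }
  data.frame(amplicon_id = amplicon_id,
             control_mean = NA_real_, control_sd = NA_real_,
             wt_threshold = wt_threshold, mutant_threshold = lower,
             hom_mutant_threshold = upper,
             n_control_cells = NA_integer_,
             strategy = "distribution_minima",
             stringsAsFactors = FALSE)
}

#' Derive thresholds for every amplicon of a dataset
#'
#' Applies [derive_thresholds()] per amplicon using the WT-control cells
#' passing the analyte coverage filter, or [minima_thresholds()] when the
#' configured strategy is \code{distribution_minima}.
#'
#' @param dataset A \code{genotyping_dataset}.
#' @param config A [run_config()].
#' @return data.frame with one row per amplicon.
#' @export
derive_thresholds_all <- function(dataset, config = run_config()) {
  man <- dataset$manifest
  counts <- dataset$counts
  ctrl_cells <- dataset$meta$cell_id[dataset$meta$is_wt_control]
  out <- lapply(seq_len(nrow(man)), function(i) {
    amp <- man$amplicon_id[i]
    rows <- counts[counts$amplicon_id == amp, , drop = FALSE]
    cov <- rows$ref_reads + rows$alt_reads
    keep <- cov >= min_coverage_for(man$analyte[i], config)
    rows <- rows[keep, , drop = FALSE]
    if (config$calling_strategy == "distribution_minima") {
      ctrl <- rows[rows$cell_id %in% ctrl_cells, , drop = FALSE]
      wt_thr <- if (nrow(ctrl) >= config$min_control_cells) {
        derive_thresholds(ctrl$alt_reads / (ctrl$ref_reads + ctrl$alt_reads),
                          amplicon_id = amp,
                          config = config)$wt_threshold
      } else NULL
      minima_thresholds(rows$alt_reads / (rows$ref_reads + rows$alt_reads),
                        amplicon_id = amp, wt_threshold = wt_thr)
    } else {
      ctrl <- rows[rows$cell_id %in% ctrl_cells, , drop = FALSE]
      derive_thresholds(ctrl$alt_reads / (ctrl$ref_reads + ctrl$alt_reads),
                        amplicon_id = amp, config = config)
    }
  })
  do.call(rbind, out)
}

#' Per-cell consensus genotype table for a dataset
#'
#' Runs the full calling pipeline: per-amplicon calls with
#' [call_amplicon()], then gDNA/cDNA consensus with [consensus_call()] for
#' every (cell, mutation) pair. WT-control cells parameterize thresholds but
#' are excluded from the output.
#'
#' @param dataset A \code{genotyping_dataset}.
#' @param thresholds data.frame from [derive_thresholds_all()]; derived
#'   on the fly when \code{NULL}.
#' @param config A [run_config()].
#' @return data.frame with one row per cell and mutation: cell_id,
#'   mutation_id, gdna_call, cdna_call, gdna_scvaf, cdna_scvaf,
#'   gdna_coverage, cdna_coverage, consensus, is_hom_gdna, is_hom_cdna,
#'   ado_flag (NA until SNP rescue), clone_id (NA until clone assignment).
#' @export
call_genotypes <- function(dataset, thresholds = NULL,
                           config = run_config()) {
  if (is.null(thresholds)) {
    thresholds <- derive_thresholds_all(dataset, config)
  }
  man <- dataset$manifest
  # amplicons that read out a linked germline SNP are not somatic targets;
  # the ADO module consumes them
  snp_ids <- stats::na.omit(man$linked_snp_id)
  man <- man[!(man$amplicon_id %in% snp_ids), , drop = FALSE]
  counts <- dataset$counts
  sample_cells <- dataset$meta$cell_id[!dataset$meta$is_wt_control]
  counts <- counts[counts$cell_id %in% sample_cells, , drop = FALSE]

  # per-amplicon calls
  amp_calls <- lapply(seq_len(nrow(man)), function(i) {
    amp <- man$amplicon_id[i]
    rows <- counts[counts$amplicon_id == amp, , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    thr <- thresholds[thresholds$amplicon_id == amp, , drop = FALSE]
    if (!nrow(thr)) return(NULL)
    res <- call_amplicon(rows$ref_reads, rows$alt_reads, man$analyte[i],
                         thr, config, ploidy = man$ploidy[i])
    cbind(data.frame(cell_id = rows$cell_id,
                     mutation_id = man$mutation_id[i],
                     analyte = man$analyte[i],
                     stringsAsFactors = FALSE), res)
  })
  ac <- do.call(rbind, amp_calls)
  if (is.null(ac) || !nrow(ac)) {
    stop("no callable observations in dataset", call. = FALSE)
  }

  # consensus per (cell, mutation)
  key <- interaction(ac$cell_id, ac$mutation_id, drop = TRUE)
  pick <- function(df, an, col) {
    v <- df[[col]][df$analyte == an]
    if (length(v)) v[1] else NA
  }
  rows <- lapply(split(ac, key), function(df) {
    data.frame(cell_id = df$cell_id[1], mutation_id = df$mutation_id[1],
               gdna_call = as.character(pick(df, "gDNA", "call")),
               cdna_call = as.character(pick(df, "cDNA", "call")),
               gdna_scvaf = as.numeric(pick(df, "gDNA", "scvaf")),
               cdna_scvaf = as.numeric(pick(df, "cDNA", "scvaf")),
               gdna_coverage = as.numeric(pick(df, "gDNA", "coverage")),
               cdna_coverage = as.numeric(pick(df, "cDNA", "coverage")),
               stringsAsFactors = FALSE)
  })
  cons <- do.call(rbind, rows)
  rownames(cons) <- NULL
  cons$consensus <- consensus_call(cons$gdna_call, cons$cdna_call)
  cons$is_hom_gdna <- !is.na(cons$gdna_call) & cons$gdna_call == "HOM_MUT"
  cons$is_hom_cdna <- !is.na(cons$cdna_call) & cons$cdna_call == "HOM_MUT"
  cons$ado_flag <- NA_character_
  cons$clone_id <- NA_character_
  cons
}
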