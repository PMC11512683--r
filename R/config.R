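#' Run configuration for genotype calling
#'
#' Bundles the tunable parameters of the genotyping pipeline. Defaults follow
#' the plate-based targeted-amplicon protocol this package implements: gDNA
#' amplicons need deeper coverage than cDNA amplicons for reliable calling,
#' mutant calls require an absolute mutant-read floor on top of the scVAF
#' threshold, and WT thresholds are set from the WT-control noise distribution
#' as mean + \code{sd_multiplier} standard deviations, with the mutant
#' threshold a fixed margin above that.
#'
#' @param min_coverage_gdna Minimum reads for a gDNA amplicon to be detected.
#' @param min_coverage_cdna Minimum reads for a cDNA amplicon to be detected.
#' @param min_mutant_reads Minimum mutant reads required for a MUT call.
#' @param mutant_margin scVAF margin added to the WT threshold to obtain the
#'   mutant-calling threshold.
#' @param sd_multiplier Number of control-noise SDs added to the control mean.
#' @param bootstrap_reps Bootstrap replicates for false-positive validation.
#' @param rng_seed Optional integer seed recorded in outputs and used by
#'   seeded operations.
#' @param calling_strategy Either \code{"control_thresholds"} (thresholds from
#'   WT-control cells) or \code{"distribution_minima"} (thresholds from the
#'   minima of the all-cell scVAF distribution).
#' @param min_control_cells Minimum WT-control cells required per locus to
#'   derive thresholds.
#' @param min_phase_cells Minimum paired cells for SNP/mutation phase
#'   inference.
#' @param phase_alpha Two-sided significance level for the phase correlation.
#' @param max_ancestral_ado Maximum ancestral dropout events assumed when
#'   rescuing a cell's clone assignment.
#'
#' @return An object of class \code{run_config} (a named list).
#' @export
#' @examples
#' cfg <- run_config()
#' cfg$min_coverage_gdna
run_config <- function(min_coverage_gdna = 50,
                       min_coverage_cdna = 30,
                       min_mutant_reads = 10,
                       mutant_margin = 0.01,
                       sd_multiplier = 3,
                       bootstrap_reps = 1000,
                       rng_seed = NULL,
                       calling_strategy = c("control_thresholds",
                                            "distribution_minima"),
                       min_control_cells = 30,
                       min_phase_cells = 20,
                       phase_alpha = 0.05,
                       max_ancestral_ado = 1) {
  calling_strategy <- match.arg(calling_strategy)
  num <- c(min_coverage_gdna = min_coverage_gdna,
           min_coverage_cdna = min_coverage_cdna,
           min_mutant_reads = min_mutant_reads,
           mutant_margin = mutant_margin,
           sd_multiplier = sd_multiplier,
           bootstrap_reps = bootstrap_reps,
           min_control_cells = min_control_cells,
           min_phase_cells = min_phase_cells,
           phase_alpha = phase_alpha)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all run_config thresholds must be strictly positive, got: ",
         paste(names(num)[!is.finite(num) | num <= 0], collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(rng_seed)) rng_seed <- as.integer(rng_seed)
  cfg <- list(min_coverage_gdna = min_coverage_gdna,
              min_coverage_cdna = min_coverage_cdna,
              min_mutant_reads = min_mutant_reads,
              mutant_margin = mutant_margin,
              sd_multiplier = sd_multiplier,
              bootstrap_reps = as.integer(bootstrap_reps),
              rng_seed = rng_seed,
              calling_strategy = calling_strategy,
              min_control_cells = as.integer(min_control_cells),
              min_phase_cells = as.integer(min_phase_cells),
              phase_alpha = phase_alpha,
              max_ancestral_ado = as.integer(max_ancestral_ado))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Keys at the top level (or under a \code{genotyping:} section) override the
#' defaults of [run_config()]. Unknown keys are rejected so typos do not
#' silently fall back to defaults.
#'
#' @param path Path to a YAML configuration file.
#' @param ... Further overrides applied after the file, e.g. from CLI flags.
#' @return A \code{run_config} object.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$genotyping)) raw <- raw$genotyping
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-20s %s\n", k, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}
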