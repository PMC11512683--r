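#' @keywords internal
#' col_classes pins the type of known columns so all-NA columns do not
#' collapse to logical on re-reading.
read_tsv_checked <- function(path, required, what, col_classes = NULL) {
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(names(col_classes), names(df))) {
    df[[col]] <- switch(col_classes[[col]],
                        character = as.character(df[[col]]),
                        numeric = as.numeric(df[[col]]),
                        integer = as.integer(df[[col]]),
                        logical = as.logical(df[[col]]),
                        df[[col]])
  }
  df
}

#' @keywords internal
write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write table to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Validate a per-cell allelic count table
#'
#' Counts are one row per (cell, amplicon) with non-negative integer
#' reference and alternate read counts; (cell_id, amplicon_id) must be
#' unique since each well is sequenced once per amplicon.
#'
#' @param counts data.frame with columns cell_id, amplicon_id, ref_reads,
#'   alt_reads.
#' @return The validated data.frame (counts coerced to integer), invisibly
#'   classed as \code{allelic_counts}.
#' @export
validate_counts <- function(counts) {
  req <- c("cell_id", "amplicon_id", "ref_reads", "alt_reads")
  missing <- setdiff(req, names(counts))
  if (length(missing)) {
    stop("counts table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("ref_reads", "alt_reads")) {
    v <- counts[[col]]
    if (any(is.na(v)) || any(v < 0)) {
      stop("counts column '", col, "' contains negative or missing values",
           call. = FALSE)
    }
    if (any(v != round(v))) {
      stop("counts column '", col, "' must contain integers", call. = FALSE)
    }
    counts[[col]] <- as.integer(round(v))
  }
  key <- paste(counts$cell_id, counts$amplicon_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- counts[duplicated(key), , drop = FALSE][1, ]
    stop("duplicated (cell_id, amplicon_id) row: ",
         dup$cell_id, " / ", dup$amplicon_id, call. = FALSE)
  }
  class(counts) <- c("allelic_counts", "data.frame")
  counts
}

#' Load and cross-reference a genotyping dataset
#'
#' Reads the three tab-separated inputs of a run — allelic counts, the
#' amplicon manifest, and cell metadata — validates each, and
#' cross-references identifiers. Amplicons observed in the counts but absent
#' from the manifest (and vice versa) are reported; duplicated
#' (cell, amplicon) rows and negative counts are rejected; a dataset without
#' WT-control cells cannot parameterize thresholds and is refused.
#'
#' @param counts_path TSV with columns cell_id, amplicon_id, ref_reads,
#'   alt_reads.
#' @param manifest_path TSV with columns amplicon_id, mutation_id, analyte,
#'   linked_snp_id, ploidy.
#' @param meta_path TSV with columns cell_id, sample_id, is_wt_control,
#'   cluster_label, sort_gate.
#' @return An object of class \code{genotyping_dataset}: a list with elements
#'   \code{counts}, \code{manifest}, \code{meta}, and \code{orphans}.
#' @export
load_dataset <- function(counts_path, manifest_path, meta_path) {
  counts <- read_tsv_checked(counts_path,
                             c("cell_id", "amplicon_id", "ref_reads",
                               "alt_reads"), "counts")
  manifest <- read_tsv_checked(manifest_path,
                               c("amplicon_id", "mutation_id", "analyte",
                                 "linked_snp_id", "ploidy"), "manifest",
                               col_classes = c(linked_snp_id = "character"))
  meta <- read_tsv_checked(meta_path,
                           c("cell_id", "sample_id", "is_wt_control",
                             "cluster_label", "sort_gate"), "metadata",
                           col_classes = c(cluster_label = "character",
                                           sort_gate = "character",
                                           is_wt_control = "logical"))
  build_dataset(counts, manifest, meta)
}

#' Assemble a genotyping dataset from in-memory tables
#'
#' Same validation and cross-referencing as [load_dataset()] but starting
#' from data.frames (e.g. fresh simulator output).
#'
#' @param counts,manifest,meta data.frames as documented in [load_dataset()].
#' @return A \code{genotyping_dataset} object.
#' @export
build_dataset <- function(counts, manifest, meta) {
  counts <- validate_counts(counts)
  if (anyDuplicated(manifest$amplicon_id)) {
    stop("manifest contains duplicated amplicon_id", call. = FALSE)
  }
  bad_analyte <- setdiff(unique(manifest$analyte), c("gDNA", "cDNA"))
  if (length(bad_analyte)) {
    stop("manifest analyte must be gDNA or cDNA, got: ",
         paste(bad_analyte, collapse = ", "), call. = FALSE)
  }
  bad_ploidy <- setdiff(unique(manifest$ploidy), c("diploid", "hemizygous"))
  if (length(bad_ploidy)) {
    stop("manifest ploidy must be diploid or hemizygous, got: ",
         paste(bad_ploidy, collapse = ", "), call. = FALSE)
  }
  snp_on_cdna <- !is.na(manifest$linked_snp_id) & manifest$analyte == "cDNA"
  if (any(snp_on_cdna)) {
    stop("a linked germline SNP may only be declared on a gDNA amplicon (",
         paste(manifest$amplicon_id[snp_on_cdna], collapse = ", "), ")",
         call. = FALSE)
  }
  if (anyDuplicated(meta$cell_id)) {
    stop("metadata contains duplicated cell_id", call. = FALSE)
  }
  meta$is_wt_control <- as.logical(meta$is_wt_control)
  if (any(is.na(meta$is_wt_control))) {
    stop("metadata is_wt_control must be TRUE/FALSE", call. = FALSE)
  }
  if (!any(meta$is_wt_control)) {
    stop("no WT-control cells in metadata; control cells are required to ",
         "derive locus-specific thresholds", call. = FALSE)
  }
  orphans <- list(
    amplicons_without_spec = setdiff(unique(counts$amplicon_id),
                                     manifest$amplicon_id),
    amplicons_without_counts = setdiff(manifest$amplicon_id,
                                       unique(counts$amplicon_id)),
    cells_without_meta = setdiff(unique(counts$cell_id), meta$cell_id),
    cells_without_counts = setdiff(meta$cell_id, unique(counts$cell_id)))
  n_orphan <- sum(lengths(orphans))
  if (n_orphan > 0) {
    message("dataset cross-reference: ", n_orphan,
            " orphan identifier(s); see $orphans")
  }
  structure(list(counts = counts, manifest = manifest, meta = meta,
                 orphans = orphans),
            class = "genotyping_dataset")
}

#' @export
print.genotyping_dataset <- function(x, ...) {
  cat("<genotyping_dataset>\n")
  cat("  observations:", nrow(x$counts), "\n")
  cat("  amplicons:   ", nrow(x$manifest), "\n")
  cat("  cells:       ", nrow(x$meta),
      sprintf("(%d WT-control)", sum(x$meta$is_wt_control)), "\n")
  invisible(x)
}

#' Write a dataset back to disk as three TSV files
#'
#' @param dataset A \code{genotyping_dataset}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             manifest = file.path(dir, "manifest.tsv"),
             meta = file.path(dir, "meta.tsv"))
  write_tsv(as.data.frame(dataset$counts), paths[["counts"]])
  write_tsv(dataset$manifest, paths[["manifest"]])
  write_tsv(dataset$meta, paths[["meta"]])
  invisible(paths)
}

#' Write per-cell consensus genotype calls to a TSV file
#'
#' One row per cell and mutation: the per-analyte calls, scVAFs and
#' coverages, the consensus genotype, any allelic-dropout flag, and the
#' clone label when clones have been assigned. The file round-trips through
#' [read_genotype_table()] losslessly.
#'
#' @param calls data.frame of consensus calls (see [consensus_table()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genotype_table <- function(calls, path) {
  if (!is.data.frame(calls) || nrow(calls) == 0) {
    stop("calls must be a non-empty data.frame", call. = FALSE)
  }
  write_tsv(calls, path)
}

#' Read a consensus genotype table written by [write_genotype_table()]
#' @param path Path to the TSV file.
#' @return data.frame of calls.
#' @export
read_genotype_table <- function(path) {
  read_tsv_checked(path, c("cell_id", "mutation_id", "consensus"),
                   "genotype calls",
                   col_classes = c(gdna_call = "character",
                                   cdna_call = "character",
                                   gdna_scvaf = "numeric",
                                   cdna_scvaf = "numeric",
                                   gdna_coverage = "numeric",
                                   cdna_coverage = "numeric",
                                   ado_flag = "character",
                                   clone_id = "character"))
}
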