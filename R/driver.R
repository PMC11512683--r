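#' Load the packaged driver-annotation reference resources
#'
#' Reference tables used by [classify_driver()]: genes in which truncating
#' mutations are drivers, hotspot residues, protein-domain windows for
#' DNMT3A/TET2/NOTCH1, and the (user-supplied, empty by default) list of
#' recurrently reported clonal-hematopoiesis variants. Each table can be
#' overridden with a user file of the same layout.
#'
#' @param dir Directory of resource TSVs; defaults to the copies shipped
#'   with the package.
#' @return List: \code{truncating_driver_genes} (character),
#'   \code{hotspot_residues} (data.frame gene, residue),
#'   \code{domain_windows} (data.frame gene, start, end),
#'   \code{ch_variant_list} (data.frame gene, protein_change, n_reports).
#' @export
driver_resources <- function(dir = system.file("extdata", "resources",
                                               package = "ampliclone")) {
  read1 <- function(name) {
    utils::read.delim(file.path(dir, name), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  }
  list(truncating_driver_genes = read1("truncating_genes.tsv")$gene,
       hotspot_residues = read1("hotspot_residues.tsv"),
       domain_windows = read1("domain_windows.tsv"),
       ch_variant_list = read1("ch_variant_list.tsv"))
}

#' @keywords internal
require_fields <- function(v, fields, op) {
  missing <- fields[!fields %in% names(v)]
  if (length(missing)) {
    stop(op, ": missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' @keywords internal
#' Shared read-support rule: SNVs need >= 5 variant reads with >= 2 on each
#' strand; indels (incl. ITDs) need >= 10 with >= 4 on each strand.
read_support_ok <- function(v) {
  is_snv <- v$variant_class == "SNV"
  min_alt <- ifelse(is_snv, 5, 10)
  min_strand <- ifelse(is_snv, 2, 4)
  v$alt_reads >= min_alt &
    v$alt_reads_forward >= min_strand &
    v$alt_reads_reverse >= min_strand
}

#' Post-processing filters for VarDict variant calls
#'
#' Excludes likely sequencing artefacts: insufficient read support
#' (5 variant reads with 2 per strand for SNVs; 10 with 4 per strand for
#' indels), mean base quality below 30, mean mapping quality below 40
#' (ignored for U2AF1/U2AF1L5, which is duplicated in hg38 and multi-maps),
#' strand-bias Fisher p below 1e-4, or positional bias within reads.
#'
#' @param v data.frame of variant records with caller == "vardict".
#' @return data.frame: pass (logical), failed_rules (comma-separated IDs).
#' @export
apply_vardict_filters <- function(v) {
  require_fields(v, c("gene", "variant_class", "alt_reads",
                      "alt_reads_forward", "alt_reads_reverse",
                      "mean_base_quality", "mean_mapping_quality",
                      "strand_bias_p", "position_bias_flag"),
                 "apply_vardict_filters")
  n <- nrow(v)
  fails <- list(
    min_reads = !read_support_ok(v),
    base_quality = v$mean_base_quality < 30,
    mapping_quality = v$mean_mapping_quality < 40 &
      !(v$gene %in% c("U2AF1", "U2AF1L5", "U2AF1;U2AF1L5")),
    strand_bias = v$strand_bias_p < 0.0001,
    position_bias = as.logical(v$position_bias_flag))
  failed <- vapply(seq_len(n), function(i) {
    paste(names(fails)[vapply(fails, `[`, logical(1), i)], collapse = ",")
  }, character(1))
  data.frame(pass = failed == "", failed_rules = failed,
             stringsAsFactors = FALSE)
}

#' Post-processing filters for Mutect2 variant calls
#'
#' A call passes when its caller filters are PASS (or fail only
#' \code{clustered_events}) and it meets the same read-support rule as
#' VarDict calls.
#'
#' @param v data.frame of variant records with caller == "mutect2";
#'   \code{caller_filters} is a comma/semicolon-separated filter string.
#' @return data.frame: pass, failed_rules.
#' @export
apply_mutect2_filters <- function(v) {
  require_fields(v, c("variant_class", "alt_reads", "alt_reads_forward",
                      "alt_reads_reverse", "caller_filters"),
                 "apply_mutect2_filters")
  filt_ok <- vapply(v$caller_filters, function(f) {
    if (is.na(f) || f == "") return(TRUE)
    parts <- trimws(strsplit(f, "[,;]")[[1]])
    all(parts %in% c("PASS", "clustered_events"))
  }, logical(1), USE.NAMES = FALSE)
  fails <- list(caller_filters = !filt_ok,
                min_reads = !read_support_ok(v))
  failed <- vapply(seq_len(nrow(v)), function(i) {
    paste(names(fails)[vapply(fails, `[`, logical(1), i)], collapse = ",")
  }, character(1))
  data.frame(pass = failed == "", failed_rules = failed,
             stringsAsFactors = FALSE)
}

#' Flag likely germline variants and artefacts
#'
#' Flags (any one excludes the variant unless rescued):
#' \itemize{
#'   \item \code{popAF}: population allele frequency > 0.001 in any of the
#'     three polymorphism databases, unless a hotspot with COSMIC count
#'     > 100 or on the clonal-hematopoiesis variant list;
#'   \item \code{germline_vaf_band}: VAF in \[0.4, 0.6\] or > 0.9, unless
#'     COSMIC count > 5 or CH-listed;
#'   \item \code{panel_of_normals}: present in the cord-blood panel of
#'     normals;
#'   \item \code{cohort_recurrent}: identical variant recurring in the
#'     cohort (>= \code{recurrence_min} samples) unless COSMIC count >= 5
#'     or reported >= 2 times in the CH studies.
#' }
#'
#' @param v data.frame of variant records (after caller filters).
#' @param recurrence_min Samples sharing a variant that count as recurrent.
#' @return Character vector of comma-separated flag IDs ("" = clean).
#' @export
flag_germline_or_artefact <- function(v, recurrence_min = 3) {
  require_fields(v, c("vaf", "population_af", "cosmic_count",
                      "ch_list_member", "in_panel_of_normals",
                      "cohort_recurrence"), "flag_germline_or_artefact")
  unevaluable <- is.na(v$population_af) | is.na(v$vaf) |
    is.na(v$cosmic_count)
  ch <- as.logical(v$ch_list_member)
  ch[is.na(ch)] <- FALSE
  popaf <- v$population_af > 0.001 &
    !(v$cosmic_count > 100 | ch)
  band <- ((v$vaf >= 0.4 & v$vaf <= 0.6) | v$vaf > 0.9) &
    !(v$cosmic_count > 5 | ch)
  pon <- as.logical(v$in_panel_of_normals)
  pon[is.na(pon)] <- FALSE
  ch_recur <- if ("ch_list_recurrence" %in% names(v)) {
    !is.na(v$ch_list_recurrence) & v$ch_list_recurrence >= 2
  } else rep(FALSE, nrow(v))
  recur <- v$cohort_recurrence >= recurrence_min &
    !(v$cosmic_count >= 5 | ch_recur)
  flags <- cbind(popAF = popaf, germline_vaf_band = band,
                 panel_of_normals = pon, cohort_recurrent = recur)
  out <- apply(flags, 1, function(r) {
    paste(colnames(flags)[which(r)], collapse = ",")
  })
  out[unevaluable] <- "unevaluable"
  out
}

#' Annotate pathogenic driver mutations
#'
#' A filtered, unflagged variant is a pathogenic driver when any of eight
#' rules fires:
#' \enumerate{
#'   \item truncating (nonsense, splice site, frameshift) in a listed
#'     driver gene;
#'   \item non-synonymous at a listed hotspot residue;
#'   \item non-synonymous within a listed DNMT3A/TET2/NOTCH1 domain window;
#'   \item truncating in CALR exon 9;
#'   \item FLT3 internal tandem duplication;
#'   \item non-synonymous with COSMIC count >= 10 and VAF < 0.4;
#'   \item non-synonymous in an annotated InterPro domain with VAF < 0.4;
#'   \item non-synonymous with COSMIC count > 100.
#' }
#' Everything else is a variant of unknown significance (VUS). The firing
#' rule IDs are recorded so each classification can be replayed.
#'
#' @param v data.frame of variant records that passed caller filters and
#'   carry no germline/artefact flags.
#' @param resources [driver_resources()] list.
#' @return data.frame: classification ("pathogenic_driver"/"VUS"),
#'   driver_rule_ids (comma-separated).
#' @export
classify_driver <- function(v, resources = driver_resources()) {
  require_fields(v, c("gene", "variant_class", "consequence",
                      "protein_position", "vaf", "cosmic_count",
                      "in_interpro_domain"), "classify_driver")
  truncating <- v$consequence %in% c("nonsense", "frameshift", "splice_site")
  nonsyn <- v$consequence %in% c("missense", "inframe", "nonsense",
                                 "frameshift", "splice_site")
  hot <- resources$hotspot_residues
  dom <- resources$domain_windows
  n <- nrow(v)
  at_hotspot <- vapply(seq_len(n), function(i) {
    any(hot$gene == v$gene[i] & hot$residue == v$protein_position[i])
  }, logical(1))
  in_window <- vapply(seq_len(n), function(i) {
    any(dom$gene == v$gene[i] &
          dom$start <= v$protein_position[i] &
          dom$end >= v$protein_position[i], na.rm = TRUE)
  }, logical(1))
  exon9 <- if ("exon" %in% names(v)) !is.na(v$exon) & v$exon == 9 else
    rep(FALSE, n)
  rules <- cbind(
    rule1_truncating_gene = truncating &
      v$gene %in% resources$truncating_driver_genes,
    rule2_hotspot = nonsyn & at_hotspot,
    rule3_domain_window = nonsyn & in_window,
    rule4_calr_exon9 = truncating & v$gene == "CALR" & exon9,
    rule5_flt3_itd = v$gene == "FLT3" & v$variant_class == "ITD",
    rule6_cosmic10_vaf = nonsyn & v$cosmic_count >= 10 & v$vaf < 0.4,
    rule7_interpro_vaf = nonsyn & as.logical(v$in_interpro_domain) &
      v$vaf < 0.4,
    rule8_cosmic100 = nonsyn & v$cosmic_count > 100)
  rules[is.na(rules)] <- FALSE
  ids <- apply(rules, 1, function(r) {
    paste(colnames(rules)[which(r)], collapse = ",")
  })
  data.frame(classification = ifelse(ids == "", "VUS", "pathogenic_driver"),
             driver_rule_ids = ids, stringsAsFactors = FALSE)
}

#' Full bulk-variant annotation pipeline
#'
#' Applies the caller-appropriate post-filters, germline/artefact flags and
#' driver rules to a variant table, recording the complete rule trace.
#' Variants are retained when they pass either caller's filter path
#' (union mode) or only when callers agree (intersect mode).
#'
#' @param variants data.frame of variant records; see [classify_driver()]
#'   and the filter functions for required fields.
#' @param resources [driver_resources()] list.
#' @param mode "union" or "intersect" consensus semantics across callers.
#' @param recurrence_min See [flag_germline_or_artefact()].
#' @return The input with columns passed_caller_filters, failed_rules,
#'   germline_artefact_flags, classification, driver_rule_ids appended.
#' @export
annotate_variants <- function(variants, resources = driver_resources(),
                              mode = c("union", "intersect"),
                              recurrence_min = 3) {
  mode <- match.arg(mode)
  n <- nrow(variants)
  pass <- rep(FALSE, n)
  failed <- rep("", n)
  vd <- which(variants$caller == "vardict")
  mt <- which(variants$caller == "mutect2")
  if (length(vd)) {
    r <- apply_vardict_filters(variants[vd, , drop = FALSE])
    pass[vd] <- r$pass
    failed[vd] <- r$failed_rules
  }
  if (length(mt)) {
    r <- apply_mutect2_filters(variants[mt, , drop = FALSE])
    pass[mt] <- r$pass
    failed[mt] <- r$failed_rules
  }
  if (mode == "intersect") {
    key <- with(variants, paste(chrom, pos, ref, alt))
    both <- tapply(pass, key, all)
    pass <- pass & both[key]
  }
  variants$passed_caller_filters <- pass
  variants$failed_rules <- failed
  variants$germline_artefact_flags <- NA_character_
  variants$classification <- "excluded"
  variants$driver_rule_ids <- ""
  ok <- which(pass)
  if (length(ok)) {
    flags <- flag_germline_or_artefact(variants[ok, , drop = FALSE],
                                       recurrence_min)
    variants$germline_artefact_flags[ok] <- flags
    clean <- ok[flags == ""]
    if (length(clean)) {
      cls <- classify_driver(variants[clean, , drop = FALSE], resources)
      variants$classification[clean] <- cls$classification
      variants$driver_rule_ids[clean] <- cls$driver_rule_ids
    }
  }
  variants
}

#' Sample-level clonal hematopoiesis classification
#'
#' A sample has CH when it carries at least one pathogenic driver mutation
#' at or above the VAF cutoff. Driver counts are reported in two VAF bands
#' (>= 0.01 and >= 0.02) alongside the call at the chosen cutoff.
#'
#' @param variants Annotated variant table for one sample (from
#'   [annotate_variants()] or with a \code{classification} column).
#' @param vaf_cutoff VAF at or above which a driver defines CH.
#' @return List: \code{ch_status} (logical), \code{n_drivers} (at cutoff),
#'   \code{n_drivers_001}, \code{n_drivers_002}.
#' @export
classify_sample_ch <- function(variants, vaf_cutoff = 0.02) {
  drv <- variants$classification == "pathogenic_driver"
  at <- function(cut) sum(drv & variants$vaf >= cut)
  list(ch_status = at(vaf_cutoff) >= 1,
       n_drivers = at(vaf_cutoff),
       n_drivers_001 = at(0.01),
       n_drivers_002 = at(0.02))
}
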