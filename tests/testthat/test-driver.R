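base_variant <- function(...) {
  v <- data.frame(gene = "DNMT3A", chrom = "chr2", pos = 25457242,
                  ref = "C", alt = "T", variant_class = "SNV",
                  consequence = "missense", protein_position = 50,
                  protein_change = "p.R50C", vaf = 0.05, depth = 800,
                  alt_reads = 40, alt_reads_forward = 20,
                  alt_reads_reverse = 20, mean_base_quality = 35,
                  mean_mapping_quality = 60, strand_bias_p = 0.5,
                  position_bias_flag = FALSE, caller = "vardict",
                  caller_filters = "PASS", population_af = 0,
                  cosmic_count = 0, ch_list_member = FALSE,
                  in_panel_of_normals = FALSE, cohort_recurrence = 1,
                  in_interpro_domain = FALSE, stringsAsFactors = FALSE)
  mods <- list(...)
  v[names(mods)] <- mods
  v
}

test_that("VarDict post-filters enforce each published threshold at its
           boundary", {
  # boundary pass: exactly 5 alt reads (2 fwd / 3 rev), BQ/MQ at minimum
  v <- base_variant(alt_reads = 5, alt_reads_forward = 2,
                    alt_reads_reverse = 3, mean_base_quality = 30,
                    mean_mapping_quality = 40, strand_bias_p = 0.0001)
  expect_true(apply_vardict_filters(v)$pass)
  # one unit below each threshold fails with the matching rule id
  cases <- list(
    list(mod = list(alt_reads = 4, alt_reads_forward = 2,
                    alt_reads_reverse = 2), rule = "min_reads"),
    list(mod = list(alt_reads_forward = 1), rule = "min_reads"),
    list(mod = list(mean_base_quality = 29), rule = "base_quality"),
    list(mod = list(mean_mapping_quality = 39), rule = "mapping_quality"),
    list(mod = list(strand_bias_p = 0.00009), rule = "strand_bias"),
    list(mod = list(position_bias_flag = TRUE), rule = "position_bias"))
  for (cs in cases) {
    vv <- do.call(base_variant, cs$mod)
    res <- apply_vardict_filters(vv)
    expect_false(res$pass)
    expect_match(res$failed_rules, cs$rule)
  }
  # U2AF1 mapping-quality exception
  u <- base_variant(gene = "U2AF1", mean_mapping_quality = 10)
  expect_true(apply_vardict_filters(u)$pass)
  # indels need 10 reads with 4 per strand
  ind <- base_variant(variant_class = "indel", alt_reads = 9,
                      alt_reads_forward = 4, alt_reads_reverse = 5)
  expect_false(apply_vardict_filters(ind)$pass)
  ind10 <- base_variant(variant_class = "indel", alt_reads = 10,
                        alt_reads_forward = 4, alt_reads_reverse = 6)
  expect_true(apply_vardict_filters(ind10)$pass)
  # missing fields are named
  expect_error(apply_vardict_filters(base_variant()[, -(13:14)]),
               "alt_reads_forward")
})

test_that("Mutect2 filters allow PASS and clustered_events only", {
  m <- base_variant(caller = "mutect2",
                    caller_filters = "clustered_events",
                    alt_reads = 6, alt_reads_forward = 3,
                    alt_reads_reverse = 3)
  expect_true(apply_mutect2_filters(m)$pass)
  m2 <- base_variant(caller = "mutect2", caller_filters = "PASS",
                     alt_reads = 4, alt_reads_forward = 2,
                     alt_reads_reverse = 2)
  expect_false(apply_mutect2_filters(m2)$pass)
  m3 <- base_variant(caller = "mutect2", caller_filters = "germline_risk")
  expect_false(apply_mutect2_filters(m3)$pass)
})

test_that("germline and artefact flags fire with their documented rescues", {
  # hotspot rescue of a common-population variant
  expect_equal(flag_germline_or_artefact(
    base_variant(population_af = 0.002, cosmic_count = 150)), "")
  expect_match(flag_germline_or_artefact(
    base_variant(population_af = 0.002)), "popAF")
  # boundary: 0.001 is not > 0.001
  expect_equal(flag_germline_or_artefact(
    base_variant(population_af = 0.001)), "")
  # germline VAF band with COSMIC rescue
  expect_match(flag_germline_or_artefact(base_variant(vaf = 0.50)),
               "germline_vaf_band")
  expect_match(flag_germline_or_artefact(base_variant(vaf = 0.95)),
               "germline_vaf_band")
  expect_equal(flag_germline_or_artefact(
    base_variant(vaf = 0.50, cosmic_count = 6)), "")
  expect_equal(flag_germline_or_artefact(base_variant(vaf = 0.399)), "")
  expect_equal(flag_germline_or_artefact(base_variant(vaf = 0.601)), "")
  # panel of normals and cohort recurrence
  expect_match(flag_germline_or_artefact(
    base_variant(in_panel_of_normals = TRUE)), "panel_of_normals")
  expect_match(flag_germline_or_artefact(
    base_variant(cohort_recurrence = 3)), "cohort_recurrent")
  expect_equal(flag_germline_or_artefact(
    base_variant(cohort_recurrence = 3, cosmic_count = 5)), "")
  # clean somatic-looking variant
  expect_equal(flag_germline_or_artefact(base_variant(vaf = 0.12)), "")
  # missing annotations are flagged, not passed
  expect_equal(flag_germline_or_artefact(
    base_variant(population_af = NA)), "unevaluable")
})

test_that("driver rules 1-8 classify the documented cases", {
  res <- driver_resources()
  cls <- function(...) classify_driver(base_variant(...), res)
  # hotspot missense
  r <- cls(protein_position = 882, consequence = "missense", vaf = 0.05)
  expect_equal(r$classification, "pathogenic_driver")
  expect_match(r$driver_rule_ids, "rule2_hotspot")
  # TET2 domain window
  r <- cls(gene = "TET2", protein_position = 1200, vaf = 0.03)
  expect_match(r$driver_rule_ids, "rule3_domain_window")
  expect_equal(cls(gene = "TET2", protein_position = 1103,
                   vaf = 0.03)$classification, "VUS")
  # truncating in a listed gene; synonymous can never be a driver
  r <- cls(gene = "ASXL1", consequence = "nonsense", protein_position = 50)
  expect_match(r$driver_rule_ids, "rule1_truncating_gene")
  expect_equal(cls(consequence = "synonymous",
                   cosmic_count = 500)$classification, "VUS")
  # CALR exon 9 truncating and FLT3-ITD
  r <- classify_driver(cbind(base_variant(gene = "CALR",
                                          consequence = "frameshift",
                                          protein_position = 370),
                             exon = 9), res)
  expect_match(r$driver_rule_ids, "rule4_calr_exon9")
  r <- cls(gene = "FLT3", variant_class = "ITD", consequence = "inframe",
           protein_position = 600)
  expect_match(r$driver_rule_ids, "rule5_flt3_itd")
  # COSMIC count rules with their VAF condition boundaries
  expect_match(cls(cosmic_count = 10, vaf = 0.39)$driver_rule_ids,
               "rule6_cosmic10_vaf")
  expect_equal(cls(cosmic_count = 10, vaf = 0.4)$classification, "VUS")
  expect_match(cls(in_interpro_domain = TRUE,
                   vaf = 0.39)$driver_rule_ids, "rule7_interpro_vaf")
  expect_match(cls(cosmic_count = 101, vaf = 0.45)$driver_rule_ids,
               "rule8_cosmic100")
  expect_equal(cls(cosmic_count = 100, vaf = 0.45)$classification, "VUS")
})

test_that("classifications replay exactly from their recorded rule trace", {
  res <- driver_resources()
  set.seed(5)
  pool <- do.call(rbind, lapply(1:40, function(i) {
    base_variant(gene = sample(c("DNMT3A", "TET2", "TP53", "GATA2"), 1),
                 consequence = sample(c("missense", "nonsense",
                                        "synonymous", "frameshift"), 1),
                 protein_position = sample(c(50, 882, 1200, 1900), 1),
                 vaf = runif(1, 0.01, 0.6),
                 cosmic_count = sample(c(0, 5, 12, 150), 1),
                 in_interpro_domain = sample(c(TRUE, FALSE), 1))
  }))
  out <- classify_driver(pool, res)
  expect_true(all((out$driver_rule_ids != "") ==
                    (out$classification == "pathogenic_driver")))
})

test_that("adding COSMIC evidence never demotes a driver", {
  res <- driver_resources()
  set.seed(6)
  for (i in 1:20) {
    v <- base_variant(consequence = "missense",
                      protein_position = sample(c(50, 882), 1),
                      vaf = runif(1, 0.01, 0.5),
                      cosmic_count = sample(0:20, 1))
    before <- classify_driver(v, res)$classification
    v$cosmic_count <- v$cosmic_count + sample(c(10, 200), 1)
    after <- classify_driver(v, res)$classification
    if (before == "pathogenic_driver") {
      expect_equal(after, "pathogenic_driver")
    }
  }
})

test_that("sample CH status respects the two VAF reporting bands", {
  v <- rbind(base_variant(vaf = 0.25), base_variant(vaf = 0.03),
             base_variant(vaf = 0.011))
  v$classification <- "pathogenic_driver"
  st <- classify_sample_ch(v, vaf_cutoff = 0.02)
  expect_true(st$ch_status)
  expect_equal(st$n_drivers_002, 2)
  expect_equal(st$n_drivers_001, 3)
  # borderline case: driver at 0.015 only counts at the 0.01 band
  v2 <- base_variant(vaf = 0.015)
  v2$classification <- "pathogenic_driver"
  expect_false(classify_sample_ch(v2, 0.02)$ch_status)
  expect_true(classify_sample_ch(v2, 0.01)$ch_status)
  # no drivers
  v3 <- base_variant()
  v3$classification <- "VUS"
  expect_false(classify_sample_ch(v3, 0.01)$ch_status)
  # raising the cutoff never makes more samples CH-positive
  cuts <- c(0.01, 0.02, 0.05, 0.1, 0.3)
  n_pos <- sapply(cuts, function(ct) classify_sample_ch(v, ct)$n_drivers)
  expect_true(all(diff(n_pos) <= 0))
})

test_that("the full annotation pipeline records a complete rule trace", {
  variants <- rbind(
    base_variant(),                                   # clean VUS
    base_variant(protein_position = 882),             # driver
    base_variant(vaf = 0.5),                          # germline band
    base_variant(mean_base_quality = 20))             # filter fail
  out <- annotate_variants(variants)
  expect_equal(out$classification,
               c("VUS", "pathogenic_driver", "excluded", "excluded"))
  expect_equal(out$passed_caller_filters, c(TRUE, TRUE, TRUE, FALSE))
  expect_match(out$germline_artefact_flags[3], "germline_vaf_band")
  expect_match(out$failed_rules[4], "base_quality")
})
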