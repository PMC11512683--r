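cfg <- run_config()

test_that("scVAF is the exact variant-read fraction", {
  expect_identical(compute_scvaf(0, 100), 0)
  expect_identical(compute_scvaf(50, 100), 0.5)
  expect_identical(compute_scvaf(3, 60), 0.05)
  expect_error(compute_scvaf(1, 0), "UNDETECTED")
  expect_error(compute_scvaf(5, 4), "\\[0, coverage\\]")
})

test_that("control thresholds reproduce the mean + 3SD (+ margin) rule", {
  # worked example: control moments 0.000719 / 0.000472 give a WT cutoff
  # of ~0.002136 and a mutant cutoff of ~0.012136 (published to 6 dp from
  # unrounded data; recomputation from the rounded moments is 1e-6 lower)
  x <- moments_sample(0.000719, 0.000472, n = 100)
  thr <- derive_thresholds(x, "TET2_pR1261C_gDNA", cfg)
  expect_equal(thr$control_mean, 0.000719, tolerance = 1e-12)
  expect_equal(thr$control_sd, 0.000472, tolerance = 1e-12)
  expect_lt(abs(thr$wt_threshold - 0.002136), 1.5e-6)
  expect_lt(abs(thr$mutant_threshold - 0.012136), 1.5e-6)
  expect_equal(thr$hom_mutant_threshold, 1 - thr$mutant_threshold)

  # zero-noise locus
  thr0 <- derive_thresholds(rep(0, 50), "clean", cfg)
  expect_equal(thr0$wt_threshold, 0)
  expect_equal(thr0$mutant_threshold, 0.01)
  expect_equal(thr0$hom_mutant_threshold, 0.99)

  # beta-distributed controls vs an independent direct-moment pass
  set.seed(31)
  b <- rbeta(500, 2, 2000)
  thr_b <- derive_thresholds(b, "beta", cfg)
  m <- sum(b) / length(b)
  s <- sqrt(sum((b - m)^2) / (length(b) - 1))
  expect_equal(thr_b$wt_threshold, m + 3 * s, tolerance = 1e-12)
  expect_equal(thr_b$mutant_threshold, m + 3 * s + 0.01, tolerance = 1e-12)

  expect_error(derive_thresholds(rep(0, 5), "few", cfg), "few")
})

test_that("amplicon calls match an exhaustive hand-enumerated truth table", {
  thr <- threshold_set("amp", wt_threshold = 0.002136, config = cfg)
  # independent plain-if oracle over (analyte, coverage, alt) cases
  oracle <- function(ref, alt, analyte) {
    cov <- ref + alt
    min_cov <- if (analyte == "gDNA") 50 else 30
    if (cov < min_cov) return("UNDETECTED")
    v <- alt / cov
    if (v < 0.002136) return("WT")
    if (v >= 0.012136) {
      if (alt < 10) return("UNDETERMINED")
      if (v >= 1 - 0.012136) return("HOM_MUT")
      return("MUT")
    }
    "UNDETERMINED"
  }
  cases <- expand.grid(
    coverage = c(0, 20, 29, 30, 49, 50, 100, 400, 1000),
    scvaf_band = c(0, 0.001, 0.0022, 0.005, 0.0122, 0.02, 0.5, 0.99,
                   0.995, 1),
    analyte = c("gDNA", "cDNA"), stringsAsFactors = FALSE)
  cases$alt <- round(cases$coverage * cases$scvaf_band)
  cases$ref <- cases$coverage - cases$alt
  keep <- cases$coverage > 0
  cases <- cases[keep, ]
  got <- mapply(function(r, a, an) {
    call_amplicon(r, a, an, thr, cfg)$call
  }, cases$ref, cases$alt, cases$analyte)
  want <- mapply(oracle, cases$ref, cases$alt, cases$analyte)
  expect_equal(unname(got), unname(want))
})

test_that("published boundary cases call as expected", {
  thr <- threshold_set("TET2", wt_threshold = 0.002136, config = cfg)
  # gDNA coverage below 50 is undetected
  expect_equal(call_amplicon(15, 5, "gDNA", thr, cfg)$call, "UNDETECTED")
  # above threshold but < 10 mutant reads
  expect_equal(call_amplicon(392, 8, "gDNA", thr, cfg)$call,
               "UNDETERMINED")
  # mid-range heterozygote
  expect_equal(call_amplicon(50, 50, "gDNA", thr, cfg)$call, "MUT")
  # near-1 scVAF is homozygous mutant
  expect_equal(call_amplicon(1, 199, "gDNA", thr, cfg)$call, "HOM_MUT")
  # hemizygous loci never get the homozygous label
  expect_equal(call_amplicon(1, 199, "gDNA", thr, cfg,
                             ploidy = "hemizygous")$call, "MUT")
})

test_that("consensus covers all input states and follows the four rules", {
  expect_equal(consensus_call("WT", "UNDETECTED"), "WT")
  expect_equal(consensus_call("UNDETECTED", "WT"), "UNDETERMINED")
  expect_equal(consensus_call("WT", "MUT"), "MUT")
  expect_equal(consensus_call("WT", "WT"), "WT")
  expect_equal(consensus_call("WT", NA), "WT")
  expect_equal(consensus_call("HOM_MUT", "UNDETECTED"), "MUT")

  states <- c("WT", "MUT", "HOM_MUT", "UNDETERMINED", "UNDETECTED")
  grid <- expand.grid(g = states, c = c(states, NA),
                      stringsAsFactors = FALSE)
  got <- consensus_call(grid$g, grid$c)
  expect_true(all(got %in% c("WT", "MUT", "UNDETERMINED")))
  # rule 1 dominates everywhere
  mut_any <- grid$g %in% c("MUT", "HOM_MUT") |
    (!is.na(grid$c) & grid$c %in% c("MUT", "HOM_MUT"))
  expect_true(all(got[mut_any] == "MUT"))
  # WT requires a WT gDNA call (or double WT); never from cDNA alone
  expect_true(all(grid$g[got == "WT"] == "WT"))
})

test_that("false-positive validation bounds and matches Monte Carlo", {
  # degenerate all-zero controls
  thr0 <- threshold_set("z", 0, config = cfg)
  expect_message(v0 <- validate_fp_probability(rep(0, 50), thr0, cfg),
                 "all-zero")
  expect_equal(v0$fp_probability, 0)

  # published-moments beta tail stays under the reported 0.006 bound
  fit <- fit_beta_moments(0.000719, 0.000472)
  tail <- pbeta(0.000719 + 3 * 0.000472 + 0.01, fit[["shape1"]],
                fit[["shape2"]], lower.tail = FALSE)
  expect_lte(tail, 0.006)

  # bootstrap tails vs an independent Monte-Carlo estimate
  set.seed(91)
  x <- rbeta(400, 2, 2000)
  thr <- threshold_set("b", 0.01, config = cfg)  # mutant threshold 0.02
  cfg_seeded <- run_config(rng_seed = 17)
  v <- validate_fp_probability(x, thr, cfg_seeded)
  # independent method-of-moments fit and 1e6-draw tail estimate
  m <- mean(x); s <- sd(x)
  k <- m * (1 - m) / s^2 - 1
  mc <- mean(rbeta(1e6, m * k, (1 - m) * k) > 0.02)
  se_boot <- sd(v$replicates)
  se_mc <- sqrt(max(mc * (1 - mc), 1e-12) / 1e6)
  expect_lt(abs(v$fp_probability - mc), 3 * (se_boot + se_mc) + 1e-9)
  expect_gte(v$fp_probability, 0)
  expect_lte(v$fp_probability, 1)
})

test_that("WT-only cells are miscalled no more often than the validated
           false-positive probability", {
  sc <- sim_config(tree = clone_tree(0L, "M"),
                   loci = data.frame(mutation_id = "M",
                                     error_rate = 0.002,
                                     has_cdna = FALSE))
  ctrl <- simulate_wt_controls(sc, n_cells = 400, seed = 21)
  cov <- ctrl$ref_reads + ctrl$alt_reads
  keep <- cov >= cfg$min_coverage_gdna
  scv <- ctrl$alt_reads[keep] / cov[keep]
  half <- seq_along(scv) %% 2 == 0
  thr <- derive_thresholds(scv[half], "M_gDNA", cfg)
  v <- validate_fp_probability(scv[half], thr, run_config(rng_seed = 3))
  # fresh WT cells, same noise process
  called <- call_amplicon(ctrl$ref_reads[keep][!half],
                          ctrl$alt_reads[keep][!half], "gDNA", thr, cfg)
  frac_mut <- mean(called$call %in% c("MUT", "HOM_MUT"))
  n <- sum(!half)
  bound <- v$fp_probability +
    3 * sqrt(max(v$fp_probability * (1 - v$fp_probability), 1 / n) / n)
  expect_lte(frac_mut, bound)
})

test_that("raising sd_multiplier or mutant_margin never adds MUT calls", {
  sim <- simulate_cells(linear_sim_config(n_cells = 400, snp = FALSE),
                        seed = 13)
  n_mut <- function(cfg2) {
    calls <- call_genotypes(sim$dataset, config = cfg2)
    sum(calls$consensus == "MUT")
  }
  by_sd <- sapply(c(2, 3, 5), function(k) n_mut(run_config(sd_multiplier = k)))
  by_margin <- sapply(c(0.005, 0.01, 0.05, 0.2),
                      function(m) n_mut(run_config(mutant_margin = m)))
  expect_true(all(diff(by_sd) <= 0))
  expect_true(all(diff(by_margin) <= 0))
})

test_that("density minima separate the three scVAF peaks", {
  mix <- function(seed, n = 2000, w = c(0.10, 0.80, 0.10)) {
    set.seed(seed)
    comp <- sample(1:3, n, replace = TRUE, prob = w)
    x <- numeric(n)
    x[comp == 1] <- rbeta(sum(comp == 1), 1, 332)       # hom-ref noise
    x[comp == 2] <- rbeta(sum(comp == 2), 1.5, 1.5)     # skewed het
    x[comp == 3] <- 1 - rbeta(sum(comp == 3), 1, 332)   # hom-alt
    x
  }
  x <- mix(1)
  thr <- minima_thresholds(x, "locus")
  expect_lt(abs(thr$mutant_threshold - 0.15), 0.05)
  expect_lt(abs(thr$hom_mutant_threshold - 0.85), 0.05)

  # grid-search oracle over an independently evaluated KDE curve
  d <- density(x, kernel = "gaussian", bw = "nrd0", from = 0, to = 1,
               n = 1001)
  lo_region <- d$x > 0.05 & d$x < 0.45
  hi_region <- d$x > 0.55 & d$x < 0.95
  expect_equal(thr$mutant_threshold,
               d$x[lo_region][which.min(d$y[lo_region])])
  expect_equal(thr$hom_mutant_threshold,
               d$x[hi_region][which.min(d$y[hi_region])])

  # unimodal distribution has no separating minima
  set.seed(2)
  expect_error(minima_thresholds(rbeta(500, 2, 2), "u"), "three")
})

test_that("minima-based calling moves borderline mutants to undetermined,
           never the reverse", {
  sc <- sim_config(n_cells = 1000, clusters = list(one = c(M = 0.5)),
                   tree = clone_tree(0L, "M"),
                   loci = data.frame(mutation_id = "M", error_rate = 0.001,
                                     ado_prob_gdna = 0.12,
                                     has_cdna = FALSE))
  sim <- simulate_cells(sc, seed = 7)
  cfg_min <- run_config(calling_strategy = "distribution_minima")
  thr_ctrl <- derive_thresholds_all(sim$dataset, cfg)
  thr_min <- derive_thresholds_all(sim$dataset, cfg_min)
  # the density minimum sits far above the control-derived cutoff
  expect_gt(thr_min$mutant_threshold, thr_ctrl$mutant_threshold)
  ctrl_calls <- call_genotypes(sim$dataset, thr_ctrl, cfg)
  min_calls <- call_genotypes(sim$dataset, thr_min, cfg_min)
  expect_identical(ctrl_calls$cell_id, min_calls$cell_id)
  # every undetermined cell under control thresholds stays undetermined,
  # and some control-called mutants are reassigned
  und_ctrl <- ctrl_calls$consensus == "UNDETERMINED"
  und_min <- min_calls$consensus == "UNDETERMINED"
  expect_true(all(und_min[und_ctrl]))
  reassigned <- ctrl_calls$consensus == "MUT" & und_min
  expect_gt(sum(reassigned), 0)
  # no cell gains a MUT call under the higher cutoff
  expect_true(all(ctrl_calls$consensus[min_calls$consensus == "MUT"]
                  == "MUT"))
})
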