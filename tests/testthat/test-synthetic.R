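test_that("the default truth encodes a consistent four-sector study", {
  cfg <- truth_config()
  sec <- cfg$sectors
  expect_equal(sec$phi_R + sec$phi_M + sec$phi_U + sec$phi_Q,
               rep(1, nrow(sec)), tolerance = 1e-12)
  expect_true(all(sec$phi_Q == sec$phi_Q[1]))       # Q is strain-independent
  expect_true(all(sec[, c("phi_R", "phi_M", "phi_U", "phi_Q")] >= 0 &
                    sec[, c("phi_R", "phi_M", "phi_U", "phi_Q")] <= 1))
  # growth-law consistency: lambda = tE phi_R = mE phi_M
  expect_equal(sec$tE * sec$phi_R, sec$lambda, tolerance = 1e-12)
  expect_equal(sec$mE * sec$phi_M, sec$lambda, tolerance = 1e-12)
  # planted efficiency-ratio fold changes
  expect_equal(sec$fold_change, c(1, 3.26, 3.24, 2.26), tolerance = 1e-12)
  # mutants grow 16-25% slower than wild type
  red <- 1 - sec$lambda[-1] / sec$lambda[1]
  expect_true(all(red >= 0.15 & red <= 0.25))
})

test_that("infeasible truth configurations are rejected", {
  expect_error(truth_config(phi_R = c(WT = 0.50, ihf = 0.175, fnr = 0.165,
                                      arcA = 0.155)), "phi_R")
  # a tiny fold change forces phi_M above the available budget
  expect_error(truth_config(fold_change = c(ihf = 0.1, fnr = 3.24,
                                            arcA = 2.26)), "infeasible")
  expect_error(truth_config(phi_R = c(0.13, 0.17, 0.16, 0.15)), "named")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- truth_config(seed = 99, n_genes = 1000)
  b1 <- generate_study(cfg)
  b2 <- generate_study(cfg)
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$peaks, b2$peaks)
  expect_identical(b1$od_series, b2$od_series)
  expect_identical(b1$deg_table, b2$deg_table)
  # a different seed perturbs the stochastic layers
  b3 <- generate_study(truth_config(seed = 100, n_genes = 1000))
  expect_false(identical(b1$counts, b3$counts))
})

test_that("the gene catalog carries lengths, classes and planted structure", {
  cfg <- truth_config(seed = 2, n_genes = 1000)
  cat <- generate_gene_catalog(cfg)
  expect_equal(nrow(cat), 1000)
  expect_true(all(cat$length > 0))
  expect_true(all(cat$me_class %in% c("utilized", "nonutilized", "outside")))
  # sector-assigned genes are never shorter than the TPM length filter
  expect_true(all(cat$length[cat$sector_true != "other"] >= 200))
  # some background genes fall below the mean fragment length and will be
  # excluded from TPM downstream
  expect_gt(sum(cat$length < cfg$mean_fragment_length), 0)
  # regulator DEGs are outside ME scope
  expect_true(all(cat$me_class[cat$is_regulator] == "outside"))

  # explicit small catalogs for fixtures
  small <- generate_gene_catalog(cfg, sector_labels = rep("M", 10))
  expect_equal(nrow(small), 10)
  expect_true(all(small$sector_true == "M"))
  expect_error(generate_gene_catalog(cfg, sector_labels = c("M", "Z")),
               "sector_labels")
})

test_that("counts are integer-valued in stochastic mode, exact in the noise-free limit", {
  noisy <- noisy_bundle()
  expect_true(all(noisy$counts >= 0))
  expect_true(all(noisy$counts == round(noisy$counts)))
  nf <- noise_free_bundle()
  # idealized mode: counts equal their expectations (real-valued)
  w <- nf$truth$weights
  depth <- nf$truth$config$library_depth
  expect_equal(unname(nf$counts[, "WT_1"]), unname(w[, "WT"] * depth))
  expect_identical(nf$counts[, "WT_1"], nf$counts[, "WT_2"])
})

test_that("OD series stay positive and encode the planted growth rates", {
  b <- noisy_bundle()
  expect_true(all(b$od_series$od > 0))
  truth <- b$truth$config$sectors
  for (s in truth$strain) {
    od <- b$od_series[b$od_series$strain == s & b$od_series$bio_rep == 2, ]
    fit <- fit_growth_rate(od$time, od$od)
    expect_lt(abs(fit$lambda - truth$lambda[truth$strain == s]) /
                truth$lambda[truth$strain == s], 0.1)
  }
})

test_that("metabolite replicate structure is 3 biological x 2 technical", {
  b <- noisy_bundle()
  tab <- table(b$peaks$strain, b$peaks$metabolite)
  expect_true(all(tab == 6))
  per <- b$peaks[b$peaks$strain == "WT" & b$peaks$metabolite == "PEP", ]
  expect_equal(sort(unique(per$bio_rep)), 1:3)
  expect_equal(sort(unique(per$tech_rep)), 1:2)
})

test_that("truth configurations round-trip through YAML", {
  cfg <- truth_config(seed = 12, n_genes = 1200, noise_cv = 0.07)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth_config(cfg, path)
  cfg2 <- read_truth_config(path)
  expect_equal(cfg2$sectors, cfg$sectors, tolerance = 1e-12)
  expect_equal(cfg2$noise_cv, 0.07)
  expect_equal(cfg2$metabolite_truth, cfg$metabolite_truth)
  # the restored config generates an identical study
  expect_identical(generate_study(cfg2)$counts, generate_study(cfg)$counts)
})

test_that("bundles round-trip through the plain-text serialization", {
  b <- noise_free_bundle()
  dir <- withr::local_tempdir()
  write_study_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "counts.tsv", "catalog.tsv", "deg.tsv", "flux.tsv", "phenotypes.csv",
    "peaks.csv", "calibration.csv", "truth.json", "regulators.tsv")))))
  r <- read_study_bundle(dir)
  expect_equal(r$counts, b$counts)
  expect_equal(r$catalog$gene, b$catalog$gene)
  expect_equal(r$deg_table$log2fc, b$deg_table$log2fc)
  expect_equal(r$flux_table, b$flux_table)
  expect_equal(r$regulators$RegB$mode, "repressor")
  expect_equal(sort(r$gene_sets$regulon_RegB),
               sort(b$gene_sets$regulon_RegB))
  # a missing mandatory file is reported by name
  unlink(file.path(dir, "counts.tsv"))
  expect_error(read_study_bundle(dir), "counts.tsv")
})
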