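test_that("cpm filter removes genes below 0.5 cpm in any library", {
  counts <- rbind(zero = c(0, 0),
                  boundary = c(1, 1),     # 0.5 cpm in both libraries
                  uneven = c(1, 0),       # 1.0 and 0.0 cpm
                  high = c(1999998, 1999999))
  colnames(counts) <- c("a", "b")
  # library sizes ~2e6 each
  keep <- filter_low_counts(counts)
  expect_false("zero" %in% keep)
  expect_false("uneven" %in% keep)
  expect_true("high" %in% keep)
  # boundary: cpm exactly 0.5 is retained (only < 0.5 is removed)
  cpm_b <- cpm(counts)["boundary", ]
  expect_equal(unname(cpm_b), c(0.5, 0.5), tolerance = 1e-6)
  expect_true("boundary" %in% keep)
  expect_error(filter_low_counts(matrix(numeric(0), 0, 0)), "empty")
})

test_that("cpm agrees with the edgeR implementation", {
  set.seed(3)
  counts <- matrix(rpois(600, 50), nrow = 100,
                   dimnames = list(sprintf("g%03d", 1:100), NULL))
  expect_equal(unname(cpm(counts)),
               unname(as.matrix(edgeR::cpm(counts))), tolerance = 1e-12)
})

test_that("TPM normalizes length-corrected rates to one million", {
  lens <- c(g1 = 1000, g2 = 500)
  tpm <- compute_tpm(c(g1 = 10, g2 = 20), lens, mean_fragment_length = 150)
  expect_equal(unname(tpm[, 1]), c(2e5, 8e5))
  expect_equal(sum(tpm), 1e6)

  # a single retained gene takes the whole million
  one <- compute_tpm(c(g1 = 7), c(g1 = 300), mean_fragment_length = 150)
  expect_equal(unname(one[1, 1]), 1e6)

  # genes shorter than the mean fragment length are excluded up front
  tpm2 <- compute_tpm(c(g1 = 10, g2 = 20, g3 = 30),
                      c(g1 = 1000, g2 = 500, g3 = 100),
                      mean_fragment_length = 150)
  expect_false("g3" %in% rownames(tpm2))
  expect_equal(unname(tpm2[, 1]), c(2e5, 8e5))

  expect_error(compute_tpm(c(g1 = 5), c(g1 = 100),
                           mean_fragment_length = 150), "all genes removed")

  # conservation on random matrices
  set.seed(8)
  m <- matrix(rpois(300, 40), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  lens <- setNames(sample(200:2000, 50), rownames(m))
  expect_equal(unname(colSums(compute_tpm(m, lens, 150))), rep(1e6, 6))
})

test_that("DEG calls respect the fold-change and p-value boundaries", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(1.0, 0.9, -2, -1),
                    adj_p = c(0.049, 1e-8, 0.05, 0.01))
  out <- apply_deg_thresholds(tab)
  expect_equal(out$call, c("up", "none", "none", "down"))
  expect_error(apply_deg_thresholds(data.frame(gene = "a")), "columns")

  tab$mutant <- "m1"
  sets <- deg_sets(apply_deg_thresholds(tab))
  expect_equal(sets$m1$up, "a")
  expect_equal(sets$m1$down, "d")
  expect_equal(sets$union, c("a", "d"))
  # up and down sets are disjoint by construction
  expect_length(intersect(sets$m1$up, sets$m1$down), 0)
})

test_that("Benjamini-Hochberg adjustment equals the step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  for (n in c(3, 17, 200, 1000)) {
    p <- runif(n)^2
    expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("sector fractions use TPM x length weights over the assigned set", {
  # hand example: M with TPM (100, 300), U with TPM 400, equal lengths
  tpm <- c(m1 = 100, m2 = 300, u1 = 400)
  lens <- c(m1 = 1000, m2 = 1000, u1 = 1000)
  sec <- c(m1 = "M", m2 = "M", u1 = "U")
  sfr <- sector_fraction_ratio(tpm, lens, sec)
  expect_equal(sfr$um_ratio, 1.0)
  expect_equal(sfr$frac_M + sfr$frac_U, 1)

  # all assigned genes in M
  expect_equal(sector_fraction_ratio(tpm, lens,
                                     c(m1 = "M", m2 = "M", u1 = "M"))$um_ratio,
               0)
  # no M gene: ratio undefined
  expect_error(sector_fraction_ratio(tpm, lens,
                                     c(m1 = "U", m2 = "U", u1 = "U")),
               "M sector")

  # invariance to uniform TPM rescaling
  expect_equal(sector_fraction_ratio(tpm * 3.7, lens, sec)$um_ratio,
               sfr$um_ratio)

  # unequal lengths weight genes by nucleotide fraction
  lens2 <- c(m1 = 2000, m2 = 1000, u1 = 1000)
  sfr2 <- sector_fraction_ratio(tpm, lens2, sec)
  expect_equal(sfr2$um_ratio, 400 / (200 + 300))
})

test_that("noise-free bundle recovers the planted U/M ratio exactly", {
  res <- noise_free_result()
  truth <- noise_free_bundle()$truth$config$sectors
  expect_equal(res$transcriptome$um_ratio, truth$um_ratio,
               tolerance = 1e-12)
  expect_equal(res$transcriptome$frac_M,
               truth$phi_M / (truth$phi_M + truth$phi_U), tolerance = 1e-12)
})
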