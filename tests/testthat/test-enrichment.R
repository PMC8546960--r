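test_that("Fisher over-representation p equals the hypergeometric oracle", {
  bg <- sprintf("g%04d", 1:1000)
  deg <- bg[1:50]
  set <- bg[c(1:5, 500:504)]     # 5 of 10 in the DEG list
  res <- fisher_set_enrichment(deg, set, bg)
  expect_equal(res$overlap, 5)
  expect_equal(res$p, hyper_tail_oracle(5, 10, 50, 1000), tolerance = 1e-12)
  expect_true(res$significant)

  # agreement with one-sided fisher.test on the same 2x2 table
  ft <- fisher.test(matrix(c(5, 5, 45, 945), 2), alternative = "greater")
  expect_equal(res$p, ft$p.value, tolerance = 1e-9)

  # sampled random tables against the oracle
  set.seed(21)
  for (i in 1:50) {
    N <- sample(10:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    x <- sample(max(0, K + n - N):min(K, n), 1)
    expect_equal(sectorAlloc:::hyper_tail_p(x, K, n, N),
                 hyper_tail_oracle(x, K, n, N), tolerance = 1e-12)
  }
})

test_that("degenerate and ineligible enrichment inputs are handled", {
  bg <- sprintf("g%03d", 1:100)
  # disjoint set: tail probability of overlap >= 0 is 1
  expect_equal(fisher_set_enrichment(bg[1:10], bg[50:60], bg,
                                     min_genes = 1)$p,
               1)
  # sets below the minimum size are skipped, not tested
  small <- fisher_set_enrichment(bg[1:10], bg[1:3], bg, min_genes = 5)
  expect_false(small$eligible)
  expect_true(is.na(small$p))
  expect_false(small$significant)
  expect_error(fisher_set_enrichment("a", "a", character()), "background")
})

test_that("enrichment p is invariant to relabeling genes outside set and list", {
  bg1 <- c(sprintf("a%02d", 1:30), sprintf("b%02d", 1:30))
  bg2 <- c(sprintf("a%02d", 1:30), sprintf("c%02d", 1:30))
  deg <- sprintf("a%02d", 1:12)
  set <- sprintf("a%02d", 8:20)
  expect_equal(fisher_set_enrichment(deg, set, bg1)$p,
               fisher_set_enrichment(deg, set, bg2)$p)
})

test_that("pathway enrichment applies the 10-DEG rule and BH correction", {
  bg <- sprintf("g%04d", 1:500)
  deg <- bg[1:60]
  paths <- list(hit = bg[c(1:30, 400:420)],     # 30 DEGs: tested, enriched
                thin = bg[c(1:9, 450:480)],     # 9 DEGs: excluded
                null = bg[300:350])
  res <- pathway_enrichment(deg, paths, bg)
  expect_true(res$tested[res$pathway == "hit"])
  expect_false(res$tested[res$pathway == "thin"])
  expect_true(res$significant[res$pathway == "hit"])
  # BH across tested pathways only
  tested_p <- res$p[res$tested]
  expect_equal(res$adj_p[res$tested], benjamini_hochberg(tested_p))
  # a single tested pathway keeps its raw p
  one <- pathway_enrichment(deg, paths["hit"], bg)
  expect_equal(one$adj_p, one$p)
})

test_that("regulator activity is inferred from target enrichment and effectors", {
  bg <- sprintf("g%04d", 1:800)
  up <- bg[1:40]; down <- bg[41:80]
  repressor <- list(id = "R", mode = "repressor", targets = bg[1:20],
                    effectors = data.frame(metabolite = "putrescine",
                                           effect = -1))
  # repressor with targets enriched among up-DEGs: activity decreased
  act <- infer_activity(repressor, up, down, bg)
  expect_equal(act$expression_call, "decreased")
  expect_equal(act$call, "decreased")

  # concordant effector evidence keeps the combined call
  changes <- data.frame(metabolite = "putrescine", direction = 1,
                        significant = TRUE)
  act2 <- infer_activity(repressor, up, down, bg,
                         metabolite_changes = changes)
  expect_equal(act2$effector_call, "decreased")
  expect_equal(act2$call, "decreased")

  # discordant evidence is reported as conflicting, both calls kept
  rep2 <- modifyList(repressor, list(targets = bg[41:60]))  # enriched down
  act3 <- infer_activity(rep2, up, down, bg,
                         metabolite_changes = changes)
  expect_equal(act3$expression_call, "increased")
  expect_equal(act3$effector_call, "decreased")
  expect_equal(act3$call, "conflicting")

  # activator with no enrichment and no effector change: unchanged
  activator <- list(id = "A", mode = "activator", targets = bg[700:720],
                    effectors = NULL)
  expect_equal(infer_activity(activator, up, down, bg)$call, "unchanged")
})

test_that("ppGpp enrichment flags planted down-regulation of positive targets", {
  b <- noise_free_bundle()
  th <- pipeline_thresholds()
  deg <- deg_sets(apply_deg_thresholds(b$deg_table))
  bg <- filter_low_counts(b$counts)
  pp <- ppgpp_enrichment(deg$ihf$up, deg$ihf$down,
                         b$gene_sets$ppgpp_positive,
                         b$gene_sets$ppgpp_negative, bg)
  pos_down <- pp[pp$target_set == "positive" & pp$deg_direction == "down", ]
  expect_true(pos_down$significant)
  expect_lt(pos_down$p, 1e-4)
  # the fnr mutant carries no planted ppGpp signal
  pp_fnr <- ppgpp_enrichment(deg$fnr$up, deg$fnr$down,
                             b$gene_sets$ppgpp_positive,
                             b$gene_sets$ppgpp_negative, bg)
  expect_false(any(pp_fnr$significant))
  # empty target list is skipped
  pp0 <- ppgpp_enrichment(deg$ihf$up, deg$ihf$down, character(),
                          b$gene_sets$ppgpp_negative, bg)
  expect_false(any(pp0$eligible[pp0$target_set == "positive"]))
})

test_that("planted regulon enrichment is recovered from the synthetic bundle", {
  b <- noise_free_bundle()
  deg <- deg_sets(apply_deg_thresholds(b$deg_table))
  bg <- filter_low_counts(b$counts)
  # RegB represses U-sector genes planted as upregulated in every mutant
  res <- fisher_set_enrichment(deg$fnr$up, b$gene_sets$regulon_RegB, bg)
  expect_true(res$significant)
  expect_lt(res$p, 0.01)
})
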