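test_that("gene marking uses the interpolated empirical quantile", {
  gs <- signals_from_densities(list(m = c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)))
  # 0.75 type-7 quantile of 1:4 is 3.25 -> only the density-4 gene passes
  expect_equal(mark_genes(gs, "m", 0.75), "g4")
  expect_setequal(mark_genes(gs, "m", 0), c("g1", "g2", "g3", "g4"))
  tied <- signals_from_densities(list(m = c(a = 2, b = 2, c = 2)))
  expect_setequal(mark_genes(tied, "m", 0.9), c("a", "b", "c"))
  expect_error(mark_genes(gs, "nope"), "empty universe")
})

test_that("two-sided Fisher p-values match hand-enumerated tables", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1.0)
  # margins (10,10,10,10): only the two extreme tables are as improbable
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(2, 1, 1, 2), fisher_enum_oracle(2, 1, 1, 2),
               tolerance = 1e-12)
  expect_message(p <- fisher_exact_2x2(0, 0, 3, 4), "degenerate")
  expect_equal(p, 1.0)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("Fisher p is invariant to transposing rows and columns", {
  set.seed(5)
  for (i in 1:25) {
    cells <- as.integer(rpois(4, 6))
    p <- suppressMessages(do.call(fisher_exact_2x2, as.list(cells)))
    p_row <- suppressMessages(
      fisher_exact_2x2(cells[3], cells[4], cells[1], cells[2]))
    p_col <- suppressMessages(
      fisher_exact_2x2(cells[2], cells[1], cells[4], cells[3]))
    expect_equal(p_row, p, tolerance = 1e-12)
    expect_equal(p_col, p, tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up closed form", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(9)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_equal(q, bh_oracle(p), tolerance = 1e-14)
  expect_true(all(q >= p))
  expect_error(bh_fdr(c(0.2, 1.7)), "\\[0, 1\\]")
})

test_that("BH q-values are monotone on sorted input and permutation-stable", {
  set.seed(10)
  p <- sort(runif(30))
  expect_true(all(diff(bh_fdr(p)) >= 0))
  perm <- sample(30)
  expect_equal(bh_fdr(p[perm])[order(perm)], bh_fdr(p))
})

test_that("enrichment calls combine density fold change, Fisher and FDR", {
  # 10 set genes at density 6, 30 others at 10/3 -> background 4, FC = 1.5
  dens <- c(rep(6, 10), rep(10 / 3, 30))
  names(dens) <- sprintf("g%02d", 1:40)
  gs <- signals_from_densities(list(m = dens))
  universe <- names(dens)
  res <- call_enrichment(gs, list(S = names(dens)[1:10]), universe)
  expect_equal(res$fold_change, 1.5, tolerance = 1e-12)
  expect_equal(c(res$a, res$b, res$c, res$d), c(10, 0, 0, 30))
  # boundary inclusive: FC of exactly 1.5 counts as enriched
  expect_equal(res$direction, "enriched")
  expect_equal(res$log2fc, log2(1.5))

  # depletion mirrors at 1/1.5
  dens2 <- c(rep(2, 10), rep(38 / 10, 30))   # set density 2, background 3.35
  names(dens2) <- names(dens)
  gs2 <- signals_from_densities(list(m = dens2))
  res2 <- call_enrichment(gs2, list(S = names(dens2)[1:10]), universe)
  expect_true(res2$fold_change < 1 / 1.5)
  expect_equal(res2$direction, "depleted")

  expect_error(call_enrichment(gs, list(S = c("g01", "zz")), universe),
               "subset")
})

test_that("raw-p mode reproduces the alpha-threshold rule", {
  dens <- c(rep(6, 10), rep(2, 30))
  names(dens) <- sprintf("g%02d", 1:40)
  gs <- signals_from_densities(list(m = dens))
  res_fdr <- call_enrichment(gs, list(S = names(dens)[1:10]), names(dens),
                             q_threshold = 1e-9)
  res_raw <- call_enrichment(gs, list(S = names(dens)[1:10]), names(dens),
                             use_raw_p = TRUE, alpha = 0.05)
  expect_equal(res_raw$p_value, res_fdr$p_value)
  expect_equal(res_raw$direction, "enriched")
})

test_that("the log2FC matrix blanks non-significant cells", {
  res <- data.frame(
    set_id = c("A", "A", "B", "B"),
    mark_name = c("m1", "m2", "m1", "m2"),
    log2fc = c(1, -1, 0.2, 2),
    direction = c("enriched", "depleted", "none", "enriched"),
    stringsAsFactors = FALSE
  )
  m <- enrichment_matrix(res)
  expect_equal(m["A", "m1"], 1)
  expect_equal(m["A", "m2"], -1)
  expect_true(is.na(m["B", "m1"]))
  expect_equal(m["B", "m2"], 2)
})

test_that("pathway filtering applies the inclusive size and domain rules", {
  tab <- data.frame(
    gene_id = c(sprintf("a%02d", 1:9), sprintf("b%02d", 1:10),
                sprintf("c%02d", 1:12)),
    pathway_id = rep(c("P9", "P10", "POther"), c(9, 10, 12)),
    domain_id = rep(c("specialized", "specialized", "primary"), c(9, 10, 12)),
    stringsAsFactors = FALSE
  )
  ma <- metabolic_annotation(tab)
  sets <- filter_pathways(ma, min_genes = 10, domain = "specialized")
  expect_equal(names(sets), "P10")          # 9 genes excluded, 10 included
  all_sets <- filter_pathways(ma, min_genes = 10, domain = NULL)
  expect_setequal(names(all_sets), c("P10", "POther"))
  expect_error(filter_pathways(ma, domain = "nope"), "unknown domain")
})

test_that("domain-level sets ignore multi-domain genes entirely", {
  tab <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    pathway_id = c("P1", "P2", "P3"),
    domain_id = c("D1", "D1", "D2"),
    stringsAsFactors = FALSE
  )
  base_sets <- domain_gene_sets(metabolic_annotation(tab))
  # add a gene belonging to two domains: no domain set may change
  tab2 <- rbind(tab,
                data.frame(gene_id = "gX", pathway_id = c("P1", "P3"),
                           domain_id = c("D1", "D2")))
  with_multi <- domain_gene_sets(metabolic_annotation(tab2))
  expect_identical(base_sets, with_multi)
})
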