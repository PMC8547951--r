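make_expression_cq <- function(ddcq_shift, n = 3, cq_base = 25, cq_ref = 18) {
  # mock dCq = cq_base - cq_ref; treated shifted by ddcq_shift cycles
  rows <- list()
  for (tr in c("treated", "mock")) {
    shift <- if (tr == "treated") ddcq_shift else 0
    rows[[length(rows) + 1L]] <- data.frame(
      target_gene = "T1", sample = paste0(tr, 1:n), genotype = "WT",
      treatment = tr, time = 30, replicate = 1:n, assay = "expression",
      antibody = "", cq = cq_base + shift + c(0.05, -0.05, 0)[1:n],
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      target_gene = "REF", sample = paste0("r", tr, 1:n), genotype = "WT",
      treatment = tr, time = 30, replicate = 1:n, assay = "expression",
      antibody = "", cq = cq_ref + c(0.05, -0.05, 0)[1:n],
      stringsAsFactors = FALSE)
  }
  cq_table(do.call(rbind, rows))
}

test_that("delta-delta-Cq fold change follows 2^-ddCq", {
  fc0 <- ddcq_fold_change(make_expression_cq(0), "T1", "REF", "WT", 30)
  expect_equal(fc0$fold_change, 1.0, tolerance = 1e-12)
  fc4 <- ddcq_fold_change(make_expression_cq(-2), "T1", "REF", "WT", 30)
  expect_equal(fc4$fold_change, 4.0, tolerance = 1e-12)
  expect_error(ddcq_fold_change(make_expression_cq(0), "T1", "NOREF",
                                "WT", 30), "reference")
})

test_that("fold change is immune to a constant plate offset on all Cq", {
  cq <- make_expression_cq(-1.5)
  shifted <- as.data.frame(cq)
  shifted$cq <- shifted$cq + 3.7
  cq_shifted <- cq_table(shifted)
  expect_equal(ddcq_fold_change(cq_shifted, "T1", "REF", "WT", 30)$fold_change,
               ddcq_fold_change(cq, "T1", "REF", "WT", 30)$fold_change,
               tolerance = 1e-12)
})

test_that("noise-free simulated kinetics reproduce the planted schedule", {
  cfg <- small_sim_config(seed = 31)
  cfg$cq$noise_sd <- 0
  cq <- simulate_cq(cfg)
  fcs <- expression_kinetics(cq, cfg$cq$reference_gene)
  truth <- cfg$cq$fc_schedule
  for (i in seq_len(nrow(truth))) {
    got <- fcs$fold_change[fcs$target == truth$target[i] &
                             fcs$genotype == truth$genotype[i] &
                             fcs$time == truth$time[i]]
    expect_equal(got, truth$fc[i], tolerance = 1e-9)
  }
})

test_that("earliest induction scans the ordered series with both criteria", {
  fcs <- data.frame(
    target = "T1", genotype = "WT", time = c(5, 30, 60, 180, 360),
    fold_change = c(1.1, 1.2, 1.3, 3, 4),
    p_value = c(0.6, 0.3, 0.2, 0.01, 0.001),
    stringsAsFactors = FALSE)
  expect_equal(earliest_induction(fcs)$earliest_time, 180)
  none <- fcs; none$p_value <- 0.5
  expect_true(is.na(earliest_induction(none)$earliest_time))
  # min_fc screens out significant-but-flat points
  flat <- fcs; flat$fold_change[4:5] <- 0.9
  expect_true(is.na(earliest_induction(flat)$earliest_time))
  expect_error(earliest_induction(fcs[0, ]), "empty")
})

test_that("relaxing alpha never yields a later induction call", {
  set.seed(13)
  for (i in 1:20) {
    fcs <- data.frame(
      target = "T1", genotype = "WT", time = c(5, 30, 60, 180, 360),
      fold_change = runif(5, 0.8, 6), p_value = runif(5),
      stringsAsFactors = FALSE)
    strict <- earliest_induction(fcs, alpha = 0.05)$earliest_time
    loose <- earliest_induction(fcs, alpha = 0.3)$earliest_time
    if (!is.na(strict)) {
      expect_false(is.na(loose))
      expect_lte(loose, strict)
    }
  }
})

test_that("planted 30-minute induction is called at 30 under noise", {
  hits <- 0L
  n_seeds <- 50L
  for (s in seq_len(n_seeds)) {
    cfg <- small_sim_config(seed = 6000 + s)
    cfg$cq$noise_sd <- 0.1
    cq <- simulate_cq(cfg)
    fcs <- expression_kinetics(cq, cfg$cq$reference_gene, targets = "CBG1")
    call <- earliest_induction(fcs[fcs$genotype == "WT", ])
    hits <- hits + identical(call$earliest_time, 30)
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("three-way ANOVA isolates a pure treatment effect", {
  grid <- expand.grid(genotype = c("WT", "mut"),
                      treatment = c("treated", "mock"),
                      time = c(5, 30, 60), replicate = 1:2,
                      stringsAsFactors = FALSE)
  grid$response <- ifelse(grid$treatment == "treated", 10, 2)
  tab <- anova3(grid)
  expect_equal(tab$sum_sq[tab$term == "treatment"],
               sum((grid$response - mean(grid$response))^2))
  others <- setdiff(tab$term, c("treatment", "Residuals"))
  expect_equal(tab$sum_sq[tab$term %in% others], rep(0, length(others)),
               tolerance = 1e-10)
  expect_equal(sum(tab$df), nrow(grid) - 1)
})

test_that("constant responses give all-zero sums of squares and NA F", {
  grid <- expand.grid(genotype = c("A", "B"), treatment = c("treated", "mock"),
                      time = c(5, 30), replicate = 1:2,
                      stringsAsFactors = FALSE)
  grid$response <- 3
  tab <- anova3(grid)
  expect_equal(tab$sum_sq, rep(0, nrow(tab)), tolerance = 1e-12)
  expect_true(all(is.na(tab$F[tab$term != "Residuals"])))
})

test_that("ANOVA matches the balanced cell-mean oracle and refuses imbalance", {
  set.seed(14)
  for (i in 1:5) {
    grid <- expand.grid(genotype = c("WT", "mut"),
                        treatment = c("treated", "mock"),
                        time = c(5, 30, 60), replicate = 1:3,
                        stringsAsFactors = FALSE)
    grid$response <- rnorm(nrow(grid), 5, 2)
    got <- anova3(grid)
    want <- anova3_oracle(grid)
    expect_equal(got$term, want$term)
    expect_equal(got$sum_sq, want$sum_sq, tolerance = 1e-10)
    expect_equal(got$F[1:7], want$F[1:7], tolerance = 1e-10)
  }
  expect_error(anova3(grid[-1, ]), "unbalanced|balance")
})

test_that("balanced sequential sums of squares are order-invariant", {
  set.seed(15)
  grid <- expand.grid(genotype = c("WT", "mut"),
                      treatment = c("treated", "mock"),
                      time = c(5, 30, 60), replicate = 1:2,
                      stringsAsFactors = FALSE)
  grid$response <- rnorm(nrow(grid), 0, 1)
  tab <- anova3(grid)
  # reversed term order in the model formula (independent route via aov)
  g <- grid; g$time <- factor(g$time)
  rev_fit <- summary(aov(response ~ time * treatment * genotype, data = g))[[1]]
  rev_ss <- setNames(rev_fit[["Sum Sq"]], trimws(rownames(rev_fit)))
  expect_equal(tab$sum_sq[tab$term == "genotype"],
               unname(rev_ss["genotype"]), tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$term == "treatment:time"],
               unname(rev_ss["time:treatment"]), tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$term == "genotype:treatment:time"],
               unname(rev_ss["time:treatment:genotype"]), tolerance = 1e-10)
})

test_that("metabolite statistics delegate to the t-test and ANOVA", {
  grid <- expand.grid(genotype = c("WT", "mut"),
                      treatment = c("treated", "mock"),
                      time = c(5, 180), replicate = 1:3,
                      stringsAsFactors = FALSE)
  grid$concentration <- ifelse(grid$treatment == "treated" & grid$time == 180,
                               150, 50) + rep(c(-1, 0, 1), each = 1,
                                              length.out = nrow(grid))
  conc <- concentration_table(grid)
  res <- metabolite_stats(conc)
  p5 <- res$per_time$p_value[res$per_time$time == 5]
  p180 <- res$per_time$p_value[res$per_time$time == 180]
  expect_true(all(p5 > 0.5))
  expect_true(all(p180 < 0.01))
  # ANOVA branch identical to calling anova3 on the same records
  obs <- data.frame(genotype = grid$genotype, treatment = grid$treatment,
                    time = grid$time, response = grid$concentration,
                    stringsAsFactors = FALSE)
  expect_equal(res$anova$sum_sq, anova3(obs)$sum_sq)
})

test_that("identical treated and mock concentrations give p = 1 everywhere", {
  grid <- expand.grid(genotype = c("WT", "mut"),
                      treatment = c("treated", "mock"),
                      time = c(5, 30), replicate = 1:3,
                      stringsAsFactors = FALSE)
  grid$concentration <- 10 + grid$replicate  # identical across treatments
  res <- metabolite_stats(concentration_table(grid))
  expect_true(all(res$per_time$p_value == 1))
})
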