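## ---------------------------------------------------------------------------
## Expression kinetics (delta-delta-Cq), earliest-induction calls, three-way
## factorial ANOVA, and metabolite statistics.
## ---------------------------------------------------------------------------

#' Delta-delta-Cq fold change for one target / genotype / time point
#'
#' Per replicate, `dCq = cq_target - cq_reference` (reference gene matched by
#' treatment and replicate); the fold change of treated over the untreated
#' control at the same time point is `2^-(mean dCq_treated - mean dCq_mock)`,
#' with a pooled-variance Student t-test on the replicate dCq values.
#'
#' @param cq a `CqTable` with `expression` records.
#' @param target target gene id.
#' @param reference_gene reference (housekeeping) gene id, e.g. ACT2.
#' @param genotype,time the condition cell to evaluate.
#' @return One-row data.frame of class `ExpressionFC`: `target`, `genotype`,
#'   `time`, `fold_change`, `p_value`, `n` (treated replicates).
#' @export
ddcq_fold_change <- function(cq, target, reference_gene, genotype, time) {
  stopifnot(inherits(cq, "CqTable"))
  expr <- cq[cq$assay == "expression" & cq$genotype == genotype &
               cq$time == time, , drop = FALSE]
  dcq <- lapply(c("treated", "mock"), function(tr) {
    tgt <- expr[expr$target_gene == target & expr$treatment == tr, ,
                drop = FALSE]
    ref <- expr[expr$target_gene == reference_gene & expr$treatment == tr, ,
                drop = FALSE]
    if (!nrow(ref)) {
      stop("missing reference-gene ('", reference_gene, "') records for ",
           genotype, " ", tr, " t=", time)
    }
    if (nrow(tgt) < 2L) {
      stop("need >= 2 ", tr, " replicates for ", target, " (", genotype,
           ", t=", time, ")")
    }
    idx <- match(tgt$replicate, ref$replicate)
    if (anyNA(idx)) {
      stop("reference record missing for replicate ",
           tgt$replicate[is.na(idx)][1L], " (", genotype, " ", tr, ")")
    }
    tgt$cq - ref$cq[idx]
  })
  ddcq <- mean(dcq[[1L]]) - mean(dcq[[2L]])
  sig <- region_significance(dcq[[1L]], dcq[[2L]])
  out <- data.frame(
    target = target, genotype = genotype, time = time,
    fold_change = 2^(-ddcq),
    p_value = sig$p_value,
    n = length(dcq[[1L]]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ExpressionFC", "data.frame")
  out
}

#' Fold-change kinetics over the full time grid
#'
#' Runs [ddcq_fold_change()] for every (target, genotype, time) combination
#' present in the expression records.
#'
#' @inheritParams ddcq_fold_change
#' @param targets character vector of target gene ids; default every
#'   expression target except the reference gene.
#' @return `ExpressionFC` data.frame, one row per target x genotype x time.
#' @export
expression_kinetics <- function(cq, reference_gene, targets = NULL) {
  stopifnot(inherits(cq, "CqTable"))
  expr <- cq[cq$assay == "expression", , drop = FALSE]
  if (!nrow(expr)) stop("no expression records in the Cq table")
  if (is.null(targets)) {
    targets <- setdiff(unique(expr$target_gene), reference_gene)
  }
  combos <- unique(expr[expr$target_gene %in% targets,
                        c("target_gene", "genotype", "time")])
  combos <- combos[order(combos$target_gene, combos$genotype, combos$time), ]
  rows <- Map(function(tg, gt, tm) ddcq_fold_change(cq, tg, reference_gene,
                                                    gt, tm),
              combos$target_gene, combos$genotype, combos$time)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ExpressionFC", "data.frame")
  out
}

#' Earliest significant induction time
#'
#' Scans an ordered fold-change series for one (target, genotype) and returns
#' the earliest time with `p <= alpha` and `fold_change > min_fc`, or `NA`
#' when no time point qualifies.  Relaxing `alpha` can only move the call
#' earlier or leave it unchanged.
#'
#' @param expression_fcs `ExpressionFC` frame for a single target and
#'   genotype.
#' @param alpha significance level, default 0.05.
#' @param min_fc minimum fold change (exclusive), default 1.
#' @return One-row data.frame of class `InductionCall`: `target`, `genotype`,
#'   `earliest_time` (minutes or NA), `alpha`, `min_fc`.
#' @export
earliest_induction <- function(expression_fcs, alpha = 0.05, min_fc = 1.0) {
  stopifnot(is.data.frame(expression_fcs))
  if (!nrow(expression_fcs)) stop("empty fold-change series")
  if (length(unique(expression_fcs$target)) != 1L ||
      length(unique(expression_fcs$genotype)) != 1L) {
    stop("expression_fcs must cover a single (target, genotype)")
  }
  fcs <- expression_fcs[order(expression_fcs$time), , drop = FALSE]
  hit <- fcs$p_value <= alpha & fcs$fold_change > min_fc
  out <- data.frame(
    target = fcs$target[1L],
    genotype = fcs$genotype[1L],
    earliest_time = if (any(hit)) fcs$time[which(hit)[1L]] else NA_real_,
    alpha = alpha, min_fc = min_fc,
    stringsAsFactors = FALSE
  )
  class(out) <- c("InductionCall", "data.frame")
  out
}

#' Three-way factorial ANOVA (genotype x treatment x duration)
#'
#' Fixed-effects least-squares ANOVA with sequential (Type I) sums of squares
#' in the order genotype, treatment, time, then the two-way interactions and
#' the three-way interaction.  The design must be fully crossed and balanced
#' (equal replication in every cell, at least 2), in which case the factors
#' are orthogonal and the sequential sums of squares are order-invariant;
#' unbalanced input is refused rather than silently picking a sums-of-squares
#' type.  Time enters as a categorical duration factor.
#'
#' @param observations data.frame with columns `genotype`, `treatment`,
#'   `time`, `response`.
#' @return data.frame of class `AnovaTable` with one row per term
#'   (`genotype`, `treatment`, `time`, their interactions, `Residuals`):
#'   `df`, `sum_sq`, `mean_sq`, `F`, `p`.  F and p are `NA` when the residual
#'   mean square is 0.
#' @export
anova3 <- function(observations) {
  stopifnot(is.data.frame(observations))
  required <- c("genotype", "treatment", "time", "response")
  missing_cols <- setdiff(required, names(observations))
  if (length(missing_cols)) {
    stop("observations missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  obs <- observations
  obs$genotype <- factor(obs$genotype)
  obs$treatment <- factor(obs$treatment)
  obs$time <- factor(obs$time)
  if (any(!is.finite(obs$response))) stop("responses must be finite")
  few <- c(genotype = nlevels(obs$genotype), treatment = nlevels(obs$treatment),
           time = nlevels(obs$time)) < 2L
  if (any(few)) {
    stop("factor(s) with fewer than 2 levels: ",
         paste(names(few)[few], collapse = ", "),
         "; a three-way ANOVA needs variation in every factor")
  }
  counts <- table(obs$genotype, obs$treatment, obs$time)
  if (any(counts < 2L)) {
    stop("design not fully crossed with >= 2 replicates per cell; ",
         "balance or subsample the input")
  }
  if (length(unique(as.vector(counts))) != 1L) {
    stop("unbalanced design (unequal cell counts); balance or subsample ",
         "the input — sums-of-squares types diverge on unbalanced data")
  }
  fit <- stats::aov(response ~ genotype * treatment * time, data = obs)
  tab <- summary(fit)[[1L]]
  term <- trimws(rownames(tab))
  out <- data.frame(
    term = term,
    df = tab[["Df"]],
    sum_sq = tab[["Sum Sq"]],
    mean_sq = tab[["Mean Sq"]],
    F = tab[["F value"]],
    p = tab[["Pr(>F)"]],
    stringsAsFactors = FALSE
  )
  degenerate <- !is.finite(out$F)
  out$F[degenerate] <- NA_real_
  out$p[degenerate] <- NA_real_
  rownames(out) <- NULL
  class(out) <- c("AnovaTable", "data.frame")
  out
}

#' Expression responses for ANOVA from Cq records
#'
#' Converts expression Cq records to per-replicate responses for [anova3()]:
#' linearized relative expression `2^-(cq_target - cq_reference)` by default,
#' or the `dCq` scale itself.
#'
#' @inheritParams ddcq_fold_change
#' @param response_scale `"linear"` (default) or `"dcq"`.
#' @return data.frame with `genotype`, `treatment`, `time`, `replicate`,
#'   `response`.
#' @export
expression_response <- function(cq, target, reference_gene,
                                response_scale = c("linear", "dcq")) {
  stopifnot(inherits(cq, "CqTable"))
  response_scale <- match.arg(response_scale)
  expr <- cq[cq$assay == "expression", , drop = FALSE]
  tgt <- expr[expr$target_gene == target, , drop = FALSE]
  ref <- expr[expr$target_gene == reference_gene, , drop = FALSE]
  if (!nrow(tgt)) stop("no expression records for target '", target, "'")
  if (!nrow(ref)) stop("no records for reference gene '", reference_gene, "'")
  key <- function(d) paste(d$genotype, d$treatment, d$time, d$replicate)
  idx <- match(key(tgt), key(ref))
  if (anyNA(idx)) {
    stop("reference record missing for ", sum(is.na(idx)), " target record(s)")
  }
  dcq <- tgt$cq - ref$cq[idx]
  data.frame(
    genotype = tgt$genotype,
    treatment = tgt$treatment,
    time = tgt$time,
    replicate = tgt$replicate,
    response = if (response_scale == "linear") 2^(-dcq) else dcq,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Metabolite accumulation statistics
#'
#' Per (genotype, time) Student t-test of treated vs mock concentrations,
#' plus the three-way factorial ANOVA on the concentration response.
#'
#' @param conc a `ConcentrationTable`.
#' @return List with `per_time` (data.frame: genotype, time, mean
#'   concentrations, fold change, p_value) and `anova` (an `AnovaTable`).
#' @export
metabolite_stats <- function(conc) {
  stopifnot(inherits(conc, "ConcentrationTable"))
  combos <- unique(conc[c("genotype", "time")])
  combos <- combos[order(combos$genotype, combos$time), ]
  rows <- Map(function(gt, tm) {
    treated <- conc$concentration[conc$genotype == gt & conc$time == tm &
                                    conc$treatment == "treated"]
    mock <- conc$concentration[conc$genotype == gt & conc$time == tm &
                                 conc$treatment == "mock"]
    if (length(treated) < 2L || length(mock) < 2L) {
      stop("need >= 2 replicates per group for ", gt, " t=", tm)
    }
    sig <- region_significance(treated, mock)
    data.frame(genotype = gt, time = tm,
               mean_treated = mean(treated), mean_mock = mean(mock),
               fold_change = mean(treated) / mean(mock),
               p_value = sig$p_value,
               stringsAsFactors = FALSE)
  }, combos$genotype, combos$time)
  per_time <- do.call(rbind, rows)
  rownames(per_time) <- NULL
  obs <- data.frame(genotype = conc$genotype, treatment = conc$treatment,
                    time = conc$time, response = conc$concentration,
                    stringsAsFactors = FALSE)
  list(per_time = per_time, anova = anova3(obs))
}
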