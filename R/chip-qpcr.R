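## ---------------------------------------------------------------------------
## ChIP-qPCR and sequential-ChIP arithmetic.
##
## All quantities assume 100% amplification efficiency (base 2): one Cq unit
## is a twofold difference in template.
## ---------------------------------------------------------------------------

#' Percent input of a ChIP fraction
#'
#' Standard dilution-adjusted percent input: the input Cq is first shifted by
#' `log2(1 / input_fraction)` to represent 100% of chromatin, then
#' `percent = 100 * 2^(adjusted_input_cq - cq_ip)`.  Downstream relative
#' abundances are treated/mock ratios and therefore insensitive to the
#' `input_fraction` chosen.
#'
#' @param cq_ip Cq of the immunoprecipitated fraction (vectorized).
#' @param cq_input Cq of the input fraction.
#' @param input_fraction fraction of chromatin used as input, in (0, 1];
#'   default 0.01 (a 1% input).
#' @return Percent input (same length as the inputs).
#' @export
percent_input <- function(cq_ip, cq_input, input_fraction = 0.01) {
  if (input_fraction <= 0 || input_fraction > 1) {
    stop("input_fraction must be in (0, 1]")
  }
  if (any(!is.finite(cq_ip)) || any(!is.finite(cq_input))) {
    stop("Cq values must be finite")
  }
  100 * 2^((cq_input - log2(1 / input_fraction)) - cq_ip)
}

#' Relative abundance of a modification (treated vs mock)
#'
#' Normalizes first to input (percent input supplied per replicate), then to
#' the mock-treated control: each treated replicate's percent input is
#' divided by the mean mock percent input, so the replicate spread of the
#' treated group is retained for error bars and testing.
#'
#' @param percent_input_treated numeric vector of treated-replicate percent
#'   inputs (> 0).
#' @param percent_input_mock numeric vector of mock-replicate percent inputs
#'   (> 0).
#' @return List of class `ChipQuant`: `ratios` (per treated replicate),
#'   `mean_ratio`, `sd_ratio`, `n_treated`, `n_mock`.
#' @export
relative_abundance <- function(percent_input_treated, percent_input_mock) {
  if (!length(percent_input_treated) || !length(percent_input_mock)) {
    stop("both groups need at least one replicate")
  }
  if (any(percent_input_treated <= 0) || any(percent_input_mock <= 0)) {
    stop("percent inputs must be > 0")
  }
  mock_mean <- mean(percent_input_mock)
  if (mock_mean == 0) stop("mock mean percent input is 0")
  ratios <- percent_input_treated / mock_mean
  structure(list(
    ratios = ratios,
    mean_ratio = mean(ratios),
    sd_ratio = if (length(ratios) > 1L) stats::sd(ratios) else NA_real_,
    n_treated = length(percent_input_treated),
    n_mock = length(percent_input_mock)
  ), class = "ChipQuant")
}

#' @export
print.ChipQuant <- function(x, ...) {
  cat(sprintf("Relative abundance: %.3f (sd %.3f, n = %d treated / %d mock)\n",
              x$mean_ratio, x$sd_ratio, x$n_treated, x$n_mock))
  invisible(x)
}

#' Sequential-ChIP pull-down efficiency (percent of first ChIP)
#'
#' Implements the published recovery metric exactly as printed:
#' `100 * 2^(cq_second - cq_first)`.  Note the printed sign convention yields
#' values above 100% when the second pull-down recovers *less* material (more
#' cycles); `sign_corrected = TRUE` computes the physically conventional
#' `100 * 2^(cq_first - cq_second)` instead.
#'
#' @param cq_first Cq measured after the first pull-down (vectorized).
#' @param cq_second Cq measured after the second pull-down.
#' @param sign_corrected use the sign-corrected form.
#' @return Percent of first ChIP.
#' @export
seqchip_efficiency <- function(cq_first, cq_second, sign_corrected = FALSE) {
  if (any(!is.finite(cq_first)) || any(!is.finite(cq_second))) {
    stop("Cq values must be finite")
  }
  d <- if (sign_corrected) cq_first - cq_second else cq_second - cq_first
  100 * 2^d
}

#' Two-group significance for a qPCR region
#'
#' Student's two-tailed t-test with pooled variance, e.g. antibody vs
#' no-antibody second pull-down, or treated vs mock.  Degenerate zero-variance
#' inputs return p = 1 when the group means agree and p = 0 otherwise.
#'
#' @param values_a,values_b numeric vectors, at least 2 replicates each.
#' @return List with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
region_significance <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("need at least 2 replicates per group")
  }
  pooled_ss <- sum((values_a - mean(values_a))^2) +
    sum((values_b - mean(values_b))^2)
  df <- length(values_a) + length(values_b) - 2L
  if (pooled_ss == 0) {
    equal <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    message("zero pooled variance in region_significance; degenerate p = ",
            if (equal) 1 else 0)
    return(list(t = if (equal) 0 else Inf, df = df,
                p_value = if (equal) 1.0 else 0.0,
                mean_a = mean(values_a), mean_b = mean(values_b)))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(values_a), mean_b = mean(values_b))
}

#' ChIP-qPCR summary over a Cq table
#'
#' Runs the percent-input and relative-abundance arithmetic over all
#' (target region, antibody) pairs of a `CqTable` holding `chip_input` and
#' `chip_ip` records for treated and mock samples, and attaches a pooled
#' t-test (treated vs mock percent input) per region.
#'
#' @param cq a `CqTable`.
#' @param input_fraction passed to [percent_input()].
#' @return data.frame with one row per (target, antibody): mean percent
#'   inputs, relative abundance, and the t-test p-value.
#' @export
chip_quantify <- function(cq, input_fraction = 0.01) {
  stopifnot(inherits(cq, "CqTable"))
  cq <- cq[cq$assay %in% c("chip_input", "chip_ip"), , drop = FALSE]
  if (!nrow(cq)) stop("no chip_input/chip_ip records in the Cq table")
  out <- list()
  for (tg in unique(cq$target_gene)) {
    sub <- cq[cq$target_gene == tg, , drop = FALSE]
    for (ab in unique(sub$antibody[sub$assay == "chip_ip"])) {
      pis <- lapply(c("treated", "mock"), function(tr) {
        ip <- sub[sub$assay == "chip_ip" & sub$antibody == ab &
                    sub$treatment == tr, , drop = FALSE]
        inp <- sub[sub$assay == "chip_input" & sub$treatment == tr, ,
                   drop = FALSE]
        if (!nrow(ip) || !nrow(inp)) {
          stop("missing ", tr, " chip records for ", tg, " / ", ab)
        }
        idx <- match(ip$replicate, inp$replicate)
        if (anyNA(idx)) stop("unmatched input replicate for ", tg, " / ", ab)
        percent_input(ip$cq, inp$cq[idx], input_fraction)
      })
      ra <- relative_abundance(pis[[1L]], pis[[2L]])
      sig <- region_significance(pis[[1L]], pis[[2L]])
      out[[length(out) + 1L]] <- data.frame(
        target_gene = tg, antibody = ab,
        percent_input_treated = mean(pis[[1L]]),
        percent_input_mock = mean(pis[[2L]]),
        relative_abundance = ra$mean_ratio,
        sd_ratio = ra$sd_ratio,
        n = ra$n_treated,
        p_value = sig$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sequential-ChIP summary over a Cq table
#'
#' Computes percent of first ChIP for every (target region, antibody) pair
#' from paired `seqchip_1st` / `seqchip_2nd` records, matched by replicate.
#'
#' @param cq a `CqTable`.
#' @param sign_corrected passed to [seqchip_efficiency()].
#' @return data.frame with one row per (target, second antibody): mean and sd
#'   of percent of first ChIP, replicate count.
#' @export
seqchip_quantify <- function(cq, sign_corrected = FALSE) {
  stopifnot(inherits(cq, "CqTable"))
  cq <- cq[cq$assay %in% c("seqchip_1st", "seqchip_2nd"), , drop = FALSE]
  if (!nrow(cq)) stop("no seqchip records in the Cq table")
  out <- list()
  for (tg in unique(cq$target_gene)) {
    sub <- cq[cq$target_gene == tg, , drop = FALSE]
    for (ab in unique(sub$antibody[sub$assay == "seqchip_2nd"])) {
      second <- sub[sub$assay == "seqchip_2nd" & sub$antibody == ab, ,
                    drop = FALSE]
      first <- sub[sub$assay == "seqchip_1st", , drop = FALSE]
      idx <- match(second$replicate, first$replicate)
      if (anyNA(idx)) stop("unmatched first-ChIP replicate for ", tg)
      eff <- seqchip_efficiency(first$cq[idx], second$cq,
                                sign_corrected = sign_corrected)
      out[[length(out) + 1L]] <- data.frame(
        target_gene = tg, antibody_second = ab,
        percent_of_first_chip = mean(eff),
        sd = if (length(eff) > 1L) stats::sd(eff) else NA_real_,
        n = length(eff),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
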