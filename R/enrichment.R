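## ---------------------------------------------------------------------------
## Enrichment / depletion calls per (gene set, mark)
##
## Effect size is the density fold change vs the metabolic-gene background;
## significance comes from Fisher's exact test on marked-gene counts (set vs
## rest of universe), BH-adjusted across the whole set x mark family.
## ---------------------------------------------------------------------------

#' Genes marked by a modification
#'
#' A gene is *marked* for a modification when its window density reaches the
#' given empirical quantile of densities over the reference universe (all
#' metabolic genes).  The quantile uses linear interpolation
#' (`stats::quantile` type 7).  The threshold quantile is a tunable analysis
#' choice, default 0.75.
#'
#' @param gene_signals `GeneSignal` frame over the universe.
#' @param mark mark name to select.
#' @param quantile marking quantile in `[0, 1]` (default 0.75).
#' @param universe optional character vector restricting the reference
#'   universe; defaults to all genes in `gene_signals` for that mark.
#' @return Character vector of marked gene ids.
#' @export
mark_genes <- function(gene_signals, mark, quantile = 0.75, universe = NULL) {
  stopifnot(is.data.frame(gene_signals), quantile >= 0, quantile <= 1)
  gs <- gene_signals[gene_signals$mark_name == mark, , drop = FALSE]
  if (!is.null(universe)) gs <- gs[gs$gene_id %in% universe, , drop = FALSE]
  if (!nrow(gs)) stop("empty universe for mark '", mark, "'")
  thr <- stats::quantile(gs$density, probs = quantile, names = FALSE, type = 7)
  gs$gene_id[gs$density >= thr]
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional exact test: the two-sided p-value sums the hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's (relative tie tolerance 1e-7).  Any
#' zero margin makes the table degenerate and returns p = 1.
#'
#' @param a,b,c,d nonnegative integer cell counts: `a` = in-set marked,
#'   `b` = in-set unmarked, `c` = out-of-set marked, `d` = out-of-set
#'   unmarked.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be nonnegative integers")
  }
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    message("degenerate 2x2 table (zero margin); p = 1")
    return(1.0)
  }
  stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE),
                     conf.int = FALSE)$p.value
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_{j>=i}(p_(j) * m / j)` capped at 1 and
#' returned in the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call per-set enrichment and depletion
#'
#' For every set x mark pair: density fold change against the background
#' (the pooled density of the whole universe), Fisher's exact test on
#' marked-gene counts, BH adjustment across the full family, and a
#' three-valued call.  `enriched` requires `FC >= fc_threshold` and
#' `q <= q_threshold`; `depleted` mirrors it at `FC <= 1/fc_threshold`;
#' everything else is `none`.  With `use_raw_p = TRUE` the unadjusted p is
#' compared against `alpha` instead of q against `q_threshold`.
#'
#' @param gene_signals multi-mark `GeneSignal` frame covering the universe.
#' @param sets named list: set_id -> character vector of member gene ids.
#' @param universe character vector of universe gene ids (the background set,
#'   typically all metabolic genes with signal).
#' @param fc_threshold minimum density fold change, default 1.5 (inclusive).
#' @param q_threshold FDR threshold, default 0.01.
#' @param mark_quantile marking quantile passed to [mark_genes()].
#' @param use_raw_p use unadjusted Fisher p-values against `alpha`.
#' @param alpha raw-p significance level (only with `use_raw_p`).
#' @param per_mark_fdr adjust within each mark separately instead of jointly
#'   across the whole set x mark matrix.
#' @return data.frame of class `EnrichmentResult` with one row per set x
#'   mark: densities, fold change, log2fc, 2x2 counts (`a`, `b`, `c`, `d`),
#'   `p_value`, `q_value` and `direction`.
#' @export
call_enrichment <- function(gene_signals, sets, universe,
                            fc_threshold = 1.5, q_threshold = 0.01,
                            mark_quantile = 0.75,
                            use_raw_p = FALSE, alpha = 0.05,
                            per_mark_fdr = FALSE) {
  stopifnot(is.data.frame(gene_signals), is.list(sets), length(sets) > 0L,
            fc_threshold >= 1, q_threshold > 0)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("'sets' must be a named list")
  }
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  for (sid in names(sets)) {
    extra <- setdiff(sets[[sid]], universe)
    if (length(extra)) {
      stop("set '", sid, "' is not a subset of the universe (e.g. ",
           extra[1L], ")")
    }
  }
  marks <- unique(gene_signals$mark_name)
  rows <- vector("list", length(marks) * length(sets))
  k <- 0L
  for (mk in marks) {
    gs <- gene_signals[gene_signals$mark_name == mk &
                         gene_signals$gene_id %in% universe, , drop = FALSE]
    miss <- setdiff(universe, gs$gene_id)
    if (length(miss)) {
      stop("universe gene(s) missing signal for mark '", mk, "': ",
           paste(utils::head(miss, 3L), collapse = ", "))
    }
    background <- set_density(gs, universe, "background")
    if (background$density <= 0) {
      stop("background density is 0 for mark '", mk, "'")
    }
    marked <- mark_genes(gs, mk, quantile = mark_quantile)
    n_marked <- length(marked)
    for (sid in names(sets)) {
      members <- unique(sets[[sid]])
      sd <- set_density(gs, members, sid)
      a <- sum(members %in% marked)
      b <- length(members) - a
      cc <- n_marked - a
      d <- length(universe) - length(members) - cc
      fc <- sd$density / background$density
      k <- k + 1L
      rows[[k]] <- data.frame(
        set_id = sid, mark_name = mk,
        n_genes = length(members),
        density = sd$density,
        background_density = background$density,
        fold_change = fc,
        log2fc = log2(fc),
        a = a, b = b, c = cc, d = d,
        p_value = fisher_exact_2x2(a, b, cc, d),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  if (per_mark_fdr) {
    res$q_value <- NA_real_
    for (mk in marks) {
      sel <- res$mark_name == mk
      res$q_value[sel] <- bh_fdr(res$p_value[sel])
    }
  } else {
    res$q_value <- bh_fdr(res$p_value)
  }
  sig <- if (use_raw_p) res$p_value <= alpha else res$q_value <= q_threshold
  res$direction <- ifelse(
    sig & res$fold_change >= fc_threshold, "enriched",
    ifelse(sig & res$fold_change <= 1 / fc_threshold, "depleted", "none")
  )
  rownames(res) <- NULL
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Log2 fold-change matrix of significant calls
#'
#' Heatmap-ready table: rows are sets, columns marks; a cell holds the log2
#' fold change when the call is enriched or depleted and `NA` (the "gray
#' cell") otherwise.
#'
#' @param results an `EnrichmentResult` frame from [call_enrichment()].
#' @return Numeric matrix (sets x marks) with NA for non-significant cells.
#' @export
enrichment_matrix <- function(results) {
  stopifnot(inherits(results, "EnrichmentResult") || is.data.frame(results))
  sets <- unique(results$set_id)
  marks <- unique(results$mark_name)
  m <- matrix(NA_real_, nrow = length(sets), ncol = length(marks),
              dimnames = list(sets, marks))
  sig <- results$direction != "none"
  m[cbind(match(results$set_id[sig], sets),
          match(results$mark_name[sig], marks))] <- results$log2fc[sig]
  m
}

#' Pathway gene sets passing a size filter within a domain
#'
#' Selects pathways of the named metabolic domain with at least `min_genes`
#' member genes (inclusive boundary), the filter applied before pathway-level
#' enrichment to keep statistical power.  `domain = NULL` disables the domain
#' filter.
#'
#' @param annotation a [metabolic_annotation()] object.
#' @param min_genes minimum pathway size, default 10 (inclusive).
#' @param domain domain id the pathways must belong to, or `NULL` for all.
#' @return Named list pathway_id -> character vector of gene ids.
#' @export
filter_pathways <- function(annotation, min_genes = 10, domain = "specialized") {
  stopifnot(inherits(annotation, "MetabolicAnnotation"), min_genes >= 1)
  pg <- pathway_genes(annotation)
  if (!is.null(domain)) {
    pd <- pathway_domains(annotation)
    all_domains <- unique(annotation$table$domain_id)
    if (!domain %in% all_domains) {
      stop("unknown domain '", domain, "'; known: ",
           paste(all_domains, collapse = ", "))
    }
    pg <- pg[vapply(pd[names(pg)], function(d) domain %in% d, logical(1))]
  }
  pg[vapply(pg, length, integer(1)) >= min_genes]
}

#' Domain gene sets from unique-domain genes
#'
#' Builds domain-level gene sets using only genes mapped to exactly one
#' metabolic domain, so multi-domain genes cannot blur domain contrasts.
#'
#' @param annotation a [metabolic_annotation()] object.
#' @return Named list domain_id -> character vector of gene ids.
#' @export
domain_gene_sets <- function(annotation) {
  ud <- unique_domain_genes(annotation)
  split(names(ud), unname(ud))
}
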