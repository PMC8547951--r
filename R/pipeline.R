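## ---------------------------------------------------------------------------
## Pipeline orchestration: read inputs -> rank-normalize -> densities ->
## enrichment -> bivalency (+ optional qPCR / metabolite stages), with a
## run manifest for provenance.
## ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' Collects input paths and analysis thresholds.  Thresholds default to the
#' standard analysis constants: 1 kb upstream / 500 bp downstream windows,
#' fold-change cut 1.5, FDR 0.01, marking quantile 0.75, minimum pathway size
#' 10.
#'
#' @param gff3 path to the gene-model GFF3.
#' @param tracks named character vector: mark name -> bedGraph path.
#' @param pathways path to the pathway annotation TSV.
#' @param cq optional Cq CSV path (enables ChIP/SeqChIP/kinetics stages).
#' @param conc optional concentration CSV path (enables metabolite stage).
#' @param out_dir output directory.
#' @param upstream_bp,downstream_bp window extents.
#' @param fc_threshold,q_threshold,mark_quantile enrichment thresholds.
#' @param use_raw_p,alpha use unadjusted Fisher p-values at level `alpha`
#'   instead of FDR.
#' @param level `"pathway"` or `"domain"` enrichment sets.
#' @param min_genes minimum pathway size (pathway level).
#' @param domain restrict pathways to this domain (`NULL` = all domains).
#' @param bivalent_marks the two mark names for co-occurrence / correlation.
#' @param subset_domain domain whose genes form the removal subset in
#'   correlation attribution (default `"specialized"`).
#' @param reference_gene qPCR reference gene for the kinetics stage.
#' @param input_fraction ChIP input fraction.
#' @param seed integer recorded in the manifest.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(gff3, tracks, pathways,
                            cq = NULL, conc = NULL,
                            out_dir = ".",
                            upstream_bp = 1000, downstream_bp = 500,
                            fc_threshold = 1.5, q_threshold = 0.01,
                            mark_quantile = 0.75,
                            use_raw_p = FALSE, alpha = 0.05,
                            level = c("pathway", "domain"),
                            min_genes = 10, domain = NULL,
                            bivalent_marks = NULL,
                            subset_domain = "specialized",
                            reference_gene = "ACT2",
                            input_fraction = 0.01,
                            seed = 1L) {
  level <- match.arg(level)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    stop("'tracks' must be a named vector: mark name -> bedGraph path")
  }
  stopifnot(fc_threshold >= 1, q_threshold > 0, mark_quantile >= 0,
            mark_quantile <= 1, upstream_bp >= 0, downstream_bp >= 0,
            min_genes >= 1)
  if (is.null(bivalent_marks)) bivalent_marks <- names(tracks)[1:2]
  structure(list(
    gff3 = gff3, tracks = tracks, pathways = pathways, cq = cq, conc = conc,
    out_dir = out_dir, upstream_bp = upstream_bp,
    downstream_bp = downstream_bp, fc_threshold = fc_threshold,
    q_threshold = q_threshold, mark_quantile = mark_quantile,
    use_raw_p = use_raw_p, alpha = alpha, level = level,
    min_genes = min_genes, domain = domain,
    bivalent_marks = bivalent_marks, subset_domain = subset_domain,
    reference_gene = reference_gene, input_fraction = input_fraction,
    seed = as.integer(seed)
  ), class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys mirror the [pipeline_config()] arguments; `tracks` is a mapping
#' mark name -> path.
#'
#' @param path YAML file path.
#' @param ... overrides applied on top of the file values.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$tracks)) vals$tracks <- unlist(vals$tracks)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[kairoscan] %s: %s", stage, paste0(...)))
}

stage_error <- function(stage, e) {
  stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
}

write_tsv_output <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_comment(), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  # hash the analysis parameters only; input/output locations are machine-
  # specific and do not affect results
  path_fields <- c("gff3", "tracks", "pathways", "cq", "conc", "out_dir")
  params <- config[setdiff(names(config), path_fields)]
  params$marks <- names(config$tracks)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(params), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: read inputs, rank-normalize tracks, build windows and
#' per-gene densities, call set enrichment, bivalency (co-occurrence,
#' correlation attribution, dual-enriched sets), then the optional ChIP-qPCR,
#' SeqChIP, expression-kinetics and metabolite stages when Cq/concentration
#' inputs are configured.  All result tables are written to
#' `config$out_dir` beside a JSON run manifest (tool version, config hash,
#' seed, per-stage record counts).
#'
#' @param config a [pipeline_config()] object.
#' @return Invisibly, a list with all stage results and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  for (p in c(config$gff3, config$tracks, config$pathways, config$cq,
              config$conc)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  results <- list()

  annotation <- tryCatch(read_gff3(config$gff3),
                         error = function(e) stage_error("read_gff3", e))
  pipeline_log("read_gff3", nrow(annotation$genes), " genes")
  pathway_annotation <- tryCatch(
    read_pathway_table(config$pathways),
    error = function(e) stage_error("read_pathways", e))
  tracks <- tryCatch(
    lapply(stats::setNames(names(config$tracks), names(config$tracks)),
           function(mk) read_bedgraph(config$tracks[[mk]], mk)),
    error = function(e) stage_error("read_tracks", e))
  pipeline_log("read_tracks", length(tracks), " tracks")
  counts$genes <- nrow(annotation$genes)
  counts$tracks <- length(tracks)

  dens <- tryCatch({
    ranked <- lapply(tracks, rank_normalize)
    windows <- build_windows(annotation, config$upstream_bp,
                             config$downstream_bp)
    gene_signals(windows, ranked)
  }, error = function(e) stage_error("density", e))
  pipeline_log("density", nrow(dens), " gene x mark densities")
  counts$densities <- nrow(dens)
  results$densities <- dens
  write_tsv_output(dens, file.path(config$out_dir, "densities.tsv"))

  universe <- intersect(metabolic_genes(pathway_annotation),
                        annotation$genes$gene_id)
  enr <- tryCatch({
    sets <- if (config$level == "pathway") {
      filter_pathways(pathway_annotation, config$min_genes, config$domain)
    } else {
      domain_gene_sets(pathway_annotation)
    }
    sets <- lapply(sets, intersect, y = universe)
    sets <- sets[vapply(sets, length, integer(1)) > 0L]
    if (!length(sets)) stop("no gene sets left after filtering")
    call_enrichment(dens, sets, universe,
                    fc_threshold = config$fc_threshold,
                    q_threshold = config$q_threshold,
                    mark_quantile = config$mark_quantile,
                    use_raw_p = config$use_raw_p, alpha = config$alpha)
  }, error = function(e) stage_error("enrichment", e))
  pipeline_log("enrichment", nrow(enr), " set x mark tests, ",
               sum(enr$direction != "none"), " significant")
  counts$enrichment_tests <- nrow(enr)
  results$enrichment <- enr
  write_tsv_output(enr, file.path(config$out_dir, "enrichment.tsv"))
  mat <- enrichment_matrix(enr)
  write_tsv_output(data.frame(set_id = rownames(mat), mat,
                              check.names = FALSE),
                   file.path(config$out_dir, "enrichment_matrix.tsv"))

  biv <- tryCatch({
    ma <- config$bivalent_marks[1L]
    mb <- config$bivalent_marks[2L]
    marked_a <- mark_genes(dens, ma, config$mark_quantile, universe)
    marked_b <- mark_genes(dens, mb, config$mark_quantile, universe)
    cooc <- co_occurrence(marked_a, marked_b, universe, ma, mb)
    subset <- intersect(
      unlist(filter_pathways(pathway_annotation, min_genes = 1,
                             domain = config$subset_domain), use.names = FALSE),
      universe)
    attribution <- correlation_attribution(dens, ma, mb, universe, subset)
    dual <- dual_enriched_sets(enr[enr$mark_name == ma, , drop = FALSE],
                               enr[enr$mark_name == mb, , drop = FALSE])
    list(co_occurrence = cooc, attribution = attribution,
         dual_enriched = dual)
  }, error = function(e) stage_error("bivalency", e))
  pipeline_log("bivalency", biv$co_occurrence$n_both, " of ",
               biv$co_occurrence$n_universe, " genes co-marked; r ",
               round(biv$attribution$full$pearson_r, 3), " -> ",
               round(biv$attribution$without_subset$pearson_r, 3))
  results$bivalency <- biv
  write_tsv_output(
    data.frame(
      metric = c("n_universe", "n_both", "fraction", "percent",
                 "r_full", "p_full", "r_without_subset", "p_without_subset",
                 "r_drop"),
      value = c(biv$co_occurrence$n_universe, biv$co_occurrence$n_both,
                biv$co_occurrence$fraction, biv$co_occurrence$percent,
                biv$attribution$full$pearson_r,
                biv$attribution$full$p_value,
                biv$attribution$without_subset$pearson_r,
                biv$attribution$without_subset$p_value,
                biv$attribution$r_drop)
    ),
    file.path(config$out_dir, "bivalency.tsv"))

  if (!is.null(config$cq)) {
    cqt <- tryCatch(read_cq_csv(config$cq),
                    error = function(e) stage_error("read_cq", e))
    counts$cq_records <- nrow(cqt)
    if (any(cqt$assay %in% c("chip_input", "chip_ip"))) {
      chip <- tryCatch(chip_quantify(cqt, config$input_fraction),
                       error = function(e) stage_error("chip", e))
      results$chip <- chip
      write_tsv_output(chip, file.path(config$out_dir, "chip.tsv"))
    }
    if (any(cqt$assay %in% c("seqchip_1st", "seqchip_2nd"))) {
      seqchip <- tryCatch(seqchip_quantify(cqt),
                          error = function(e) stage_error("seqchip", e))
      results$seqchip <- seqchip
      write_tsv_output(seqchip, file.path(config$out_dir, "seqchip.tsv"))
    }
    if (any(cqt$assay == "expression")) {
      kin <- tryCatch({
        fcs <- expression_kinetics(cqt, config$reference_gene)
        combos <- unique(fcs[c("target", "genotype")])
        calls <- do.call(rbind, Map(function(tg, gt) {
          earliest_induction(fcs[fcs$target == tg & fcs$genotype == gt, ,
                                 drop = FALSE], config$alpha)
        }, combos$target, combos$genotype))
        list(fold_changes = fcs, induction = calls)
      }, error = function(e) stage_error("kinetics", e))
      results$kinetics <- kin
      write_tsv_output(kin$fold_changes,
                       file.path(config$out_dir, "kinetics.tsv"))
      write_tsv_output(kin$induction,
                       file.path(config$out_dir, "induction.tsv"))
    }
  }
  if (!is.null(config$conc)) {
    conc <- tryCatch(read_conc_csv(config$conc),
                     error = function(e) stage_error("read_conc", e))
    met <- tryCatch(metabolite_stats(conc),
                    error = function(e) stage_error("metabolite", e))
    results$metabolite <- met
    write_tsv_output(met$per_time,
                     file.path(config$out_dir, "metabolite_stats.tsv"))
    write_tsv_output(met$anova,
                     file.path(config$out_dir, "metabolite_anova.tsv"))
  }

  manifest <- list(
    tool = "kairoscan",
    version = ks_version(),
    seed = config$seed,
    config_hash = config_hash(config),
    counts = counts
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  pipeline_log("done", "outputs in ", config$out_dir)
  invisible(results)
}
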