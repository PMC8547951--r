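## ---------------------------------------------------------------------------
## Seeded synthetic-data generators.
##
## Every input the pipeline consumes can be generated with planted ground
## truth: per-pathway per-mark signal multipliers, a co-marked (bivalent)
## gene subset, qPCR fold-change / percent-input schedules, and metabolite
## accumulation means.  All generators are deterministic given the seed.
## ---------------------------------------------------------------------------

derive_seed <- function(seed, offset) {
  ((as.numeric(seed) + offset * 7919) %% 2147483646) + 1
}

#' Simulation configuration
#'
#' Defaults define the standard simulated study: 1000 genes on 2 chromosomes,
#' 20 pathways of 20 genes each (half in the `specialized` domain), two marks
#' (H3K27me3, H3K18ac) with lognormal baseline bin signal, all planted
#' multipliers at 1 (a global null), and qPCR schedules with a 5 min--6 hr
#' sampling grid and 6 replicates.
#'
#' @param seed integer RNG seed.
#' @param n_chroms,chrom_length_bp chromosome count and length.
#' @param n_genes total gene count.
#' @param gene_length_range min/max gene length (bp).
#' @param bin_size_bp signal track bin width.
#' @param marks list of mark specs: `list(name=, meanlog=, sdlog=)`.
#' @param pathways data.frame with columns `pathway_id`, `domain_id`,
#'   `n_genes`, plus one numeric multiplier column per mark name.
#' @param bivalent_set list: `size` (ignored when `pathway_id` set),
#'   `marks` (pair), `multiplier` (1 = inert), `pathway_id` (optional pathway
#'   whose genes form the bivalent set).
#' @param multi_pathway_fraction fraction of pathway genes additionally
#'   assigned to a second pathway in another domain (exercises the
#'   unique-domain filter); default 0.
#' @param upstream_bp,downstream_bp gene window extents used when planting
#'   signal multipliers.
#' @param cq list controlling qPCR simulation: `targets`, `reference_gene`,
#'   `genotypes`, `times` (minutes), `replicates`, `noise_sd` (cycles),
#'   `cq_base`, `cq_ref`, `fc_schedule` (data.frame target, genotype, time,
#'   fc), `chip_schedule` (data.frame target, antibody, percent_mock,
#'   ratio_treated), `seqchip_schedule` (data.frame target, antibody_second,
#'   percent_of_first), `cq_input`.
#' @param conc list controlling metabolite simulation: `genotypes`, `times`,
#'   `replicates`, `base_nM`, `accumulation` (data.frame genotype, time,
#'   fold), `noise_sdlog`.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length_bp = 2.5e6,
                       n_genes = 1000L,
                       gene_length_range = c(1000L, 3000L),
                       bin_size_bp = 200L,
                       marks = list(
                         list(name = "H3K27me3", meanlog = 0, sdlog = 0.75),
                         list(name = "H3K18ac", meanlog = 0, sdlog = 0.75)
                       ),
                       pathways = NULL,
                       bivalent_set = list(size = 20L,
                                           marks = c("H3K27me3", "H3K18ac"),
                                           multiplier = 1,
                                           pathway_id = NULL),
                       multi_pathway_fraction = 0,
                       upstream_bp = 1000L,
                       downstream_bp = 500L,
                       cq = NULL,
                       conc = NULL) {
  mark_names <- vapply(marks, `[[`, character(1), "name")
  if (is.null(pathways)) {
    pathways <- data.frame(
      pathway_id = sprintf("PWY%02d", 1:20),
      domain_id = rep(c("specialized", "amino-acid", "carbohydrate",
                        "lipid"), c(10, 4, 3, 3)),
      n_genes = 20L,
      stringsAsFactors = FALSE
    )
    for (mk in mark_names) pathways[[mk]] <- 1
  }
  for (mk in mark_names) {
    if (is.null(pathways[[mk]])) pathways[[mk]] <- 1
  }
  if (any(vapply(mark_names, function(mk) any(pathways[[mk]] < 0),
                 logical(1)))) {
    stop("pathway multipliers must be >= 0")
  }
  if (sum(pathways$n_genes) > n_genes) {
    stop("total pathway gene demand (", sum(pathways$n_genes),
         ") exceeds n_genes (", n_genes, ")")
  }
  if (bivalent_set$multiplier < 0) stop("bivalent multiplier must be >= 0")
  if (is.null(cq)) {
    times <- c(5, 30, 60, 180, 360)
    targets <- c("CBG1", "CBG2", "CBG3")
    genotypes <- c("WT", "clf")
    # wild type induces from 30 min; the mutant earlier and higher
    fc_wt <- c(1, 4, 8, 16, 8)
    fc_clf <- c(2, 8, 16, 32, 16)
    cq <- list(
      targets = targets,
      reference_gene = "ACT2",
      genotypes = genotypes,
      times = times,
      replicates = 6L,
      noise_sd = 0.2,
      cq_base = 25,
      cq_ref = 18,
      fc_schedule = data.frame(
        target = rep(rep(targets, each = length(times)), length(genotypes)),
        genotype = rep(genotypes, each = length(times) * length(targets)),
        time = rep(times, length(targets) * length(genotypes)),
        fc = c(rep(fc_wt, length(targets)), rep(fc_clf, length(targets))),
        stringsAsFactors = FALSE
      ),
      chip_schedule = data.frame(
        target = rep(targets, each = 2),
        antibody = rep(c("H3K18ac", "H3K27me3"), length(targets)),
        percent_mock = 2,
        ratio_treated = rep(c(1.8, 0.5), length(targets)),
        stringsAsFactors = FALSE
      ),
      seqchip_schedule = data.frame(
        target = c("CBG1", "CBG1", "neg_control"),
        antibody_second = c("H3K18ac", "NoAb", "H3K18ac"),
        percent_of_first = c(25, 0.5, 2),
        stringsAsFactors = FALSE
      ),
      cq_input = 20
    )
  }
  if (any(cq$fc_schedule$fc <= 0)) stop("planted fold changes must be > 0")
  if (is.null(conc)) {
    conc <- list(
      genotypes = c("WT", "clf"),
      times = c(5, 30, 60, 180, 360),
      replicates = 6L,
      base_nM = 50,
      accumulation = data.frame(
        genotype = rep(c("WT", "clf"), each = 5),
        time = rep(c(5, 30, 60, 180, 360), 2),
        fold = c(1, 1, 1, 3, 6,     # wild type accumulates late
                 1, 1, 3, 6, 8),    # mutant accumulates earlier
        stringsAsFactors = FALSE
      ),
      noise_sdlog = 0.25
    )
  }
  structure(list(
    seed = as.integer(seed),
    n_chroms = as.integer(n_chroms),
    chrom_length_bp = chrom_length_bp,
    n_genes = as.integer(n_genes),
    gene_length_range = gene_length_range,
    bin_size_bp = as.integer(bin_size_bp),
    marks = marks,
    mark_names = mark_names,
    pathways = pathways,
    bivalent_set = bivalent_set,
    multi_pathway_fraction = multi_pathway_fraction,
    upstream_bp = upstream_bp,
    downstream_bp = downstream_bp,
    cq = cq,
    conc = conc
  ), class = "SimConfig")
}

#' Plant an enrichment effect in a configuration
#'
#' Sets the signal multiplier of one pathway for one or more marks.
#'
#' @param config a [sim_config()] object.
#' @param pathway_id pathway to modify.
#' @param marks mark name(s).
#' @param multiplier nonnegative multiplier.
#' @return The modified `SimConfig`.
#' @export
plant_enrichment <- function(config, pathway_id, marks, multiplier) {
  stopifnot(inherits(config, "SimConfig"), multiplier >= 0)
  row <- match(pathway_id, config$pathways$pathway_id)
  if (is.na(row)) stop("unknown pathway '", pathway_id, "'")
  for (mk in marks) {
    if (!mk %in% config$mark_names) stop("unknown mark '", mk, "'")
    config$pathways[[mk]][row] <- multiplier
  }
  config
}

#' Plant a bivalent (co-marked) gene set
#'
#' Marks one pathway's genes as the bivalent set: both paired marks get the
#' given multiplier over those genes' windows.
#'
#' @inheritParams plant_enrichment
#' @param multiplier nonnegative multiplier applied to both paired marks.
#' @export
plant_bivalent <- function(config, pathway_id, multiplier) {
  stopifnot(inherits(config, "SimConfig"), multiplier >= 0)
  if (!pathway_id %in% config$pathways$pathway_id) {
    stop("unknown pathway '", pathway_id, "'")
  }
  config$bivalent_set$pathway_id <- pathway_id
  config$bivalent_set$multiplier <- multiplier
  config
}

#' Simulate a genome annotation
#'
#' Places `n_genes` non-overlapping genes with uniform-random strands, leaving
#' margins so every gene window (1 kb upstream / 500 bp downstream) fits
#' inside chromosome bounds.  Deterministic given the config seed.
#'
#' @param config a [sim_config()] object.
#' @return A [genome_annotation()] object.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(derive_seed(config$seed, 1))
  margin <- max(config$upstream_bp, config$downstream_bp)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  per_chrom <- diff(round(seq(0, config$n_genes,
                              length.out = config$n_chroms + 1)))
  max_len <- config$gene_length_range[2L]
  rows <- list()
  gi <- 0L
  for (ci in seq_len(config$n_chroms)) {
    n <- per_chrom[ci]
    if (n == 0L) next
    usable <- config$chrom_length_bp - 2 * margin
    slot <- floor(usable / n)
    if (slot < max_len + 2L) {
      stop("chromosome length ", config$chrom_length_bp,
           " too small to place ", n, " genes of up to ", max_len, " bp")
    }
    lens <- sample(seq(config$gene_length_range[1L],
                       config$gene_length_range[2L]), n, replace = TRUE)
    offsets <- vapply(slot - lens, function(room) sample.int(room, 1L) - 1L,
                      integer(1))
    starts <- margin + (seq_len(n) - 1L) * slot + offsets
    strands <- sample(c("+", "-"), n, replace = TRUE)
    rows[[ci]] <- data.frame(
      gene_id = sprintf("G%04d", gi + seq_len(n)),
      chrom = chroms[ci],
      start = starts,
      end = starts + lens,
      strand = strands,
      stringsAsFactors = FALSE
    )
    gi <- gi + n
  }
  genes <- do.call(rbind, rows)
  chrom_sizes <- stats::setNames(rep(config$chrom_length_bp,
                                     config$n_chroms), chroms)
  genome_annotation(genes, chrom_sizes)
}

#' Simulate the metabolic pathway annotation
#'
#' Assigns each pathway its configured number of genes, sampled without
#' replacement so genes belong to at most one pathway by default;
#' `multi_pathway_fraction > 0` additionally assigns that fraction of pathway
#' genes to a second pathway in a different domain, creating multi-domain
#' genes for the unique-domain filter.
#'
#' @param config a [sim_config()] object.
#' @param annotation result of [simulate_genome()].
#' @return A [metabolic_annotation()] object.
#' @export
simulate_pathway_annotation <- function(config, annotation) {
  stopifnot(inherits(config, "SimConfig"),
            inherits(annotation, "GenomeAnnotation"))
  set.seed(derive_seed(config$seed, 2))
  pool <- sample(annotation$genes$gene_id)
  pw <- config$pathways
  rows <- list()
  taken <- 0L
  for (i in seq_len(nrow(pw))) {
    ids <- pool[taken + seq_len(pw$n_genes[i])]
    taken <- taken + pw$n_genes[i]
    rows[[i]] <- data.frame(gene_id = ids, pathway_id = pw$pathway_id[i],
                            domain_id = pw$domain_id[i],
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (config$multi_pathway_fraction > 0) {
    n_extra <- ceiling(config$multi_pathway_fraction * nrow(tab))
    extra_idx <- sample(nrow(tab), n_extra)
    extra <- tab[extra_idx, , drop = FALSE]
    for (j in seq_len(nrow(extra))) {
      other <- pw[pw$domain_id != extra$domain_id[j], , drop = FALSE]
      if (!nrow(other)) next
      k <- sample(nrow(other), 1L)
      extra$pathway_id[j] <- other$pathway_id[k]
      extra$domain_id[j] <- other$domain_id[k]
    }
    tab <- rbind(tab, extra)
  }
  metabolic_annotation(tab)
}

bivalent_gene_ids <- function(config, pathway_annotation) {
  bs <- config$bivalent_set
  if (bs$multiplier == 1) return(character(0))
  if (!is.null(bs$pathway_id)) {
    pg <- pathway_genes(pathway_annotation)
    if (!bs$pathway_id %in% names(pg)) {
      stop("bivalent pathway '", bs$pathway_id, "' not in the annotation")
    }
    return(pg[[bs$pathway_id]])
  }
  set.seed(derive_seed(config$seed, 3))
  sample(metabolic_genes(pathway_annotation), bs$size)
}

#' Simulate binned signal tracks with planted effects
#'
#' Per mark, every genome bin draws a lognormal baseline value; bins
#' overlapping the window of a gene carrying a planted multiplier (its
#' pathway's per-mark multiplier, times the bivalent multiplier for bivalent
#' genes and paired marks) have the draw multiplied.  When windows with
#' different factors overlap a bin, the largest factor applies.
#'
#' @param config a [sim_config()] object.
#' @param annotation result of [simulate_genome()].
#' @param pathway_annotation result of [simulate_pathway_annotation()].
#' @return Named list of raw [signal_track()] objects (not yet
#'   rank-normalized).
#' @export
simulate_tracks <- function(config, annotation, pathway_annotation) {
  stopifnot(inherits(config, "SimConfig"),
            inherits(annotation, "GenomeAnnotation"),
            inherits(pathway_annotation, "MetabolicAnnotation"))
  windows <- build_windows(annotation, config$upstream_bp,
                           config$downstream_bp)
  pg <- pathway_genes(pathway_annotation)
  bivalent <- bivalent_gene_ids(config, pathway_annotation)
  bin_frames <- list()
  for (ch in names(annotation$chrom_sizes)) {
    L <- annotation$chrom_sizes[[ch]]
    starts <- seq(0, L - 1, by = config$bin_size_bp)
    bin_frames[[ch]] <- data.frame(
      chrom = ch, start = starts, end = pmin(starts + config$bin_size_bp, L),
      stringsAsFactors = FALSE
    )
  }
  bins0 <- do.call(rbind, bin_frames)
  rownames(bins0) <- NULL
  win_gr <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = windows$win_start + 1L, end = windows$win_end))
  bin_gr <- GenomicRanges::GRanges(
    bins0$chrom, IRanges::IRanges(start = bins0$start + 1L, end = bins0$end))
  hits <- GenomicRanges::findOverlaps(bin_gr, win_gr)
  bin_hit <- S4Vectors::queryHits(hits)
  gene_hit <- windows$gene_id[S4Vectors::subjectHits(hits)]

  tracks <- list()
  for (mi in seq_along(config$marks)) {
    mk <- config$marks[[mi]]
    set.seed(derive_seed(config$seed, 10 + mi))
    values <- stats::rlnorm(nrow(bins0), meanlog = mk$meanlog,
                            sdlog = mk$sdlog)
    gene_factor <- stats::setNames(rep(1, nrow(annotation$genes)),
                                   annotation$genes$gene_id)
    for (pi in seq_len(nrow(config$pathways))) {
      m <- config$pathways[[mk$name]][pi]
      if (m != 1) {
        ids <- pg[[config$pathways$pathway_id[pi]]]
        gene_factor[ids] <- gene_factor[ids] * m
      }
    }
    if (length(bivalent) && mk$name %in% config$bivalent_set$marks) {
      gene_factor[bivalent] <- gene_factor[bivalent] *
        config$bivalent_set$multiplier
    }
    if (any(gene_factor != 1)) {
      hit_factor <- gene_factor[gene_hit]
      boosted <- hit_factor != 1
      if (any(boosted)) {
        fac <- tapply(hit_factor[boosted], bin_hit[boosted], max)
        idx <- as.integer(names(fac))
        values[idx] <- values[idx] * pmax(as.numeric(fac), 0)
      }
    }
    bins <- bins0
    bins$value <- values
    tracks[[mk$name]] <- signal_track(mk$name, bins, ranked = FALSE)
  }
  tracks
}

#' Simulate a qPCR Cq table
#'
#' Expression records follow the planted fold-change schedule:
#' `cq = cq_base - log2(FC) + N(0, noise)` for treated, `cq_base + noise` for
#' mock, with a constant-expression reference gene.  ChIP records encode the
#' planted percent-input schedule (`cq_ip = cq_input - log2(1/f) -
#' log2(pi/100)`), and SeqChIP records the planted percent-of-first-ChIP via
#' `cq_2nd = cq_1st + log2(pi/100)`.
#'
#' @param config a [sim_config()] object.
#' @param input_fraction input fraction assumed when encoding ChIP percent
#'   inputs (default 0.01).
#' @return A `CqTable`.
#' @export
simulate_cq <- function(config, input_fraction = 0.01) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(derive_seed(config$seed, 20))
  qc <- config$cq
  noise <- function(n) stats::rnorm(n, 0, qc$noise_sd)
  reps <- seq_len(qc$replicates)
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  rec <- function(target, genotype, treatment, time, assay, antibody, cqv) {
    data.frame(
      target_gene = target,
      sample = paste(genotype, treatment, time, reps, sep = "_"),
      genotype = genotype, treatment = treatment, time = time,
      replicate = reps, assay = assay, antibody = antibody, cq = cqv,
      stringsAsFactors = FALSE
    )
  }
  # expression
  fs <- qc$fc_schedule
  for (i in seq_len(nrow(fs))) {
    fc <- fs$fc[i]
    add(rec(fs$target[i], fs$genotype[i], "treated", fs$time[i],
            "expression", "", qc$cq_base - log2(fc) + noise(qc$replicates)))
    add(rec(fs$target[i], fs$genotype[i], "mock", fs$time[i],
            "expression", "", qc$cq_base + noise(qc$replicates)))
  }
  for (gt in unique(fs$genotype)) {
    for (tm in unique(fs$time)) {
      for (tr in c("treated", "mock")) {
        add(rec(qc$reference_gene, gt, tr, tm, "expression", "",
                qc$cq_ref + noise(qc$replicates)))
      }
    }
  }
  # ChIP: one shared input per (target, treatment); IP per antibody
  cs <- qc$chip_schedule
  adj <- log2(1 / input_fraction)
  for (tg in unique(cs$target)) {
    for (tr in c("treated", "mock")) {
      add(rec(tg, "WT", tr, 30, "chip_input", "",
              qc$cq_input + noise(qc$replicates)))
    }
  }
  for (i in seq_len(nrow(cs))) {
    pi_mock <- cs$percent_mock[i]
    pi_treated <- pi_mock * cs$ratio_treated[i]
    for (tr in c("treated", "mock")) {
      pi_val <- if (tr == "treated") pi_treated else pi_mock
      add(rec(cs$target[i], "WT", tr, 30, "chip_ip", cs$antibody[i],
              qc$cq_input - adj - log2(pi_val / 100) + noise(qc$replicates)))
    }
  }
  # SeqChIP: one shared first-ChIP measurement per target region
  ss <- qc$seqchip_schedule
  for (tg in unique(ss$target)) {
    cq1 <- 24 + noise(qc$replicates)
    add(rec(tg, "WT", "treated", 0, "seqchip_1st", "first", cq1))
    sub <- ss[ss$target == tg, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      add(rec(tg, "WT", "treated", 0, "seqchip_2nd", sub$antibody_second[i],
              cq1 + log2(sub$percent_of_first[i] / 100) +
                noise(qc$replicates)))
    }
  }
  cq_table(do.call(rbind, rows))
}

#' Simulate a metabolite concentration table
#'
#' Mock samples draw around the base concentration; treated samples are
#' multiplied by the planted per-time accumulation fold.  Noise is
#' multiplicative lognormal so concentrations stay positive.
#'
#' @param config a [sim_config()] object.
#' @return A `ConcentrationTable`.
#' @export
simulate_concentrations <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(derive_seed(config$seed, 30))
  cc <- config$conc
  rows <- list()
  for (gt in cc$genotypes) {
    for (tm in cc$times) {
      fold <- cc$accumulation$fold[cc$accumulation$genotype == gt &
                                     cc$accumulation$time == tm]
      if (!length(fold)) fold <- 1
      for (tr in c("treated", "mock")) {
        mu <- cc$base_nM * if (tr == "treated") fold else 1
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = gt, treatment = tr, time = tm,
          replicate = seq_len(cc$replicates),
          concentration = mu * exp(stats::rnorm(cc$replicates, 0,
                                                cc$noise_sdlog)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  concentration_table(do.call(rbind, rows))
}

#' Planted ground truth of a simulated dataset
#'
#' Long-format record of every planted effect; recovery tests read truth only
#' from here.
#'
#' @param config a [sim_config()] object.
#' @param pathway_annotation result of [simulate_pathway_annotation()].
#' @return data.frame with columns `kind`, `id1`, `id2`, `id3`, `value`.
#' @export
truth_table <- function(config, pathway_annotation) {
  stopifnot(inherits(config, "SimConfig"))
  rows <- list()
  add <- function(kind, id1, id2 = "", id3 = "", value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, id1 = id1, id2 = id2, id3 = id3, value = value,
      stringsAsFactors = FALSE)
  }
  pw <- config$pathways
  for (mk in config$mark_names) {
    add("set_mark_multiplier", pw$pathway_id, mk, "", pw[[mk]])
  }
  bivalent <- bivalent_gene_ids(config, pathway_annotation)
  if (length(bivalent)) {
    add("co_marked_gene", bivalent, "", "",
        config$bivalent_set$multiplier)
  }
  fs <- config$cq$fc_schedule
  add("expression_fc", fs$target, fs$genotype, as.character(fs$time), fs$fc)
  cs <- config$cq$chip_schedule
  add("chip_abundance_ratio", cs$target, cs$antibody, "", cs$ratio_treated)
  ss <- config$cq$seqchip_schedule
  add("seqchip_percent", ss$target, ss$antibody_second, "",
      ss$percent_of_first)
  ac <- config$conc$accumulation
  add("camalexin_fold", ac$genotype, "", as.character(ac$time), ac$fold)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete dataset
#'
#' Runs every generator under the config seed and, when `out_dir` is given,
#' writes the full file set: `genome.gff3`, one `<mark>.bedgraph` per mark,
#' `pathways.tsv`, `cq.csv`, `camalexin.csv` and `truth.tsv`.  Identical
#' config and seed give a byte-identical file set.
#'
#' @param config a [sim_config()] object.
#' @param out_dir optional output directory (created if needed).
#' @return List with `annotation`, `pathway_annotation`, `tracks` (raw),
#'   `cq`, `concentrations`, `truth`, and `files` (named paths when written).
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  annotation <- simulate_genome(config)
  pathway_annotation <- simulate_pathway_annotation(config, annotation)
  tracks <- simulate_tracks(config, annotation, pathway_annotation)
  cq <- simulate_cq(config)
  concentrations <- simulate_concentrations(config)
  truth <- truth_table(config, pathway_annotation)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      genome = file.path(out_dir, "genome.gff3"),
      pathways = file.path(out_dir, "pathways.tsv"),
      cq = file.path(out_dir, "cq.csv"),
      camalexin = file.path(out_dir, "camalexin.csv"),
      truth = file.path(out_dir, "truth.tsv")
    )
    write_gff3(annotation, files[["genome"]])
    write_pathway_table(pathway_annotation, files[["pathways"]])
    write_cq_csv(cq, files[["cq"]])
    write_conc_csv(concentrations, files[["camalexin"]])
    con <- file(files[["truth"]], "w")
    writeLines(header_comment(), con)
    utils::write.table(truth, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    for (mk in names(tracks)) {
      f <- file.path(out_dir, paste0(mk, ".bedgraph"))
      write_bedgraph(tracks[[mk]], f)
      files[[paste0("track_", mk)]] <- f
    }
  }
  list(annotation = annotation, pathway_annotation = pathway_annotation,
       tracks = tracks, cq = cq, concentrations = concentrations,
       truth = truth, files = files)
}
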