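#' @keywords internal
"_PACKAGE"

ks_version <- function() {
  as.character(utils::packageVersion("kairoscan"))
}

header_comment <- function() {
  sprintf("# kairoscan %s", ks_version())
}

## ---------------------------------------------------------------------------
## Domain containers
##
## All genomic coordinates are 0-based half-open internally.  GFF3 (1-based,
## closed) is converted at the read/write boundary; bedGraph is native.
## ---------------------------------------------------------------------------

#' Construct a genome annotation
#'
#' A `GenomeAnnotation` holds the gene models signal is aggregated onto: one
#' interval per gene (0-based, half-open) plus per-chromosome lengths.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`); coordinates 0-based half-open.
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @return An object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(genes, chrom_sizes) {
  stopifnot(is.data.frame(genes))
  required <- c("gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols)) {
    stop("genes is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  genes <- genes[required]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$strand <- as.character(genes$strand)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicated gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  if (any(genes$start < 0) || any(genes$end <= genes$start)) {
    stop("gene intervals must satisfy 0 <= start < end")
  }
  chrom_sizes <- unlist(chrom_sizes)
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be named")
  }
  unknown <- setdiff(genes$chrom, names(chrom_sizes))
  if (length(unknown)) {
    stop("genes reference chromosomes absent from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  }
  too_big <- genes$end > chrom_sizes[genes$chrom]
  if (any(too_big)) {
    stop("gene(s) extend past chromosome end: ",
         paste(genes$gene_id[too_big], collapse = ", "))
  }
  rownames(genes) <- NULL
  structure(list(genes = genes, chrom_sizes = chrom_sizes),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d genes on %d chromosome(s) (%s bp)\n",
              nrow(x$genes), length(x$chrom_sizes),
              format(sum(x$chrom_sizes), big.mark = ",")))
  invisible(x)
}

#' Construct a binned signal track
#'
#' A `SignalTrack` is a per-mark collection of genome bins with nonnegative
#' signal values (raw coverage-like values, or fractional ranks after
#' [rank_normalize()]).  Bins must be sorted and non-overlapping within each
#' chromosome.
#'
#' @param mark_name name of the epigenetic mark (e.g. `"H3K27me3"`).
#' @param bins data.frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open coordinates).
#' @param ranked logical; `TRUE` once values are genome-wide fractional ranks.
#' @return An object of class `SignalTrack`.
#' @export
signal_track <- function(mark_name, bins, ranked = FALSE) {
  stopifnot(is.character(mark_name), length(mark_name) == 1L,
            is.data.frame(bins))
  required <- c("chrom", "start", "end", "value")
  missing_cols <- setdiff(required, names(bins))
  if (length(missing_cols)) {
    stop("bins is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bins <- bins[required]
  bins$chrom <- as.character(bins$chrom)
  bins$start <- as.numeric(bins$start)
  bins$end <- as.numeric(bins$end)
  if (any(!is.finite(bins$value))) stop("bin values must be finite")
  if (any(bins$value < 0)) stop("bin values must be >= 0")
  if (any(bins$end <= bins$start)) stop("bins must satisfy start < end")
  bins <- bins[order(bins$chrom, bins$start), , drop = FALSE]
  by_chrom <- split(bins, bins$chrom)
  for (cb in by_chrom) {
    if (nrow(cb) > 1L && any(cb$start[-1L] < cb$end[-nrow(cb)])) {
      stop("overlapping bins on chromosome ", cb$chrom[1L],
           " in track '", mark_name, "'")
    }
  }
  rownames(bins) <- NULL
  structure(list(mark_name = mark_name, bins = bins, ranked = ranked),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack '%s': %d bins%s\n", x$mark_name, nrow(x$bins),
              if (isTRUE(x$ranked)) " (rank-normalized)" else ""))
  invisible(x)
}

#' Construct a metabolic annotation
#'
#' Maps genes to metabolic pathways and pathways to metabolic domains
#' (PlantCyc/PMN-style hierarchy).  Domain membership of a gene is inherited
#' from its pathways; a gene has a *unique domain* only when all of its
#' pathways agree on exactly one domain.
#'
#' @param table data.frame with columns `gene_id`, `pathway_id`, `domain_id`,
#'   one row per membership.
#' @return An object of class `MetabolicAnnotation`.
#' @export
metabolic_annotation <- function(table) {
  stopifnot(is.data.frame(table))
  required <- c("gene_id", "pathway_id", "domain_id")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("annotation is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  table <- table[required]
  for (cl in required) table[[cl]] <- as.character(table[[cl]])
  if (!nrow(table)) stop("metabolic annotation is empty")
  dup <- duplicated(table)
  if (any(dup)) {
    warning(sum(dup), " duplicated annotation row(s) removed")
    table <- table[!dup, , drop = FALSE]
  }
  rownames(table) <- NULL
  structure(list(table = table), class = "MetabolicAnnotation")
}

#' @export
print.MetabolicAnnotation <- function(x, ...) {
  cat(sprintf("MetabolicAnnotation: %d genes, %d pathways, %d domains\n",
              length(unique(x$table$gene_id)),
              length(unique(x$table$pathway_id)),
              length(unique(x$table$domain_id))))
  invisible(x)
}

#' Gene, pathway and domain accessors for a metabolic annotation
#'
#' @param annotation a [metabolic_annotation()] object.
#' @param gene_id single gene identifier (for `unique_domain`).
#' @return `metabolic_genes`: character vector of all annotated gene ids.
#'   `gene_pathways`: named list gene_id -> pathway ids.
#'   `pathway_genes`: named list pathway_id -> gene ids.
#'   `pathway_domains`: named list pathway_id -> domain ids.
#'   `unique_domain`: the single common domain of all the gene's pathways, or
#'   `NA_character_` when its pathways do not share exactly one domain.
#' @export
metabolic_genes <- function(annotation) {
  stopifnot(inherits(annotation, "MetabolicAnnotation"))
  sort(unique(annotation$table$gene_id))
}

#' @rdname metabolic_genes
#' @export
gene_pathways <- function(annotation) {
  stopifnot(inherits(annotation, "MetabolicAnnotation"))
  tab <- unique(annotation$table[c("gene_id", "pathway_id")])
  split(tab$pathway_id, tab$gene_id)
}

#' @rdname metabolic_genes
#' @export
pathway_genes <- function(annotation) {
  stopifnot(inherits(annotation, "MetabolicAnnotation"))
  tab <- unique(annotation$table[c("gene_id", "pathway_id")])
  split(tab$gene_id, tab$pathway_id)
}

#' @rdname metabolic_genes
#' @export
pathway_domains <- function(annotation) {
  stopifnot(inherits(annotation, "MetabolicAnnotation"))
  tab <- unique(annotation$table[c("pathway_id", "domain_id")])
  split(tab$domain_id, tab$pathway_id)
}

#' @rdname metabolic_genes
#' @export
unique_domain <- function(annotation, gene_id) {
  stopifnot(inherits(annotation, "MetabolicAnnotation"),
            is.character(gene_id), length(gene_id) == 1L)
  doms <- unique(annotation$table$domain_id[annotation$table$gene_id == gene_id])
  if (length(doms) == 1L) doms else NA_character_
}

#' Genes mapped to exactly one metabolic domain
#'
#' Domain-level analyses include only genes whose pathways all map to a single
#' common domain, so each gene contributes to exactly one domain's density.
#'
#' @inheritParams metabolic_genes
#' @return Named character vector: unique domain per qualifying gene.
#' @export
unique_domain_genes <- function(annotation) {
  stopifnot(inherits(annotation, "MetabolicAnnotation"))
  tab <- unique(annotation$table[c("gene_id", "domain_id")])
  n_dom <- table(tab$gene_id)
  keep <- names(n_dom)[n_dom == 1L]
  tab <- tab[tab$gene_id %in% keep, , drop = FALSE]
  stats::setNames(tab$domain_id, tab$gene_id)[sort(tab$gene_id)]
}

## ---------------------------------------------------------------------------
## Cq and concentration tables
## ---------------------------------------------------------------------------

cq_assays <- c("expression", "chip_input", "chip_ip", "seqchip_1st",
               "seqchip_2nd")

cq_key_cols <- c("target_gene", "sample", "genotype", "treatment", "time",
                 "replicate", "assay", "antibody")

#' Construct a qPCR quantification-cycle table
#'
#' Long-format Cq records for expression, ChIP and sequential-ChIP assays.
#' The combination of target, sample, genotype, treatment, time, replicate,
#' assay and antibody must be unique.
#'
#' @param records data.frame with columns `target_gene`, `sample`, `genotype`,
#'   `treatment` (`"treated"` or `"mock"`), `time` (minutes), `replicate`,
#'   `assay` (one of expression, chip_input, chip_ip, seqchip_1st,
#'   seqchip_2nd), `antibody` (may be empty), `cq`.
#' @return A data.frame of class `CqTable`.
#' @export
cq_table <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c(cq_key_cols, "cq")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("Cq records missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[required]
  for (cl in c("target_gene", "sample", "genotype", "treatment", "assay",
               "antibody")) {
    records[[cl]] <- as.character(records[[cl]])
  }
  records$time <- as.numeric(records$time)
  records$replicate <- as.integer(records$replicate)
  records$cq <- as.numeric(records$cq)
  if (!all(records$treatment %in% c("treated", "mock"))) {
    stop("treatment must be 'treated' or 'mock'")
  }
  if (!all(records$assay %in% cq_assays)) {
    stop("assay must be one of: ", paste(cq_assays, collapse = ", "))
  }
  if (any(!is.finite(records$cq))) stop("cq values must be finite")
  dup <- duplicated(records[cq_key_cols])
  if (any(dup)) {
    stop("duplicated Cq record key(s), first at row ", which(dup)[1L])
  }
  rownames(records) <- NULL
  class(records) <- c("CqTable", "data.frame")
  records
}

#' Construct a metabolite concentration table
#'
#' @param records data.frame with columns `genotype`, `treatment`, `time`
#'   (minutes), `replicate`, `concentration` (nM, nonnegative).
#' @return A data.frame of class `ConcentrationTable`.
#' @export
concentration_table <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("genotype", "treatment", "time", "replicate", "concentration")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("concentration records missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  records <- records[required]
  records$genotype <- as.character(records$genotype)
  records$treatment <- as.character(records$treatment)
  records$time <- as.numeric(records$time)
  records$replicate <- as.integer(records$replicate)
  records$concentration <- as.numeric(records$concentration)
  if (!all(records$treatment %in% c("treated", "mock"))) {
    stop("treatment must be 'treated' or 'mock'")
  }
  if (any(!is.finite(records$concentration)) || any(records$concentration < 0)) {
    stop("concentrations must be finite and >= 0")
  }
  rownames(records) <- NULL
  class(records) <- c("ConcentrationTable", "data.frame")
  records
}

## ---------------------------------------------------------------------------
## GFF3
## ---------------------------------------------------------------------------

#' Read gene models from GFF3
#'
#' Imports features of type `gene` (all other feature types are ignored) and
#' converts their 1-based closed GFF3 coordinates to the internal 0-based
#' half-open convention.  Chromosome sizes come from `##sequence-region`
#' pragmas when present, otherwise from the maximum feature end per
#' chromosome.
#'
#' @param path GFF3 file path.
#' @return A [genome_annotation()] object.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("GFF3 parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- if (is.null(gr$ID)) rep(NA_character_, length(gr)) else
    as.character(gr$ID)
  if (length(gr) && (anyNA(ids) || any(!nzchar(ids)))) {
    bad <- which(is.na(ids) | !nzchar(ids))[1L]
    stop("gene feature without ID attribute (feature #", bad, ") in ", path)
  }
  genes <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (any(genes$strand == "*")) {
    stop("gene(s) without strand in ", path, ": ",
         paste(genes$gene_id[genes$strand == "*"], collapse = ", "))
  }
  # ##sequence-region pragmas are authoritative for chromosome sizes; fall
  # back to seqinfo, then to the maximum feature end per chromosome
  pragmas <- grep("^##sequence-region", readLines(path), value = TRUE)
  known <- numeric(0)
  if (length(pragmas)) {
    parts <- strsplit(trimws(pragmas), "\\s+")
    for (p in parts) {
      if (length(p) >= 4L) known[p[2L]] <- as.numeric(p[4L])
    }
  }
  sl <- GenomeInfoDb::seqlengths(gr)
  sl <- sl[!is.na(sl)]
  known <- c(known, sl[setdiff(names(sl), names(known))])
  max_end <- tapply(genes$end, genes$chrom, max)
  chrom_sizes <- numeric(0)
  chroms <- union(names(known), names(max_end))
  for (ch in chroms) {
    chrom_sizes[ch] <- if (ch %in% names(known)) as.numeric(known[[ch]])
                       else as.numeric(max_end[[ch]])
  }
  genome_annotation(genes, chrom_sizes)
}

#' Write gene models to GFF3
#'
#' Internal 0-based half-open intervals are converted back to 1-based closed
#' GFF3 coordinates; `##sequence-region` pragmas record chromosome sizes and a
#' comment line records the tool name and version.
#'
#' @param annotation a [genome_annotation()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  g <- annotation$genes
  lines <- c(
    "##gff-version 3",
    header_comment(),
    sprintf("##sequence-region %s 1 %d", names(annotation$chrom_sizes),
            as.integer(annotation$chrom_sizes)),
    sprintf("%s\tkairoscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            g$chrom, g$start + 1L, g$end, g$strand, g$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## bedGraph
## ---------------------------------------------------------------------------

#' Read a binned signal track from bedGraph
#'
#' bedGraph is 0-based half-open, matching the internal convention, so no
#' coordinate conversion is applied.  Overlapping bins are an error (no silent
#' merging), as are negative values.
#'
#' @param path bedGraph file path (4 columns: chrom, start, end, value).
#' @param mark_name mark name to attach to the track.
#' @param ranked logical; set `TRUE` when the file already holds fractional
#'   ranks (e.g. written by [write_bedgraph()] after [rank_normalize()]).
#' @return A [signal_track()] object.
#' @export
read_bedgraph <- function(path, mark_name, ranked = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("bedGraph file has no data lines: ", path)
  df <- utils::read.table(text = lines[keep], sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric"))
  signal_track(mark_name, df, ranked = ranked)
}

#' Write a signal track to bedGraph
#'
#' @param track a [signal_track()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "SignalTrack"))
  b <- track$bins
  lines <- c(
    header_comment(),
    sprintf("track type=bedGraph name=%s", track$mark_name),
    sprintf("%s\t%d\t%d\t%s", b$chrom, as.integer(b$start), as.integer(b$end),
            format(b$value, digits = 15, trim = TRUE, scientific = FALSE))
  )
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Pathway TSV, Cq CSV, concentration CSV
## ---------------------------------------------------------------------------

#' Read a metabolic pathway annotation table
#'
#' Tab-separated file with columns `gene_id`, `pathway_id`, `domain_id`, one
#' row per gene-pathway membership; the pathway's domain assignment is carried
#' to the gene.  Exact duplicate rows are removed with a warning.
#'
#' @param path TSV file path.
#' @return A [metabolic_annotation()] object.
#' @export
read_pathway_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = "character")
  if (!nrow(df)) stop("pathway table is empty: ", path)
  metabolic_annotation(df)
}

#' @rdname read_pathway_table
#' @param annotation a [metabolic_annotation()] object.
#' @export
write_pathway_table <- function(annotation, path) {
  stopifnot(inherits(annotation, "MetabolicAnnotation"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_comment(), con)
  utils::write.table(annotation$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_typed_csv <- function(path, numeric_cols) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#", colClasses = "character")
  for (cl in intersect(numeric_cols, names(df))) {
    parsed <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(parsed) & !is.na(df[[cl]]))
    if (length(bad)) {
      stop("non-numeric '", cl, "' value \"", df[[cl]][bad[1L]],
           "\" at data row ", bad[1L], " of ", path)
    }
    df[[cl]] <- parsed
  }
  df
}

#' Read and write qPCR Cq tables (CSV)
#'
#' Headered CSV matching the [cq_table()] schema; times are minutes (the
#' 5 min--6 hr sampling grid is encoded as 5, 30, 60, 180, 360).
#'
#' @param path CSV file path.
#' @return A `CqTable`.
#' @export
read_cq_csv <- function(path) {
  cq_table(read_typed_csv(path, c("time", "replicate", "cq")))
}

#' @rdname read_cq_csv
#' @param table a `CqTable`.
#' @export
write_cq_csv <- function(table, path) {
  stopifnot(inherits(table, "CqTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_comment(), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write metabolite concentration tables (CSV)
#'
#' @param path CSV file path.
#' @return A `ConcentrationTable`.
#' @export
read_conc_csv <- function(path) {
  concentration_table(
    read_typed_csv(path, c("time", "replicate", "concentration")))
}

#' @rdname read_conc_csv
#' @param table a `ConcentrationTable`.
#' @export
write_conc_csv <- function(table, path) {
  stopifnot(inherits(table, "ConcentrationTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_comment(), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
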