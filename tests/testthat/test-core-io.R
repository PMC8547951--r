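test_that("GFF3 coordinates convert 1-based closed to 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 10000",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=gA.1",  # non-gene: ignored
    "chr1\tsrc\tgene\t1\t500\t.\t-\t.\tID=gB"
  ), f)
  ann <- read_gff3(f)
  expect_equal(nrow(ann$genes), 2L)
  gA <- ann$genes[ann$genes$gene_id == "gA", ]
  expect_equal(gA$start, 1000)
  expect_equal(gA$end, 2000)
  # internal length equals GFF3 end - start + 1
  expect_equal(gA$end - gA$start, 2000 - 1001 + 1)
  expect_equal(unname(ann$chrom_sizes["chr1"]), 10000)
})

test_that("GFF3 gene count is preserved and round trip is the identity", {
  set.seed(42)
  n <- 50L
  starts <- sort(sample.int(90000, n)) + seq_len(n) * 100
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = "chr1",
    start = starts,
    end = starts + sample(100:900, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  ann <- genome_annotation(genes, c(chr1 = 2e5))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, f)
  ann2 <- read_gff3(f)
  expect_equal(nrow(ann2$genes), n)
  expect_identical(ann2$genes, ann$genes)
  expect_equal(unname(ann2$chrom_sizes), unname(as.numeric(ann$chrom_sizes)))
})

test_that("GFF3 gene features without an ID are a parse error", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tName=foo"
  ), f)
  expect_error(read_gff3(f), "ID")
})

test_that("chromosome sizes fall back to max gene end without pragmas", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr7\tsrc\tgene\t100\t2500\t.\t+\t.\tID=x"
  ), f)
  expect_equal(unname(read_gff3(f)$chrom_sizes["chr7"]), 2500)
})

test_that("bedGraph reads 0-based bins verbatim and round trips", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t200\t5.0", "chr1\t200\t400\t1.25"), f)
  tr <- read_bedgraph(f, "H3K27me3")
  expect_equal(tr$bins$start, c(0, 200))
  expect_equal(tr$bins$value, c(5, 1.25))
  g <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, g)
  expect_identical(read_bedgraph(g, "H3K27me3")$bins, tr$bins)
})

test_that("overlapping or negative bedGraph bins are rejected", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t200\t1.0", "chr1\t100\t300\t1.0"), f)
  expect_error(read_bedgraph(f, "m"), "overlap")
  writeLines("chr1\t0\t200\t-1.0", f)
  expect_error(read_bedgraph(f, "m"), ">= 0")
})

test_that("pathway table builds maps and the unique-domain rule", {
  tab <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g3"),
    pathway_id = c("P1", "P2", "P1", "P3", "P4"),
    domain_id = c("D1", "D2", "D1", "D1", "D1"),
    stringsAsFactors = FALSE
  )
  ma <- metabolic_annotation(tab)
  expect_setequal(gene_pathways(ma)[["g1"]], c("P1", "P2"))
  # two domains -> undefined; shared single domain -> defined
  expect_true(is.na(unique_domain(ma, "g1")))
  expect_equal(unique_domain(ma, "g3"), "D1")
  expect_equal(unique_domain(ma, "g2"), "D1")
  expect_setequal(names(unique_domain_genes(ma)), c("g2", "g3"))
})

test_that("pathway table round trips; duplicates warn; empty file errors", {
  tab <- data.frame(gene_id = c("g1", "g2"), pathway_id = "P1",
                    domain_id = "D1", stringsAsFactors = FALSE)
  ma <- metabolic_annotation(tab)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pathway_table(ma, f)
  expect_identical(read_pathway_table(f)$table, ma$table)

  expect_warning(metabolic_annotation(tab[c(1, 1, 2), ]), "duplicated")
  writeLines("gene_id\tpathway_id\tdomain_id", f)
  expect_error(read_pathway_table(f), "empty")
})

test_that("Cq CSV round trips with minute-coded times", {
  recs <- data.frame(
    target_gene = "CBG1", sample = paste0("s", 1:10), genotype = "WT",
    treatment = rep(c("treated", "mock"), each = 5),
    time = 60,   # "1 hr" encoded as 60 minutes
    replicate = rep(1:5, 2), assay = "expression", antibody = "",
    cq = seq(20, 21, length.out = 10),
    stringsAsFactors = FALSE
  )
  cq <- cq_table(recs)
  expect_equal(nrow(cq), 10L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cq_csv(cq, f)
  back <- read_cq_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(cq))
  expect_equal(unique(back$time), 60)
})

test_that("Cq CSV rejects duplicate keys and non-numeric values by row", {
  recs <- data.frame(
    target_gene = "t", sample = "s", genotype = "WT", treatment = "mock",
    time = 5, replicate = 1L, assay = "expression", antibody = "",
    cq = 20, stringsAsFactors = FALSE
  )
  expect_error(cq_table(recs[c(1, 1), ]), "duplicated")

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("target_gene,sample,genotype,treatment,time,replicate,assay,antibody,cq",
               "t,s,WT,mock,5,1,expression,,not_a_number"), f)
  expect_error(read_cq_csv(f), "row 1")
})

test_that("concentration CSV round trips and rejects negatives", {
  conc <- concentration_table(data.frame(
    genotype = "WT", treatment = rep(c("treated", "mock"), each = 3),
    time = 180, replicate = rep(1:3, 2),
    concentration = c(150.5, 160, 140, 50, 55, 45),
    stringsAsFactors = FALSE
  ))
  f <- withr::local_tempfile(fileext = ".csv")
  write_conc_csv(conc, f)
  expect_equal(as.data.frame(read_conc_csv(f)), as.data.frame(conc))
  expect_error(concentration_table(data.frame(
    genotype = "WT", treatment = "mock", time = 5, replicate = 1,
    concentration = -1)), ">= 0")
})
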