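# Readers/writers and genotype classification.

test_that("genotype classification maps GT/FILTER/GQ to the five classes", {
  cfg <- quality_config(min_gq = 20)
  # definitional single-allele mappings
  expect_equal(classify_gt("1/1", 1L, pass = TRUE, gq = 30, config = cfg), 2L)
  expect_equal(classify_gt("0/0", 1L, pass = TRUE, gq = 30, config = cfg), 1L)
  expect_equal(classify_gt("0/1", 1L, pass = TRUE, gq = 30, config = cfg), 3L)
  # missing wins over everything
  expect_equal(classify_gt("./.", 1L, pass = FALSE, gq = 5, config = cfg), 5L)
  expect_equal(classify_gt(".", 1L, pass = TRUE, gq = 99, config = cfg), 5L)
  # quality downgrades
  expect_equal(classify_gt("1/1", 1L, pass = FALSE, gq = 99, config = cfg), 4L)
  expect_equal(classify_gt("1/1", 1L, pass = TRUE, gq = 19, config = cfg), 4L)
  expect_equal(classify_gt("1/1", 1L, pass = TRUE, gq = 20, config = cfg), 2L)
  # NA GQ counts as passing (GQ optional in the file)
  expect_equal(classify_gt("1/1", 1L, pass = TRUE, gq = NA, config = cfg), 2L)
})

test_that("multi-allelic genotypes classify per decomposed allele", {
  cfg <- quality_config()
  # full enumeration of GT strings for a two-ALT row against each allele
  cases <- list(
    #  GT        allele1  allele2
    c("0/0", 1L, 1L),
    c("1/1", 2L, 3L),   # hom for allele 1: HOM_ALT in rec1, other-allele in rec2
    c("2/2", 3L, 2L),
    c("0/1", 3L, 3L),
    c("0/2", 3L, 3L),
    c("1/2", 3L, 3L),
    c("./.", 5L, 5L)
  )
  for (cs in cases) {
    expect_equal(classify_gt(cs[1], 1L, TRUE, 99, cfg), as.integer(cs[2]),
                 label = paste("GT", cs[1], "vs allele 1"))
    expect_equal(classify_gt(cs[1], 2L, TRUE, 99, cfg), as.integer(cs[3]),
                 label = paste("GT", cs[1], "vs allele 2"))
  }
})

test_that("read_multistrain_vcf decomposes multi-allelic rows", {
  vcf <- write_temp_vcf(c(
    minimal_vcf_header(c("A", "B", "C")),
    "chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT:GQ\t1/1:99\t2/2:99\t0/0:99",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT:GQ\t0/1:99\t./.:.\t1/1:99",
    "chr2\t50\t.\tG\tA\t.\tLowQual\t.\tGT:GQ\t1/1:99\t0/0:99\t./.:."
  ))
  mat <- read_multistrain_vcf(vcf, panel = c("A", "B", "C"))
  # decomposition conservation: records = sum of ALT counts
  expect_equal(nrow(mat$sites), 4L)
  expect_equal(mat$sites$key,
               c("chr1:100:A:G", "chr1:100:A:T", "chr1:200:C:T", "chr2:50:G:A"))
  # A is hom for allele G: HOM_ALT in the A->G record, het-equivalent in A->T
  expect_equal(unname(mat$gt[1, ]), c(HA, HE, HR))
  expect_equal(unname(mat$gt[2, ]), c(HE, HA, HR))
  expect_equal(unname(mat$gt[3, ]), c(HE, MI, HA))
  # soft-filtered row: set genotypes LOW_QUALITY, missing stays missing
  expect_equal(unname(mat$gt[4, ]), c(LQ, LQ, MI))
})

test_that("panel strain absent from the VCF is a fatal error", {
  vcf <- write_temp_vcf(c(
    minimal_vcf_header(c("A", "B")),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:GQ\t1/1:99\t0/0:99"
  ))
  expect_error(read_multistrain_vcf(vcf, panel = c("A", "ZZZ")), "ZZZ")
})

test_that("VCF round-trip preserves genotype classifications bit-exact", {
  sim <- simulate_strain_panel(n_strains = 6, n_sites = 300,
                               n_private_per_strain = 5, seed = 11)
  sim <- simulate_annotations(sim, seed = 12)
  path <- tempfile(fileext = ".vcf")
  write_multistrain_vcf(sim$matrix, path)
  back <- read_multistrain_vcf(path)
  expect_identical(back$sites$key, sim$matrix$sites$key)
  expect_identical(unname(back$gt), unname(sim$matrix$gt))
  expect_identical(unname(back$raw), unname(sim$matrix$raw))
  expect_identical(unname(back$gq), unname(sim$matrix$gq))
  # annotations survive the CSQ round trip
  a0 <- data.table::setorder(data.table::copy(sim$matrix$annotations),
                             key, transcript_id)
  a1 <- data.table::setorder(data.table::copy(back$annotations),
                             key, transcript_id)
  expect_equal(a1$gene_id, a0$gene_id)
  expect_equal(a1$consequence, a0$consequence)
  expect_equal(a1$sift_score, a0$sift_score)
  expect_equal(a1$sift_call, ifelse(is.na(a0$sift_call), NA, a0$sift_call))
})

test_that("gene models normalize, merge abutting CDS and survive odd inputs", {
  bed <- tempfile(fileext = ".bed")
  # BED is 0-based half-open; [9,20) + [20,30) abut -> one interval 10..30
  writeLines(c("chr1\t9\t20\tgeneA\t0\t+",
               "chr1\t20\t30\tgeneA\t0\t+",
               "chrUn_scaffold\t99\t200\tgeneB\t0\t-"), bed)
  gm <- read_gene_models(bed)
  expect_equal(nrow(gm), 2L)
  expect_equal(gm[gene_id == "geneA", c(start, end)], c(10L, 30L))
  # unplaced contig retained verbatim
  expect_equal(gm[gene_id == "geneB", chrom], "chrUn_scaffold")

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tCDS\t10\t20\t.\t+\t0\tID=cds1;gene_id=geneC",
               "chr1\tsrc\tCDS\t15\t40\t.\t+\t0\tID=cds2;gene_id=geneC",
               "chr1\tsrc\tCDS\t50\t60\t.\t+\t0\tnote=unattributed"), gff)
  expect_warning(gm2 <- read_gene_models(gff), "without gene attribution")
  # overlapping CDS merged; the unattributed CDS is skipped
  expect_equal(gm2[gene_id == "geneC", c(start, end)], c(10L, 40L))
  expect_equal(nrow(gm2), 1L)

  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_warning(gm3 <- read_gene_models(empty), "no gene models")
  expect_equal(nrow(gm3), 0L)
})

test_that("GMT parsing dedups genes, preserves order and rejects bad lines", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("P1\tdesc\tG1\tG2\tG2", "KEGG:P2\tdesc\tG3"), gmt)
  ps <- read_gmt(gmt)
  expect_length(ps, 2L)
  expect_equal(ps[[1]]$genes, c("G1", "G2"))
  expect_equal(ps[[2]]$database, "KEGG")
  expect_equal(vapply(ps, `[[`, "", "pathway_id"), c("P1", "KEGG:P2"))

  bad <- tempfile(fileext = ".gmt")
  writeLines("P1\tdesc-only", bad)
  expect_error(read_gmt(bad), "line 1")
  writeLines(c("P1\tdesc\tG1", "P2\tdesc\t\t"), bad)
  expect_error(read_gmt(bad), "line 2")
})

test_that("GMT round-trips through write_gmt", {
  ps <- simulate_pathway_db(n_pathways = 5, genes_per_pathway = 8,
                            universe_size = 50, seed = 4)$pathways
  path <- tempfile(fileext = ".gmt")
  write_gmt(ps, path)
  back <- read_gmt(path)
  expect_equal(lapply(back, `[[`, "genes"), lapply(ps, `[[`, "genes"))
  expect_equal(vapply(back, `[[`, "", "database"),
               vapply(ps, `[[`, "", "database"))
})
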