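test_that("VCF records parse GT/DP/GQ, code genotypes, and split multiallelics", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeTinyVcf(f, list(
    list(chrom = "sc1", pos = 100, ref = "A", alt = "G",
         calls = c("0/0:30:90", "0/1:28:88", "1/1:33:95")),
    list(chrom = "sc1", pos = 200, ref = "C", alt = "T",
         calls = c("./.:0:0", "0|1:25:80", "0/0:31:90")),
    list(chrom = "sc1", pos = 300, ref = "A", alt = "G,T",
         calls = c("1/2:30:90", "0/1:30:90", "2/2:30:90")),
    list(chrom = "sc2", pos = 50, ref = "A", alt = "AT",
         calls = c("0/1:30:90", "0/0:30:90", "1/1:30:90"))
  ))
  x <- readVcfCalls(f)
  expect_equal(length(x), 5L)  # multiallelic row split into two
  expect_equal(unname(genotypes(x)[1L, ]), c(0L, 1L, 2L))
  expect_true(is.na(genotypes(x)[2L, 1L]))
  expect_equal(unname(genotypes(x)[2L, 2L]), 1L)  # phased treated unphased
  mc <- S4Vectors::mcols(variantRanges(x))
  # split record: alt alleles of the two rows equal the source alt list
  expect_equal(as.character(mc$alt[3:4]), c("G", "T"))
  # 1/2 w.r.t. alt G: one G allele; w.r.t. alt T: one T allele
  expect_equal(unname(genotypes(x)[3L, ]), c(1L, 1L, 0L))
  expect_equal(unname(genotypes(x)[4L, ]), c(1L, 0L, 2L))
  expect_equal(as.character(mc$vclass), c("SNP", "SNP", "SNP", "SNP", "INDEL"))
  expect_equal(unname(readDepth(x)[1L, ]), c(30L, 28L, 33L))
  expect_equal(unname(genoQual(x)[2L, ]), c(0L, 80L, 90L))
})

test_that("records without DP/GQ fields get zeros", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeTinyVcf(f, list(
    list(chrom = "sc1", pos = 10, ref = "A", alt = "C",
         calls = c("0/0", "0/1", "1/1"))), format = "GT")
  x <- readVcfCalls(f)
  expect_equal(unname(readDepth(x)[1L, ]), c(0L, 0L, 0L))
  expect_equal(unname(genoQual(x)[1L, ]), c(0L, 0L, 0L))
  expect_equal(unname(genotypes(x)[1L, ]), c(0L, 1L, 2L))
})

test_that("VCF round trip preserves scaffold, pos, alleles and GT/DP/GQ", {
  cfg <- simConfig(seed = 11, n_scaffolds = 2, scaffold_length_bp = 50000L,
                   n_genes_per_scaffold = 3, n_samples = 12)
  pop <- simulatePopulationVcf(simulateGenome(cfg)$genome, cfg)
  f <- withr::local_tempfile(fileext = ".vcf")
  writeVcfCalls(pop$calls, f)
  back <- readVcfCalls(f)
  expect_equal(as.character(GenomicRanges::seqnames(variantRanges(back))),
               as.character(GenomicRanges::seqnames(variantRanges(pop$calls))))
  expect_equal(GenomicRanges::start(variantRanges(back)),
               GenomicRanges::start(variantRanges(pop$calls)))
  expect_equal(S4Vectors::mcols(variantRanges(back))$ref,
               S4Vectors::mcols(variantRanges(pop$calls))$ref)
  expect_equal(S4Vectors::mcols(variantRanges(back))$alt,
               S4Vectors::mcols(variantRanges(pop$calls))$alt)
  expect_equal(genotypes(back), genotypes(pop$calls),
               ignore_attr = TRUE)
  expect_equal(readDepth(back), readDepth(pop$calls), ignore_attr = TRUE)
  expect_equal(genoQual(back), genoQual(pop$calls), ignore_attr = TRUE)
  expect_equal(sampleIds(back), sampleIds(pop$calls))
})

test_that("inconsistent VCF column counts fail naming the line", {
  f <- withr::local_tempfile(fileext = ".vcf")
  lines <- readLines(writeTinyVcf(f, list(
    list(chrom = "sc1", pos = 10, ref = "A", alt = "C",
         calls = c("0/0:30:90", "0/1:30:90", "1/1:30:90")))))
  lines <- c(lines, "sc1\t20\t.\tA\tC\t.\tPASS\t.\tGT:DP:GQ\t0/0:30:90")
  writeLines(lines, f)
  expect_error(readVcfCalls(f), "line 7")
  expect_error(readVcfCalls(withr::local_tempfile(lines = "no header")),
               "header")
})

test_that("GFF3 models load 1-based closed, pick the longest CDS transcript, and skip orphans", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\t.\tgene\t101\t400\t.\t+\t.\tID=gA",
    "chr1\t.\tmRNA\t101\t400\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\t.\tCDS\t101\t160\t.\t+\t0\tParent=gA.t1",
    "chr1\t.\tCDS\t201\t242\t.\t+\t0\tParent=gA.t1",
    "chr1\t.\tmRNA\t101\t400\t.\t+\t.\tID=gA.t2;Parent=gA",
    "chr1\t.\tCDS\t101\t160\t.\t+\t0\tParent=gA.t2",
    "chr1\t.\tCDS\t201\t245\t.\t+\t0\tParent=gA.t2",
    "chr1\t.\tCDS\t301\t339\t.\t+\t0\tParent=gA.t2",
    "chr1\t.\tCDS\t900\t950\t.\t+\t0\tParent=nosuch"
  ), f)
  expect_warning(m <- readGff3Genes(f), "without a parent gene")
  # the 3-interval transcript has the longer CDS (60+45+39 = 144)
  cds <- m@cds
  expect_equal(length(cds), 3L)
  expect_equal(GenomicRanges::start(cds), c(101L, 201L, 301L))
  expect_equal(GenomicRanges::end(cds), c(160L, 245L, 339L))
  expect_equal(sum(GenomicRanges::width(cds)), 144L)
  expect_equal(geneIds(m), "gA")
})

test_that("CDS total length must be divisible by 3 after phase", {
  gr_gene <- GenomicRanges::GRanges("c", IRanges::IRanges(101, 241), strand = "+")
  S4Vectors::mcols(gr_gene)$gene_id <- "g"
  mk_cds <- function(e2) {
    cds <- GenomicRanges::GRanges("c", IRanges::IRanges(c(101, 201), c(160, e2)),
                                  strand = "+")
    S4Vectors::mcols(cds)$gene_id <- "g"
    S4Vectors::mcols(cds)$phase <- c(0L, 0L)
    cds
  }
  # 60 + 41 = 101 bp and 60 + 40 = 100 bp are invalid; 60 + 42 = 102 is valid
  expect_error(GeneModelSet(gr_gene, mk_cds(241), mk_cds(241)), "divisible")
  expect_error(GeneModelSet(gr_gene, mk_cds(240), mk_cds(240)), "divisible")
  expect_s4_class(GeneModelSet(gr_gene, mk_cds(242), mk_cds(242)),
                  "GeneModelSet")
})

test_that("empty GFF3 yields an empty model set", {
  f <- withr::local_tempfile(lines = "##gff-version 3", fileext = ".gff3")
  m <- readGff3Genes(f)
  expect_equal(length(m@genes), 0L)
})

test_that("call matrices round trip and reject bad tokens", {
  set.seed(3)
  m <- matrix(sample(c("AA", "AB", "BB", "NoCall"), 96 * 20, replace = TRUE),
              20, 96, dimnames = list(sprintf("m%02d", 1:20),
                                      sprintf("s%02d", 1:96)))
  cm <- CallMatrix(m, dqc = round(runif(96, 0.9, 1), 4))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCallMatrix(cm, f)
  back <- readCallMatrix(f)
  expect_identical(calls(back), calls(cm))
  expect_equal(dishQC(back), dishQC(cm))

  f2 <- withr::local_tempfile(
    lines = c("probeset_id\ts1\ts2", "m1\tAA\tAA", "m2\tAB\tBA"))
  expect_error(readCallMatrix(f2), "BA")
  f3 <- withr::local_tempfile(
    lines = c("probeset_id\ts1\ts2", "m1\tAA\tAA"))
  expect_equal(unname(calls(readCallMatrix(f3))[1L, ]), c("AA", "AA"))
})

test_that("design tables round trip, refuse duplicates, and write header-only when empty", {
  cand <- randomCandidates(100, 300000L, seed = 5)
  cand$must_include <- FALSE
  cand$p_convert <- NA_real_
  d <- ArrayDesign(cand[, c("marker_id", "scaffold", "pos", "ref", "alt",
                            "effect", "priority", "maf", "must_include",
                            "p_convert")])
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDesign(d, f)
  back <- readDesign(f)
  expect_equal(designMarkers(back), designMarkers(d))

  dup <- d
  dup@markers$marker_id[2] <- dup@markers$marker_id[1]
  expect_error(writeDesign(dup, f), "duplicate")

  empty <- ArrayDesign(designMarkers(d)[0, ])
  writeDesign(empty, f)
  expect_length(readLines(f), 1L)
  expect_equal(nrow(designMarkers(readDesign(f))), 0L)
})
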