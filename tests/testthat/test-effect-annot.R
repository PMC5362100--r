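# A plus-strand gene whose codons are known exactly:
#   ATG GAA TGG CCA TAA  (M E W P *)
TINY_CODONS <- c("ATG", "GAA", "TGG", "CCA", "TAA")

test_that("coding substitutions classify by codon translation", {
  g <- makeTinyGene(TINY_CODONS, strand = "+")
  s <- g$gene_start
  cls <- function(offset, alt)
    classifyEffect("chr1", s + offset, substring(paste(TINY_CODONS,
      collapse = ""), offset + 1, offset + 1), alt, g$models, g$genome)
  expect_equal(cls(5, "G"), "synonymous")      # GAA -> GAG (E -> E)
  expect_equal(cls(4, "T"), "missense")        # GAA -> GTA (E -> V)
  expect_equal(cls(8, "A"), "stop_gained")     # TGG -> TGA (W -> *)
  expect_equal(cls(13, "C"), "stop_lost")      # TAA -> CAA (* -> Q)
  expect_equal(cls(14, "G"), "stop_retained")  # TAA -> TAG (* -> *)
  expect_equal(cls(0, "C"), "start_lost")      # ATG -> CTG
  expect_equal(cls(2, "A"), "start_lost")      # ATG -> ATA (I, not Met)
})

test_that("near-gene and intronic positions classify by distance and side", {
  g <- makeTinyGene(TINY_CODONS, strand = "+", gene_start = 3001L,
                    scaffold_len = 6000L, intron_len = 300L)
  base <- function(p) substring(as.character(g$genome[[1]]), p, p)
  alt_of <- function(p) setdiff(c("A", "C", "G", "T"), base(p))[1]
  cls <- function(p) classifyEffect("chr1", p, base(p), alt_of(p),
                                    g$models, g$genome)
  expect_equal(cls(3001L - 1500L), "upstream2k")
  expect_equal(cls(3001L - 2000L), "upstream2k")
  expect_equal(cls(3001L - 2001L), "intergenic")
  gene_end <- max(g$ex_end)
  expect_equal(cls(gene_end + 1999L), "downstream2k")
  expect_equal(cls(gene_end + 2001L), "intergenic")
  # intron runs between the two exons
  i_start <- g$ex_end[1] + 1L; i_end <- g$ex_start[2] - 1L
  expect_equal(cls(i_start), "splice_donor")
  expect_equal(cls(i_start + 1L), "splice_donor")
  expect_equal(cls(i_start + 2L), "splice_region")
  expect_equal(cls(i_start + 7L), "splice_region")
  expect_equal(cls(i_start + 8L), "intron")
  expect_equal(cls(i_end), "splice_acceptor")
  expect_equal(cls(i_end - 1L), "splice_acceptor")
  expect_equal(cls(i_end - 7L), "splice_region")
})

test_that("the priority map is total over the effect vocabulary", {
  effects <- c("synonymous", "missense", "stop_gained", "start_lost",
               "stop_lost", "stop_retained", "initiator_codon",
               "splice_donor", "splice_acceptor", "splice_region", "intron",
               "upstream2k", "downstream2k", "intergenic")
  pr <- priorityLevel(effects)
  expect_true(all(pr %in% 1:4))
  expect_equal(priorityLevel("missense"), 4L)
  expect_equal(priorityLevel("splice_donor"), 4L)
  expect_equal(priorityLevel("synonymous"), 3L)
  expect_equal(priorityLevel(c("intron", "splice_region", "upstream2k",
                               "downstream2k")), rep(2L, 4))
  expect_equal(priorityLevel("intergenic"), 1L)
  expect_error(priorityLevel("frameshift"), "unknown")
})

test_that("large-effect classes are exactly the stop/start/splice-site disruptors", {
  expect_true(all(isLargeEffect(c("stop_gained", "start_lost", "stop_lost",
                                  "splice_donor", "splice_acceptor"))))
  expect_false(any(isLargeEffect(c("missense", "synonymous", "splice_region",
                                   "intron", "intergenic", "stop_retained",
                                   "initiator_codon"))))
})

test_that("all substitutions across a small CDS match the translate-and-compare oracle", {
  for (strand in c("+", "-")) {
    g <- makeTinyGene(TINY_CODONS, strand = strand, intron_len = 200L,
                      seed = 7L)
    chr <- as.character(g$genome[[1]])
    cds_pos <- unlist(mapply(seq, g$ex_start, g$ex_end, SIMPLIFY = FALSE))
    for (p in cds_pos) {
      refb <- substring(chr, p, p)
      for (altb in setdiff(c("A", "C", "G", "T"), refb)) {
        got <- classifyEffect("chr1", p, refb, altb, g$models, g$genome)
        want <- codingEffectOracle(g$genome, g$models, p, altb)
        expect_equal(got, want,
                     label = sprintf("strand %s pos %d %s>%s: %s",
                                     strand, p, refb, altb, got))
      }
    }
  }
})

test_that("minus-strand classification equals the reverse-complemented mirror", {
  g <- makeTinyGene(TINY_CODONS, strand = "-", intron_len = 300L,
                    scaffold_len = 7000L, gene_start = 2500L, seed = 12L)
  len <- nchar(as.character(g$genome[[1]]))
  # mirror fixture: reverse-complement scaffold, flip coordinates and strand
  rc <- Biostrings::reverseComplement(g$genome[[1]])
  mirror_genome <- Biostrings::DNAStringSet(stats::setNames(
    as.character(rc), "chr1"))
  flip <- function(gr) {
    out <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(len - GenomicRanges::end(gr) + 1L,
                       len - GenomicRanges::start(gr) + 1L),
      strand = "+")
    S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
    out[order(GenomicRanges::start(out))]
  }
  mg <- flip(g$models@genes)
  mc <- flip(g$models@cds)
  mirror <- GeneModelSet(mg, mc, mc)
  comp <- function(b) chartr("ACGT", "TGCA", b)
  chr <- as.character(g$genome[[1]])
  set.seed(5)
  for (p in sort(sample(seq(g$gene_start - 2200L, max(g$ex_end) + 2200L), 60))) {
    refb <- substring(chr, p, p)
    altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
    e1 <- classifyEffect("chr1", p, refb, altb, g$models, g$genome)
    e2 <- classifyEffect("chr1", len - p + 1L, comp(refb), comp(altb),
                         mirror, mirror_genome)
    expect_equal(e1, e2, label = sprintf("pos %d (%s)", p, e1))
  }
})

test_that("overlapping genes resolve to the highest-priority effect, ties to first gene id", {
  # two plus-strand genes; SNP intronic in gA but coding in gB
  gA <- makeTinyGene(TINY_CODONS, strand = "+", gene_start = 501L,
                     intron_len = 300L, scaffold_len = 3000L, seed = 3L)
  chr <- as.character(gA$genome[[1]])
  # place a second, single-exon gene entirely inside gA's intron
  i_start <- gA$ex_end[1] + 1L
  b_start <- i_start + 50L
  cdsB <- paste(TINY_CODONS, collapse = "")
  substr(chr, b_start, b_start + nchar(cdsB) - 1L) <- cdsB
  genome <- Biostrings::DNAStringSet(stats::setNames(chr, "chr1"))
  gB_rng <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(b_start, b_start + nchar(cdsB) - 1L), strand = "+")
  S4Vectors::mcols(gB_rng)$gene_id <- "gB"
  gB_cds <- gB_rng
  S4Vectors::mcols(gB_cds)$phase <- 0L
  genes <- c(gA$models@genes, gB_rng)
  cds <- c(gA$models@cds, gB_cds)
  models <- GeneModelSet(genes, cds, cds)
  # missense in gB (priority 4) beats intron in gA (priority 2)
  p <- b_start + 4L  # second base of GAA codon
  ann <- annotateSnpEffects("chr1", p, "A", "T", models, genome)
  expect_equal(ann$effect, "missense")
  expect_equal(ann$gene_id, "gB")
})
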