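# Shared fixture builders and independent brute-force oracles.

# Build a VariantCallSet from compact per-site specs.
makeVcs <- function(scaffold, pos, ref, alt, gt, dp = NULL, gq = NULL) {
  n <- length(pos)
  k <- ncol(gt)
  if (is.null(dp)) dp <- matrix(50L, n, k)
  if (is.null(gq)) gq <- matrix(99L, n, k)
  VariantCallSet(scaffold, pos, ref, alt, gt, dp, gq,
                 samples = sprintf("s%02d", seq_len(k)))
}

# Minimal hand-written VCF text.
writeTinyVcf <- function(path, records,
                         samples = c("s1", "s2", "s3"),
                         format = "GT:DP:GQ") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    vapply(records, function(r)
      paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".",
              format, r$calls), collapse = "\t"), character(1))
  ), path)
  path
}

# A small single-gene genome built by hand: known CDS on a known strand.
# cds_codons: character vector of codons (first ATG, last a stop).
makeTinyGene <- function(cds_codons, strand = "+", scaffold_len = 2000L,
                         gene_start = 501L, intron_len = 0L, seed = 42L) {
  set.seed(seed)
  chr <- sample(c("A", "C", "G", "T"), scaffold_len, replace = TRUE)
  cds_seq <- paste(cds_codons, collapse = "")
  cds_len <- nchar(cds_seq)
  if (intron_len > 0L) {
    # split the CDS into two exons around a mid codon boundary
    half <- 3L * (length(cds_codons) %/% 2L)
    ex_len <- c(half, cds_len - half)
  } else ex_len <- cds_len
  ex_start <- gene_start + cumsum(c(0L, head(ex_len, -1L) + intron_len))
  ex_end <- ex_start + ex_len - 1L
  plus_seq <- if (strand == "+") cds_seq else
    chartr("ACGT", "TGCA", paste(rev(strsplit(cds_seq, "")[[1]]),
                                 collapse = ""))
  chars <- strsplit(plus_seq, "")[[1]]
  off <- 0L
  for (e in seq_along(ex_start)) {
    chr[ex_start[e]:ex_end[e]] <- chars[(off + 1L):(off + ex_len[e])]
    off <- off + ex_len[e]
  }
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(chr, collapse = ""), "chr1"))
  tx_order <- if (strand == "+") seq_along(ex_start) else
    rev(seq_along(ex_start))
  cum <- cumsum(c(0L, ex_len[tx_order][-length(ex_len)]))
  phase <- integer(length(ex_start))
  phase[tx_order] <- (3L - (cum %% 3L)) %% 3L
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(gene_start, max(ex_end)), strand = strand)
  S4Vectors::mcols(genes)$gene_id <- "g1"
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(ex_start, ex_end),
                                strand = strand)
  S4Vectors::mcols(cds)$gene_id <- "g1"
  S4Vectors::mcols(cds)$phase <- phase
  list(genome = genome, models = GeneModelSet(genes, cds, cds),
       gene_start = gene_start, ex_start = ex_start, ex_end = ex_end,
       strand = strand, cds_len = cds_len)
}

# Independent effect oracle for coding positions: mutate the genome string,
# re-extract the spliced CDS with Biostrings, translate both proteins with
# Biostrings::translate and compare.
codingEffectOracle <- function(genome, models, pos, alt) {
  cds <- models@cds
  strand <- as.character(GenomicRanges::strand(cds))[1]
  chr <- as.character(genome[[1]])
  mut <- chr
  substr(mut, pos, pos) <- alt
  splice <- function(s) {
    pieces <- substring(s, GenomicRanges::start(cds),
                        GenomicRanges::end(cds))
    out <- paste(pieces, collapse = "")
    if (strand == "-")
      out <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(out)))
    out
  }
  ref_cds <- Biostrings::DNAString(splice(chr))
  alt_cds <- Biostrings::DNAString(splice(mut))
  ref_aa <- strsplit(as.character(
    Biostrings::translate(ref_cds, no.init.codon = TRUE)), "")[[1]]
  alt_aa <- strsplit(as.character(
    Biostrings::translate(alt_cds, no.init.codon = TRUE)), "")[[1]]
  d <- which(ref_aa != alt_aa)
  codon_changed <- which(strsplit(as.character(ref_cds), "")[[1]] !=
                           strsplit(as.character(alt_cds), "")[[1]])
  codon_i <- (codon_changed[1] - 1) %/% 3 + 1
  if (codon_i == 1)
    return(if (alt_aa[1] == "M") "initiator_codon" else "start_lost")
  if (!length(d))
    return(if (ref_aa[codon_i] == "*") "stop_retained" else "synonymous")
  if (ref_aa[d[1]] == "*") return("stop_lost")
  if (alt_aa[d[1]] == "*") return("stop_gained")
  "missense"
}

# Brute-force per-site filter oracle (no vectorization, no sorting).
naiveFilterOracle <- function(vcs, mafMin = 0.05, missingMax = 0.1,
                              indelRadius = 20L) {
  gr <- variantRanges(vcs)
  mc <- S4Vectors::mcols(gr)
  sc <- as.character(GenomicRanges::seqnames(gr))
  pos <- GenomicRanges::start(gr)
  is_snp <- mc$vclass == "SNP"
  keep <- logical(length(gr))
  for (i in which(is_snp)) {
    nv <- 0L; altc <- 0L
    for (j in seq_along(sampleIds(vcs))) {
      g <- genotypes(vcs)[i, j]; d <- readDepth(vcs)[i, j]
      q <- genoQual(vcs)[i, j]
      if (!is.na(g) && d >= 10 && d <= 100 && q >= 20) {
        nv <- nv + 1L; altc <- altc + g
      }
    }
    if (nv == 0L) next
    miss <- (length(sampleIds(vcs)) - nv) / length(sampleIds(vcs))
    p <- altc / (2 * nv)
    maf <- min(p, 1 - p)
    near <- FALSE
    for (k in which(!is_snp))
      if (sc[k] == sc[i] && abs(pos[k] - pos[i]) <= indelRadius)
        near <- TRUE
    keep[i] <- maf >= mafMin && miss <= missingMax && !near
  }
  keep[is_snp]
}

# Exhaustive per-window argmax oracle for the primary scan.
naiveWindowSelect <- function(cand, windowBp) {
  if (!nrow(cand)) return(cand)
  picked <- list()
  for (w in unique(sort((cand$pos - 1L) %/% windowBp))) {
    inw <- cand[(cand$pos - 1L) %/% windowBp == w, , drop = FALSE]
    best <- inw[1L, , drop = FALSE]
    for (r in seq_len(nrow(inw))) {
      b <- inw[r, ]
      better <- b$priority > best$priority ||
        (b$priority == best$priority && b$maf > best$maf) ||
        (b$priority == best$priority && b$maf == best$maf &&
           b$pos < best$pos)
      if (better) best <- b
    }
    picked[[length(picked) + 1L]] <- best
  }
  out <- do.call(rbind, picked)
  out[order(out$pos), , drop = FALSE]
}

# Exhaustive two-sided Fisher oracle over all tables with fixed margins,
# using choose() directly (independent of dhyper).
bruteFisher <- function(tbl) {
  r1 <- sum(tbl[1, ]); r2 <- sum(tbl[2, ]); c1 <- sum(tbl[, 1])
  total <- r1 + r2
  ptab <- function(a) choose(r1, a) * choose(r2, c1 - a) / choose(total, c1)
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- vapply(support, ptab, numeric(1))
  p_obs <- ptab(tbl[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

randomCandidates <- function(n, scaffoldLen, seed) {
  set.seed(seed)
  pos <- sort(sample.int(scaffoldLen, n))
  data.frame(
    marker_id = paste0("sc:", pos), scaffold = "sc", pos = pos,
    ref = "A", alt = "G",
    effect = sample(c("missense", "synonymous", "intron", "intergenic"),
                    n, replace = TRUE),
    priority = 0L, maf = round(runif(n, 0.05, 0.5), 3),
    stringsAsFactors = FALSE) -> d
  d$priority <- priorityLevel(d$effect)
  d
}
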