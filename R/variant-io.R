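#' Read a population VCF into a VariantCallSet
#'
#' Parses a VCF v4.x file with per-sample GT (and optionally DP, GQ) fields.
#' Multiallelic records are split into one site per alternate allele; in the
#' split record, sample alleles equal to the current alternate count as ALT
#' and all other alleles (reference or another alternate) count as REF.
#' Phased separators \code{|} are accepted and treated as unphased.  Records
#' lacking DP or GQ get 0 for the missing field.
#'
#' @param path path to a plain-text VCF file.
#' @param requiredFields per-sample FORMAT fields that must be declared in
#'   the header.
#' @return a \code{\linkS4class{VariantCallSet}} ordered as in the file.
#' @export
readVcfCalls <- function(path, requiredFields = c("GT")) {
  .checkVcfShape(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  missing_fields <- setdiff(requiredFields, fmt)
  if (length(missing_fields))
    stop("VCF lacks required per-sample fields: ",
         paste(missing_fields, collapse = ", "))
  fix <- vcf@fix
  samples <- colnames(vcf@gt)[-1L]
  gt_chr <- vcfR::extract.gt(vcf, element = "GT")
  dp <- if ("DP" %in% fmt)
    suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)) else
      matrix(0, nrow(fix), length(samples))
  gq <- if ("GQ" %in% fmt)
    suppressWarnings(vcfR::extract.gt(vcf, "GQ", as.numeric = TRUE)) else
      matrix(0, nrow(fix), length(samples))
  dp[is.na(dp)] <- 0; gq[is.na(gq)] <- 0

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec_idx <- rep.int(seq_len(nrow(fix)), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len))
  alt_allele <- unlist(alts)

  out_gt <- matrix(NA_integer_, length(rec_idx), length(samples))
  ulev <- unique(as.vector(gt_chr))
  for (k in unique(alt_idx)) {
    code_k <- vapply(ulev, .gtCodeForAlt, integer(1), k = k)
    rows_k <- which(alt_idx == k)
    src <- gt_chr[rec_idx[rows_k], , drop = FALSE]
    out_gt[rows_k, ] <- code_k[match(as.vector(src), ulev)]
  }
  VariantCallSet(
    scaffold = fix[rec_idx, "CHROM"],
    pos      = as.integer(fix[rec_idx, "POS"]),
    ref      = fix[rec_idx, "REF"],
    alt      = alt_allele,
    gt = out_gt,
    dp = dp[rec_idx, , drop = FALSE],
    gq = gq[rec_idx, , drop = FALSE],
    samples = samples
  )
}

# Diploid genotype string -> 0/1/2/NA with respect to alt index k.
.gtCodeForAlt <- function(s, k) {
  if (is.na(s) || s == "." || s == "./." || s == ".|.") return(NA_integer_)
  al <- strsplit(s, "[/|]")[[1L]]
  if (any(al == ".")) return(NA_integer_)
  sum(al == as.character(k))
}

# Structural pre-check so parse failures can name the offending line.
.checkVcfShape <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr))
    stop("malformed VCF header: no #CHROM line in ", path)
  ncol_expected <- length(strsplit(lines[hdr[1L]], "\t", fixed = TRUE)[[1L]])
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nc <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  bad <- body[nc != ncol_expected]
  if (length(bad))
    stop(sprintf("VCF line %d: %d columns, expected %d",
                 bad[1L], nc[which(body == bad[1L])], ncol_expected))
  invisible(TRUE)
}

#' Write a VariantCallSet as a plain-text VCF
#'
#' Emits VCF v4.2 with GT:DP:GQ per sample; the round trip through
#' \code{\link{readVcfCalls}} preserves scaffold, position, alleles and all
#' three per-call fields.
#'
#' @param x a \code{VariantCallSet}.
#' @param path output file path.
#' @export
writeVcfCalls <- function(x, path) {
  gr <- variantRanges(x)
  mc <- mcols(gr)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[genotypes(x) + 1L],
                   nrow = length(gr))
  gt_str[is.na(gt_str)] <- "./."
  body_cells <- matrix(paste(gt_str, readDepth(x), genoQual(x), sep = ":"),
                       nrow = length(gr))
  fix <- cbind(as.character(seqnames(gr)), start(gr),
               paste0(as.character(seqnames(gr)), ":", start(gr)),
               as.character(mc$ref), as.character(mc$alt),
               ".", "PASS", ".", "GT:DP:GQ")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleIds(x)), collapse = "\t"),
    do.call(paste, c(lapply(seq_len(ncol(fix)), function(j) fix[, j]),
                     lapply(seq_len(ncol(body_cells)),
                            function(j) body_cells[, j]),
                     sep = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects gene / mRNA / exon / CDS features.  One transcript per gene is
#' assumed; when a gene has several, the transcript with the longest total
#' CDS is kept.  CDS or exon features whose parentage cannot be traced to a
#' gene are skipped with a warning.  Genes whose exon rows are absent reuse
#' their CDS intervals as exons.
#'
#' @param path path to a GFF3 file.
#' @return a \code{\linkS4class{GeneModelSet}} (coordinates 1-based closed).
#' @export
readGff3Genes <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  if (!length(g))
    return(GeneModelSet(GRanges(), GRanges(), GRanges()))
  type <- as.character(g$type)
  genes <- g[type == "gene"]
  tx <- g[type %in% c("mRNA", "transcript")]
  tx_parent <- vapply(tx$Parent, function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  tx2gene <- stats::setNames(tx_parent, tx$ID)

  .parentTx <- function(feat) vapply(feat$Parent, function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  cds <- g[type == "CDS"]
  exons <- g[type == "exon"]
  cds_tx <- .parentTx(cds); exon_tx <- .parentTx(exons)
  cds_gene <- tx2gene[cds_tx]
  # features may hang directly off a gene
  direct <- is.na(cds_gene) & cds_tx %in% genes$ID
  cds_gene[direct] <- cds_tx[direct]
  orphan <- is.na(cds_gene)
  if (any(orphan)) {
    warning(sum(orphan), " CDS feature(s) without a parent gene skipped")
    cds <- cds[!orphan]; cds_gene <- cds_gene[!orphan]; cds_tx <- cds_tx[!orphan]
  }
  exon_gene <- tx2gene[exon_tx]
  direct <- is.na(exon_gene) & exon_tx %in% genes$ID
  exon_gene[direct] <- exon_tx[direct]
  keep <- !is.na(exon_gene)
  exons <- exons[keep]; exon_gene <- exon_gene[keep]; exon_tx <- exon_tx[keep]

  # one transcript per gene: keep the longest-CDS transcript
  keep_tx <- character(0)
  if (length(cds)) {
    cds_len <- tapply(GenomicRanges::width(cds), cds_tx, sum)
    tx_gene <- tx2gene[names(cds_len)]
    tx_gene[is.na(tx_gene)] <- names(cds_len)[is.na(tx_gene)]
    ord <- order(tx_gene, -as.numeric(cds_len))
    keep_tx <- names(cds_len)[ord][!duplicated(tx_gene[ord])]
    sel <- cds_tx %in% keep_tx
    cds <- cds[sel]; cds_gene <- cds_gene[sel]
  }
  if (length(exons) && length(keep_tx)) {
    sel <- exon_tx %in% keep_tx | exon_tx %in% genes$ID
    exons <- exons[sel]; exon_gene <- exon_gene[sel]
  }

  mk <- function(x, gid, phase = NULL) {
    out <- GRanges(seqnames(x), IRanges(start(x), end(x)),
                   strand = strand(x))
    mcols(out)$gene_id <- unname(gid)
    if (!is.null(phase)) mcols(out)$phase <- phase
    out[order(mcols(out)$gene_id, start(out))]
  }
  gene_gr <- GRanges(seqnames(genes), IRanges(start(genes), end(genes)),
                     strand = strand(genes))
  mcols(gene_gr)$gene_id <- genes$ID
  ph <- if (length(cds)) {
    p <- as.integer(as.character(cds$phase))
    p[is.na(p)] <- 0L
    p
  } else integer(0)
  cds_gr <- mk(cds, cds_gene, ph)
  exon_gr <- if (length(exons)) mk(exons, exon_gene) else cds_gr
  GeneModelSet(gene_gr, exon_gr, cds_gr)
}

#' Write gene models as GFF3
#'
#' @param models a \code{GeneModelSet}.
#' @param path output file path.
#' @export
writeGff3Genes <- function(models, path) {
  genes <- models@genes
  lines <- "##gff-version 3"
  row <- function(chr, src, type, s, e, str, phase, attr)
    paste(chr, src, type, s, e, ".", str, phase, attr, sep = "\t")
  for (i in seq_along(genes)) {
    gid <- mcols(genes)$gene_id[i]
    chr <- as.character(seqnames(genes))[i]
    str <- as.character(strand(genes))[i]
    mid <- paste0(gid, ".t1")
    lines <- c(lines,
      row(chr, "snparraykit", "gene", start(genes)[i], end(genes)[i], str,
          ".", paste0("ID=", gid)),
      row(chr, "snparraykit", "mRNA", start(genes)[i], end(genes)[i], str,
          ".", paste0("ID=", mid, ";Parent=", gid)))
    ex <- models@exons[mcols(models@exons)$gene_id == gid]
    for (j in seq_along(ex))
      lines <- c(lines, row(chr, "snparraykit", "exon", start(ex)[j],
                            end(ex)[j], str, ".", paste0("Parent=", mid)))
    cd <- models@cds[mcols(models@cds)$gene_id == gid]
    for (j in seq_along(cd))
      lines <- c(lines, row(chr, "snparraykit", "CDS", start(cd)[j],
                            end(cd)[j], str, mcols(cd)$phase[j],
                            paste0("Parent=", mid)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an array call matrix
#'
#' Tab-separated, markers as rows: first column the marker id, header row the
#' sample ids, cells in AA / AB / BB / NoCall.  An optional comment line
#' \code{#DQC} immediately after the header carries per-sample DQC values.
#'
#' @param path input file path.
#' @return a \code{\linkS4class{CallMatrix}}.
#' @export
readCallMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty call-matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-1L]
  dqc <- numeric()
  body <- fields[-1L]
  if (length(body) && body[[1L]][1L] == "#DQC") {
    dqc <- as.numeric(body[[1L]][-1L])
    body <- body[-1L]
  }
  if (!length(body)) {
    m <- matrix(character(), 0L, length(samples),
                dimnames = list(character(), samples))
    return(CallMatrix(m, dqc))
  }
  nc <- lengths(body)
  if (any(nc != length(header)))
    stop(sprintf("call-matrix row %d: %d fields, expected %d",
                 which(nc != length(header))[1L] + 1L,
                 nc[nc != length(header)][1L], length(header)))
  m <- do.call(rbind, body)
  markers <- m[, 1L]
  m <- m[, -1L, drop = FALSE]
  dimnames(m) <- list(markers, samples)
  bad <- which(!(m %in% CALL_TOKENS))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    stop(sprintf("call-matrix cell (%s, %s): unknown token '%s'",
                 markers[i], samples[j], m[bad[1L]]))
  }
  CallMatrix(m, dqc)
}

#' Write an array call matrix
#'
#' @param x a \code{CallMatrix}.
#' @param path output file path.
#' @export
writeCallMatrix <- function(x, path) {
  m <- calls(x)
  lines <- paste(c("probeset_id", colnames(m)), collapse = "\t")
  if (length(dishQC(x)))
    lines <- c(lines, paste(c("#DQC", format(dishQC(x), trim = TRUE)),
                            collapse = "\t"))
  if (nrow(m))
    lines <- c(lines, paste(rownames(m),
                            apply(m, 1L, paste, collapse = "\t"),
                            sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write an array design table
#'
#' Tab-separated: marker id, scaffold, position, alleles, effect class,
#' priority, MAF, must-include flag, p-convert and probe template.  Writing
#' is refused when marker ids are duplicated.
#'
#' @param design an \code{\linkS4class{ArrayDesign}}.
#' @param path output file path.
#' @export
writeDesign <- function(design, path) {
  m <- designMarkers(design)
  if (anyDuplicated(m$marker_id))
    stop("duplicate marker ids; design not written")
  probes <- probeTemplates(design)
  m$probe <- if (length(probes)) unname(probes[m$marker_id]) else
    rep(NA_character_, nrow(m))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read an array design table written by \code{\link{writeDesign}}
#'
#' @param path input file path.
#' @return an \code{\linkS4class{ArrayDesign}}.
#' @export
readDesign <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                         colClasses = c(marker_id = "character",
                                        scaffold = "character",
                                        ref = "character", alt = "character",
                                        effect = "character",
                                        pos = "integer", priority = "integer",
                                        maf = "numeric",
                                        p_convert = "numeric",
                                        must_include = "logical",
                                        probe = "character"),
                         stringsAsFactors = FALSE)
  probes <- character()
  if ("probe" %in% names(d)) {
    if (nrow(d) && !all(is.na(d$probe)))
      probes <- stats::setNames(d$probe, d$marker_id)
    d$probe <- NULL
  }
  if (!nrow(d))
    d <- d[, DESIGN_COLS, drop = FALSE]
  d$must_include <- as.logical(d$must_include)
  ArrayDesign(d[, DESIGN_COLS], probes)
}
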