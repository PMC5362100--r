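#' Priority level of an effect class
#'
#' Non-synonymous coding and splice-site-disrupting classes get priority 4,
#' synonymous coding 3, gene-body and near-gene classes (intron,
#' splice_region, 2-kb upstream/downstream) 2, and intergenic 1.
#'
#' @param effect character vector of effect classes.
#' @return integer priorities in 1..4.
#' @export
priorityLevel <- function(effect) {
  map <- c(
    missense = 4L, stop_gained = 4L, start_lost = 4L, stop_lost = 4L,
    initiator_codon = 4L, splice_donor = 4L, splice_acceptor = 4L,
    synonymous = 3L, stop_retained = 3L,
    intron = 2L, splice_region = 2L, upstream2k = 2L, downstream2k = 2L,
    intergenic = 1L
  )
  bad <- setdiff(unique(effect), names(map))
  if (length(bad)) stop("unknown effect class: ", paste(bad, collapse = ", "))
  unname(map[effect])
}

#' Is an effect class "large-effect"?
#'
#' Large-effect SNPs are those predicted to cause stop or start codon loss,
#' introduce a new stop codon, or disrupt a splice donor or acceptor site.
#'
#' @param effect character vector of effect classes.
#' @return logical vector.
#' @export
isLargeEffect <- function(effect) {
  effect %in% c("stop_gained", "start_lost", "stop_lost",
                "splice_donor", "splice_acceptor")
}

# Per-gene preprocessed structures used by the classifier.
.geneIndex <- function(models, genome) {
  cds <- models@cds
  genes <- models@genes
  gids <- mcols(genes)$gene_id
  strands <- stats::setNames(as.character(strand(genes)), gids)
  idx <- list(genes = genes, strands = strands)
  if (length(cds)) {
    ord <- order(mcols(cds)$gene_id, start(cds))
    cds <- cds[ord]
    gid <- mcols(cds)$gene_id
    minus <- strands[gid] == "-"
    # transcription order: ascending for +, descending for -
    tx_ord <- order(gid, ifelse(minus, -1L, 1L) * start(cds))
    cds_tx <- cds[tx_ord]
    gid_tx <- mcols(cds_tx)$gene_id
    w <- GenomicRanges::width(cds_tx)
    offset <- unlist(lapply(split(w, factor(gid_tx, unique(gid_tx))),
                            function(v) cumsum(c(0L, v[-length(v)]))),
                     use.names = FALSE)
    mcols(cds_tx)$offset <- offset
    first <- !duplicated(gid_tx)
    phase0 <- stats::setNames(mcols(cds_tx)$phase[first], gid_tx[first])
    # spliced, phase-trimmed CDS sequence per gene, transcription orientation
    seqs <- vapply(split(seq_along(cds_tx), factor(gid_tx, unique(gid_tx))),
                   function(ii) {
      g <- cds_tx[ii]
      chr <- as.character(seqnames(g))[1L]
      pieces <- substring(as.character(genome[[chr]]), start(g), end(g))
      if (strands[gid_tx[ii[1L]]] == "-")
        pieces <- chartr("ACGTacgt", "TGCAtgca",
                         vapply(pieces, function(s)
                           paste(rev(strsplit(s, "")[[1L]]), collapse = ""),
                           character(1)))
      s <- paste(pieces, collapse = "")
      substring(s, phase0[gid_tx[ii[1L]]] + 1L)
    }, character(1))
    idx$cds <- cds_tx
    idx$phase0 <- phase0
    idx$cds_seq <- seqs
  } else {
    idx$cds <- GRanges(); idx$phase0 <- integer(); idx$cds_seq <- character()
  }
  # introns = gene span minus exons, per gene
  exons <- models@exons
  introns <- GRanges()
  if (length(exons)) {
    ex_by <- split(exons, mcols(exons)$gene_id)
    parts <- lapply(names(ex_by), function(gid) {
      ex <- IRanges::reduce(IRanges::ranges(ex_by[[gid]]))
      gi <- genes[gids == gid]
      if (!length(gi)) return(GRanges())
      gaps <- IRanges::setdiff(IRanges::ranges(gi), ex)
      if (!length(gaps)) return(GRanges())
      out <- GRanges(seqnames(gi)[1L], gaps, strand = strand(gi)[1L])
      mcols(out)$gene_id <- gid
      out
    })
    parts <- parts[vapply(parts, length, integer(1)) > 0L]
    if (length(parts)) introns <- do.call(c, parts)
  }
  idx$introns <- introns
  idx
}

#' Classify SNP functional effects against gene models
#'
#' Assigns each SNP exactly one effect class.  SNPs in coding sequence are
#' classified by strand-aware codon translation (synonymous, missense,
#' stop_gained, stop_lost, stop_retained; changes in the annotated start
#' codon give start_lost, or initiator_codon when the alternate codon still
#' encodes Met).  Intronic SNPs within 2 bp of the exon boundary are
#' splice_donor (5' side of the intron) or splice_acceptor (3' side), within
#' 3-8 bp splice_region, otherwise intron.  Exonic positions outside the CDS
#' (untranslated regions) are classed with the gene body as intron.  SNPs
#' within 2,000 bp of a gene span are upstream2k or downstream2k relative to
#' the gene's strand; everything else is intergenic.  When a SNP hits several
#' genes the highest-priority effect wins, ties going to the
#' lexicographically first gene id.
#'
#' @param scaffold,pos,ref,alt SNP coordinate and allele vectors.
#' @param models a \code{\linkS4class{GeneModelSet}}.
#' @param genome a \code{\link[Biostrings]{DNAStringSet}} of scaffolds.
#' @param flankBp near-gene flank width in bp (default 2000).
#' @return data.frame with columns \code{scaffold}, \code{pos}, \code{ref},
#'   \code{alt}, \code{gene_id} (\code{"."} for intergenic), \code{effect},
#'   \code{priority}, \code{large_effect}.
#' @export
annotateSnpEffects <- function(scaffold, pos, ref, alt, models, genome,
                               flankBp = 2000L) {
  n <- length(pos)
  stopifnot(length(scaffold) == n, length(ref) == n, length(alt) == n)
  out_eff <- rep("intergenic", n)
  out_gene <- rep(".", n)
  if (n == 0L)
    return(data.frame(scaffold = character(), pos = integer(),
                      ref = character(), alt = character(),
                      gene_id = character(), effect = character(),
                      priority = integer(), large_effect = logical()))
  idx <- .geneIndex(models, genome)
  snp_gr <- GRanges(scaffold, IRanges(pos, pos))
  cand <- list()  # data.frames: snp, gene, effect

  # --- CDS hits ---
  if (length(idx$cds)) {
    h <- GenomicRanges::findOverlaps(snp_gr, idx$cds, ignore.strand = TRUE)
    if (length(h)) {
      qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
      gid <- mcols(idx$cds)$gene_id[si]
      str_minus <- idx$strands[gid] == "-"
      cds_pos <- mcols(idx$cds)$offset[si] +
        ifelse(str_minus, end(idx$cds)[si] - pos[qi],
               pos[qi] - start(idx$cds)[si]) + 1L
      p_adj <- cds_pos - idx$phase0[gid]
      seqs <- idx$cds_seq[gid]
      eff <- rep(NA_character_, length(qi))
      unresolvable <- p_adj < 1L | p_adj > nchar(seqs) - (nchar(seqs) %% 3L)
      if (any(unresolvable))
        warning(sum(unresolvable),
                " coding SNP(s) in a truncated model classified as intron")
      ok <- !unresolvable
      if (any(ok)) {
        codon_i <- (p_adj[ok] - 1L) %/% 3L + 1L
        in_codon <- (p_adj[ok] - 1L) %% 3L + 1L
        ref_codon <- toupper(substring(seqs[ok], (codon_i - 1L) * 3L + 1L,
                                       codon_i * 3L))
        alt_base <- ifelse(str_minus[ok],
                           chartr("ACGT", "TGCA", toupper(alt[qi[ok]])),
                           toupper(alt[qi[ok]]))
        alt_codon <- ref_codon
        substr(alt_codon, in_codon, in_codon) <- alt_base
        gc <- Biostrings::GENETIC_CODE
        ref_aa <- unname(gc[ref_codon]); alt_aa <- unname(gc[alt_codon])
        e <- ifelse(ref_aa == alt_aa,
                    ifelse(ref_aa == "*", "stop_retained", "synonymous"),
                    ifelse(ref_aa == "*", "stop_lost",
                           ifelse(alt_aa == "*", "stop_gained", "missense")))
        at_start <- codon_i == 1L & idx$phase0[gid][ok] == 0L
        e[at_start] <- ifelse(alt_aa[at_start] == "M",
                              "initiator_codon", "start_lost")
        eff[ok] <- e
      }
      eff[unresolvable] <- "intron"
      cand[[length(cand) + 1L]] <-
        data.frame(snp = qi, gene = gid, effect = eff)
    }
  }

  # --- intron hits (incl. splice classes) ---
  if (length(idx$introns)) {
    h <- GenomicRanges::findOverlaps(snp_gr, idx$introns, ignore.strand = TRUE)
    if (length(h)) {
      qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
      gid <- mcols(idx$introns)$gene_id[si]
      minus <- as.character(strand(idx$introns))[si] == "-"
      d_left <- pos[qi] - start(idx$introns)[si] + 1L
      d_right <- end(idx$introns)[si] - pos[qi] + 1L
      d_donor <- ifelse(minus, d_right, d_left)
      d_acc <- ifelse(minus, d_left, d_right)
      d_min <- pmin(d_donor, d_acc)
      eff <- ifelse(d_donor <= 2L, "splice_donor",
                    ifelse(d_acc <= 2L, "splice_acceptor",
                           ifelse(d_min <= 8L, "splice_region", "intron")))
      cand[[length(cand) + 1L]] <-
        data.frame(snp = qi, gene = gid, effect = eff)
    }
  }

  # --- gene body (UTR exon) fallback ---
  h <- GenomicRanges::findOverlaps(snp_gr, idx$genes, ignore.strand = TRUE)
  if (length(h)) {
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    cand[[length(cand) + 1L]] <-
      data.frame(snp = qi, gene = mcols(idx$genes)$gene_id[si],
                 effect = "intron")
  }

  # --- 2-kb flanks ---
  if (length(idx$genes)) {
    up <- GenomicRanges::flank(idx$genes, flankBp, start = TRUE,
                               ignore.strand = FALSE)
    dn <- GenomicRanges::flank(idx$genes, flankBp, start = FALSE,
                               ignore.strand = FALSE)
    GenomicRanges::start(up) <- pmax(1L, GenomicRanges::start(up))
    GenomicRanges::start(dn) <- pmax(1L, GenomicRanges::start(dn))
    for (side in c("upstream2k", "downstream2k")) {
      fl <- if (side == "upstream2k") up else dn
      h <- GenomicRanges::findOverlaps(snp_gr, fl, ignore.strand = TRUE)
      if (length(h))
        cand[[length(cand) + 1L]] <- data.frame(
          snp = S4Vectors::queryHits(h),
          gene = mcols(idx$genes)$gene_id[S4Vectors::subjectHits(h)],
          effect = side)
    }
  }

  if (length(cand)) {
    all_c <- do.call(rbind, cand)
    all_c$priority <- priorityLevel(all_c$effect)
    # gene-level precedence: within one gene, CDS beats intron beats flank;
    # the candidate rows arrive in that order, so keep the first row per
    # (snp, gene) at the highest priority, then the best gene per snp.
    all_c$rowid <- seq_len(nrow(all_c))
    o <- order(all_c$snp, all_c$gene, -all_c$priority, all_c$rowid)
    all_c <- all_c[o, ]
    all_c <- all_c[!duplicated(paste(all_c$snp, all_c$gene)), ]
    o <- order(all_c$snp, -all_c$priority, all_c$gene)
    all_c <- all_c[o, ]
    best <- all_c[!duplicated(all_c$snp), ]
    out_eff[best$snp] <- best$effect
    out_gene[best$snp] <- best$gene
  }

  data.frame(
    scaffold = as.character(scaffold), pos = as.integer(pos),
    ref = toupper(ref), alt = toupper(alt),
    gene_id = out_gene, effect = out_eff,
    priority = priorityLevel(out_eff),
    large_effect = isLargeEffect(out_eff),
    stringsAsFactors = FALSE
  )
}

#' Classify a single SNP
#'
#' Convenience wrapper around \code{\link{annotateSnpEffects}} for one locus.
#'
#' @inheritParams annotateSnpEffects
#' @return the effect class (character scalar).
#' @export
classifyEffect <- function(scaffold, pos, ref, alt, models, genome,
                           flankBp = 2000L) {
  annotateSnpEffects(scaffold, pos, ref, alt, models, genome, flankBp)$effect
}
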