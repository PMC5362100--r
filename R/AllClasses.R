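#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
NULL

GT_LEVELS   <- c(HOM_REF = 0L, HET = 1L, HOM_ALT = 2L)
CALL_TOKENS <- c("AA", "AB", "BB", "NoCall")

EFFECT_LEVELS <- c(
  "synonymous", "missense", "stop_gained", "start_lost", "stop_lost",
  "stop_retained", "initiator_codon", "splice_donor", "splice_acceptor",
  "splice_region", "intron", "upstream2k", "downstream2k", "intergenic"
)

SNP_CATEGORIES <- c(
  "PolyHighResolution", "NoMinorHom", "MonoHighResolution",
  "OTV", "CallRateBelowThreshold", "Other"
)

FAMILY_COMBOS <- c("AAxAA", "AAxAB", "AAxBB", "ABxAA", "ABxAB", "UNTYPED")

#' Population variant calls
#'
#' Holds variant sites (SNPs and indels) together with per-sample genotype,
#' read depth and genotype quality, mirroring the GT:DP:GQ triplet of a
#' population VCF.  Genotypes are coded 0 (homozygous reference),
#' 1 (heterozygous), 2 (homozygous alternate) and \code{NA} (missing).
#' Multiallelic records are split so that each row carries exactly one
#' alternate allele.
#'
#' @slot ranges \code{GRanges} of the variant anchor positions, with metadata
#'   columns \code{ref}, \code{alt} (single alleles, uppercase) and
#'   \code{vclass} (\code{"SNP"} or \code{"INDEL"}).
#' @slot gt integer matrix, sites x samples, coded as above.
#' @slot dp integer matrix of per-call read depth, same shape.
#' @slot gq integer matrix of per-call phred-scaled genotype quality.
#' @slot samples character vector of sample identifiers (column order).
#'
#' @export
setClass("VariantCallSet",
  representation(
    ranges  = "GRanges",
    gt      = "matrix",
    dp      = "matrix",
    gq      = "matrix",
    samples = "character"
  )
)

setValidity("VariantCallSet", function(object) {
  n <- length(object@ranges)
  k <- length(object@samples)
  msg <- character()
  for (nm in c("gt", "dp", "gq")) {
    m <- slot(object, nm)
    if (!identical(dim(m), c(n, k)))
      msg <- c(msg, sprintf("'%s' must be a %d x %d matrix", nm, n, k))
  }
  mc <- mcols(object@ranges)
  if (!all(c("ref", "alt", "vclass") %in% colnames(mc)))
    msg <- c(msg, "ranges must carry 'ref', 'alt' and 'vclass' columns")
  else {
    ref <- as.character(mc$ref); alt <- as.character(mc$alt)
    vcl <- as.character(mc$vclass)
    if (any(!nzchar(ref)) || any(!nzchar(alt)))
      msg <- c(msg, "alleles must be non-empty")
    if (!all(vcl %in% c("SNP", "INDEL")))
      msg <- c(msg, "vclass must be 'SNP' or 'INDEL'")
    is_snp_shape <- nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
    if (any(vcl == "SNP" & !is_snp_shape))
      msg <- c(msg, "vclass 'SNP' requires two distinct single-base alleles")
    if (any(vcl == "SNP" & !grepl("^[ACGT]$", ref)))
      msg <- c(msg, "SNP ref alleles must be uppercase A/C/G/T")
    if (any(vcl == "SNP" & !grepl("^[ACGT]$", alt)))
      msg <- c(msg, "SNP alt alleles must be uppercase A/C/G/T")
  }
  if (any(GenomicRanges::start(object@ranges) < 1L))
    msg <- c(msg, "positions must be >= 1")
  bad_gt <- object@gt[!is.na(object@gt)]
  if (length(bad_gt) && !all(bad_gt %in% 0:2))
    msg <- c(msg, "gt codes must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' Gene models
#'
#' A set of protein-coding gene models: one transcript per gene, with gene
#' spans, exons and phased CDS intervals in 1-based closed coordinates as in
#' GFF3.
#'
#' @slot genes \code{GRanges} of gene spans; strand set; metadata column
#'   \code{gene_id}.
#' @slot exons \code{GRanges} of exons with \code{gene_id}.
#' @slot cds \code{GRanges} of coding intervals with \code{gene_id} and
#'   \code{phase} (0/1/2).
#'
#' @export
setClass("GeneModelSet",
  representation(genes = "GRanges", exons = "GRanges", cds = "GRanges")
)

setValidity("GeneModelSet", function(object) {
  msg <- character()
  if (length(object@genes) && is.null(mcols(object@genes)$gene_id))
    msg <- c(msg, "genes must carry a gene_id column")
  if (length(object@cds)) {
    if (is.null(mcols(object@cds)$gene_id) || is.null(mcols(object@cds)$phase))
      return("cds must carry gene_id and phase columns")
    ph <- mcols(object@cds)$phase
    if (!all(ph %in% 0:2)) msg <- c(msg, "phase must be 0, 1 or 2")
    cds_by <- split(object@cds, mcols(object@cds)$gene_id)
    for (gid in names(cds_by)) {
      g <- cds_by[[gid]]
      o <- order(GenomicRanges::start(g))
      s <- GenomicRanges::start(g)[o]; e <- GenomicRanges::end(g)[o]
      if (length(s) > 1L && any(s[-1L] <= e[-length(e)]))
        msg <- c(msg, sprintf("gene %s: CDS intervals overlap", gid))
      first_phase <- if (as.character(GenomicRanges::strand(g))[1] == "-")
        mcols(g)$phase[o][length(o)] else mcols(g)$phase[o][1L]
      len <- sum(e - s + 1L) - first_phase
      if (len %% 3L != 0L)
        msg <- c(msg, sprintf(
          "gene %s: CDS length %d not divisible by 3 after phase", gid, len))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Array genotype call matrix
#'
#' Genotype calls from an array run: markers x samples over the vocabulary
#' AA / AB / BB / NoCall, where allele "A" always denotes the marker's design
#' reference allele.  Optionally carries per-sample dish QC (DQC) values.
#'
#' @slot calls character matrix, markers as rows, samples as columns.
#' @slot dqc numeric per-sample DQC in [0,1], or zero-length when absent.
#'
#' @export
setClass("CallMatrix",
  representation(calls = "matrix", dqc = "numeric")
)

setValidity("CallMatrix", function(object) {
  msg <- character()
  m <- object@calls
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "calls must have marker rownames and sample colnames")
  if (!all(m %in% CALL_TOKENS))
    msg <- c(msg, "calls must be one of AA, AB, BB, NoCall")
  if (length(object@dqc)) {
    if (length(object@dqc) != ncol(m))
      msg <- c(msg, "dqc length must equal the sample count")
    if (any(object@dqc < 0 | object@dqc > 1, na.rm = TRUE))
      msg <- c(msg, "dqc values must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' Array design
#'
#' The ordered list of markers selected for array manufacture, with their
#' effect annotation, priority level, minor allele frequency, must-include
#' status and optional externally supplied p-convert scores, plus the
#' flanking probe templates.
#'
#' @slot markers data.frame with columns \code{marker_id}, \code{scaffold},
#'   \code{pos}, \code{ref}, \code{alt}, \code{effect}, \code{priority},
#'   \code{maf}, \code{must_include}, \code{p_convert}; sorted by scaffold
#'   then position, unique on (scaffold, pos).
#' @slot probes named character vector of probe template sequences with the
#'   variant base written \code{[ref/alt]}; may be empty until
#'   \code{\link{probeSequences}} is run.
#'
#' @export
setClass("ArrayDesign",
  representation(markers = "data.frame", probes = "character")
)

DESIGN_COLS <- c("marker_id", "scaffold", "pos", "ref", "alt", "effect",
                 "priority", "maf", "must_include", "p_convert")

setValidity("ArrayDesign", function(object) {
  m <- object@markers
  msg <- character()
  if (!all(DESIGN_COLS %in% names(m)))
    return(paste("markers must have columns:", paste(DESIGN_COLS, collapse = ", ")))
  if (anyDuplicated(m$marker_id))
    msg <- c(msg, "duplicate marker ids")
  if (anyDuplicated(paste(m$scaffold, m$pos)))
    msg <- c(msg, "duplicate (scaffold, pos) markers")
  if (nrow(m) > 1L) {
    o <- order(m$scaffold, m$pos)
    if (!identical(o, seq_len(nrow(m))))
      msg <- c(msg, "markers must be sorted by scaffold then pos")
  }
  if (!all(m$priority %in% 1:4)) msg <- c(msg, "priority must be 1-4")
  if (length(object@probes) && !all(names(object@probes) %in% m$marker_id))
    msg <- c(msg, "probe names must be marker ids")
  if (length(msg)) msg else TRUE
})
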