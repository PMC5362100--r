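#' Construct a VariantCallSet
#'
#' @param scaffold character vector of scaffold ids.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt character allele vectors (one alternate allele per site).
#' @param gt integer matrix sites x samples coded 0/1/2/NA.
#' @param dp,gq integer matrices of read depth and genotype quality.
#' @param samples character sample ids.
#' @param vclass optional variant class; derived from allele lengths when
#'   \code{NULL} (two distinct single bases = SNP, otherwise INDEL).
#' @return a \code{\linkS4class{VariantCallSet}}.
#' @export
VariantCallSet <- function(scaffold, pos, ref, alt, gt, dp, gq, samples,
                           vclass = NULL) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (is.null(vclass))
    vclass <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L & ref != alt,
                     "SNP", "INDEL")
  gr <- GRanges(scaffold, IRanges(start = as.integer(pos),
                                  width = nchar(ref)))
  mcols(gr) <- DataFrame(ref = ref, alt = alt, vclass = vclass)
  gt <- matrix(as.integer(gt), nrow = length(gr))
  dp <- matrix(as.integer(dp), nrow = length(gr))
  gq <- matrix(as.integer(gq), nrow = length(gr))
  colnames(gt) <- colnames(dp) <- colnames(gq) <- samples
  new("VariantCallSet", ranges = gr, gt = gt, dp = dp, gq = gq,
      samples = as.character(samples))
}

#' Construct a CallMatrix
#'
#' @param calls character matrix of AA/AB/BB/NoCall, markers as rows and
#'   samples as columns (dimnames required).
#' @param dqc optional numeric per-sample DQC values in [0,1].
#' @return a \code{\linkS4class{CallMatrix}}.
#' @export
CallMatrix <- function(calls, dqc = numeric()) {
  new("CallMatrix", calls = calls, dqc = as.numeric(dqc))
}

#' Construct a GeneModelSet
#'
#' @param genes,exons,cds \code{GRanges} as documented for
#'   \code{\linkS4class{GeneModelSet}}.
#' @return a \code{\linkS4class{GeneModelSet}}.
#' @export
GeneModelSet <- function(genes, exons, cds) {
  new("GeneModelSet", genes = genes, exons = exons, cds = cds)
}

#' Construct an ArrayDesign from a marker table
#'
#' Markers are sorted by scaffold then position and deduplicated on
#' (scaffold, pos) before validation.
#'
#' @param markers data.frame with the design columns (see
#'   \code{\linkS4class{ArrayDesign}}).
#' @param probes optional named character vector of probe templates.
#' @return an \code{\linkS4class{ArrayDesign}}.
#' @export
ArrayDesign <- function(markers, probes = character()) {
  markers <- markers[!duplicated(paste(markers$scaffold, markers$pos)), ,
                     drop = FALSE]
  markers <- markers[order(markers$scaffold, markers$pos), , drop = FALSE]
  rownames(markers) <- NULL
  new("ArrayDesign", markers = markers, probes = probes)
}

# ---- generics ----

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("readDepth", function(x) standardGeneric("readDepth"))
#' @rdname accessors
#' @export
setGeneric("genoQual", function(x) standardGeneric("genoQual"))
#' @rdname accessors
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))
#' @rdname accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))
#' @rdname accessors
#' @export
setGeneric("dishQC", function(x) standardGeneric("dishQC"))
#' @rdname accessors
#' @export
setGeneric("designMarkers", function(x) standardGeneric("designMarkers"))
#' @rdname accessors
#' @export
setGeneric("probeTemplates", function(x) standardGeneric("probeTemplates"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Accessors for SNPArrayKit classes
#'
#' \code{sampleIds} and \code{markerIds} return identifier vectors;
#' \code{genotypes}, \code{readDepth} and \code{genoQual} the per-call
#' matrices of a \code{VariantCallSet}; \code{variantRanges} its site
#' \code{GRanges}; \code{calls} and \code{dishQC} the call grid and DQC of a
#' \code{CallMatrix}; \code{designMarkers} and \code{probeTemplates} the
#' marker table and probes of an \code{ArrayDesign}; \code{geneIds} the gene
#' identifiers of a \code{GeneModelSet}.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
setMethod("sampleIds", "VariantCallSet", function(x) x@samples)
#' @rdname accessors
setMethod("sampleIds", "CallMatrix", function(x) colnames(x@calls))
#' @rdname accessors
setMethod("markerIds", "CallMatrix", function(x) rownames(x@calls))
#' @rdname accessors
setMethod("markerIds", "ArrayDesign", function(x) x@markers$marker_id)
#' @rdname accessors
setMethod("genotypes", "VariantCallSet", function(x) x@gt)
#' @rdname accessors
setMethod("readDepth", "VariantCallSet", function(x) x@dp)
#' @rdname accessors
setMethod("genoQual", "VariantCallSet", function(x) x@gq)
#' @rdname accessors
setMethod("variantRanges", "VariantCallSet", function(x) x@ranges)
#' @rdname accessors
setMethod("calls", "CallMatrix", function(x) x@calls)
#' @rdname accessors
setMethod("dishQC", "CallMatrix", function(x) x@dqc)
#' @rdname accessors
setMethod("designMarkers", "ArrayDesign", function(x) x@markers)
#' @rdname accessors
setMethod("probeTemplates", "ArrayDesign", function(x) x@probes)
#' @rdname accessors
setMethod("geneIds", "GeneModelSet", function(x) mcols(x@genes)$gene_id)

#' @rdname accessors
setMethod("length", "VariantCallSet", function(x) length(x@ranges))

#' Subset a VariantCallSet by site
#'
#' @param x a \code{VariantCallSet}.
#' @param i site index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "VariantCallSet", function(x, i, j, ..., drop = FALSE) {
  new("VariantCallSet",
      ranges = x@ranges[i],
      gt = x@gt[i, , drop = FALSE],
      dp = x@dp[i, , drop = FALSE],
      gq = x@gq[i, , drop = FALSE],
      samples = x@samples)
})

setMethod("show", "VariantCallSet", function(object) {
  vcl <- table(mcols(object@ranges)$vclass)
  cat(sprintf("VariantCallSet: %d sites (%s) x %d samples\n",
              length(object@ranges),
              paste(sprintf("%d %s", as.integer(vcl), names(vcl)),
                    collapse = ", "),
              length(object@samples)))
})

setMethod("show", "CallMatrix", function(object) {
  cat(sprintf("CallMatrix: %d markers x %d samples%s\n",
              nrow(object@calls), ncol(object@calls),
              if (length(object@dqc)) " (with DQC)" else ""))
})

setMethod("show", "GeneModelSet", function(object) {
  cat(sprintf("GeneModelSet: %d genes, %d exons, %d CDS intervals\n",
              length(object@genes), length(object@exons), length(object@cds)))
})

setMethod("show", "ArrayDesign", function(object) {
  cat(sprintf("ArrayDesign: %d markers on %d scaffolds (%d must-include, %d probes)\n",
              nrow(object@markers),
              length(unique(object@markers$scaffold)),
              sum(object@markers$must_include),
              length(object@probes)))
})

#' Round half away from zero
#'
#' Rounding used for the printed-table percentages: ties go up (0.05 -> 0.1)
#' rather than to even as in \code{\link[base]{round}}.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
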