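#' Candidate table from filtered, annotated variants
#'
#' Runs the site filters, annotates the passing SNPs against the gene
#' models, and returns the candidate table consumed by
#' \code{\link{assembleDesign}}.  Marker ids are synthesized as
#' \code{scaffold:pos}.
#'
#' @param x a \code{\linkS4class{VariantCallSet}}.
#' @param models a \code{\linkS4class{GeneModelSet}}.
#' @param genome a \code{\link[Biostrings]{DNAStringSet}}.
#' @param mafMin,missingMax,indelRadius,dpMin,dpMax,gqMin filter thresholds
#'   (see \code{\link{applySiteFilters}}).
#' @param pConvert optional named numeric vector of externally supplied
#'   p-convert values keyed by marker id (carried, never computed).
#' @return list with \code{candidates} (data.frame) and \code{filter_stats}.
#' @export
buildCandidates <- function(x, models, genome, mafMin = 0.05,
                            missingMax = 0.1, indelRadius = 20L,
                            dpMin = 10L, dpMax = 100L, gqMin = 20L,
                            pConvert = NULL) {
  flt <- applySiteFilters(x, mafMin, missingMax, indelRadius,
                          dpMin, dpMax, gqMin)
  snps <- flt$variants
  gr <- variantRanges(snps)
  st <- flt$stats[flt$stats$passed, , drop = FALSE]
  ann <- annotateSnpEffects(as.character(seqnames(gr)), start(gr),
                            as.character(mcols(gr)$ref),
                            as.character(mcols(gr)$alt), models, genome)
  cand <- data.frame(
    marker_id = paste0(ann$scaffold, ":", ann$pos),
    scaffold = ann$scaffold, pos = ann$pos, ref = ann$ref, alt = ann$alt,
    effect = ann$effect, priority = ann$priority, maf = st$maf,
    stringsAsFactors = FALSE)
  cand$p_convert <- if (!is.null(pConvert))
    unname(pConvert[cand$marker_id]) else NA_real_
  list(candidates = cand, filter_stats = flt$stats)
}

#' Design an array from a population variant set
#'
#' End-to-end convenience: filter, annotate, select (primary 3-kb scan plus
#' 1-kb fill-in, must-include and large-effect seeding, capacity trim) and
#' attach probe templates.
#'
#' @inheritParams buildCandidates
#' @param config a \code{\link{selectionConfig}}.
#' @param mustIncludeIds marker ids (scaffold:pos) that must be on the array.
#' @return an \code{\linkS4class{ArrayDesign}} with probes attached.
#' @export
designFromPopulation <- function(x, models, genome,
                                 config = selectionConfig(),
                                 mustIncludeIds = character(),
                                 mafMin = 0.05, missingMax = 0.1,
                                 indelRadius = 20L, dpMin = 10L,
                                 dpMax = 100L, gqMin = 20L,
                                 pConvert = NULL) {
  bc <- buildCandidates(x, models, genome, mafMin, missingMax, indelRadius,
                        dpMin, dpMax, gqMin, pConvert)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  design <- assembleDesign(bc$candidates, lens, mustIncludeIds, config)
  probeSequences(design, genome, config$probeFlankBp)
}

#' True genotypes of a sample subset at the design markers
#'
#' Utility for simulation studies: extracts the 0/1/2 genotype matrix of a
#' variant set at the markers of a design, rows named by marker id.
#'
#' @param x a \code{\linkS4class{VariantCallSet}}.
#' @param design an \code{\linkS4class{ArrayDesign}}.
#' @param samples sample ids (default: all).
#' @return integer matrix markers x samples.
#' @export
designGenotypes <- function(x, design, samples = sampleIds(x)) {
  gr <- variantRanges(x)
  key <- paste0(as.character(seqnames(gr)), ":", start(gr))
  m <- designMarkers(design)
  idx <- match(m$marker_id, key)
  if (anyNA(idx))
    stop("design markers absent from the variant set: ",
         paste(utils::head(m$marker_id[is.na(idx)]), collapse = ", "))
  gt <- genotypes(x)[idx, match(samples, sampleIds(x)), drop = FALSE]
  dimnames(gt) <- list(m$marker_id, samples)
  gt
}
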