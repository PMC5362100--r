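#' Per-call validity under depth and quality thresholds
#'
#' A genotype call is invalidated (treated as missing) when its read depth is
#' below \code{dpMin} or above \code{dpMax}, or its genotype quality is below
#' \code{gqMin}; the removal inequalities are strict, so boundary values
#' (DP = 10, DP = 100, GQ = 20 at the defaults) remain valid.  Any one
#' failing condition invalidates the call.
#'
#' @param dp read depth (vector ok).
#' @param gq phred-scaled genotype quality (vector ok).
#' @param dpMin,dpMax,gqMin thresholds; defaults DP in [10, 100], GQ >= 20.
#' @return logical: \code{TRUE} when the call is valid.
#' @export
callIsValid <- function(dp, gq, dpMin = 10L, dpMax = 100L, gqMin = 20L) {
  stopifnot(dpMin > 0L, gqMin > 0L, dpMin < dpMax)
  !(dp < dpMin | dp > dpMax | gq < gqMin)
}

#' Per-site missing rate and minor allele frequency
#'
#' The missing rate is the proportion of individuals whose genotype is absent
#' or invalidated by \code{\link{callIsValid}}.  The minor allele frequency
#' is computed over valid calls only: a heterozygote contributes one
#' alternate allele, a homozygous-alternate call two, with denominator twice
#' the number of valid calls.
#'
#' @param x a \code{\linkS4class{VariantCallSet}}.
#' @param dpMin,dpMax,gqMin thresholds passed to \code{\link{callIsValid}}.
#' @return data.frame with one row per site: \code{scaffold}, \code{pos},
#'   \code{n_valid}, \code{missing_rate}, \code{maf} (\code{NA} when no call
#'   is valid).
#' @export
siteStats <- function(x, dpMin = 10L, dpMax = 100L, gqMin = 20L) {
  gt <- genotypes(x)
  valid <- !is.na(gt) &
    callIsValid(readDepth(x), genoQual(x), dpMin, dpMax, gqMin)
  n <- ncol(gt)
  n_valid <- rowSums(valid)
  alt_count <- rowSums(gt * valid, na.rm = TRUE)
  p <- alt_count / (2 * n_valid)
  maf <- pmin(p, 1 - p)
  maf[n_valid == 0L] <- NA_real_
  gr <- variantRanges(x)
  data.frame(
    scaffold = as.character(seqnames(gr)),
    pos = start(gr),
    n_valid = n_valid,
    missing_rate = (n - n_valid) / n,
    maf = maf,
    stringsAsFactors = FALSE
  )
}

#' Flag SNPs close to a predicted indel
#'
#' A SNP is flagged when some indel on the same scaffold has an anchor
#' position within \code{radiusBp} of the SNP position (inclusive).
#'
#' @param snpScaffold,snpPos SNP coordinates.
#' @param indelScaffold,indelPos indel anchor coordinates.
#' @param radiusBp flag radius in bp (default 20).
#' @return logical vector along the SNPs.
#' @export
flagNearIndel <- function(snpScaffold, snpPos, indelScaffold, indelPos,
                          radiusBp = 20L) {
  if (!length(snpPos)) return(logical(0))
  if (!length(indelPos)) return(rep(FALSE, length(snpPos)))
  lev <- union(unique(snpScaffold), unique(indelScaffold))
  snp_gr <- GRanges(factor(snpScaffold, lev), IRanges(snpPos, snpPos))
  ind_gr <- GRanges(factor(indelScaffold, lev),
                    IRanges(indelPos - radiusBp, indelPos + radiusBp))
  IRanges::overlapsAny(snp_gr, ind_gr)
}

#' Apply the candidate-SNP site filters
#'
#' Splits a variant set into SNPs and indels, invalidates calls by depth and
#' quality, and keeps SNP sites with minor allele frequency at least
#' \code{mafMin}, missing rate at most \code{missingMax}, and no indel within
#' \code{indelRadius} bp.  Boundary values pass: sites are removed only for
#' MAF strictly below or missing rate strictly above the thresholds.
#'
#' @param x a \code{\linkS4class{VariantCallSet}} for one cohort.
#' @param mafMin minimum minor allele frequency (default 0.05).
#' @param missingMax maximum missing rate (default 0.1).
#' @param indelRadius indel-proximity radius in bp (default 20).
#' @param dpMin,dpMax,gqMin per-call validity thresholds.
#' @return list with \code{variants} (the passing SNPs, input order
#'   preserved) and \code{stats}, the per-SNP filter report (columns
#'   \code{scaffold}, \code{pos}, \code{missing_rate}, \code{maf},
#'   \code{near_indel}, \code{passed}).
#' @export
applySiteFilters <- function(x, mafMin = 0.05, missingMax = 0.1,
                             indelRadius = 20L,
                             dpMin = 10L, dpMax = 100L, gqMin = 20L) {
  gr <- variantRanges(x)
  is_snp <- mcols(gr)$vclass == "SNP"
  snps <- x[which(is_snp)]
  indel_gr <- gr[!is_snp]
  st <- siteStats(snps, dpMin, dpMax, gqMin)
  st$near_indel <- flagNearIndel(st$scaffold, st$pos,
                                 as.character(seqnames(indel_gr)),
                                 start(indel_gr), indelRadius)
  st$passed <- !is.na(st$maf) & st$maf >= mafMin &
    st$missing_rate <= missingMax & !st$near_indel
  st$maf[is.na(st$maf)] <- NA_real_
  list(variants = snps[which(st$passed)],
       stats = st[, c("scaffold", "pos", "missing_rate", "maf",
                      "near_indel", "passed")])
}
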