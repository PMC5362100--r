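#' Per-sample QC gating
#'
#' A sample passes when its call rate (fraction of non-NoCall markers) is at
#' least \code{crThreshold} and, when DQC values are present, its DQC is at
#' least \code{dqcThreshold}.
#'
#' @param x a \code{\linkS4class{CallMatrix}}.
#' @param crThreshold call-rate cutoff (default 0.970, the platform default).
#' @param dqcThreshold dish-QC cutoff (default 0.82, the platform default).
#' @return data.frame: \code{sample_id}, \code{call_rate}, \code{dqc}
#'   (\code{NA} when absent), \code{passed}.
#' @export
sampleQC <- function(x, crThreshold = 0.970, dqcThreshold = 0.82) {
  m <- calls(x)
  cr <- colSums(m != "NoCall") / nrow(m)
  dqc <- if (length(dishQC(x))) dishQC(x) else rep(NA_real_, ncol(m))
  data.frame(
    sample_id = colnames(m),
    call_rate = unname(cr),
    dqc = unname(dqc),
    passed = unname(cr >= crThreshold & (is.na(dqc) | dqc >= dqcThreshold)),
    stringsAsFactors = FALSE
  )
}

#' Classify one marker's call vector into a cluster category
#'
#' Call-based approximation of the intensity-clustering categories: a marker
#' with call rate below \code{crThreshold} is CallRateBelowThreshold; one
#' showing all three genotypes is PolyHighResolution; one homozygote class
#' plus heterozygotes is NoMinorHom; a single homozygote class only is
#' MonoHighResolution; anything else (e.g. two homozygote classes with no
#' heterozygote, or heterozygotes only) is Other.  OTV is intensity-based and
#' can only be assigned via externally supplied labels (see
#' \code{\link{classifySnps}}).
#'
#' @param callsVec character vector of calls for one marker over the passing
#'   samples.
#' @param crThreshold marker call-rate cutoff (default 0.970).
#' @return the category (character scalar).
#' @export
classifySnpCalls <- function(callsVec, crThreshold = 0.970) {
  if (!length(callsVec)) stop("empty call vector")
  m <- matrix(callsVec, nrow = 1L,
              dimnames = list("m", seq_along(callsVec)))
  classifySnps(CallMatrix(m), crThreshold)
}

#' Classify every marker of a call matrix
#'
#' Vectorized form of \code{\link{classifySnpCalls}}; externally supplied
#' category labels (e.g. OTV from intensity clustering) override the
#' call-based assignment for the named markers.
#'
#' @param x a \code{\linkS4class{CallMatrix}} restricted to passing samples.
#' @param crThreshold marker call-rate cutoff (default 0.970).
#' @param externalLabels optional named character vector of category labels
#'   keyed by marker id.
#' @return named character vector of categories along the markers.
#' @export
classifySnps <- function(x, crThreshold = 0.970, externalLabels = NULL) {
  m <- calls(x)
  if (!ncol(m)) stop("call matrix has no samples")
  n_aa <- rowSums(m == "AA")
  n_ab <- rowSums(m == "AB")
  n_bb <- rowSums(m == "BB")
  cr <- (n_aa + n_ab + n_bb) / ncol(m)
  n_hom_classes <- (n_aa > 0L) + (n_bb > 0L)
  cat <- rep("Other", nrow(m))
  cat[n_hom_classes == 1L & n_ab == 0L] <- "MonoHighResolution"
  cat[n_hom_classes == 1L & n_ab > 0L] <- "NoMinorHom"
  cat[n_aa > 0L & n_ab > 0L & n_bb > 0L] <- "PolyHighResolution"
  cat[cr < crThreshold] <- "CallRateBelowThreshold"
  names(cat) <- rownames(m)
  if (!is.null(externalLabels)) {
    bad <- setdiff(externalLabels, SNP_CATEGORIES)
    if (length(bad)) stop("unknown category label: ",
                          paste(bad, collapse = ", "))
    hit <- intersect(names(externalLabels), names(cat))
    cat[hit] <- externalLabels[hit]
  }
  cat
}

#' Conversion summary over cluster categories
#'
#' Converted markers are those validated as polymorphic:
#' PolyHighResolution plus NoMinorHom.  Percentages are of the design total,
#' rounded half-up to one decimal.
#'
#' @param categories character vector of per-marker categories, or a named
#'   integer vector of category counts.
#' @return list with \code{table} (category, count, percent in category
#'   order plus a Total row), \code{converted} (count) and
#'   \code{converted_pct}.
#' @export
conversionSummary <- function(categories) {
  counts <- if (is.numeric(categories)) {
    bad <- setdiff(names(categories), SNP_CATEGORIES)
    if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
    v <- stats::setNames(integer(length(SNP_CATEGORIES)), SNP_CATEGORIES)
    v[names(categories)] <- as.integer(categories)
    v
  } else {
    table(factor(categories, levels = SNP_CATEGORIES))
  }
  counts <- as.integer(counts)
  total <- sum(counts)
  pct <- roundHalfUp(100 * counts / total, 1)
  converted <- counts[1L] + counts[2L]
  list(
    table = data.frame(
      category = c(SNP_CATEGORIES, "Total"),
      count = c(counts, total),
      percent = c(pct, roundHalfUp(sum(100 * counts / total), 1)),
      stringsAsFactors = FALSE),
    converted = converted,
    converted_pct = roundHalfUp(100 * converted / total, 1)
  )
}

#' Allele-pair (SNP type) conversion summary
#'
#' Markers are keyed by their unordered allele pair printed alphabetically
#' (A/C, A/G, A/T, C/G, C/T, G/T), without strand collapsing.  The
#' conversion rate per type is converted / on-chip rounded half-up to two
#' decimals; transitions are the A/G plus C/T types.
#'
#' @param ref,alt allele vectors over the designed markers.
#' @param converted logical vector: is the marker converted?
#' @return list with \code{table} (type, on_chip, on_chip_pct, converted,
#'   converted_pct, conversion_rate plus a Total row) and
#'   \code{transitions} (converted transition count).
#' @export
snpTypeSummary <- function(ref, alt, converted) {
  stopifnot(length(ref) == length(alt), length(ref) == length(converted))
  type <- paste(pmin(ref, alt), pmax(ref, alt), sep = "/")
  lev <- sort(unique(type))
  on_chip <- as.integer(table(factor(type, lev)))
  conv <- as.integer(table(factor(type[converted], lev)))
  tab <- data.frame(
    type = lev, on_chip = on_chip,
    on_chip_pct = roundHalfUp(100 * on_chip / sum(on_chip), 1),
    converted = conv,
    converted_pct = roundHalfUp(100 * conv / sum(conv), 1),
    conversion_rate = roundHalfUp(conv / on_chip, 2),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$on_chip), ]
  rownames(tab) <- NULL
  total <- data.frame(type = "Total", on_chip = sum(on_chip),
                      on_chip_pct = 100, converted = sum(conv),
                      converted_pct = 100,
                      conversion_rate = roundHalfUp(sum(conv) / sum(on_chip), 2))
  list(table = rbind(tab, total),
       transitions = sum(conv[lev %in% c("A/G", "C/T")]))
}

#' Inter-marker spacing distribution
#'
#' Intervals are consecutive position differences between markers on the
#' same scaffold; a scaffold with k markers contributes k - 1 intervals, so
#' the percentage denominator is (number of markers) - (number of
#' scaffolds).
#'
#' @param scaffold,pos marker coordinates (any order; sorted internally).
#' @param binEdges interval bin edges in bp; the default bins are <200,
#'   200-500, 500-1000, 1000-2000, 2000-3000, 3000-4000, 4000-5000 and
#'   >=5000.
#' @return list with \code{intervals} (bp vector), \code{table} (bin, count,
#'   percent), \code{mean_spacing} (total span / intervals) and
#'   \code{n_intervals}.
#' @export
spacingDistribution <- function(scaffold, pos,
                                binEdges = c(200, 500, 1000, 2000, 3000,
                                             4000, 5000)) {
  o <- order(scaffold, pos)
  scaffold <- scaffold[o]; pos <- pos[o]
  same <- scaffold[-1L] == scaffold[-length(scaffold)]
  intervals <- diff(pos)[same]
  breaks <- c(-Inf, binEdges, Inf)
  labels <- c(paste0("<", binEdges[1L]),
              paste(binEdges[-length(binEdges)], binEdges[-1L], sep = "-"),
              paste0(">=", binEdges[length(binEdges)]))
  counts <- as.integer(table(cut(intervals, breaks, right = FALSE,
                                 labels = labels)))
  span <- tapply(pos, scaffold, function(p) max(p) - min(p))
  list(
    intervals = intervals,
    table = data.frame(bin = labels, count = counts,
                       percent = roundHalfUp(100 * counts /
                                             max(1L, length(intervals)), 1),
                       stringsAsFactors = FALSE),
    mean_spacing = sum(span) / max(1L, length(intervals)),
    n_intervals = length(intervals)
  )
}

#' Per-gene SNP count distribution
#'
#' Counts, per gene, the markers associated with that gene (any effect class
#' other than intergenic), binned as 1, 2-5, 6-10 and >10, with the mean
#' markers per hit gene rounded half-up to one decimal.
#'
#' @param geneId per-marker gene id (\code{"."} for intergenic markers).
#' @param effect optional per-marker effect class; when supplied, markers
#'   with effect \code{"intergenic"} are excluded (otherwise exclusion is by
#'   \code{geneId == "."}).
#' @return list with \code{table} (bin, count, percent over hit genes),
#'   \code{n_genes}, \code{n_markers_in_genes} and \code{mean_per_gene}.
#' @export
geneSnpDistribution <- function(geneId, effect = NULL) {
  keep <- if (is.null(effect)) geneId != "." else effect != "intergenic"
  g <- geneId[keep]
  per_gene <- table(g)
  bins <- cut(as.integer(per_gene), c(0, 1, 5, 10, Inf),
              labels = c("1", "2-5", "6-10", ">10"))
  counts <- as.integer(table(bins))
  n_genes <- length(per_gene)
  list(
    table = data.frame(bin = levels(bins), count = counts,
                       percent = roundHalfUp(100 * counts / max(1L, n_genes), 1),
                       stringsAsFactors = FALSE),
    n_genes = n_genes,
    n_markers_in_genes = length(g),
    mean_per_gene = roundHalfUp(length(g) / max(1L, n_genes), 1)
  )
}
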