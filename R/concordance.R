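#' Per-marker concordance between two call matrices
#'
#' Compares array calls against sequencing-derived genotypes (mapped onto
#' AA/AB/BB in the design's ref/alt orientation) for samples present on both
#' platforms.  Only samples non-missing on both platforms at a marker enter
#' that marker's comparison; markers with no comparable call get an undefined
#' (\code{NA}) rate.
#'
#' @param array,seq \code{\linkS4class{CallMatrix}} objects.
#' @param sharedSamples sample ids to compare; defaults to the intersection
#'   of the two matrices' samples.
#' @return data.frame: \code{marker_id}, \code{n_compared}, \code{n_match},
#'   \code{rate}.
#' @export
genotypeConcordance <- function(array, seq, sharedSamples = NULL) {
  a <- calls(array); s <- calls(seq)
  if (is.null(sharedSamples))
    sharedSamples <- intersect(colnames(a), colnames(s))
  if (!length(sharedSamples)) stop("no shared samples to compare")
  missing_s <- setdiff(sharedSamples, colnames(a))
  missing_s <- c(missing_s, setdiff(sharedSamples, colnames(s)))
  if (length(missing_s))
    stop("shared sample(s) absent from a matrix: ",
         paste(unique(missing_s), collapse = ", "))
  markers <- intersect(rownames(a), rownames(s))
  if (!length(markers)) stop("no shared markers to compare")
  a <- a[markers, sharedSamples, drop = FALSE]
  s <- s[markers, sharedSamples, drop = FALSE]
  both <- a != "NoCall" & s != "NoCall"
  n_compared <- rowSums(both)
  n_match <- rowSums(both & a == s)
  data.frame(
    marker_id = markers,
    n_compared = unname(n_compared),
    n_match = unname(n_match),
    rate = unname(ifelse(n_compared > 0L, n_match / n_compared, NA_real_)),
    stringsAsFactors = FALSE
  )
}

#' Summarize per-marker concordance
#'
#' Reports the mean rate over converted markers (undefined rates excluded),
#' the mean over all on-chip markers (markers with no record or an undefined
#' rate contribute 0, reflecting assays that never produced a comparable
#' call), a binned distribution of the defined rates, and the cumulative
#' share of converted markers at or above \code{threshold}.
#'
#' @param records output of \code{\link{genotypeConcordance}}.
#' @param convertedIds marker ids of converted markers.
#' @param onChipIds all designed marker ids; defaults to the record ids.
#' @param breaks bin breaks over [0, 1] for the distribution.
#' @param threshold high-concordance cutoff (default 0.971).
#' @return list with \code{mean_converted}, \code{mean_all},
#'   \code{share_above} (fraction of converted markers with rate >=
#'   threshold), and \code{table} (bin, count, percent of defined rates).
#' @export
concordanceSummary <- function(records, convertedIds,
                               onChipIds = records$marker_id,
                               breaks = c(0, 0.9, 0.95, 0.971, 1),
                               threshold = 0.971) {
  r <- stats::setNames(records$rate, records$marker_id)
  conv <- r[intersect(convertedIds, names(r))]
  conv_def <- conv[!is.na(conv)]
  all_r <- r[intersect(onChipIds, names(r))]
  all_r <- all_r[!is.na(all_r)]
  n_all <- length(onChipIds)
  def <- records$rate[!is.na(records$rate)]
  bins <- cut(def, breaks, include.lowest = TRUE)
  counts <- as.integer(table(bins))
  list(
    mean_converted = mean(conv_def),
    mean_all = sum(all_r) / n_all,
    share_above = sum(conv_def >= threshold) / length(conv_def),
    table = data.frame(bin = levels(bins), count = counts,
                       percent = roundHalfUp(100 * counts /
                                             max(1L, length(def)), 1),
                       stringsAsFactors = FALSE)
  )
}
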