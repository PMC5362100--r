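#' Classify the parental genotype combination of a marker
#'
#' Same-homozygote pairs fold into \code{AAxAA} (the accounting is symmetric
#' in the allele labels), while the hom x het orientation is preserved
#' (\code{AAxAB} vs \code{ABxAA}).  Any parent NoCall makes the marker
#' \code{UNTYPED} and it is excluded from the accounting.
#'
#' @param p1,p2 parent call vectors over markers (AA/AB/BB/NoCall).
#' @return character vector of combos (AAxAA, AAxAB, AAxBB, ABxAA, ABxAB,
#'   UNTYPED).
#' @export
classifyParentCombo <- function(p1, p2) {
  stopifnot(length(p1) == length(p2))
  hom1 <- p1 %in% c("AA", "BB"); hom2 <- p2 %in% c("AA", "BB")
  out <- rep("UNTYPED", length(p1))
  typed <- p1 != "NoCall" & p2 != "NoCall"
  out[typed & hom1 & hom2 & p1 == p2] <- "AAxAA"
  out[typed & hom1 & hom2 & p1 != p2] <- "AAxBB"
  out[typed & hom1 & p2 == "AB"] <- "AAxAB"
  out[typed & p1 == "AB" & hom2] <- "ABxAA"
  out[typed & p1 == "AB" & p2 == "AB"] <- "ABxAB"
  out
}

#' Mendelian-consistent offspring genotypes
#'
#' Given the two parental calls at a marker, the set of offspring genotypes
#' consistent with Mendelian transmission: same homozygotes give only that
#' homozygote, hom x het gives the parental homozygote and the heterozygote,
#' opposite homozygotes give only AB, and het x het gives all three (so no
#' error is detectable there).
#'
#' @param p1,p2 parental calls (scalars).
#' @return character vector of allowed genotypes.
#' @export
expectedOffspring <- function(p1, p2) {
  combo <- classifyParentCombo(p1, p2)
  if (combo == "UNTYPED") stop("combo is untyped (a parent is NoCall)")
  switch(combo,
    AAxAA = p1,
    AAxBB = "AB",
    AAxAB = c(p1, "AB"),
    ABxAA = c(p2, "AB"),
    ABxAB = c("AA", "AB", "BB"))
}

# markers x offspring logical matrix: is the call Mendelian-unexpected?
.unexpectedCalls <- function(p1, p2, off) {
  combo <- classifyParentCombo(p1, p2)
  allowed <- matrix(FALSE, length(p1), 3L,
                    dimnames = list(NULL, c("AA", "AB", "BB")))
  allowed[combo == "AAxAA", ] <-
    outer(p1[combo == "AAxAA"], c("AA", "AB", "BB"), "==")
  allowed[combo == "AAxBB", "AB"] <- TRUE
  hh <- combo == "AAxAB"
  allowed[hh, ] <- outer(p1[hh], c("AA", "AB", "BB"), "==")
  allowed[hh, "AB"] <- TRUE
  hh <- combo == "ABxAA"
  allowed[hh, ] <- outer(p2[hh], c("AA", "AB", "BB"), "==")
  allowed[hh, "AB"] <- TRUE
  allowed[combo == "ABxAB", ] <- TRUE
  idx <- match(off, c("AA", "AB", "BB"))  # NA for NoCall
  ok <- allowed[cbind(rep(seq_len(nrow(off)), ncol(off)), as.vector(idx))]
  unexp <- matrix(!is.na(as.vector(idx)) & !ok, nrow(off), ncol(off),
                  dimnames = dimnames(off))
  list(combo = combo, unexpected = unexp,
       called = matrix(!is.na(as.vector(idx)), nrow(off), ncol(off)))
}

#' Family-based genotyping error table
#'
#' Pools a full-sib family's offspring calls per parental genotype
#' combination.  For every combo it reports the marker count, the number of
#' markers with at least one Mendelian-unexpected offspring call and its
#' percentage, the offspring call rate, an optional concordance rate
#' (supplied per marker from an array-versus-sequencing comparison), and the
#' error call rate (unexpected calls / non-missing offspring calls).
#' Markers with any parent NoCall are excluded entirely; a totals row pools
#' all typed combos.
#'
#' @param p1,p2 parent call vectors along the markers of \code{offspring}.
#' @param offspring a \code{\linkS4class{CallMatrix}} of the offspring
#'   (markers x individuals) on the same markers, same order.
#' @param markerConcordance optional named numeric vector of per-marker
#'   concordance rates (names = marker ids).
#' @return data.frame with one row per observed combo plus \code{Total}:
#'   \code{combo}, \code{n_markers}, \code{n_error_markers},
#'   \code{error_marker_pct}, \code{call_rate}, \code{concordance_rate},
#'   \code{error_call_rate}.
#' @export
familyErrorTable <- function(p1, p2, offspring, markerConcordance = NULL) {
  off <- calls(offspring)
  if (length(p1) != nrow(off) || length(p2) != nrow(off))
    stop("parent call vectors must align with the offspring markers")
  u <- .unexpectedCalls(p1, p2, off)
  typed <- u$combo != "UNTYPED"
  combos <- c("AAxAA", "AAxAB", "AAxBB", "ABxAA", "ABxAB")
  conc <- if (!is.null(markerConcordance))
    unname(markerConcordance[rownames(off)]) else rep(NA_real_, nrow(off))
  row_stats <- function(sel) {
    n_mark <- sum(sel)
    n_err <- sum(rowSums(u$unexpected[sel, , drop = FALSE]) > 0L)
    n_called <- sum(u$called[sel, , drop = FALSE])
    n_unexp <- sum(u$unexpected[sel, , drop = FALSE])
    data.frame(
      n_markers = n_mark,
      n_error_markers = n_err,
      error_marker_pct = roundHalfUp(100 * n_err / max(1L, n_mark), 1),
      call_rate = n_called / max(1L, n_mark * ncol(off)),
      concordance_rate = mean(conc[sel], na.rm = TRUE),
      error_call_rate = n_unexp / max(1L, n_called))
  }
  rows <- do.call(rbind, lapply(combos, function(cb)
    cbind(combo = cb, row_stats(u$combo == cb))))
  rows <- rbind(rows, cbind(combo = "Total", row_stats(typed)))
  rows$concordance_rate[is.nan(rows$concordance_rate)] <- NA_real_
  rownames(rows) <- NULL
  rows
}

#' Per-offspring genotyping accuracy
#'
#' For each offspring, accuracy is 1 minus the fraction of its non-missing
#' calls (at markers typed in both parents) that are Mendelian-unexpected.
#'
#' @inheritParams familyErrorTable
#' @return list with \code{per_individual} (data.frame: \code{sample_id},
#'   \code{n_typed}, \code{n_unexpected}, \code{accuracy}) and
#'   \code{mean_accuracy}.
#' @export
perIndividualAccuracy <- function(p1, p2, offspring) {
  off <- calls(offspring)
  u <- .unexpectedCalls(p1, p2, off)
  typed <- u$combo != "UNTYPED"
  n_typed <- colSums(u$called[typed, , drop = FALSE])
  n_unexp <- colSums(u$unexpected[typed, , drop = FALSE])
  acc <- 1 - n_unexp / pmax(1L, n_typed)
  per <- data.frame(sample_id = colnames(off), n_typed = unname(n_typed),
                    n_unexpected = unname(n_unexp),
                    accuracy = unname(acc), stringsAsFactors = FALSE)
  list(per_individual = per, mean_accuracy = mean(acc))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric point probabilities,
#' over all tables with the observed margins, that do not exceed the
#' observed table's probability.
#'
#' @param tbl 2x2 matrix of non-negative counts (rows = groups, columns =
#'   outcome).
#' @return the two-sided probability.
#' @export
fisherExact2x2 <- function(tbl) {
  stopifnot(is.matrix(tbl), all(dim(tbl) == 2L), all(tbl >= 0))
  m <- sum(tbl[1L, ])          # group-1 margin
  n <- sum(tbl[2L, ])          # group-2 margin
  k <- sum(tbl[, 1L])          # first-outcome margin
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tbl[1L, 1L], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
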