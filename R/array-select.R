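#' Selection configuration
#'
#' Parameters of the two-pass window selection.  Defaults reflect a ~200 K
#' capacity over a ~560 Mb genome: a 3-kb primary window, 1-kb fill-in
#' window, and a ~2,800 bp target spacing.
#'
#' @param primaryWindowBp primary scan window width (bp).
#' @param fillinWindowBp fill-in window width (bp); must be smaller than the
#'   primary window.
#' @param targetSpacingBp target average marker spacing (bp) used to compute
#'   each scaffold's expected marker count.
#' @param capacity maximum number of markers on the array.
#' @param probeFlankBp probe template flank length (bp) either side of the
#'   variant base.
#' @param fillinOrder \code{"quality"} processes deficit windows by their
#'   best candidate's rank (priority, MAF, position); \code{"position"}
#'   processes them left to right.
#' @return a list of class \code{SelectionConfig}.
#' @export
selectionConfig <- function(primaryWindowBp = 3000L, fillinWindowBp = 1000L,
                            targetSpacingBp = 2800L, capacity = 200000L,
                            probeFlankBp = 35L,
                            fillinOrder = c("quality", "position")) {
  stopifnot(fillinWindowBp < primaryWindowBp, capacity >= 1L,
            targetSpacingBp >= 1L, probeFlankBp >= 1L)
  structure(list(primaryWindowBp = as.integer(primaryWindowBp),
                 fillinWindowBp = as.integer(fillinWindowBp),
                 targetSpacingBp = as.integer(targetSpacingBp),
                 capacity = as.integer(capacity),
                 probeFlankBp = as.integer(probeFlankBp),
                 fillinOrder = match.arg(fillinOrder)),
            class = "SelectionConfig")
}

#' Expected marker count for a scaffold
#'
#' @param scaffoldLengthBp scaffold length in bp (vector ok).
#' @param targetSpacingBp target average spacing (default 2800 bp).
#' @return \code{max(1, floor(length / spacing))} per scaffold.
#' @export
expectedSnpCount <- function(scaffoldLengthBp, targetSpacingBp = 2800L) {
  stopifnot(all(scaffoldLengthBp >= 1L))
  pmax(1L, as.integer(scaffoldLengthBp %/% targetSpacingBp))
}

# (priority desc, maf desc, pos asc) candidate ordering
.candOrder <- function(d) order(-d$priority, -d$maf, d$pos)

#' Primary window scan over one scaffold
#'
#' The scaffold is tiled by consecutive non-overlapping windows of
#' \code{windowBp} anchored at position 1; in each window holding at least
#' one candidate exactly one SNP is selected: highest priority level, ties
#' broken by highest MAF, then smallest position.
#'
#' @param candidates data.frame of candidates on one scaffold with at least
#'   \code{pos}, \code{priority}, \code{maf} columns, sorted by \code{pos}.
#' @param windowBp window width in bp (default 3000).
#' @return the selected candidate rows, ordered by position.
#' @export
primaryWindowScan <- function(candidates, windowBp = 3000L) {
  if (!nrow(candidates)) return(candidates)
  win <- (candidates$pos - 1L) %/% windowBp
  o <- order(win, -candidates$priority, -candidates$maf, candidates$pos)
  sel <- candidates[o, , drop = FALSE][!duplicated(win[o]), , drop = FALSE]
  sel[order(sel$pos), , drop = FALSE]
}

#' Fill-in scan for under-covered scaffolds
#'
#' Runs only when the scaffold holds fewer selected markers than expected.
#' The scaffold is re-tiled with \code{windowBp} windows; among windows
#' containing no already-selected marker, the best remaining candidate per
#' window (priority, then MAF, then position) is added, windows processed in
#' order of their best candidate's rank (or left to right when
#' \code{order = "position"}), until the deficit is covered or candidates run
#' out.
#'
#' @param candidates remaining (unselected) candidates on the scaffold.
#' @param selectedPos positions of markers already selected on the scaffold.
#' @param expected expected marker count from \code{\link{expectedSnpCount}}.
#' @param windowBp fill-in window width (default 1000 bp).
#' @param order window processing order, \code{"quality"} or
#'   \code{"position"}.
#' @return the added candidate rows, ordered by position.
#' @export
fillinScan <- function(candidates, selectedPos, expected, windowBp = 1000L,
                       order = c("quality", "position")) {
  order <- match.arg(order)
  deficit <- expected - length(selectedPos)
  if (deficit <= 0L || !nrow(candidates))
    return(candidates[0L, , drop = FALSE])
  occupied <- unique((selectedPos - 1L) %/% windowBp)
  win <- (candidates$pos - 1L) %/% windowBp
  free <- !(win %in% occupied)
  cand <- candidates[free, , drop = FALSE]
  win <- win[free]
  if (!nrow(cand)) return(candidates[0L, , drop = FALSE])
  o <- base::order(win, -cand$priority, -cand$maf, cand$pos)
  best <- cand[o, , drop = FALSE][!duplicated(win[o]), , drop = FALSE]
  rank <- if (order == "quality") .candOrder(best) else
    base::order(best$pos)
  add <- best[rank[seq_len(min(deficit, nrow(best)))], , drop = FALSE]
  add[base::order(add$pos), , drop = FALSE]
}

#' Assemble the final array design
#'
#' Must-include and large-effect candidates are seeded into the design first;
#' the primary 3-kb window scan and, for scaffolds left below their expected
#' marker count, the 1-kb fill-in pass then run per scaffold over the
#' remaining candidates.  If the total exceeds the array capacity,
#' non-must-include markers are dropped in ascending (priority, MAF) order.
#' The output is sorted by scaffold and position and unique on
#' (scaffold, pos).
#'
#' @param candidates data.frame of annotated candidates with columns
#'   \code{marker_id}, \code{scaffold}, \code{pos}, \code{ref}, \code{alt},
#'   \code{effect}, \code{priority}, \code{maf} and optionally
#'   \code{p_convert}.
#' @param scaffoldLengths named integer vector of scaffold lengths (bp);
#'   names must cover every scaffold in \code{candidates}.
#' @param mustIncludeIds marker ids that must be on the design (e.g. trait-
#'   associated SNPs); an unresolvable id is an error.
#' @param config a \code{\link{selectionConfig}}.
#' @return an \code{\linkS4class{ArrayDesign}} (probes not yet attached).
#' @export
assembleDesign <- function(candidates, scaffoldLengths,
                           mustIncludeIds = character(),
                           config = selectionConfig()) {
  stopifnot(inherits(config, "SelectionConfig"))
  d <- candidates
  if (is.null(d$p_convert)) d$p_convert <- NA_real_
  d <- d[!duplicated(paste(d$scaffold, d$pos)), , drop = FALSE]
  missing_ids <- setdiff(mustIncludeIds, d$marker_id)
  if (length(missing_ids))
    stop("must-include id(s) not found among candidates: ",
         paste(missing_ids, collapse = ", "))
  missing_sc <- setdiff(unique(d$scaffold), names(scaffoldLengths))
  if (length(missing_sc))
    stop("no scaffold length for: ", paste(missing_sc, collapse = ", "))
  d$must_include <- d$marker_id %in% mustIncludeIds
  d <- d[order(d$scaffold, d$pos), , drop = FALSE]

  seed <- d$must_include | isLargeEffect(d$effect)
  picked <- lapply(split(seq_len(nrow(d)), d$scaffold), function(ii) {
    sc <- d$scaffold[ii[1L]]
    dd <- d[ii, , drop = FALSE]
    seeded <- dd[seed[ii], , drop = FALSE]
    rest <- dd[!seed[ii], , drop = FALSE]
    prim <- primaryWindowScan(rest, config$primaryWindowBp)
    sel_pos <- c(seeded$pos, prim$pos)
    expected <- expectedSnpCount(scaffoldLengths[[sc]],
                                 config$targetSpacingBp)
    remaining <- rest[!(rest$pos %in% prim$pos), , drop = FALSE]
    fill <- fillinScan(remaining, sel_pos, expected,
                       config$fillinWindowBp, config$fillinOrder)
    rbind(seeded, prim, fill)
  })
  sel <- do.call(rbind, picked)
  sel <- sel[!duplicated(paste(sel$scaffold, sel$pos)), , drop = FALSE]

  if (nrow(sel) > config$capacity) {
    n_drop <- nrow(sel) - config$capacity
    droppable <- which(!sel$must_include)
    if (length(droppable) < n_drop)
      stop("capacity ", config$capacity,
           " cannot hold all must-include markers")
    drop_order <- droppable[order(sel$priority[droppable],
                                  sel$maf[droppable])]
    sel <- sel[-drop_order[seq_len(n_drop)], , drop = FALSE]
  }
  ArrayDesign(sel[, DESIGN_COLS])
}

#' Probe template sequences for a design
#'
#' Extracts the plus-strand genomic sequence \code{flankBp} either side of
#' each marker, with the variant base written \code{[ref/alt]}.  Flanks are
#' truncated at scaffold edges without padding.
#'
#' @param design an \code{\linkS4class{ArrayDesign}}.
#' @param genome a \code{\link[Biostrings]{DNAStringSet}} of scaffolds.
#' @param flankBp flank width in bp (default 35).
#' @return the design with \code{probeTemplates} filled (named by marker id).
#' @export
probeSequences <- function(design, genome, flankBp = 35L) {
  m <- designMarkers(design)
  probes <- character(nrow(m))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  for (sc in unique(m$scaffold)) {
    ii <- which(m$scaffold == sc)
    s <- as.character(genome[[sc]])
    left_start <- pmax(1L, m$pos[ii] - flankBp)
    right_end <- pmin(lens[[sc]], m$pos[ii] + flankBp)
    probes[ii] <- paste0(
      substring(s, left_start, m$pos[ii] - 1L),
      "[", m$ref[ii], "/", m$alt[ii], "]",
      substring(s, m$pos[ii] + 1L, right_end))
  }
  new("ArrayDesign", markers = m,
      probes = stats::setNames(probes, m$marker_id))
}
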