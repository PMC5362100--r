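#' Simulation configuration
#'
#' Parameters of the synthetic study generator.  The defaults emulate the
#' structure of an array-design study — a multi-scaffold genome with
#' protein-coding genes, a re-sequenced wild cohort at ~30x depth, a
#' 96-sample array run and a full-sib family with 24 offspring — at desk
#' scale (10 x 500 kb scaffolds by default).
#'
#' @param seed integer seed fixing every downstream draw.
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length_bp scaffold length (bp), recycled across scaffolds.
#' @param n_genes_per_scaffold genes per scaffold.
#' @param n_samples re-sequenced population size.
#' @param maf_law function(n) drawing n true minor allele frequencies in
#'   (0, 0.5].
#' @param mean_depth mean per-call read depth (Poisson).
#' @param call_missing_rate per-call probability of a missing genotype in the
#'   population VCF.
#' @param indel_rate per-bp indel probability.
#' @param snp_density per-bp SNP site probability.
#' @param array_error_rate per-call array miscall probability (uniform over
#'   the two wrong genotypes).
#' @param array_nocall_rate per-call array NoCall probability.
#' @param n_offspring full-sib family size.
#' @param n_force_mono,n_force_hetfree,n_force_lowcr marker counts forced
#'   monomorphic / heterozygote-free / low-call-rate in simulated array runs,
#'   to exercise category classification.
#' @return a list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L, n_scaffolds = 10L,
                      scaffold_length_bp = 500000L,
                      n_genes_per_scaffold = 20L, n_samples = 96L,
                      maf_law = function(n) stats::runif(n, 0.01, 0.5),
                      mean_depth = 30, call_missing_rate = 0.02,
                      indel_rate = 2e-4, snp_density = 5e-3,
                      array_error_rate = 0.01, array_nocall_rate = 0.005,
                      n_offspring = 24L, n_force_mono = 30L,
                      n_force_hetfree = 30L, n_force_lowcr = 30L) {
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              scaffold_length_bp = as.integer(scaffold_length_bp),
              n_genes_per_scaffold = as.integer(n_genes_per_scaffold),
              n_samples = as.integer(n_samples), maf_law = maf_law,
              mean_depth = mean_depth, call_missing_rate = call_missing_rate,
              indel_rate = indel_rate, snp_density = snp_density,
              array_error_rate = array_error_rate,
              array_nocall_rate = array_nocall_rate,
              n_offspring = as.integer(n_offspring),
              n_force_mono = as.integer(n_force_mono),
              n_force_hetfree = as.integer(n_force_hetfree),
              n_force_lowcr = as.integer(n_force_lowcr))
  rates <- unlist(cfg[c("call_missing_rate", "indel_rate", "snp_density",
                        "array_error_rate", "array_nocall_rate")])
  stopifnot(all(rates >= 0 & rates <= 1))
  structure(cfg, class = "SimConfig")
}

.gtToCall <- function(gt) {
  out <- c("AA", "AB", "BB")[gt + 1L]
  out[is.na(out)] <- "NoCall"
  out
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate a genome with coding genes
#'
#' Scaffolds are uniform-random nucleotide sequences into which
#' non-overlapping multi-exon genes are written: each CDS starts with ATG,
#' ends with a stop codon, contains no internal stop, and has total length
#' divisible by 3.  Roughly half the genes are placed on the minus strand.
#' Exons coincide with CDS intervals (no UTRs are modeled).
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{genome}
#'   (\code{\link[Biostrings]{DNAStringSet}}) and \code{models}
#'   (\code{\linkS4class{GeneModelSet}}).
#' @export
simulateGenome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"), cfg$scaffold_length_bp >= 3000L)
  set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1L, paste, collapse = "")
  sense_codons <- setdiff(codons, STOP_CODONS)
  scaffolds <- character(cfg$n_scaffolds)
  gene_rows <- list(); cds_rows <- list()
  for (sc in seq_len(cfg$n_scaffolds)) {
    len <- cfg$scaffold_length_bp
    chr <- sample(bases, len, replace = TRUE)
    sc_name <- sprintf("scaffold_%02d", sc)
    ng <- cfg$n_genes_per_scaffold
    if (ng > 0L) {
      # draw gene structures, then pack left to right with random gaps
      structs <- lapply(seq_len(ng), function(i) {
        n_codons <- sample(80:240, 1L)
        n_exons <- sample(2:4, 1L)
        cds_seq <- paste0("ATG",
                          paste(sample(sense_codons, n_codons, TRUE),
                                collapse = ""),
                          sample(STOP_CODONS, 1L))
        cds_len <- nchar(cds_seq)
        cuts <- sort(sample(seq_len(cds_len - 1L), n_exons - 1L))
        exon_len <- diff(c(0L, cuts, cds_len))
        intron_len <- sample(200:800, n_exons - 1L, replace = TRUE)
        list(cds_seq = cds_seq, exon_len = exon_len, intron_len = intron_len,
             span = sum(exon_len) + sum(intron_len),
             strand = sample(c("+", "-"), 1L))
      })
      spans <- vapply(structs, `[[`, numeric(1), "span")
      slack <- len - sum(spans) - 4000L * (ng + 1L)
      if (slack < 0L) stop("cannot pack ", ng, " genes into ", len, " bp")
      gaps <- 4000L + diff(c(0L, sort(sample.int(slack, ng))))
      starts <- cumsum(gaps) + cumsum(c(0L, spans[-ng]))
      for (i in seq_len(ng)) {
        st <- structs[[i]]
        gid <- sprintf("gene_%02d_%03d", sc, i)
        gstart <- starts[i]; gend <- gstart + st$span - 1L
        # exon intervals on the plus strand of the scaffold
        ex_start <- gstart + cumsum(c(0L, st$exon_len[-length(st$exon_len)] +
                                        st$intron_len))
        ex_end <- ex_start + st$exon_len - 1L
        # write the (strand-oriented) CDS into the exon bases
        cds_plus <- if (st$strand == "+") st$cds_seq else
          chartr("ACGT", "TGCA",
                 paste(rev(strsplit(st$cds_seq, "")[[1L]]), collapse = ""))
        cds_chars <- strsplit(cds_plus, "")[[1L]]
        offset <- 0L
        for (e in seq_along(ex_start)) {
          w <- st$exon_len[e]
          # plus-strand exon order matches plus-strand CDS string order
          chr[ex_start[e]:ex_end[e]] <- cds_chars[(offset + 1L):(offset + w)]
          offset <- offset + w
        }
        # GFF3 phase per CDS interval, in transcription order
        tx_order <- if (st$strand == "+") seq_along(ex_start) else
          rev(seq_along(ex_start))
        len_tx <- (ex_end - ex_start + 1L)[tx_order]
        cum_before <- cumsum(c(0L, len_tx[-length(len_tx)]))
        phase_tx <- (3L - (cum_before %% 3L)) %% 3L
        phase <- integer(length(ex_start))
        phase[tx_order] <- phase_tx
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          scaffold = sc_name, start = gstart, end = gend,
          strand = st$strand, gene_id = gid)
        cds_rows[[length(cds_rows) + 1L]] <- data.frame(
          scaffold = sc_name, start = ex_start, end = ex_end,
          strand = st$strand, gene_id = gid, phase = phase)
      }
    }
    scaffolds[sc] <- paste(chr, collapse = "")
    names(scaffolds)[sc] <- sc_name
  }
  genome <- Biostrings::DNAStringSet(scaffolds)
  if (length(gene_rows)) {
    gdf <- do.call(rbind, gene_rows)
    cdf <- do.call(rbind, cds_rows)
    genes <- GRanges(gdf$scaffold, IRanges(gdf$start, gdf$end),
                     strand = gdf$strand)
    mcols(genes)$gene_id <- gdf$gene_id
    cds <- GRanges(cdf$scaffold, IRanges(cdf$start, cdf$end),
                   strand = cdf$strand)
    mcols(cds)$gene_id <- cdf$gene_id
    mcols(cds)$phase <- cdf$phase
    models <- GeneModelSet(genes, cds, cds)
  } else {
    models <- GeneModelSet(GRanges(), GRanges(), GRanges())
  }
  list(genome = genome, models = models)
}

#' Simulate a population variant set
#'
#' SNP sites are placed uniformly along the scaffolds with true minor allele
#' frequencies drawn from \code{maf_law}; genotypes follow Hardy-Weinberg
#' proportions.  Per-call depth is Poisson around \code{mean_depth} and GQ is
#' a deterministic ramp of DP plus noise (degraded at low depth).  Indels are
#' sprinkled at \code{indel_rate}; a per-call fraction
#' \code{call_missing_rate} of genotypes is set missing with DP = GQ = 0.
#'
#' @param genome a \code{DNAStringSet} from \code{\link{simulateGenome}}.
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{calls} (a \code{\linkS4class{VariantCallSet}})
#'   and \code{truth} (data.frame: scaffold, pos, vclass, true_maf).
#' @export
simulatePopulationVcf <- function(genome, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 1L)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  total <- sum(lens)
  n_snp <- round(total * cfg$snp_density)
  n_indel <- round(total * cfg$indel_rate)
  draw_sites <- function(n) {
    gpos <- sort(sample.int(total - 10L, n))
    sc_idx <- findInterval(gpos - 1L, cumsum(c(0, lens))[-(length(lens) + 1L)])
    data.frame(scaffold = names(lens)[sc_idx],
               pos = gpos - c(0, cumsum(lens))[sc_idx],
               stringsAsFactors = FALSE)
  }
  sites <- draw_sites(n_snp + n_indel)
  sites <- sites[sites$pos >= 2L, ]
  sites <- sites[!duplicated(paste(sites$scaffold, sites$pos)), ]
  is_indel <- rep(FALSE, nrow(sites))
  if (n_indel > 0L)
    is_indel[sample.int(nrow(sites), min(n_indel, nrow(sites)))] <- TRUE
  base_at <- function(sc, p) substring(as.character(genome[[sc]]), p, p)
  ref <- mapply(base_at, sites$scaffold, sites$pos, USE.NAMES = FALSE)
  bases <- c("A", "C", "G", "T")
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1),
                USE.NAMES = FALSE)
  # indels: 1-3 bp insertions after the anchor base
  if (any(is_indel))
    alt[is_indel] <- paste0(ref[is_indel],
                            vapply(which(is_indel), function(i)
                              paste(sample(bases, sample(1:3, 1L), TRUE),
                                    collapse = ""), character(1)))
  n_sites <- nrow(sites)
  k <- cfg$n_samples
  maf <- cfg$maf_law(n_sites)
  stopifnot(all(maf > 0 & maf <= 0.5))
  gt <- matrix(stats::rbinom(n_sites * k, 2L, rep(maf, k)), n_sites, k)
  miss <- matrix(stats::runif(n_sites * k) < cfg$call_missing_rate,
                 n_sites, k)
  gt[miss] <- NA_integer_
  dp <- matrix(stats::rpois(n_sites * k, cfg$mean_depth), n_sites, k)
  gq <- pmax(0L, pmin(99L, round(3 * dp +
                                   stats::rnorm(n_sites * k, 0, 3))))
  dp[miss] <- 0L; gq[miss] <- 0L
  samples <- sprintf("oyster_%03d", seq_len(k))
  vcs <- VariantCallSet(sites$scaffold, sites$pos, ref, alt,
                        gt, dp, gq, samples)
  list(calls = vcs,
       truth = data.frame(sites, vclass = ifelse(is_indel, "INDEL", "SNP"),
                          true_maf = maf, stringsAsFactors = FALSE))
}

#' Simulate an array genotyping run
#'
#' Converts true genotypes at the design markers into AA/AB/BB calls, injects
#' NoCall at \code{array_nocall_rate} and miscalls at
#' \code{array_error_rate} (uniform over the two wrong genotypes), and forces
#' designated marker subsets monomorphic, heterozygote-free and low-call-rate
#' so every cluster category is exercised.  The generating category label per
#' marker is exported.
#'
#' @param trueGt integer matrix (markers x samples, coded 0/1/2) of the true
#'   genotypes of the array samples at the design markers; rownames are
#'   marker ids.
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{matrix} (a \code{\linkS4class{CallMatrix}}),
#'   \code{truth_category} (named character), \code{true_calls} (the
#'   noise-free call matrix) and \code{error_mask} (logical matrix of
#'   injected miscalls).
#' @export
simulateArrayCalls <- function(trueGt, cfg) {
  stopifnot(inherits(cfg, "SimConfig"), !is.null(rownames(trueGt)))
  set.seed(cfg$seed + 2L)
  n <- nrow(trueGt); k <- ncol(trueGt)
  if (is.null(colnames(trueGt)))
    colnames(trueGt) <- sprintf("array_%03d", seq_len(k))
  forced <- sample.int(n, min(n, cfg$n_force_mono + cfg$n_force_hetfree +
                                cfg$n_force_lowcr))
  mono <- forced[seq_len(min(length(forced), cfg$n_force_mono))]
  hetfree <- setdiff(forced, mono)[seq_len(min(length(forced) - length(mono),
                                               cfg$n_force_hetfree))]
  lowcr <- setdiff(forced, c(mono, hetfree))
  gt <- trueGt
  gt[mono, ] <- 0L
  gt[hetfree, ] <- ifelse(gt[hetfree, , drop = FALSE] >= 1L, 1L, 0L)

  label <- character(n)
  has3 <- rowSums(gt == 0L) > 0L & rowSums(gt == 1L) > 0L &
    rowSums(gt == 2L) > 0L
  has_het <- rowSums(gt == 1L) > 0L
  hom_classes <- (rowSums(gt == 0L) > 0L) + (rowSums(gt == 2L) > 0L)
  label[has3] <- "PolyHighResolution"
  label[!has3 & hom_classes == 1L & has_het] <- "NoMinorHom"
  label[!has3 & hom_classes == 1L & !has_het] <- "MonoHighResolution"
  label[label == ""] <- "Other"
  label[lowcr] <- "CallRateBelowThreshold"
  names(label) <- rownames(trueGt)

  true_calls <- matrix(.gtToCall(gt), n, k, dimnames = dimnames(trueGt))
  out <- true_calls
  err <- matrix(stats::runif(n * k) < cfg$array_error_rate, n, k)
  if (any(err)) {
    wrong <- vapply(out[err], function(cl)
      sample(setdiff(c("AA", "AB", "BB"), cl), 1L), character(1))
    out[err] <- wrong
  }
  nocall <- matrix(stats::runif(n * k) < cfg$array_nocall_rate, n, k)
  # forced low-CR markers: a fixed 10% of samples NoCall, below any
  # plausible call-rate threshold
  n_nc <- max(ceiling(0.1 * k), ceiling((1 - 0.97) * k) + 1L)
  for (i in lowcr)
    nocall[i, sample.int(k, n_nc)] <- TRUE
  out[nocall] <- "NoCall"
  err[nocall] <- FALSE
  list(matrix = CallMatrix(out), truth_category = label,
       true_calls = true_calls, error_mask = err)
}

#' Simulate a full-sib family genotyped on the array
#'
#' Offspring genotypes are drawn by independent Mendelian transmission per
#' marker from the two parental genotypes; miscalls are injected uniformly at
#' \code{array_error_rate} and NoCalls at \code{array_nocall_rate}.  The
#' injected-error mask is exported.
#'
#' @param parentGt integer matrix (markers x 2, coded 0/1/2) of the true
#'   parental genotypes; rownames are marker ids.
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{p1}, \code{p2} (parent call vectors),
#'   \code{offspring} (a \code{\linkS4class{CallMatrix}}),
#'   \code{true_offspring} (noise-free call matrix) and \code{error_mask}.
#' @export
simulateFamily <- function(parentGt, cfg) {
  stopifnot(inherits(cfg, "SimConfig"), ncol(parentGt) == 2L,
            !is.null(rownames(parentGt)))
  set.seed(cfg$seed + 3L)
  n <- nrow(parentGt); k <- cfg$n_offspring
  a1 <- matrix(stats::rbinom(n * k, 1L, rep(parentGt[, 1L] / 2, k)), n, k)
  a2 <- matrix(stats::rbinom(n * k, 1L, rep(parentGt[, 2L] / 2, k)), n, k)
  gt <- a1 + a2
  true_calls <- matrix(.gtToCall(gt), n, k,
                       dimnames = list(rownames(parentGt),
                                       sprintf("offspring_%02d", seq_len(k))))
  out <- true_calls
  err <- matrix(stats::runif(n * k) < cfg$array_error_rate, n, k)
  if (any(err)) {
    out[err] <- vapply(out[err], function(cl)
      sample(setdiff(c("AA", "AB", "BB"), cl), 1L), character(1))
  }
  nocall <- matrix(stats::runif(n * k) < cfg$array_nocall_rate, n, k)
  out[nocall] <- "NoCall"
  err[nocall] <- FALSE
  list(p1 = .gtToCall(parentGt[, 1L]), p2 = .gtToCall(parentGt[, 2L]),
       offspring = CallMatrix(out), true_offspring = true_calls,
       error_mask = err)
}
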