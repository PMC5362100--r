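test_that("expected marker count is floor(length/spacing) with a floor of one", {
  expect_equal(expectedSnpCount(560e6, 2800), 200000L)
  expect_equal(expectedSnpCount(2800), 1L)
  expect_equal(expectedSnpCount(7000), 2L)
  expect_equal(expectedSnpCount(100), 1L)
  expect_equal(expectedSnpCount(c(2800, 7000)), c(1L, 2L))
})

test_that("primary scan picks one SNP per 3-kb tile by priority, MAF, then position", {
  cand <- data.frame(
    marker_id = paste0("sc:", c(100, 900, 2500, 3500, 4000, 9100)),
    scaffold = "sc", pos = c(100, 900, 2500, 3500, 4000, 9100),
    ref = "A", alt = "G",
    effect = c("synonymous", "missense", "synonymous",
               "missense", "missense", "intron"),
    priority = c(3L, 4L, 3L, 4L, 4L, 2L),
    maf = c(0.4, 0.2, 0.3, 0.10, 0.30, 0.25),
    stringsAsFactors = FALSE)
  sel <- primaryWindowScan(cand, 3000L)
  # window 1: priority-4 SNP wins over higher-MAF priority-3 SNPs
  expect_true(900 %in% sel$pos)
  expect_false(any(c(100, 2500) %in% sel$pos))
  # window 2: two priority-4 SNPs, MAF 0.30 beats 0.10
  expect_true(4000 %in% sel$pos)
  expect_false(3500 %in% sel$pos)
  # window with a single candidate selects it
  expect_true(9100 %in% sel$pos)
  expect_equal(nrow(sel), 3L)

  # position tie-break: equal priority and MAF -> smallest position
  tie <- cand[1:2, ]
  tie$priority <- 4L; tie$maf <- 0.3
  expect_equal(primaryWindowScan(tie, 3000L)$pos, 100)
})

test_that("primary scan equals the exhaustive per-window argmax oracle", {
  for (seed in 1:5) {
    cand <- randomCandidates(200, 50000L, seed = seed)
    sel <- primaryWindowScan(cand, 3000L)
    want <- naiveWindowSelect(cand, 3000L)
    expect_equal(sel$pos, want$pos)
    # no two selected SNPs share a tile; each is maximal in its tile
    win <- (sel$pos - 1L) %/% 3000L
    expect_false(any(duplicated(win)))
    all_win <- (cand$pos - 1L) %/% 3000L
    for (r in seq_len(nrow(sel)))
      expect_equal(sel$priority[r], max(cand$priority[all_win == win[r]]))
  }
})

test_that("fill-in adds the best candidates in empty 1-kb windows up to the deficit", {
  cand <- randomCandidates(30, 10000L, seed = 9)
  # already at the expected count: nothing added
  expect_equal(nrow(fillinScan(cand, selectedPos = c(500, 1500), expected = 2L)), 0L)
  # deficit 5 but a single candidate: one added, no error
  one <- cand[1, , drop = FALSE]
  expect_equal(nrow(fillinScan(one, selectedPos = 9999, expected = 6L)), 1L)

  # deficit 2 with 3 candidate-bearing empty windows: the two best-ranked
  c3 <- data.frame(
    marker_id = c("a", "b", "c"), scaffold = "sc",
    pos = c(1500, 2500, 3500), ref = "A", alt = "G",
    effect = "intergenic", priority = c(1L, 1L, 1L),
    maf = c(0.10, 0.40, 0.25), stringsAsFactors = FALSE)
  add <- fillinScan(c3, selectedPos = 500, expected = 3L)
  expect_equal(sort(add$marker_id), c("b", "c"))
  # windows already holding a selected marker are skipped
  add2 <- fillinScan(c3, selectedPos = c(500, 2700), expected = 4L)
  expect_equal(sort(add2$marker_id), c("a", "c"))
})

test_that("assembled designs keep must-include markers, respect capacity, and deduplicate", {
  cand <- randomCandidates(60, 36000L, seed = 21)
  lens <- c(sc = 36000L)
  # a must-include marker in a window with a higher-priority rival stays on
  weak <- cand[cand$priority == min(cand$priority), ][1, ]
  d <- assembleDesign(cand, lens, mustIncludeIds = weak$marker_id,
                      config = selectionConfig(capacity = 1000L))
  expect_true(weak$marker_id %in% markerIds(d))
  expect_true(all(designMarkers(d)$must_include ==
                    (markerIds(d) == weak$marker_id)))

  # capacity pressure: worst non-must markers dropped, must-include kept
  d_all <- assembleDesign(cand, lens, mustIncludeIds = weak$marker_id,
                          config = selectionConfig(capacity = 1000L))
  n_sel <- nrow(designMarkers(d_all))
  cap <- n_sel - 2L
  d_cap <- assembleDesign(cand, lens, mustIncludeIds = weak$marker_id,
                          config = selectionConfig(capacity = cap))
  m_all <- designMarkers(d_all); m_cap <- designMarkers(d_cap)
  expect_equal(nrow(m_cap), cap)
  expect_true(weak$marker_id %in% m_cap$marker_id)
  dropped <- setdiff(m_all$marker_id, m_cap$marker_id)
  # exhaustive ranking: the dropped two are the worst (priority, maf) non-must
  nonmust <- m_all[!m_all$must_include, ]
  worst <- nonmust$marker_id[order(nonmust$priority, nonmust$maf)][1:2]
  expect_setequal(dropped, worst)

  # duplicate (scaffold,pos) submitted twice -> one marker
  dup <- rbind(cand, cand[1, ])
  d_dup <- assembleDesign(dup, lens)
  expect_false(any(duplicated(paste(designMarkers(d_dup)$scaffold,
                                    designMarkers(d_dup)$pos))))

  expect_error(assembleDesign(cand, lens, mustIncludeIds = "sc:999999"),
               "not found")
})

test_that("identical inputs give byte-identical written designs", {
  cand <- randomCandidates(150, 80000L, seed = 33)
  lens <- c(sc = 80000L)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeDesign(assembleDesign(cand, lens), f1)
  writeDesign(assembleDesign(cand, lens), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("probe templates carry the [ref/alt] center and truncate at edges", {
  set.seed(2)
  genome <- Biostrings::DNAStringSet(stats::setNames(
    paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = ""),
    "sc"))
  chr <- as.character(genome[[1]])
  pos <- c(10L, 250L, 495L)
  ref <- substring(chr, pos, pos)
  alt <- vapply(ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                character(1), USE.NAMES = FALSE)
  m <- data.frame(marker_id = paste0("sc:", pos), scaffold = "sc", pos = pos,
                  ref = ref, alt = alt, effect = "intergenic", priority = 1L,
                  maf = 0.2, must_include = FALSE, p_convert = NA_real_,
                  stringsAsFactors = FALSE)
  d <- probeSequences(ArrayDesign(m), genome, flankBp = 35L)
  pr <- probeTemplates(d)
  # interior marker: 35 + [X/Y] + 35 characters
  expect_equal(nchar(pr[["sc:250"]]), 35 + 5 + 35)
  expect_equal(substring(pr[["sc:250"]], 36, 40),
               sprintf("[%s/%s]", ref[2], alt[2]))
  # marker at pos 10: left flank truncated to 9 bp
  expect_equal(nchar(pr[["sc:10"]]), 9 + 5 + 35)
  # probe center matches the genome reference base; flanks match the genome
  for (i in seq_along(pos)) {
    p <- pr[[paste0("sc:", pos[i])]]
    expect_equal(sub(".*\\[(.)/.*", "\\1", p), ref[i])
    left <- sub("\\[.*", "", p)
    expect_equal(left, substring(chr, pos[i] - nchar(left), pos[i] - 1))
  }
})
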