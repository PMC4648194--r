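# Upstream windows, mismatch-tolerant motif scanning and Table-2-style
# reporting.

test_that("upstream windows follow strand and truncate at scaffold edges", {
  scaffold <- random_dna_str(600)
  plus <- list(gene_id = "gp", start = 201L, end = 500L, strand = "+")
  w <- upstream_region(plus, scaffold, 130)
  expect_equal(w$sequence, substr(scaffold, 71, 200))
  expect_equal(w$width, 130)
  expect_false(w$truncated)

  minus <- list(gene_id = "gm", start = 101L, end = 400L, strand = "-")
  wm <- upstream_region(minus, scaffold, 130)
  expect_equal(wm$sequence, rhizoglob:::revcomp(substr(scaffold, 401, 530)))

  edge <- list(gene_id = "ge", start = 51L, end = 350L, strand = "+")
  we <- upstream_region(edge, scaffold, 130)
  expect_equal(we$width, 50)
  expect_true(we$truncated)

  off <- list(gene_id = "go", start = 550L, end = 700L, strand = "+")
  expect_error(upstream_region(off, scaffold), "does not lie")
})

test_that("case coding matches the published Fnr examples", {
  expect_equal(case_code("TTTAAGAGGCCAAT", "TTTAAGAGGCCAAT"), "TTTAAGAGGCCAAT")
  expect_equal(case_code("TTTAAGAGGCCAAT", "TCTAAGCGACTGAT"), "TcTAAGcGaCtgAT")
  expect_equal(case_code("TTTAAGAGGCCAAT", "GTCAAGGAGCCAAA"), "gTcAAGgaGCCAAa")
  expect_error(case_code("TATAAT", "TATAA"), "equal length")
})

test_that("lowercase count equals the Hamming distance (property)", {
  set.seed(71)
  for (k in 1:50) {
    n <- sample(4:14, 1)
    cons <- random_dna_str(n)
    obs <- random_dna_str(n)
    coded <- case_code(cons, obs)
    n_lower <- sum(grepl("[acgt]", strsplit(coded, "")[[1]]))
    hd <- sum(strsplit(cons, "")[[1]] != strsplit(obs, "")[[1]])
    expect_equal(n_lower, hd)
    expect_equal(toupper(coded), toupper(obs))
  }
})

test_that("a planted -35 box is reported with exact signed positions", {
  w <- paste0(strrep("A", 89), "TTGACA", strrep("A", 35))
  expect_equal(nchar(w), 130)
  hits <- scan_hamming(w, "TTGACA", max_mismatches = 0, motif = "-35")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$near, -36L)
  expect_equal(hits$far, -41L)
  expect_equal(hits$position, "-36 to -41")
  expect_equal(hits$matched, "TTGACA")
  expect_equal(hits$n_mismatch, 0L)
})

test_that("the Fnr-like hit of the published Table-2 row is recovered", {
  # plant TCTAAGCGACTGAT (9/14 identities to the Fnr consensus) at -115..-102
  obs <- "TCTAAGCGACTGAT"
  w <- paste0(strrep("C", 15), obs, strrep("C", 101))
  expect_equal(nchar(w), 130)
  hits <- scan_hamming(w, "TTTAAGAGGCCAAT", max_mismatches = 5, motif = "Fnr")
  planted <- hits[hits$far == -115L, ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$position, "-102 to -115")
  expect_equal(planted$matched, "TcTAAGcGaCtgAT")
  expect_equal(planted$n_identical, 9L)
  expect_equal(planted$n_mismatch, 5L)
})

test_that("partial Shine-Dalgarno matches are maximal and proximity-ranked", {
  w <- paste0(strrep("C", 117), "GGAG", strrep("C", 9))
  hits <- scan_partial(w, "AGGAGG", min_match_len = 3, motif = "SD")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, "-10 to -13")

  w2 <- paste0(strrep("C", 118), "AGGAGG", strrep("C", 6))
  hits2 <- scan_partial(w2, "AGGAGG", min_match_len = 3)
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$n_identical, 6L)

  # both a 3-mer and a 4-mer present: both reported, nearer first
  w3 <- paste0(strrep("C", 100), "GAGG", strrep("C", 20), "AGG", "CCC")
  hits3 <- scan_partial(w3, "AGGAGG", min_match_len = 3)
  expect_equal(nrow(hits3), 2)
  expect_equal(hits3$matched[1], "AGG")   # nearer to the gene
  expect_equal(hits3$matched[2], "GAGG")
  expect_true(hits3$primary[1])
})

test_that("windows shorter than the consensus yield no hits", {
  expect_equal(nrow(scan_hamming("TATA", "TATAAT", 1)), 0)
  expect_equal(nrow(scan_partial("", "AGGAGG")), 0)
  expect_error(scan_partial("ACGT", "AGGAGG", min_match_len = 2), "at least 3")
})

test_that("planted motifs are recovered exactly through the full scan", {
  set.seed(72)
  for (k in 1:10) {
    gen <- single_globin_genome(
      seed = 100 + k,
      promoters = tibble::tibble(
        motif = c("-10", "-35", "Fnr", "SD"),
        offset = c(-95L, -41L, -120L, -12L),
        n_mismatches = c(1L, 0L, sample(0:5, 1), 0L)
      )
    )
    genes <- gen$annotation[gen$annotation$product == "globin", ]
    hits <- scan_promoters(genes, gen)
    tm <- gen$truth[gen$truth$kind == "motif", ]
    for (i in seq_len(nrow(tm))) {
      h <- hits[hits$motif == tm$motif[i] & hits$far == tm$offset_far[i], ]
      expect_equal(nrow(h), 1, info = tm$motif[i])
      expect_equal(h$near, tm$offset_near[i])
      expect_equal(h$n_mismatch, tm$n_mismatches[i])
    }
  }
})

test_that("strand-symmetric windows give identical hit lists", {
  # a minus-strand gene on the reverse-complemented scaffold has exactly
  # the same coding-strand upstream window as the original plus-strand gene
  gen <- single_globin_genome(
    seed = 81, strand = "+",
    promoters = tibble::tibble(motif = "Fnr", offset = -100L, n_mismatches = 3L))
  g <- gen$annotation[gen$annotation$product == "globin", ]
  scaffold <- gen$scaffolds[[1]]
  L <- nchar(scaffold)
  flipped <- rhizoglob:::revcomp(scaffold)
  g_flip <- dplyr::mutate(g, start = L - g$end + 1L, end = L - g$start + 1L,
                          strand = "-")
  wp <- upstream_region(g, scaffold)
  wm <- upstream_region(g_flip, flipped)
  expect_identical(wp$sequence, wm$sequence)
  hp <- scan_promoters(g, setNames(scaffold, g$scaffold_id))
  hm <- scan_promoters(g_flip, setNames(flipped, g$scaffold_id))
  expect_equal(hp, hm)
})

test_that("full-length zero-mismatch Fnr hits are absent from random windows", {
  set.seed(73)
  n_hit <- 0
  for (k in 1:1000) {
    w <- random_dna_str(130)
    n_hit <- n_hit + nrow(scan_hamming(w, "TTTAAGAGGCCAAT", 0))
  }
  expect_equal(n_hit, 0)
})

test_that("the promoter report renders N.D. and repeats rows for extra Fnr hits", {
  hits <- rbind(
    scan_hamming(paste0(strrep("A", 89), "TTGACA", strrep("A", 35)),
                 "TTGACA", 0, motif = "-35", gene_id = "g1"),
    scan_partial(paste0(strrep("C", 117), "GGAG", strrep("C", 9)),
                 "AGGAGG", motif = "SD", gene_id = "g1")
  )
  rep1 <- promoter_report(hits, gene_ids = "g1")
  expect_equal(rep1$p10, "N.D.")
  expect_equal(rep1$p35, "-36 to -41")
  expect_equal(rep1$fnr_sequence, "N.D.")
  expect_equal(rep1$sd, "-10 to -13")

  # two Fnr hits: one continuation row
  w <- paste0(strrep("C", 10), "TTTAAGAGGCCAAT", strrep("C", 80),
              "TTTAAGAGGCCAAT", strrep("C", 12))
  fnr <- scan_hamming(w, "TTTAAGAGGCCAAT", 0, motif = "Fnr", gene_id = "g2")
  expect_equal(nrow(fnr), 2)
  rep2 <- promoter_report(fnr, gene_ids = "g2")
  expect_equal(nrow(rep2), 2)
  expect_equal(rep2$gene_id, c("g2", ""))
  expect_equal(sum(rep2$fnr_sequence == "TTTAAGAGGCCAAT"), 2)

  expect_equal(nrow(promoter_report(rhizoglob:::empty_hits(),
                                    gene_ids = character())), 0)
})
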