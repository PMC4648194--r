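# ORF detection and the globin classifier.

test_that("a minimal ORF is found with stop-inclusive coordinates", {
  orfs <- extract_orfs("ATGAAATAA", min_len_aa = 2)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$protein, "MK")
  expect_equal(orfs$start, 1)
  expect_equal(orfs$end, 9)
  expect_equal(orfs$strand, "+")
})

test_that("the reverse complement yields the same protein on the minus strand", {
  orfs <- extract_orfs(rhizoglob:::revcomp("ATGAAATAA"), min_len_aa = 2)
  expect_equal(orfs$protein, "MK")
  expect_equal(orfs$strand, "-")
  expect_equal(c(orfs$start, orfs$end), c(1, 9))
})

test_that("degenerate scaffolds yield no ORFs and bad characters are rejected", {
  expect_equal(nrow(extract_orfs(strrep("N", 300), min_len_aa = 2)), 0)
  expect_error(extract_orfs("ATGAAQTAA"), "position 6")
})

test_that("ORF invariants hold on random scaffolds", {
  set.seed(55)
  for (k in 1:5) {
    orfs <- extract_orfs(random_dna_str(3000, gc = 0.4), min_len_aa = 20)
    if (nrow(orfs) == 0) next
    expect_true(all((orfs$end - orfs$start + 1) %% 3 == 0))
    expect_true(all(nchar(orfs$protein) == (orfs$end - orfs$start + 1) / 3 - 1))
    expect_false(any(grepl("\\*", orfs$protein)))
    expect_true(all(substr(orfs$protein, 1, 1) == "M"))
    expect_true(!is.unsorted(orfs$start))
  }
})

test_that("alternative start codons are reported as M", {
  orfs <- extract_orfs("GTGAAATAA", min_len_aa = 2)
  expect_equal(orfs$protein, "MK")
  orfs <- extract_orfs("TTGAAATAA", min_len_aa = 2)
  expect_equal(orfs$protein, "MK")
})

test_that("every shipped reference classifies as itself and is accepted", {
  set.seed(61)
  for (i in seq_len(nrow(REFS))) {
    call <- classify_globin(REFS$sequence[i], REFS, gene_id = REFS$id[i])
    expect_equal(call$best_reference, REFS$id[i])
    expect_equal(call$type, REFS$type[i])
    expect_true(call$accepted)
    expect_equal(call$f8_res, "H")
    expect_equal(call$percent_identity, 100)
  }
})

test_that("the F8 gate flips acceptance when His is mutated to Ala", {
  ref <- REFS[REFS$type == "SDgb", ]
  broken <- ref$sequence
  substr(broken, ref$f8, ref$f8) <- "A"
  set.seed(62)
  call <- classify_globin(broken, REFS)
  expect_false(call$f8_his_ok)
  expect_false(call$accepted)
  expect_true(call$z_ok)  # only the F8 criterion fails
})

test_that("short candidates fail the length criterion", {
  ref <- REFS[REFS$type == "SDgb", ]
  set.seed(63)
  call <- classify_globin(substr(ref$sequence, 1, 60), REFS)
  expect_false(call$length_ok)
  expect_false(call$accepted)
})

test_that("architecture refinement promotes long single-domain matches", {
  # an SDgb globin domain fused to a large unrelated tail reads as fHb
  set.seed(64)
  ref <- REFS[REFS$type == "SDgb", ]
  fused <- paste0(ref$sequence, random_aa(260))
  call <- classify_globin(fused, REFS)
  expect_equal(call$best_reference, ref$id)
  expect_equal(call$type, "fHb")
  expect_equal(call$glb, "fhb")
})

test_that("mean z degrades monotonically with substitution rate", {
  ref <- REFS[REFS$type == "SDgb", ]
  rates <- c(0, 0.1, 0.2, 0.4)
  set.seed(65)
  mean_z <- vapply(rates, function(r) {
    mean(vapply(1:30, function(k) {
      q <- mutate_protein(ref$sequence, r, protect = ref$f8)
      alignment_zscore(q, ref$sequence, n_shuffles = 60)$z
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_z) <= 0))
})

test_that("mass and key-residue bookkeeping are consistent", {
  ref <- REFS[REFS$type == "tHb1", ]
  set.seed(66)
  call <- classify_globin(ref$sequence, REFS)
  expect_gt(call$mass_kda, 0)
  # glycine-only protein of same length would be lighter; crude bracket
  expect_lt(call$mass_kda, nchar(ref$sequence) * 0.19)
  expect_equal(call$f8_idx, ref$f8)
  expect_equal(call$e7_idx, ref$e7)
  expect_equal(call$b10_idx, ref$b10)
  expect_equal(call$cd1_idx, ref$cd1)
})

test_that("distribution tallies aggregate copies and Venn regions", {
  calls <- tibble::tibble(
    genome = c("g1", "g1", "g1"),
    glb = c("sdgb", "sdgb", "thb")
  )
  t <- tally_distribution(calls)
  expect_equal(t$copy_number$n_genomes[t$copy_number$glb == "sdgb" &
                                         t$copy_number$copies == 2], 1)
  expect_equal(t$copy_number$n_genomes[t$copy_number$glb == "thb" &
                                         t$copy_number$copies == 1], 1)
  expect_equal(t$venn$n_genomes[t$venn$region == "sdgb+thb"], 1)
  expect_equal(sum(t$venn$n_genomes), 1)
  empty <- tally_distribution(tibble::tibble(genome = character(),
                                             glb = character()))
  expect_equal(nrow(empty$per_genome), 0)
})
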