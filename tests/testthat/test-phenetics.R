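# Identity matrices, UPGMA phenograms, Newick round trips, progressive
# alignment and lineage segregation.

test_that("percent identity follows its definition", {
  expect_equal(percent_identity("ACDE", "ACDE"), 100)
  expect_equal(percent_identity("ACDE", "ACDF"), 75)
  set.seed(101)
  for (k in 1:20) {
    a <- random_aa(sample(20:60, 1)); b <- random_aa(sample(20:60, 1))
    expect_equal(percent_identity(a, b), percent_identity(b, a))
  }
})

test_that("the shorter-sequence denominator is exposed", {
  a <- "ACDEFGHIKL"
  b <- "ACDEF"
  expect_equal(percent_identity(a, b, denominator = "shorter"), 100)
  expect_lte(percent_identity(a, b), 100)
})

test_that("the hand-computed 3-taxon UPGMA tree is reproduced exactly", {
  d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phen <- upgma(d)
  expect_equal(phen$newick, "((A:1,B:1):3,C:4);")
  two <- upgma(d[1:2, 1:2])
  expect_equal(two$newick, "(A:1,B:1);")
  expect_error(upgma(d[1, 1, drop = FALSE]), "at least 2")
})

test_that("UPGMA output is ultrametric and round-trips its cophenetic matrix", {
  set.seed(102)
  for (k in 1:20) {
    n <- 6
    m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    v <- runif(n * (n - 1) / 2, 1, 100)
    m[lower.tri(m)] <- v
    m <- m + t(m)
    phen <- upgma(m)
    depths <- ape::node.depth.edgelength(phen$tree)
    leaf_depths <- depths[seq_len(n)]
    expect_lt(max(leaf_depths) - min(leaf_depths), 1e-9)
    # feeding the cophenetic distances back recovers them exactly
    coph <- cophenetic(phen$tree)
    phen2 <- upgma(coph)
    coph2 <- cophenetic(phen2$tree)
    expect_equal(coph2[rownames(coph), colnames(coph)], coph,
                 tolerance = 1e-9)
  }
})

test_that("UPGMA heights match average-linkage clustering (independent check)", {
  set.seed(103)
  for (k in 1:5) {
    n <- 7
    m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    v <- runif(n * (n - 1) / 2, 1, 50)
    m[lower.tri(m)] <- v
    m <- m + t(m)
    phen <- upgma(m)
    hc <- hclust(as.dist(m), method = "average")
    expect_equal(sort(unique(round(ape::branching.times(phen$tree), 9))),
                 sort(unique(round(hc$height / 2, 9))))
  }
})

test_that("newick output parses back to the same tree", {
  set.seed(104)
  n <- 6
  m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  m[lower.tri(m)] <- runif(15, 1, 100)
  m <- m + t(m)
  phen <- upgma(m)
  reread <- ape::read.tree(text = to_newick(phen))
  expect_equal(sort(reread$tip.label), sort(phen$tree$tip.label))
  expect_equal(cophenetic(reread), cophenetic(phen$tree)[rownames(cophenetic(reread)),
                                                         colnames(cophenetic(reread))],
               tolerance = 1e-9)
})

test_that("progressive alignment preserves sequences and reduces to pairwise", {
  s <- setNames(REFS$sequence[c(2, 5, 4)], REFS$id[c(2, 5, 4)])
  msa <- progressive_msa(s)
  expect_true(all(nchar(msa) == attr(msa, "width")))
  expect_gte(attr(msa, "width"), max(nchar(s)))
  expect_equal(unname(gsub("-", "", msa[names(s)])), unname(s))

  msa2 <- progressive_msa(s[1:2])
  aln <- global_align(s[[1]], s[[2]])
  expect_equal(as.vector(unname(msa2)), c(aln$a_aln, aln$b_aln))

  tri <- setNames(rep(REFS$sequence[2], 3), c("a", "b", "c"))
  expect_false(any(grepl("-", progressive_msa(tri))))
  expect_error(progressive_msa(setNames(s, NULL)), "named")
})

test_that("a planted insertion stays confined to one column block", {
  base <- REFS$sequence[REFS$type == "SDgb"]
  ins <- paste0(substr(base, 1, 70), "WWWWW", substr(base, 71, nchar(base)))
  s <- c(plain1 = base, plain2 = base, with_ins = ins)
  msa <- progressive_msa(s)
  expect_equal(attr(msa, "width"), nchar(base) + 5)
  gaps1 <- gregexpr("-", msa[["plain1"]])[[1]]
  expect_equal(as.integer(gaps1), 71:75)
})

test_that("lineage segregation separates the 2/2 from the 3/3 families", {
  set.seed(105)
  leaves <- list()
  for (i in seq_len(nrow(REFS))) {
    for (r in 1:2) {
      leaves[[paste0(REFS$id[i], "_", r)]] <-
        mutate_protein(REFS$sequence[i], 0.1, protect = REFS$f8[i])
    }
  }
  seqs <- unlist(leaves)
  phen <- phenogram(seqs)
  groups <- setNames(ifelse(grepl("thb", names(seqs)), "T", "MS"), names(seqs))
  seg <- lineage_segregation(phen, groups)
  expect_true(all(seg$monophyletic))
  expect_equal(seg$purity, c(1, 1))
})

test_that("a mislabeled leaf lowers clade purity", {
  set.seed(106)
  seqs <- c(
    t1 = mutate_protein(REFS$sequence[6], 0.05),
    t2 = mutate_protein(REFS$sequence[6], 0.05),
    m1 = mutate_protein(REFS$sequence[2], 0.05),
    m2 = mutate_protein(REFS$sequence[2], 0.05)
  )
  phen <- phenogram(seqs)
  wrong <- c(t1 = "T", t2 = "T", m1 = "T", m2 = "M")  # m1 mislabeled
  seg <- lineage_segregation(phen, wrong)
  expect_lt(seg$purity[seg$group == "T"], 1)
  single <- lineage_segregation(phen, c(t1 = "x", t2 = "x", m1 = "x", m2 = "x"))
  expect_true(single$monophyletic)
})

test_that("planted asymmetric divergence shows in the domain split", {
  set.seed(107)
  fhb <- REFS$sequence[REFS$type == "fHb"]
  glb <- substr(fhb, 1, 140)
  flav <- substr(fhb, 141, nchar(fhb))
  a <- paste0(mutate_protein(glb, 0.05), mutate_protein(flav, 0.3))
  ds <- domain_split_identity(fhb, a, type = "fHb")
  expect_gt(ds$globin_identity, ds$nonglobin_identity)
  # identical inputs: both domains at 100
  ds0 <- domain_split_identity(fhb, fhb, type = "fHb")
  expect_equal(ds0$globin_identity, 100)
  expect_equal(ds0$nonglobin_identity, 100)
  expect_error(domain_split_identity(REFS$sequence[2], REFS$sequence[2],
                                     type = "SDgb"), "multidomain")
})
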