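# Shared fixtures and independent oracles used across the test files.

REFS <- reference_globins()

# Exhaustive enumeration of all global alignments with affine gaps
# (gap run of length k costs open + k * extend). Independent of the DP
# implementation: plain recursion over alignment prefixes, no memoization.
brute_force_align_score <- function(a, b, sub = blosum62(), gap_open = 10,
                                    gap_extend = 0.5) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, sub[ac[i], bc[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      cost <- gap_extend + if (prev != "X") gap_open else 0
      best <- max(best, -cost + rec(i + 1, j, "X"))
    }
    if (j <= m) {
      cost <- gap_extend + if (prev != "Y") gap_open else 0
      best <- max(best, -cost + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "M")
}

random_aa <- function(n) {
  paste(sample(rhizoglob:::AA20, n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Uniformly random proper rotation matrix (QR of a Gaussian matrix).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# One-globin genome used by several closed-loop tests.
single_globin_genome <- function(seed, ref_id = "ref_sdgb_syn", rate = 0,
                                 strand = "+", promoters = NULL,
                                 neighbors = NULL, genome = "g") {
  generate_genome(genome_spec(
    seed = seed, n_scaffolds = 1, scaffold_length = 8000, genome = genome,
    plantings = list(globin_planting(ref_id, rate, strand = strand,
                                     start = 3000, promoters = promoters,
                                     neighbors = neighbors))
  ))
}
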