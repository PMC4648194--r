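# Percent-identity distances, UPGMA phenogram construction, Newick export,
# progressive multiple alignment along the guide tree, lineage segregation
# and per-domain conservation.

#' Percent identity of two proteins
#'
#' Identical aligned residue pairs over alignment columns where both
#' sequences are non-gap, times 100 (the default denominator; pass
#' `denominator = "shorter"` to divide by the shorter sequence length
#' instead).
#'
#' @inheritParams global_align
#' @param denominator "aligned" (both-non-gap columns, default) or
#'   "shorter".
#' @return Identity in \[0, 100\].
#' @export
percent_identity <- function(a, b, denominator = c("aligned", "shorter"),
                             matrix = blosum62(), gap_open = 10,
                             gap_extend = 0.5) {
  denominator <- match.arg(denominator)
  # canonicalize operand order: co-optimal alignments can differ between
  # (a, b) and (b, a), and identity must be symmetric
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  aln <- global_align(a, b, matrix, gap_open, gap_extend)
  if (denominator == "aligned") return(aln$percent_identity)
  both <- aln$a_idx > 0 & aln$b_idx > 0
  a_chr <- strsplit(aln$a_aln, "")[[1]]
  b_chr <- strsplit(aln$b_aln, "")[[1]]
  100 * sum(both & a_chr == b_chr) / min(nchar(a), nchar(b))
}

#' Pairwise percent-identity matrix
#'
#' @param seqs Named character vector of protein sequences.
#' @param ... Passed to [percent_identity()].
#' @return Symmetric matrix of identities (diagonal 100).
#' @export
identity_matrix <- function(seqs, ...) {
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- percent_identity(seqs[[i]], seqs[[j]], ...)
    }
  }
  m
}

#' UPGMA phenogram from a distance matrix
#'
#' Classic unweighted pair-group agglomeration: repeatedly merge the
#' minimum-distance pair (ties broken by the lexicographically smallest
#' label pair, labels compared by each cluster's smallest leaf label), set
#' the merge height to half the merge distance, and update distances as
#' size-weighted averages. The result is ultrametric: all leaves sit at
#' height 0 and every root-to-leaf path has the same length.
#'
#' @param d Symmetric distance matrix with row/column labels (or a `dist`).
#'   For identity-based phenograms use `100 - identity_matrix(seqs)`.
#' @return An object of class `rg_phenogram`: list with `tree` (an
#'   [ape::phylo]), `newick`, `labels`, `root_height` and the input
#'   distance matrix `d`.
#' @examples
#' d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)$newick
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  }
  if (n < 2) abort("upgma() needs at least 2 taxa")
  if (any(abs(d - t(d)) > 1e-9) || any(diag(d) != 0) || any(d < 0)) {
    abort("d must be a symmetric non-negative matrix with zero diagonal")
  }
  labels <- rownames(d)
  # active clusters: newick fragment, size, height, smallest member label
  cl <- lapply(labels, function(l) list(nwk = l, size = 1L, h = 0, min = l))
  D <- d
  while (length(cl) > 1) {
    m <- length(cl)
    best <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      key <- sort(c(cl[[i]]$min, cl[[j]]$min))
      if (is.null(best) || D[i, j] < best$d - 1e-12 ||
          (abs(D[i, j] - best$d) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = D[i, j], key = key)
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    new <- list(
      nwk = sprintf("(%s:%s,%s:%s)",
                    cl[[i]]$nwk, format(h - cl[[i]]$h, digits = 15),
                    cl[[j]]$nwk, format(h - cl[[j]]$h, digits = 15)),
      size = cl[[i]]$size + cl[[j]]$size, h = h,
      min = min(cl[[i]]$min, cl[[j]]$min)
    )
    # size-weighted average distances to the merged cluster, which takes
    # cluster i's slot (so child order in the newick follows input order)
    keep <- setdiff(seq_len(m), c(i, j))
    newd <- (cl[[i]]$size * D[i, keep] + cl[[j]]$size * D[j, keep]) /
      (cl[[i]]$size + cl[[j]]$size)
    D[i, keep] <- newd; D[keep, i] <- newd; D[i, i] <- 0
    D <- D[-j, -j, drop = FALSE]
    cl[[i]] <- new
    cl <- cl[-j]
  }
  nwk <- paste0(cl[[1]]$nwk, ";")
  tree <- ape::read.tree(text = nwk)
  structure(list(tree = tree, newick = nwk, labels = labels,
                 root_height = cl[[1]]$h, d = d),
            class = "rg_phenogram")
}

#' @export
print.rg_phenogram <- function(x, ...) {
  cat(sprintf("<rg_phenogram> %d leaves, root height %.3f\n",
              length(x$labels), x$root_height))
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Build a phenogram from protein sequences
#'
#' Computes the pairwise identity matrix, converts it to distances
#' `100 - identity` (no multiple-hit correction: this is a phenogram, not
#' a phylogeny) and runs [upgma()].
#'
#' @param seqs Named character vector of proteins.
#' @param ... Passed to [percent_identity()].
#' @return An `rg_phenogram`.
#' @export
phenogram <- function(seqs, ...) {
  upgma(100 - identity_matrix(seqs, ...))
}

#' Newick text for a phenogram
#'
#' @param x An `rg_phenogram` (or an [ape::phylo]).
#' @return Newick string with branch lengths.
#' @export
to_newick <- function(x) {
  if (inherits(x, "rg_phenogram")) return(x$newick)
  ape::write.tree(x)
}

#' Lineage segregation report
#'
#' For each group of leaves (family or lineage), reports whether the group
#' forms a connected subtree of the rooted phenogram (monophyly in the
#' phenetic sense) and the purity of the smallest clade covering it.
#'
#' @param x An `rg_phenogram` or [ape::phylo].
#' @param groups Named character vector: leaf label -> group.
#' @return Tibble with `group`, `n_leaves`, `clade_size`, `purity`,
#'   `monophyletic`.
#' @export
lineage_segregation <- function(x, groups) {
  tree <- if (inherits(x, "rg_phenogram")) x$tree else x
  if (!all(tree$tip.label %in% names(groups))) {
    abort("every leaf must be assigned a group")
  }
  bind_rows(lapply(unique(groups[tree$tip.label]), function(g) {
    tips <- tree$tip.label[groups[tree$tip.label] == g]
    if (length(tips) == 1) {
      return(tibble(group = g, n_leaves = 1L, clade_size = 1L,
                    purity = 1, monophyletic = TRUE))
    }
    mrca <- ape::getMRCA(tree, tips)
    clade <- ape::extract.clade(tree, mrca)$tip.label
    tibble(group = g, n_leaves = length(tips),
           clade_size = length(clade),
           purity = length(tips) / length(clade),
           monophyletic = length(clade) == length(tips))
  }))
}

# ---- progressive multiple alignment -------------------------------------

profile_freq <- function(prof, alphabet) {
  # prof: character matrix (rows sequences, cols alignment columns)
  f <- matrix(0, length(alphabet), ncol(prof))
  for (i in seq_len(nrow(prof))) {
    idx <- match(prof[i, ], alphabet)
    ok <- !is.na(idx)
    f[cbind(idx[ok], which(ok))] <- f[cbind(idx[ok], which(ok))] + 1
  }
  cnt <- colSums(f)
  cnt[cnt == 0] <- 1
  sweep(f, 2, cnt, "/")
}

align_profiles <- function(pa, pb, sub, gap_open, gap_extend) {
  alphabet <- rownames(sub)
  S <- t(profile_freq(pa, alphabet)) %*% sub %*% profile_freq(pb, alphabet)
  res <- gotoh_traceback_mat(S, gap_open, gap_extend)
  ncols <- length(res$a_idx)
  out <- matrix("-", nrow(pa) + nrow(pb), ncols)
  rownames(out) <- c(rownames(pa), rownames(pb))
  for (k in seq_len(ncols)) {
    if (res$a_idx[k] > 0) out[seq_len(nrow(pa)), k] <- pa[, res$a_idx[k]]
    if (res$b_idx[k] > 0) out[nrow(pa) + seq_len(nrow(pb)), k] <- pb[, res$b_idx[k]]
  }
  out
}

#' Progressive multiple sequence alignment along a guide tree
#'
#' Profile-profile global alignment (same scoring model and tie-breaks as
#' [global_align()], with column scores as frequency-weighted mean
#' substitution scores) applied bottom-up in guide-tree merge order.
#' Columns are never reordered and every input residue is preserved; for
#' two sequences the result equals the pairwise global alignment.
#'
#' @param seqs Named character vector of proteins.
#' @param guide An `rg_phenogram` or [ape::phylo] whose leaves are exactly
#'   `names(seqs)`; by default a UPGMA guide is built from `seqs`.
#' @inheritParams global_align
#' @return Named character vector of gapped rows (the alignment), with
#'   attribute `width`.
#' @export
progressive_msa <- function(seqs, guide = NULL, matrix = blosum62(),
                            gap_open = 10, gap_extend = 0.5) {
  if (is.null(names(seqs))) abort("seqs must be named")
  if (length(seqs) == 1) {
    return(structure(seqs, width = nchar(seqs[[1]])))
  }
  if (is.null(guide)) guide <- phenogram(seqs, matrix = matrix,
                                         gap_open = gap_open,
                                         gap_extend = gap_extend)
  tree <- if (inherits(guide, "rg_phenogram")) guide$tree else guide
  if (!setequal(tree$tip.label, names(seqs))) {
    abort("guide tree leaves must match sequence names")
  }
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  build <- function(node) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
      m <- matrix(strsplit(seqs[[lab]], "")[[1]], nrow = 1)
      rownames(m) <- lab
      return(m)
    }
    kids <- children[[as.character(node)]]
    prof <- build(kids[1])
    for (k in kids[-1]) {
      prof <- align_profiles(prof, build(k), matrix, gap_open, gap_extend)
    }
    prof
  }
  prof <- build(ntip + 1L)
  out <- apply(prof, 1, paste, collapse = "")
  structure(out[names(seqs)], width = ncol(prof))
}

#' Per-domain identity of two multidomain globins
#'
#' For a pair of flavohemoglobins or globin-coupled sensors, locates the
#' N-terminal globin domain boundary in each sequence by aligning it to the
#' single-domain globin reference, then reports percent identity separately
#' for the globin segments and the remaining (flavin or transmitter)
#' segments.
#'
#' @param a,b Protein sequences of the same multidomain type.
#' @param type "fHb" or "GCS" (single-domain types are rejected).
#' @param refs Reference set (the SDgb entry anchors the boundary).
#' @param z_threshold Minimum permutation Z for the globin-domain anchor
#'   alignment; below it the boundary is declared not locatable.
#' @param n_shuffles Permutations for the anchor Z.
#' @return One-row tibble: `globin_identity`, `nonglobin_identity`,
#'   `boundary_a`, `boundary_b`.
#' @export
domain_split_identity <- function(a, b, type = c("fHb", "GCS"),
                                  refs = reference_globins(),
                                  z_threshold = 6, n_shuffles = 100) {
  type <- tryCatch(match.arg(type),
                   error = function(e) abort(
                     "domain_split_identity() applies to multidomain types (fHb, GCS)"))
  sdgb <- refs$sequence[refs$type == "SDgb"][1]
  boundary <- function(seq, what) {
    z <- alignment_zscore(seq, sdgb, n_shuffles = n_shuffles)
    if (!is.finite(z$z) || z$z <= z_threshold) {
      abort(sprintf("globin-domain boundary not locatable in %s (z = %.2f)",
                    what, z$z))
    }
    # fitting alignment: the single-domain reference sits inside the
    # multidomain query with free query tails
    aln <- global_align(seq, sdgb, free_a_ends = TRUE)
    max(aln$a_idx[aln$b_idx > 0 & aln$a_idx > 0])
  }
  ba <- boundary(a, "sequence a")
  bb <- boundary(b, "sequence b")
  if (ba >= nchar(a) || bb >= nchar(b)) {
    abort("no non-globin segment: sequences look single-domain")
  }
  tibble(
    globin_identity = percent_identity(substr(a, 1, ba), substr(b, 1, bb)),
    nonglobin_identity = percent_identity(substr(a, ba + 1, nchar(a)),
                                          substr(b, bb + 1, nchar(b))),
    boundary_a = ba, boundary_b = bb
  )
}
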