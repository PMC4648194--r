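# Global affine-gap alignment (Gotoh) and the permutation Z score used to
# accept globin candidates.

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh global alignment. A gap run of length `k` costs
#' `gap_open + k * gap_extend`. The traceback is deterministic: on ties the
#' diagonal move is preferred over the vertical ("up", gap in `b`) over the
#' horizontal ("left", gap in `a`).
#'
#' @param a,b Amino-acid strings (non-empty).
#' @param matrix Substitution matrix; defaults to [blosum62()].
#' @param gap_open,gap_extend Gap penalties (positive numbers).
#' @param free_a_ends Make leading/trailing gaps in `b` free (a fitting
#'   alignment of `b` within `a`, e.g. a single-domain reference within a
#'   multidomain query). Default FALSE: true global alignment.
#' @return An object of class `rg_alignment`: a list with `score`, the
#'   aligned index vectors `a_idx`/`b_idx` (1-based, `0` marks a gap), the
#'   gapped alignment strings `a_aln`/`b_aln`, `percent_identity` (identical
#'   pairs over columns where both rows are non-gap, times 100), and
#'   `n_columns`.
#' @examples
#' global_align("HEALTH", "HEALTH")$percent_identity
#' @export
global_align <- function(a, b, matrix = blosum62(), gap_open = 10,
                         gap_extend = 0.5, free_a_ends = FALSE) {
  if (!nzchar(a) || !nzchar(b)) abort("global_align() requires non-empty sequences")
  ai <- aa_encode(a, rownames(matrix), "sequence a")
  bi <- aa_encode(b, rownames(matrix), "sequence b")
  S <- matrix[ai, bi, drop = FALSE]
  res <- gotoh_traceback_mat(S, gap_open, gap_extend, free_a_ends)
  a_chr <- strsplit(toupper(a), "")[[1]]
  b_chr <- strsplit(toupper(b), "")[[1]]
  a_aln <- ifelse(res$a_idx == 0, "-", a_chr[pmax(res$a_idx, 1)])
  b_aln <- ifelse(res$b_idx == 0, "-", b_chr[pmax(res$b_idx, 1)])
  both <- res$a_idx > 0 & res$b_idx > 0
  n_ident <- sum(both & a_aln == b_aln)
  structure(
    list(
      score = res$score,
      a_idx = res$a_idx, b_idx = res$b_idx,
      a_aln = paste(a_aln, collapse = ""),
      b_aln = paste(b_aln, collapse = ""),
      percent_identity = if (sum(both) > 0) 100 * n_ident / sum(both) else NA_real_,
      n_columns = length(res$a_idx)
    ),
    class = "rg_alignment"
  )
}

#' @export
print.rg_alignment <- function(x, ...) {
  cat(sprintf("<rg_alignment> score %.1f, %d columns, %.1f%% identity\n",
              x$score, x$n_columns, x$percent_identity))
  invisible(x)
}

#' Alignment score only (no traceback)
#'
#' Fast path used by the permutation null; identical scoring model to
#' [global_align()].
#'
#' @inheritParams global_align
#' @return Numeric score.
#' @export
align_score <- function(a, b, matrix = blosum62(), gap_open = 10,
                        gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) abort("align_score() requires non-empty sequences")
  gotoh_score_int(aa_encode(a, rownames(matrix), "sequence a"),
                  aa_encode(b, rownames(matrix), "sequence b"),
                  matrix, gap_open, gap_extend)
}

#' Permutation Z score of an alignment
#'
#' Standardizes the query-versus-reference global alignment score against a
#' null of uniformly shuffled query sequences:
#' `z = (score - mean(null)) / sd(null)`. This plays the role of a
#' structure-profile significance score in the acceptance rule `z > 6`.
#'
#' @param query Amino-acid string.
#' @param ref Reference amino-acid string.
#' @param n_shuffles Number of residue permutations (at least 50).
#' @param seed Optional integer; when supplied the RNG state is set locally
#'   and restored, so results are reproducible per seed.
#' @inheritParams global_align
#' @return A list with `z`, `score`, `null_mean`, `null_sd` and the logical
#'   `degenerate` (TRUE when the null sd is 0, in which case `z` is `+Inf`
#'   and a warning is raised).
#' @export
alignment_zscore <- function(query, ref, n_shuffles = 100, seed = NULL,
                             matrix = blosum62(), gap_open = 10,
                             gap_extend = 0.5) {
  if (n_shuffles < 50) {
    abort("n_shuffles must be at least 50 for a stable permutation null")
  }
  qi <- aa_encode(query, rownames(matrix), "query")
  ri <- aa_encode(ref, rownames(matrix), "reference")
  run <- function() {
    obs <- gotoh_score_int(qi, ri, matrix, gap_open, gap_extend)
    null <- shuffled_scores_int(qi, ri, matrix, gap_open, gap_extend,
                                as.integer(n_shuffles))
    list(obs = obs, null = null)
  }
  r <- if (is.null(seed)) run() else with_preserved_seed(seed, run())
  mu <- mean(r$null)
  s <- sd(r$null)
  degenerate <- !is.finite(s) || s == 0
  if (degenerate) {
    warn("degenerate permutation null (sd = 0); reporting z = +Inf")
    z <- Inf
  } else {
    z <- (r$obs - mu) / s
  }
  list(z = z, score = r$obs, null_mean = mu, null_sd = s,
       degenerate = degenerate)
}

# Evaluate `expr` under a locally seeded RNG, restoring the caller's state.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Map a reference fold position onto the query
#'
#' Given an alignment produced by `global_align(query, ref)` and a 1-based
#' residue index in the reference, returns the query residue index aligned
#' to that reference column, or `NA` when the reference column is aligned
#' to a gap.
#'
#' @param alignment An `rg_alignment` from [global_align()] with the query
#'   as `a` and the reference as `b`.
#' @param ref_index 1-based residue index in the reference.
#' @return Integer query index, or `NA_integer_` for a gap.
#' @export
map_fold_position <- function(alignment, ref_index) {
  stopifnot(inherits(alignment, "rg_alignment"))
  ref_len <- max(alignment$b_idx)
  if (ref_index < 1 || ref_index > ref_len) {
    abort(sprintf("ref_index %d out of range 1..%d", ref_index, ref_len))
  }
  col <- which(alignment$b_idx == ref_index)
  qi <- alignment$a_idx[col]
  if (qi == 0) NA_integer_ else qi
}
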