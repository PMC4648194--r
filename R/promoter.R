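# Strand-aware 130-nt upstream windows and mismatch-tolerant scanning for
# -10 / -35 / Fnr / Shine-Dalgarno elements, reported Table-2-style with
# case-coded match strings and signed positions (-1 is the nucleotide
# immediately 5' of the start codon).

#' Default motif definitions
#'
#' The four consensus elements scanned upstream of globin genes: the
#' canonical -10 (TATAAT) and -35 (TTGACA) boxes and the Fnr box
#' (TTTAAGAGGCCAAT), matched full-length with a mismatch budget, and the
#' Shine-Dalgarno consensus (AGGAGG) matched by maximal exact substrings.
#'
#' @param canonical_max_mm Mismatch budget for -10/-35 (default 1).
#' @param fnr_max_mm Mismatch budget for the 14-nt Fnr box (default 5,
#'   i.e. at least 9/14 identities).
#' @param sd_min_len Minimum exact Shine-Dalgarno substring (default 3 nt).
#' @return Tibble with columns `motif`, `consensus`, `mode`,
#'   `max_mismatches`, `min_match_len`.
#' @export
motif_definitions <- function(canonical_max_mm = 1, fnr_max_mm = 5,
                              sd_min_len = 3) {
  tibble(
    motif = c("-10", "-35", "Fnr", "SD"),
    consensus = unname(MOTIF_CONSENSUS[c("-10", "-35", "Fnr", "SD")]),
    mode = c("hamming", "hamming", "hamming", "partial"),
    max_mismatches = c(canonical_max_mm, canonical_max_mm, fnr_max_mm, NA),
    min_match_len = c(NA, NA, NA, sd_min_len)
  )
}

#' Extract the upstream window of a gene
#'
#' Coding-strand nucleotides immediately 5' of the start codon: for a +
#' strand gene, `scaffold[start - window .. start - 1]`; for a - strand
#' gene, the reverse complement of `scaffold[end + 1 .. end + window]`.
#' Truncated (with a flag) when the scaffold edge is nearer than `window`.
#'
#' @param gene One-row data frame (or list) with `gene_id`, `start`, `end`,
#'   `strand`.
#' @param scaffold Scaffold nucleotide string.
#' @param window Window width in nt (default 130).
#' @return One-row tibble: `gene_id`, `sequence`, `width`, `truncated`.
#' @export
upstream_region <- function(gene, scaffold, window = 130) {
  L <- nchar(scaffold)
  if (gene$start < 1 || gene$end > L || gene$start > gene$end) {
    abort(sprintf("gene %s does not lie on the scaffold", gene$gene_id))
  }
  if (gene$strand == "+") {
    from <- max(1L, gene$start - as.integer(window))
    to <- gene$start - 1L
    seq <- if (to >= from) substr(scaffold, from, to) else ""
  } else {
    from <- gene$end + 1L
    to <- min(L, gene$end + as.integer(window))
    seq <- if (to >= from) revcomp(substr(scaffold, from, to)) else ""
  }
  tibble(gene_id = gene$gene_id, sequence = seq, width = nchar(seq),
         truncated = nchar(seq) < window)
}

#' Case-code an observed motif against its consensus
#'
#' Position i is uppercase iff the observed base equals the consensus base,
#' else the observed base in lowercase — the Table-2 convention for showing
#' identical and non-identical nucleotides.
#'
#' @param consensus,observed Equal-length nucleotide strings.
#' @return Case-coded string.
#' @examples
#' case_code("TTTAAGAGGCCAAT", "TCTAAGCGACTGAT")
#' @export
case_code <- function(consensus, observed) {
  if (nchar(consensus) != nchar(observed)) {
    abort("consensus and observed must have equal length")
  }
  co <- strsplit(toupper(consensus), "")[[1]]
  ob <- strsplit(toupper(observed), "")[[1]]
  paste(ifelse(ob == co, ob, tolower(ob)), collapse = "")
}

empty_hits <- function() {
  tibble(gene_id = character(), motif = character(), near = integer(),
         far = integer(), position = character(), matched = character(),
         n_identical = integer(), n_mismatch = integer(), primary = logical())
}

# Signed offsets of a placement covering window indices i..i+k-1 in a
# window of width W: index j corresponds to offset j - W - 1.
hit_row <- function(gene_id, motif, W, i, k, matched, n_mismatch) {
  far <- i - W - 1L
  near <- i + k - 1L - W - 1L
  tibble(gene_id = gene_id, motif = motif, near = as.integer(near),
         far = as.integer(far),
         position = sprintf("%d to %d", near, far),
         matched = matched, n_identical = as.integer(k - n_mismatch),
         n_mismatch = as.integer(n_mismatch), primary = NA)
}

#' Full-length Hamming scan of a motif over an upstream window
#'
#' Every placement of the full consensus with at most `max_mismatches`
#' mismatches, each reported with signed near/far offsets and a case-coded
#' match string. The best hit (fewest mismatches, then nearest to the
#' gene) is flagged `primary`.
#'
#' @param window One-row tibble from [upstream_region()] (or a plain
#'   nucleotide string).
#' @param consensus Motif consensus string.
#' @param max_mismatches Mismatch budget.
#' @param motif Motif name for the report.
#' @param gene_id Gene label (taken from `window` when it is a tibble).
#' @return Tibble of hits (possibly empty), columns as in the Table-2-style
#'   report.
#' @export
scan_hamming <- function(window, consensus, max_mismatches = 0,
                         motif = "motif", gene_id = NULL) {
  w <- if (is.data.frame(window)) window$sequence else window
  gene_id <- gene_id %||% (if (is.data.frame(window)) window$gene_id else "gene")
  W <- nchar(w); k <- nchar(consensus)
  if (W < k) return(empty_hits())
  wc <- strsplit(toupper(w), "")[[1]]
  cc <- strsplit(toupper(consensus), "")[[1]]
  starts <- seq_len(W - k + 1)
  idx <- outer(0:(k - 1), starts, `+`)
  mm <- colSums(matrix(wc[idx], nrow = k) != cc)
  keep <- which(mm <= max_mismatches)
  if (length(keep) == 0) return(empty_hits())
  hits <- bind_rows(lapply(keep, function(i) {
    obs <- substr(w, i, i + k - 1)
    hit_row(gene_id, motif, W, i, k, case_code(consensus, obs), mm[i])
  }))
  rank_hits(hits)
}

#' Maximal exact partial matches of a motif (Shine-Dalgarno mode)
#'
#' Maximal exact substring matches of the consensus within the window with
#' length at least `min_match_len`, reported nearest-to-gene first. Used
#' for the Shine-Dalgarno element, whose reported hits are often shorter
#' than the 6-nt consensus.
#'
#' @inheritParams scan_hamming
#' @param min_match_len Minimum exact match length (>= 3).
#' @return Tibble of hits (possibly empty).
#' @export
scan_partial <- function(window, consensus, min_match_len = 3,
                         motif = "SD", gene_id = NULL) {
  if (min_match_len < 3) abort("min_match_len must be at least 3")
  w <- if (is.data.frame(window)) window$sequence else window
  gene_id <- gene_id %||% (if (is.data.frame(window)) window$gene_id else "gene")
  W <- nchar(w); k <- nchar(consensus)
  if (W == 0) return(empty_hits())
  wc <- strsplit(toupper(w), "")[[1]]
  cc <- strsplit(toupper(consensus), "")[[1]]
  spans <- list()
  for (p in seq_len(W)) {
    for (c0 in seq_len(k)) {
      if (wc[p] != cc[c0]) next
      # maximal: not extendable to the left
      if (p > 1 && c0 > 1 && wc[p - 1] == cc[c0 - 1]) next
      len <- 0
      while (p + len <= W && c0 + len <= k && wc[p + len] == cc[c0 + len]) {
        len <- len + 1
      }
      if (len >= min_match_len) {
        spans[[length(spans) + 1]] <- c(p, len)
      }
    }
  }
  if (length(spans) == 0) return(empty_hits())
  spans <- unique(do.call(rbind, spans))
  # drop spans fully contained in another kept span
  contained <- vapply(seq_len(nrow(spans)), function(i) {
    any(vapply(seq_len(nrow(spans)), function(j) {
      j != i && spans[j, 1] <= spans[i, 1] &&
        spans[j, 1] + spans[j, 2] >= spans[i, 1] + spans[i, 2] &&
        spans[j, 2] > spans[i, 2]
    }, logical(1)))
  }, logical(1))
  spans <- spans[!contained, , drop = FALSE]
  hits <- bind_rows(lapply(seq_len(nrow(spans)), function(i) {
    p <- spans[i, 1]; len <- spans[i, 2]
    obs <- substr(w, p, p + len - 1)
    hit_row(gene_id, motif, W, p, len, toupper(obs), 0)
  }))
  rank_hits(hits)
}

# Order hits by (mismatches, proximity to the gene) and flag the first as
# primary.
rank_hits <- function(hits) {
  hits <- hits |> arrange(.data$n_mismatch, abs(.data$near))
  hits$primary <- seq_len(nrow(hits)) == 1
  hits
}

#' Scan the upstream windows of a gene table for all motifs
#'
#' @param genes Tibble with `gene_id`, `scaffold_id`, `start`, `end`,
#'   `strand`.
#' @param scaffolds Named character vector of scaffold sequences (or an
#'   `rg_genome`).
#' @param window Upstream window width (default 130 nt).
#' @param motifs Motif definition tibble from [motif_definitions()].
#' @return Long tibble of hits across genes and motifs.
#' @export
scan_promoters <- function(genes, scaffolds, window = 130,
                           motifs = motif_definitions()) {
  if (inherits(scaffolds, "rg_genome")) scaffolds <- scaffolds$scaffolds
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (!g$scaffold_id %in% names(scaffolds)) {
      abort(sprintf("scaffold '%s' not found for gene %s", g$scaffold_id,
                    g$gene_id))
    }
    win <- upstream_region(g, scaffolds[[g$scaffold_id]], window)
    bind_rows(lapply(seq_len(nrow(motifs)), function(m) {
      md <- motifs[m, ]
      if (md$mode == "hamming") {
        scan_hamming(win, md$consensus, md$max_mismatches, motif = md$motif)
      } else {
        scan_partial(win, md$consensus, md$min_match_len, motif = md$motif)
      }
    }))
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) empty_hits() else res
}

#' Table-2-style promoter report
#'
#' One row per gene with the primary -10, -35 and Shine-Dalgarno positions
#' and the Fnr hit (case-coded sequence plus position); genes with several
#' Fnr hits get one continuation row per extra hit, and absent elements are
#' rendered "N.D.".
#'
#' @param hits Long hit tibble from [scan_promoters()].
#' @param gene_ids Genes to report (default: those present in `hits`);
#'   pass the full gene list so motif-free genes still get an all-"N.D."
#'   row.
#' @return Tibble with columns `gene_id`, `p10`, `p35`, `fnr_sequence`,
#'   `fnr_position`, `sd`.
#' @export
promoter_report <- function(hits, gene_ids = unique(hits$gene_id)) {
  rows <- lapply(gene_ids, function(g) {
    h <- hits[hits$gene_id == g, ]
    pos_of <- function(m) {
      x <- h[h$motif == m & h$primary, ]
      if (nrow(x) == 0) "N.D." else x$position[1]
    }
    fnr <- h[h$motif == "Fnr", ] |> arrange(.data$n_mismatch, abs(.data$near))
    n_fnr <- max(1L, nrow(fnr))
    tibble(
      gene_id = c(g, rep("", n_fnr - 1L)),
      p10 = c(pos_of("-10"), rep("", n_fnr - 1L)),
      p35 = c(pos_of("-35"), rep("", n_fnr - 1L)),
      fnr_sequence = if (nrow(fnr) == 0) "N.D." else fnr$matched,
      fnr_position = if (nrow(fnr) == 0) "" else fnr$position,
      sd = c(pos_of("SD"), rep("", n_fnr - 1L))
    )
  })
  if (length(rows) == 0) {
    return(tibble(gene_id = character(), p10 = character(), p35 = character(),
                  fnr_sequence = character(), fnr_position = character(),
                  sd = character()))
  }
  bind_rows(rows)
}
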