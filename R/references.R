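# The packaged reference globin set.
#
# The classifier needs eight reference queries spanning the M, S and T
# globin families (fHb, SDgb, GCS, protoglobin, sensor single-domain globin,
# and truncated hemoglobin classes 1-3). This package ships a SYNTHETIC
# stand-in reference set, generated deterministically below: each reference
# has the family's domain architecture (single globin domain, or globin
# domain fused N-terminally to a flavin-reductase-sized or transmitter-sized
# segment), lengths anchored to the family averages (fHb ~400 aa, SDgb ~141,
# GCS ~510, tHb ~130-150), and the conserved myoglobin-fold pocket residues
# (proximal His at F8, distal Gln at E7 in 3/3 references, Tyr B10, Phe CD1).
# M/S-family globin domains descend from one shared 3/3 template and T-family
# references from an unrelated 2/2 template, so the two-lineage structure of
# bacterial globins is preserved. Users can substitute real reference
# sequences via `read_reference_set()`.

# Residue sampling weights loosely matching globin composition (helix
# formers enriched).
.AA_WEIGHTS <- c(
  A = 9, R = 4, N = 4, D = 5, C = 1, Q = 4, E = 6, G = 7, H = 2, I = 5,
  L = 10, K = 6, M = 2, F = 4, P = 4, S = 6, T = 5, W = 1, V = 7, Y = 3
)

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE, prob = .AA_WEIGHTS[AA20]),
        collapse = "")
}

set_residues <- function(seq, at) {
  for (i in seq_along(at)) substr(seq, at[[i]], at[[i]]) <- names(at)[i]
  seq
}

#' The packaged reference globin set (synthetic)
#'
#' Returns the eight-reference query set used by [classify_globin()]:
#' one flavohemoglobin (fHb), one single-domain globin (SDgb), one
#' globin-coupled sensor (GCS), one protoglobin, one sensor single-domain
#' globin (SSDgb) and one truncated hemoglobin (tHb) per class 1/2/3.
#' The shipped sequences are synthetic stand-ins constructed with the
#' families' domain architectures and conserved fold residues (see the
#' package vignette); supply real sequences with [read_reference_set()] to
#' reproduce a database study.
#'
#' @return A tibble with columns `id`, `family` ("M", "S" or "T"), `type`
#'   (fHb, SDgb, GCS, protoglobin, SSDgb, tHb1, tHb2, tHb3), `thb_class`
#'   (1/2/3 or NA), `sequence`, and the 1-based fold-position columns
#'   `f8`, `e7`, `b10`, `cd1`. The residue at `f8` is His for every
#'   reference.
#' @export
reference_globins <- function() {
  if (!is.null(.rg_cache$refs)) return(.rg_cache$refs)
  refs <- with_preserved_seed(101, build_reference_set())
  .rg_cache$refs <- refs
  refs
}

build_reference_set <- function() {
  # 3/3 globin-domain template (M/S families) and an unrelated 2/2
  # template (T family). Fold positions are fixed template indices.
  fold33 <- c(Y = 30L, F = 42L, Q = 62L, H = 88L)   # B10, CD1, E7, F8
  fold22 <- c(Y = 24L, F = 36L, H = 52L, H = 76L)
  core33 <- set_residues(random_protein(141), fold33)
  core22 <- set_residues(random_protein(130), fold22)
  protect33 <- unname(fold33)
  protect22 <- unname(fold22)

  diverge <- function(core, rate, protect) {
    mutate_protein(core, rate, seed = NULL, protect = protect)
  }

  glb_fhb <- substr(diverge(core33, 0.25, protect33), 1, 140)
  glb_gcs <- diverge(core33, 0.25, protect33)
  refs <- tibble::tribble(
    ~id, ~family, ~type, ~thb_class, ~sequence,
    "ref_fhb_syn",  "M", "fHb",  NA_integer_,
      paste0(glb_fhb, random_protein(260)),
    "ref_sdgb_syn", "M", "SDgb", NA_integer_,
      diverge(core33, 0.20, protect33),
    "ref_gcs_syn",  "S", "GCS",  NA_integer_,
      paste0(glb_gcs, random_protein(369)),
    "ref_protoglobin_syn", "S", "protoglobin", NA_integer_,
      paste0(random_protein(55), diverge(core33, 0.45, protect33)),
    "ref_ssdgb_syn", "S", "SSDgb", NA_integer_,
      diverge(core33, 0.40, protect33),
    "ref_thb1_syn", "T", "tHb1", 1L, diverge(core22, 0.30, protect22),
    "ref_thb2_syn", "T", "tHb2", 2L, diverge(core22, 0.30, protect22),
    "ref_thb3_syn", "T", "tHb3", 3L, diverge(core22, 0.30, protect22)
  )
  offset <- c(rep(0L, 3), 55L, 0L, 0L, 0L, 0L)
  is33 <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  pos <- function(k) ifelse(is33, unname(fold33[k]), unname(fold22[k])) + offset
  refs$b10 <- as.integer(pos(1))
  refs$cd1 <- as.integer(pos(2))
  refs$e7  <- as.integer(pos(3))
  refs$f8  <- as.integer(pos(4))
  stopifnot(all(substr(refs$sequence, refs$f8, refs$f8) == "H"))
  refs
}

#' Read a user-supplied reference set
#'
#' Loads reference globins from an amino-acid FASTA plus a fold-position
#' table, in the shape returned by [reference_globins()].
#'
#' @param fasta Path to an amino-acid FASTA; record ids must match `id` in
#'   the metadata table.
#' @param meta Path to a TSV with columns `id`, `family`, `type`,
#'   `thb_class`, `f8`, `e7`, `b10`, `cd1`.
#' @return A tibble as in [reference_globins()].
#' @export
read_reference_set <- function(fasta, meta) {
  seqs <- read_fasta(fasta)
  m <- readr::read_tsv(meta, show_col_types = FALSE)
  out <- dplyr::left_join(m, seqs, by = "id")
  if (anyNA(out$sequence)) {
    abort(sprintf("reference id(s) missing from FASTA: %s",
                  paste(out$id[is.na(out$sequence)], collapse = ", ")))
  }
  bad <- substr(out$sequence, out$f8, out$f8) != "H"
  if (any(bad)) {
    abort(sprintf("reference(s) without His at the stated F8 position: %s",
                  paste(out$id[bad], collapse = ", ")))
  }
  tibble::as_tibble(out)
}

#' Write the packaged reference set to FASTA (+ metadata TSV)
#'
#' @param fasta Output FASTA path.
#' @param meta Optional output TSV path for the fold-position metadata.
#' @return Invisibly, the reference tibble.
#' @export
write_reference_set <- function(fasta, meta = NULL) {
  refs <- reference_globins()
  write_fasta(setNames(refs$sequence, refs$id), fasta, type = "AA")
  if (!is.null(meta)) {
    readr::write_tsv(refs[, c("id", "family", "type", "thb_class",
                              "f8", "e7", "b10", "cd1")], meta)
  }
  invisible(refs)
}
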