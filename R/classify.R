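# Globin classification: permutation-Z scoring against the reference set,
# the three acceptance criteria, family/type assignment and fold-position
# mapping.

#' Classification thresholds and scoring parameters
#'
#' @param min_len_aa Length acceptance floor in residues (default 100; the
#'   "~100 amino acids" criterion implemented as `>= 100`).
#' @param z_threshold Permutation-Z acceptance threshold (default 6). The
#'   permutation Z emulates a structure-profile significance score; the
#'   default is retained from the published rule but the two scales differ,
#'   so it is exposed here.
#' @param n_shuffles Permutations per query/reference pair (minimum 50).
#' @param t_fhb Architecture threshold in residues: a single-domain M-family
#'   best match of at least this length is called fHb (default 300,
#'   bracketing the ~400 aa fHb vs ~141 aa SDgb averages).
#' @param t_gcs Architecture threshold for calling GCS from a single-domain
#'   S-family best match (default 350, vs the ~510 aa GCS average).
#' @param accept_gcs_glu_f8 Accept Glu at F8 for GCS calls (flagged as a
#'   possible alignment artifact) instead of rejecting (default TRUE).
#' @param gap_open,gap_extend Alignment gap penalties.
#' @return A named list of thresholds.
#' @export
globin_thresholds <- function(min_len_aa = 100, z_threshold = 6,
                              n_shuffles = 100, t_fhb = 300, t_gcs = 350,
                              accept_gcs_glu_f8 = TRUE,
                              gap_open = 10, gap_extend = 0.5) {
  list(min_len_aa = min_len_aa, z_threshold = z_threshold,
       n_shuffles = n_shuffles, t_fhb = t_fhb, t_gcs = t_gcs,
       accept_gcs_glu_f8 = accept_gcs_glu_f8,
       gap_open = gap_open, gap_extend = gap_extend)
}

# Lowercase gene-style label used in tallies (thb classes collapse to thb).
glb_label <- function(type) {
  dplyr::case_match(type,
    "fHb" ~ "fhb", "SDgb" ~ "sdgb", "GCS" ~ "gcs",
    c("tHb1", "tHb2", "tHb3") ~ "thb",
    "protoglobin" ~ "protoglobin", "SSDgb" ~ "ssdgb"
  )
}

#' Classify one protein against the reference globins
#'
#' Scores the query against every reference with the permutation Z on the
#' global alignment score, picks the best reference (highest Z; ties broken
#' by percent identity, then reference order), inherits family/type/class
#' from it (refined by domain architecture: long single-domain M matches
#' become fHb, long single-domain S matches become GCS), maps the
#' myoglobin-fold pocket positions F8/E7/B10/CD1 onto the query, and
#' applies the three acceptance criteria: length >= `min_len_aa`,
#' Z > `z_threshold`, and His at the mapped F8 (Glu tolerated for GCS calls
#' when `accept_gcs_glu_f8`, flagged in `f8_artifact`).
#'
#' @param protein Amino-acid string.
#' @param refs Reference tibble as from [reference_globins()].
#' @param thresholds See [globin_thresholds()].
#' @param gene_id Label for the output row.
#' @return A one-row tibble (the globin call): best reference, family,
#'   type, tHb class, label, score, `z`, percent identity, length, mass
#'   (kDa), key-residue assignments, the three flags and `accepted`.
#' @export
classify_globin <- function(protein, refs = reference_globins(),
                            thresholds = globin_thresholds(),
                            gene_id = "query") {
  stopifnot(nrow(refs) > 0)
  th <- modifyList(globin_thresholds(), thresholds)
  zs <- vapply(refs$sequence, function(rs) {
    r <- alignment_zscore(protein, rs, n_shuffles = th$n_shuffles,
                          gap_open = th$gap_open, gap_extend = th$gap_extend)
    c(r$z, r$score)
  }, numeric(2), USE.NAMES = FALSE)
  z <- zs[1, ]; raw <- zs[2, ]
  best <- which(z == max(z))
  if (length(best) > 1) {
    pid <- vapply(best, function(i) {
      global_align(protein, refs$sequence[i], gap_open = th$gap_open,
                   gap_extend = th$gap_extend)$percent_identity
    }, numeric(1))
    best <- best[order(-pid)][1]
  }
  ref <- refs[best, ]
  aln <- global_align(protein, ref$sequence, gap_open = th$gap_open,
                      gap_extend = th$gap_extend)
  len <- nchar(protein)

  key <- lapply(c(f8 = "f8", e7 = "e7", b10 = "b10", cd1 = "cd1"), function(k) {
    qi <- map_fold_position(aln, ref[[k]])
    list(idx = qi,
         res = if (is.na(qi)) NA_character_ else substr(protein, qi, qi))
  })

  type <- ref$type
  family <- ref$family
  if (type == "SDgb" && len >= th$t_fhb) {
    type <- "fHb"
  } else if (type %in% c("SSDgb", "protoglobin") && len >= th$t_gcs) {
    type <- "GCS"; family <- "S"
  }

  length_ok <- len >= th$min_len_aa
  z_ok <- z[best] > th$z_threshold
  f8_res <- key$f8$res
  f8_artifact <- identical(f8_res, "E") && type == "GCS"
  f8_his_ok <- identical(f8_res, "H") ||
    (f8_artifact && isTRUE(th$accept_gcs_glu_f8))

  tibble(
    gene_id = gene_id, best_reference = ref$id, family = family, type = type,
    thb_class = ref$thb_class, glb = glb_label(type),
    alignment_score = raw[best], z_score = z[best],
    percent_identity = aln$percent_identity,
    length_aa = len, mass_kda = protein_mass_kda(protein),
    f8_res = key$f8$res, f8_idx = key$f8$idx %||% NA_integer_,
    e7_res = key$e7$res, e7_idx = key$e7$idx %||% NA_integer_,
    b10_res = key$b10$res, b10_idx = key$b10$idx %||% NA_integer_,
    cd1_res = key$cd1$res, cd1_idx = key$cd1$idx %||% NA_integer_,
    length_ok = length_ok, z_ok = z_ok, f8_his_ok = f8_his_ok,
    f8_artifact = f8_artifact,
    accepted = length_ok && z_ok && f8_his_ok
  )
}

#' Classify a table of genes
#'
#' Data-frame-first wrapper around [classify_globin()]: classifies every
#' row of `genes` (e.g. the output of [extract_orfs_all()]) and returns one
#' call per gene, carrying positional metadata through.
#'
#' @param genes Tibble with at least `gene_id` and `protein`; `scaffold_id`,
#'   `start`, `end`, `strand` and `genome` are carried through when present.
#' @inheritParams classify_globin
#' @return A tibble of globin calls, one row per input gene.
#' @export
classify_globins <- function(genes, refs = reference_globins(),
                             thresholds = globin_thresholds()) {
  if (nrow(genes) == 0) {
    return(tibble(
      gene_id = character(), best_reference = character(),
      family = character(), type = character(), thb_class = integer(),
      glb = character(), alignment_score = numeric(), z_score = numeric(),
      percent_identity = numeric(), length_aa = integer(),
      mass_kda = numeric(), f8_res = character(), f8_idx = integer(),
      e7_res = character(), e7_idx = integer(), b10_res = character(),
      b10_idx = integer(), cd1_res = character(), cd1_idx = integer(),
      length_ok = logical(), z_ok = logical(), f8_his_ok = logical(),
      f8_artifact = logical(), accepted = logical()
    ))
  }
  calls <- bind_rows(lapply(seq_len(nrow(genes)), function(i) {
    classify_globin(genes$protein[i], refs, thresholds,
                    gene_id = genes$gene_id[i])
  }))
  meta <- intersect(c("genome", "scaffold_id", "start", "end", "strand"),
                    names(genes))
  if (length(meta) > 0) {
    calls <- left_join(calls, genes[, c("gene_id", meta)], by = "gene_id")
  }
  calls
}

#' Tally globin distribution across genomes
#'
#' Aggregates accepted calls into the per-genome copy-number table and the
#' four-set co-occurrence (Venn) regions over fhb/sdgb/gcs/thb.
#'
#' @param calls Tibble of calls with columns `genome` and `glb`.
#' @return A list with `per_genome` (genome x glb counts), `copy_number`
#'   (glb, copies, n_genomes) and `venn` (region, n_genomes).
#' @export
tally_distribution <- function(calls) {
  if (nrow(calls) == 0 || !all(c("genome", "glb") %in% names(calls))) {
    if (nrow(calls) > 0) abort("calls must carry 'genome' and 'glb' columns")
    return(list(
      per_genome = tibble(genome = character(), glb = character(), n = integer()),
      copy_number = tibble(glb = character(), copies = integer(),
                           n_genomes = integer()),
      venn = tibble(region = character(), n_genomes = integer())
    ))
  }
  per_genome <- calls |> count(.data$genome, .data$glb)
  copy_number <- per_genome |>
    count(.data$glb, copies = .data$n, name = "n_genomes") |>
    arrange(.data$glb, .data$copies)
  list(per_genome = per_genome, copy_number = copy_number,
       venn = summarize_venn(calls))
}
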