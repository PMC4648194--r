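# ORF detection on both strands under translation table 11.

#' Extract maximal open reading frames from a scaffold
#'
#' Finds all maximal ORFs on both strands in all six frames: each ORF runs
#' from the most upstream start codon (ATG/GTG/TTG) after the previous
#' in-frame stop to its stop codon (TAA/TAG/TGA), inclusive. Proteins are
#' translated under code 11 with alternative starts reported as M;
#' coordinates are 1-based and include the stop codon, so the protein
#' length is `(end - start + 1) / 3 - 1`.
#'
#' @param scaffold Nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param min_len_aa Minimum protein length in residues (default 100, the
#'   usual acceptance floor for globin candidates).
#' @param scaffold_id Label used for coordinates and gene ids.
#' @return A tibble sorted by scaffold coordinate with columns `gene_id`,
#'   `scaffold_id`, `start`, `end`, `strand`, `length_aa`, `protein`.
#' @examples
#' extract_orfs("ATGAAATAA", min_len_aa = 2)
#' @export
extract_orfs <- function(scaffold, min_len_aa = 100, scaffold_id = "scaffold") {
  scaffold <- toupper(scaffold)
  chars <- strsplit(scaffold, "")[[1]]
  bad <- which(!chars %in% c(DNA4, "N"))
  if (length(bad) > 0) {
    abort(sprintf("non-IUPAC character '%s' at position %d", chars[bad[1]], bad[1]))
  }
  L <- nchar(scaffold)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") scaffold else revcomp(scaffold)
    for (f in 0:2) {
      n_cod <- (L - f) %/% 3
      if (n_cod < 2) next
      cod_start <- f + 3 * (seq_len(n_cod) - 1) + 1
      codons <- substring(s, cod_start, cod_start + 2)
      stop_idx <- which(codons %in% STOP_CODONS)
      start_is <- codons %in% START_CODONS
      prev <- 0L
      for (st in stop_idx) {
        if (st - prev >= 2) {
          seg <- (prev + 1L):(st - 1L)
          hit <- seg[start_is[seg]]
          if (length(hit) > 0) {
            i0 <- hit[1]
            len_aa <- st - i0
            if (len_aa >= min_len_aa) {
              nt <- substr(s, cod_start[i0], cod_start[st] + 2)
              rc_start <- cod_start[i0]
              rc_end <- cod_start[st] + 2L
              if (strand == "+") {
                gstart <- rc_start; gend <- rc_end
              } else {
                gstart <- L - rc_end + 1L; gend <- L - rc_start + 1L
              }
              prot <- translate_orf(substr(nt, 1, nchar(nt) - 3))
              out[[length(out) + 1]] <- tibble(
                scaffold_id = scaffold_id, start = gstart, end = gend,
                strand = strand, length_aa = len_aa, protein = prot
              )
            }
          }
        }
        prev <- st
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(gene_id = character(), scaffold_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  length_aa = integer(), protein = character()))
  }
  res <- bind_rows(out) |> arrange(.data$start, .data$end, .data$strand)
  res$gene_id <- sprintf("%s_orf%03d", scaffold_id, seq_len(nrow(res)))
  res[, c("gene_id", "scaffold_id", "start", "end", "strand", "length_aa",
          "protein")]
}

#' Extract ORFs from every scaffold of a genome
#'
#' @param scaffolds Named character vector of scaffold sequences (or an
#'   `rg_genome`).
#' @inheritParams extract_orfs
#' @return A tibble as in [extract_orfs()], one block per scaffold.
#' @export
extract_orfs_all <- function(scaffolds, min_len_aa = 100) {
  if (inherits(scaffolds, "rg_genome")) scaffolds <- scaffolds$scaffolds
  bind_rows(lapply(names(scaffolds), function(id) {
    extract_orfs(scaffolds[[id]], min_len_aa = min_len_aa, scaffold_id = id)
  }))
}
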