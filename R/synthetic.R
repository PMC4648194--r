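# Synthetic-data generator: genomes with planted globin ORFs, promoter/SD
# motifs at known upstream offsets, flanking neighbor ORFs, and a
# machine-readable truth table, so every downstream stage has a closed-loop
# test with known ground truth.

#' Mutate a protein by random substitutions
#'
#' Substitutes each position independently with probability `rate`
#' (substitutions are uniform over the 19 other residues), so the expected
#' substituted fraction equals `rate`. Positions listed in `protect`
#' (typically the proximal F8 His) are never substituted.
#'
#' @param sequence Amino-acid string over the 20 standard residues.
#' @param rate Substitution probability per position, in \[0, 1\].
#' @param seed Optional integer seed (RNG state is restored afterwards);
#'   `NULL` draws from the current RNG stream.
#' @param protect Integer vector of 1-based positions never substituted.
#' @return Mutated amino-acid string of the same length.
#' @export
mutate_protein <- function(sequence, rate, seed = NULL, protect = integer(0)) {
  if (rate < 0 || rate > 1) abort("rate must be in [0, 1]")
  chars <- check_aa20(sequence)
  run <- function() {
    hit <- runif(length(chars)) < rate
    hit[protect] <- FALSE
    for (i in which(hit)) {
      chars[i] <- sample(setdiff(AA20, chars[i]), 1)
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else with_preserved_seed(seed, run())
}

#' Back-translate a protein with the fixed codon table
#'
#' One fixed codon per residue (translation table 11), so back-translation
#' is deterministic and translating the result recovers the input exactly.
#'
#' @param protein Amino-acid string over the 20 standard residues.
#' @return Nucleotide string of length `3 * nchar(protein)` (no start/stop).
#' @export
back_translate <- function(protein) {
  chars <- check_aa20(protein)
  paste(CODON_FOR_AA[chars], collapse = "")
}

#' Describe one planted globin
#'
#' @param reference_id Id of a reference globin (see [reference_globins()]).
#' @param substitution_rate Per-position substitution rate in \[0, 1\].
#' @param scaffold_index Which scaffold carries the planting (1-based).
#' @param strand "+" or "-".
#' @param start 1-based genomic start of the planted gene (its ATG on the
#'   coding strand for "+"; for "-" the gene body still spans
#'   `start .. start + gene_length - 1` and is transcribed leftwards).
#' @param promoters Optional tibble/data.frame of motif plantings with
#'   columns `motif` ("-10", "-35", "Fnr", "SD"), `offset` (negative
#'   integer: the 5'-most planted position, in \[-130, -1\]) and
#'   `n_mismatches`. Offsets -1..-3 are reserved for the in-frame stop
#'   guard.
#' @param neighbors Optional tibble of neighbor plantings with columns
#'   `product`, `distance` (signed edge-to-edge gap in nt, |distance| <=
#'   5000; positive = downstream of the globin in its transcription
#'   direction) and `length` (nt, rounded up to a codon multiple >= 9).
#' @param protect_f8 Protect the reference F8 His from mutation (default
#'   TRUE so truth labels stay valid).
#' @return A `globin_planting` list.
#' @export
globin_planting <- function(reference_id, substitution_rate = 0,
                            scaffold_index = 1L, strand = "+", start = 1000L,
                            promoters = NULL, neighbors = NULL,
                            protect_f8 = TRUE) {
  stopifnot(strand %in% c("+", "-"))
  if (substitution_rate < 0 || substitution_rate > 1) {
    abort("substitution_rate must be in [0, 1]")
  }
  if (!is.null(promoters)) {
    promoters <- as_tibble(promoters)
    if (any(promoters$offset > -1 | promoters$offset < -130)) {
      abort("promoter offsets must lie in [-130, -1]")
    }
  }
  if (!is.null(neighbors)) {
    neighbors <- as_tibble(neighbors)
    if (any(abs(neighbors$distance) > 5000)) {
      abort("neighbor distances must satisfy |distance| <= 5000")
    }
  }
  structure(list(reference_id = reference_id,
                 substitution_rate = substitution_rate,
                 scaffold_index = as.integer(scaffold_index),
                 strand = strand, start = as.integer(start),
                 promoters = promoters, neighbors = neighbors,
                 protect_f8 = isTRUE(protect_f8)),
            class = "globin_planting")
}

#' Describe a synthetic genome
#'
#' @param seed Integer seed; the same spec and seed always yield
#'   byte-identical outputs.
#' @param n_scaffolds Number of scaffolds.
#' @param scaffold_length Scaffold length in nt (all scaffolds equal).
#' @param plantings List of [globin_planting()] objects.
#' @param background_gc GC fraction of the i.i.d. background sequence.
#' @param genome Genome label used in truth/annotation output.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(seed, n_scaffolds = 1L, scaffold_length = 6000L,
                        plantings = list(), background_gc = 0.5,
                        genome = "synthetic_genome") {
  if (background_gc < 0 || background_gc > 1) abort("background_gc must be in [0, 1]")
  structure(list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
                 scaffold_length = as.integer(scaffold_length),
                 plantings = plantings, background_gc = background_gc,
                 genome = genome),
            class = "genome_spec")
}

# Consensus strings for motif planting (shared with the promoter module).
MOTIF_CONSENSUS <- c(
  "-10" = "TATAAT", "-35" = "TTGACA",
  "Fnr" = "TTTAAGAGGCCAAT", "SD" = "AGGAGG"
)

# Mutate exactly n positions of a consensus, each to a different base.
plant_mismatches <- function(consensus, n) {
  chars <- strsplit(consensus, "")[[1]]
  if (n > length(chars)) abort("n_mismatches exceeds motif length")
  for (i in if (n > 0) sample(length(chars), n) else integer(0)) {
    chars[i] <- sample(setdiff(DNA4, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA4, n, replace = TRUE, prob = p[DNA4]), collapse = "")
}

`substr_assign` <- function(x, start, value) {
  substr(x, start, start + nchar(value) - 1) <- value
  x
}

#' Generate a synthetic genome with planted globins and ground truth
#'
#' Emits i.i.d. background scaffolds at the requested GC content, embeds
#' each planted globin as `ATG + back-translated (optionally mutated)
#' reference + TAA` with an in-frame TAA guard immediately upstream (so the
#' maximal ORF starts exactly at the planted ATG), writes promoter/SD motifs
#' at their stated upstream offsets with exactly the stated mismatch counts,
#' places neighbor ORFs at their signed edge-to-edge distances, and records
#' every planted feature in a flat truth table.
#'
#' @param spec A [genome_spec()].
#' @param refs Reference set (defaults to the packaged synthetic set).
#' @return A list of class `rg_genome` with `scaffolds` (named character),
#'   `annotation` (tibble of genes: the planted globins and neighbors) and
#'   `truth` (flat tibble, one row per planted feature, `kind` in
#'   "globin"/"motif"/"neighbor").
#' @export
generate_genome <- function(spec, refs = reference_globins()) {
  stopifnot(inherits(spec, "genome_spec"))
  with_preserved_seed(spec$seed, generate_genome_impl(spec, refs))
}

generate_genome_impl <- function(spec, refs) {
  L <- spec$scaffold_length
  scaffolds <- setNames(
    vapply(seq_len(spec$n_scaffolds), function(i) random_dna(L, spec$background_gc),
           character(1)),
    sprintf("%s_scaffold%02d", spec$genome, seq_len(spec$n_scaffolds))
  )
  ann <- list()
  truth <- list()
  reserved <- list()  # per-planting reserved intervals for overlap checks

  for (pi in seq_along(spec$plantings)) {
    p <- spec$plantings[[pi]]
    if (p$scaffold_index < 1 || p$scaffold_index > spec$n_scaffolds) {
      abort(sprintf("planting %d: scaffold_index out of range", pi))
    }
    ref <- refs[refs$id == p$reference_id, ]
    if (nrow(ref) != 1) abort(sprintf("unknown reference_id '%s'", p$reference_id))
    protect <- if (p$protect_f8) ref$f8 else integer(0)
    mut <- mutate_protein(ref$sequence, p$substitution_rate, protect = protect)
    gene_nt <- paste0("ATG", back_translate(mut), "TAA")
    glen <- nchar(gene_nt)
    gstart <- p$start
    gend <- gstart + glen - 1L
    scaf_id <- names(scaffolds)[p$scaffold_index]
    if (gstart < 134 || gend > L - 133) {
      abort(sprintf("planting %d does not fit scaffold with upstream margin", pi))
    }
    gene_id <- sprintf("%s_glb%02d", scaf_id, pi)

    has_promoters <- !is.null(p$promoters) && nrow(p$promoters) > 0
    win <- if (has_promoters) 131L else 3L  # reserved upstream footprint
    resv <- if (p$strand == "+") c(gstart - win, gend) else c(gstart, gend + win)
    for (r in reserved) {
      if (r$scaffold == scaf_id && resv[1] <= r$iv[2] && r$iv[1] <= resv[2]) {
        abort(sprintf("plantings overlap on %s: %s and %s", scaf_id, r$id, gene_id))
      }
    }
    reserved[[length(reserved) + 1]] <- list(scaffold = scaf_id, id = gene_id, iv = resv)

    seq <- scaffolds[[p$scaffold_index]]
    if (p$strand == "+") {
      seq <- substr_assign(seq, gstart, gene_nt)
      seq <- substr_assign(seq, gstart - 3L, "TAA")  # in-frame guard stop
    } else {
      seq <- substr_assign(seq, gstart, revcomp(gene_nt))
      seq <- substr_assign(seq, gend + 1L, revcomp("TAA"))
    }

    truth[[length(truth) + 1]] <- tibble(
      genome = spec$genome, kind = "globin", scaffold_id = scaf_id,
      gene_id = gene_id, reference_id = ref$id, family = ref$family,
      type = ref$type, thb_class = ref$thb_class,
      start = gstart, end = gend, strand = p$strand,
      protein = paste0("M", mut),
      motif = NA_character_, offset_far = NA_integer_,
      offset_near = NA_integer_, n_mismatches = NA_integer_,
      observed = NA_character_, product = "globin",
      distance = NA_integer_, length = glen
    )
    ann[[length(ann) + 1]] <- tibble(
      gene_id = gene_id, scaffold_id = scaf_id, start = gstart, end = gend,
      strand = p$strand, type = "gene", product = "globin"
    )

    if (has_promoters) {
      prom <- p$promoters
      iv <- cbind(prom$offset, prom$offset + nchar(MOTIF_CONSENSUS[prom$motif]) - 1L)
      if (any(iv[, 2] > -1L)) abort("planted motif extends past position -1")
      if (any(iv[, 2] >= -3L)) {
        abort("positions -1..-3 are reserved for the upstream stop guard")
      }
      if (nrow(prom) > 1) {
        for (i in seq_len(nrow(prom) - 1)) for (j in (i + 1):nrow(prom)) {
          if (iv[i, 1] <= iv[j, 2] && iv[j, 1] <= iv[i, 2]) {
            abort(sprintf("planted motifs overlap: %s and %s",
                          prom$motif[i], prom$motif[j]))
          }
        }
      }
      for (i in seq_len(nrow(prom))) {
        cons <- MOTIF_CONSENSUS[[prom$motif[i]]]
        obs <- plant_mismatches(cons, prom$n_mismatches[i])
        k <- nchar(obs)
        if (p$strand == "+") {
          gpos <- gstart + prom$offset[i]  # offset -j -> position gstart - j
          seq <- substr_assign(seq, gpos, obs)
        } else {
          gpos <- gend - (prom$offset[i] + k - 1L)
          seq <- substr_assign(seq, gpos, revcomp(obs))
        }
        truth[[length(truth) + 1]] <- tibble(
          genome = spec$genome, kind = "motif", scaffold_id = scaf_id,
          gene_id = gene_id, reference_id = NA_character_,
          family = NA_character_, type = NA_character_, thb_class = NA_integer_,
          start = NA_integer_, end = NA_integer_, strand = p$strand,
          protein = NA_character_, motif = prom$motif[i],
          offset_far = as.integer(prom$offset[i]),
          offset_near = as.integer(prom$offset[i] + k - 1L),
          n_mismatches = as.integer(prom$n_mismatches[i]),
          observed = obs, product = NA_character_,
          distance = NA_integer_, length = k
        )
      }
    }

    if (!is.null(p$neighbors) && nrow(p$neighbors) > 0) {
      for (i in seq_len(nrow(p$neighbors))) {
        nb <- p$neighbors[i, ]
        naa <- max(1L, ceiling((nb$length - 6L) / 3L))
        nprot <- random_protein(naa)
        nb_nt <- paste0("ATG", back_translate(nprot), "TAA")
        nlen <- nchar(nb_nt)
        # positive distance = downstream in the focal gene's direction
        right <- (nb$distance > 0) == (p$strand == "+")
        if (right) {
          nstart <- gend + abs(nb$distance) + 1L
        } else {
          nstart <- gstart - abs(nb$distance) - nlen
        }
        nend <- nstart + nlen - 1L
        if (nstart < 1 || nend > L) {
          abort(sprintf("neighbor '%s' does not fit scaffold", nb$product))
        }
        nid <- sprintf("%s_nbr%02d_%02d", scaf_id, pi, i)
        for (r in reserved) {
          if (r$scaffold == scaf_id && nstart <= r$iv[2] && r$iv[1] <= nend) {
            abort(sprintf("plantings overlap on %s: %s and %s", scaf_id, r$id, nid))
          }
        }
        reserved[[length(reserved) + 1]] <- list(scaffold = scaf_id, id = nid,
                                                 iv = c(nstart, nend))
        seq <- substr_assign(seq, nstart,
                             if (p$strand == "+") nb_nt else revcomp(nb_nt))
        ann[[length(ann) + 1]] <- tibble(
          gene_id = nid, scaffold_id = scaf_id, start = nstart, end = nend,
          strand = p$strand, type = "gene", product = nb$product
        )
        truth[[length(truth) + 1]] <- tibble(
          genome = spec$genome, kind = "neighbor", scaffold_id = scaf_id,
          gene_id = nid, reference_id = NA_character_, family = NA_character_,
          type = NA_character_, thb_class = NA_integer_,
          start = nstart, end = nend, strand = p$strand,
          protein = NA_character_, motif = NA_character_,
          offset_far = NA_integer_, offset_near = NA_integer_,
          n_mismatches = NA_integer_, observed = NA_character_,
          product = nb$product, distance = as.integer(nb$distance),
          length = nlen
        )
      }
    }
    scaffolds[[p$scaffold_index]] <- seq
  }

  structure(list(
    scaffolds = scaffolds,
    annotation = if (length(ann)) bind_rows(ann) else empty_annotation(),
    truth = if (length(truth)) bind_rows(truth) else NULL,
    genome = spec$genome, spec = spec
  ), class = "rg_genome")
}

empty_annotation <- function() {
  tibble(gene_id = character(), scaffold_id = character(), start = integer(),
         end = integer(), strand = character(), type = character(),
         product = character())
}

#' Write a synthetic genome to disk
#'
#' Writes scaffolds as wrapped FASTA, annotation as GFF3 and the truth
#' table as TSV.
#'
#' @param genome An `rg_genome` from [generate_genome()].
#' @param dir Output directory (created if needed).
#' @param stem File stem (default the genome label).
#' @return Invisibly, a named list of the three paths.
#' @export
write_genome <- function(genome, dir, stem = genome$genome) {
  stopifnot(inherits(genome, "rg_genome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    fasta = file.path(dir, paste0(stem, ".fna")),
    gff3 = file.path(dir, paste0(stem, ".gff3")),
    truth = file.path(dir, paste0(stem, ".truth.tsv"))
  )
  write_fasta(genome$scaffolds, paths$fasta, type = "DNA")
  write_gff3(genome$annotation, paths$gff3)
  readr::write_tsv(genome$truth, paths$truth)
  invisible(paths)
}

#' Simulate a cohort of genomes with known globin composition
#'
#' Convenience wrapper used for closed-loop tests of the whole pipeline:
#' each genome gets one scaffold per planted globin (copies are never
#' tandemly arrayed, mirroring the organization seen in rhizobial
#' assemblies).
#'
#' @param composition Named list: genome label -> character vector of
#'   reference ids (one planted globin per element).
#' @param substitution_rate Substitution rate applied to every planting.
#' @param seed Integer; genome i uses seed `seed + i`.
#' @return A named list of `rg_genome` objects.
#' @export
simulate_cohort <- function(composition, substitution_rate = 0, seed = 1) {
  refs <- reference_globins()
  out <- vector("list", length(composition))
  names(out) <- names(composition)
  for (i in seq_along(composition)) {
    ids <- composition[[i]]
    plant <- lapply(seq_along(ids), function(k) {
      globin_planting(ids[k], substitution_rate, scaffold_index = k,
                      start = 1000L)
    })
    len <- max(vapply(ids, function(id) {
      3L * (nchar(refs$sequence[refs$id == id]) + 2L)
    }, integer(1))) + 2500L
    out[[i]] <- generate_genome(genome_spec(
      seed = seed + i, n_scaffolds = length(ids), scaffold_length = len,
      plantings = plant, genome = names(composition)[i]
    ))
  }
  out
}
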