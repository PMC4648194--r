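# End-to-end orchestration: identify -> promoters -> neighborhoods ->
# phenetics, cohort summaries (copy-number table, Venn regions), and
# deterministic report output.

#' Pipeline configuration
#'
#' @param genomes Either a named character vector of scaffold FASTA paths
#'   (names = genome labels; unnamed paths use the file stem), or a named
#'   list of named character vectors of scaffold sequences.
#' @param gff Optional named character vector of GFF3 paths (per genome);
#'   genomes without one get ORFs called ab initio.
#' @param refs Optional reference set tibble (default: packaged synthetic
#'   references).
#' @param window Upstream window in nt (default 130).
#' @param span Neighborhood span in nt (default 5000).
#' @param min_len_aa,z_threshold,n_shuffles,accept_gcs_glu_f8 Classifier
#'   thresholds (see [globin_thresholds()]).
#' @param canonical_max_mm,fnr_max_mm,sd_min_len Motif thresholds (see
#'   [motif_definitions()]).
#' @param seed Integer seed governing every stochastic step of the run.
#' @param outdir Output directory (NULL for in-memory only).
#' @param resume Reuse stage outputs already present in `outdir`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genomes, gff = NULL, refs = NULL, window = 130,
                            span = 5000, min_len_aa = 100, z_threshold = 6,
                            n_shuffles = 100, accept_gcs_glu_f8 = TRUE,
                            canonical_max_mm = 1, fnr_max_mm = 5,
                            sd_min_len = 3, seed = 1, outdir = NULL,
                            resume = FALSE) {
  stopifnot(window > 0, span > 0, min_len_aa > 0, z_threshold > 0)
  structure(list(genomes = genomes, gff = gff, refs = refs, window = window,
                 span = span, min_len_aa = min_len_aa,
                 z_threshold = z_threshold, n_shuffles = n_shuffles,
                 accept_gcs_glu_f8 = accept_gcs_glu_f8,
                 canonical_max_mm = canonical_max_mm,
                 fnr_max_mm = fnr_max_mm, sd_min_len = sd_min_len,
                 seed = as.integer(seed), outdir = outdir, resume = resume),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$genomes)) y$genomes <- unlist(y$genomes)
  if (!is.null(y$gff)) y$gff <- unlist(y$gff)
  do.call(pipeline_config, y)
}

load_genome_inputs <- function(config) {
  g <- config$genomes
  if (is.list(g) && !is.data.frame(g)) {
    if (is.null(names(g))) abort("in-memory genomes must be named")
    return(g)
  }
  paths <- as.character(g)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("genome file(s) not found: %s", paste(missing, collapse = ", ")))
  }
  labels <- names(g)
  if (is.null(labels)) labels <- rep("", length(paths))
  stems <- tools::file_path_sans_ext(basename(paths))
  labels <- ifelse(labels == "" | is.na(labels), stems, labels)
  out <- lapply(paths, function(p) {
    fa <- read_fasta(p)
    setNames(fa$sequence, fa$id)
  })
  names(out) <- labels
  out
}

#' Run the full globin characterization pipeline
#'
#' For each genome: gene models (GFF3 when provided, ab initio maximal
#' ORFs otherwise), classification against the reference set with the
#' three acceptance criteria, then for accepted globins the upstream motif
#' scan, the neighborhood map and the tandem-array check; across genomes,
#' the copy-number and Venn-region summaries and the percent-identity
#' UPGMA phenogram. Identical config and seed produce identical outputs.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @return An `rg_run`: list with `calls`, `accepted`, `promoter_hits`,
#'   `promoter_table`, `neighborhoods`, `tandem`, `tallies`, `venn`,
#'   `phenogram` (NULL when < 2 accepted globins), `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  with_preserved_seed(config$seed, run_pipeline_impl(config))
}

run_pipeline_impl <- function(config) {
  genomes <- load_genome_inputs(config)
  refs <- config$refs %||% reference_globins()
  th <- globin_thresholds(min_len_aa = config$min_len_aa,
                          z_threshold = config$z_threshold,
                          n_shuffles = config$n_shuffles,
                          accept_gcs_glu_f8 = config$accept_gcs_glu_f8)
  motifs <- motif_definitions(canonical_max_mm = config$canonical_max_mm,
                              fnr_max_mm = config$fnr_max_mm,
                              sd_min_len = config$sd_min_len)
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  calls_path <- if (!is.null(outdir)) file.path(outdir, "calls.tsv") else NULL

  per_genome <- lapply(names(genomes), function(gname) {
    scaffolds <- genomes[[gname]]
    if (!is.null(config$gff) && gname %in% names(config$gff)) {
      genes <- read_gff3(config$gff[[gname]])
      missing_scaf <- setdiff(unique(genes$scaffold_id), names(scaffolds))
      if (length(missing_scaf) > 0) {
        abort(sprintf("stage identify, genome %s: GFF3 scaffold(s) %s not in FASTA",
                      gname, paste(missing_scaf, collapse = ", ")))
      }
      genes$protein <- vapply(seq_len(nrow(genes)), function(i) {
        nt <- substr(scaffolds[[genes$scaffold_id[i]]], genes$start[i], genes$end[i])
        if (genes$strand[i] == "-") nt <- revcomp(nt)
        if (nchar(nt) %% 3 != 0) return(NA_character_)
        translate_orf(substr(nt, 1, nchar(nt) - 3))
      }, character(1))
      genes$length_aa <- nchar(genes$protein)
      candidates <- genes |>
        filter(!is.na(.data$protein), .data$length_aa >= config$min_len_aa,
               !grepl("\\*", .data$protein))
    } else {
      # ab initio: classify long ORFs; keep shorter ORFs as annotation for
      # the neighborhood stage
      genes <- extract_orfs_all(scaffolds, min_len_aa = min(30, config$min_len_aa))
      candidates <- genes |> filter(.data$length_aa >= config$min_len_aa)
    }
    list(genome = gname, scaffolds = scaffolds, genes = genes,
         candidates = candidates)
  })
  names(per_genome) <- names(genomes)

  all_genes <- bind_rows(lapply(per_genome, function(pg) {
    mutate(pg$candidates, genome = pg$genome)
  }))
  calls <- if (!is.null(calls_path) && config$resume && file.exists(calls_path)) {
    readr::read_tsv(calls_path, show_col_types = FALSE)
  } else {
    classify_globins(all_genes, refs = refs, thresholds = th)
  }
  accepted <- calls |> filter(.data$accepted)

  promoter_hits <- bind_rows(lapply(per_genome, function(pg) {
    acc <- accepted |> filter(.data$genome == pg$genome)
    if (nrow(acc) == 0) return(empty_hits())
    scan_promoters(acc, pg$scaffolds, window = config$window, motifs = motifs)
  }))
  promoter_table <- promoter_report(promoter_hits,
                                    gene_ids = accepted$gene_id)

  neighborhoods <- bind_rows(lapply(per_genome, function(pg) {
    acc <- accepted |> filter(.data$genome == pg$genome)
    if (nrow(acc) == 0) return(NULL)
    ann <- mutate(pg$genes, product = if ("product" %in% names(pg$genes))
      .data$product else NA_character_)
    map_neighborhoods(acc, ann, span = config$span)
  }))
  tandem <- bind_rows(lapply(per_genome, function(pg) {
    acc <- accepted |> filter(.data$genome == pg$genome)
    tandem_array_check(acc, pg$genes, span = config$span)
  }))

  tallies <- tally_distribution(accepted)
  phen <- NULL
  if (nrow(accepted) >= 2) {
    prots <- all_genes$protein[match(accepted$gene_id, all_genes$gene_id)]
    names(prots) <- accepted$gene_id
    phen <- phenogram(prots)
  }

  run <- structure(list(
    calls = calls, accepted = accepted, promoter_hits = promoter_hits,
    promoter_table = promoter_table, neighborhoods = neighborhoods,
    tandem = tandem, tallies = tallies, venn = tallies$venn,
    phenogram = phen, config = config
  ), class = "rg_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

# Flatten list columns for TSV output.
flatten_neighborhoods <- function(nb) {
  if (nrow(nb) == 0) return(mutate(nb, categories = character(0)))
  mutate(nb, categories = vapply(.data$categories, paste, character(1),
                                 collapse = ";"))
}

write_run <- function(run, outdir) {
  cfg <- run$config
  readr::write_tsv(run$calls, file.path(outdir, "calls.tsv"))
  readr::write_tsv(run$promoter_table, file.path(outdir, "promoters.tsv"))
  readr::write_tsv(flatten_neighborhoods(run$neighborhoods),
                   file.path(outdir, "neighborhoods.tsv"))
  readr::write_tsv(run$tandem, file.path(outdir, "tandem.tsv"))
  readr::write_tsv(run$tallies$copy_number, file.path(outdir, "copy_number.tsv"))
  readr::write_tsv(run$venn, file.path(outdir, "venn.tsv"))
  if (!is.null(run$phenogram)) {
    writeLines(run$phenogram$newick, file.path(outdir, "phenogram.nwk"))
  }
  prov <- list(
    package = "rhizoglob",
    version = as.character(utils::packageVersion("rhizoglob")),
    seed = cfg$seed,
    thresholds = cfg[c("window", "span", "min_len_aa", "z_threshold",
                       "n_shuffles", "canonical_max_mm", "fnr_max_mm",
                       "sd_min_len")],
    n_genomes = length(unique(run$calls$genome)),
    n_accepted = nrow(run$accepted)
  )
  jsonlite::write_json(prov, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.rg_run <- function(x, ...) {
  cat(sprintf("<rg_run> %d genomes, %d calls (%d accepted)\n",
              length(unique(x$calls$genome)), nrow(x$calls), nrow(x$accepted)))
  invisible(x)
}

VENN_SETS <- c("fhb", "gcs", "sdgb", "thb")

#' Venn-region counts of globin co-occurrence
#'
#' For each genome, the set of globin types present (fhb/sdgb/gcs/thb)
#' defines one of the 15 non-empty regions of the four-set Venn diagram;
#' counts are genomes per region. Region counts sum to the number of
#' genomes with at least one globin.
#'
#' @param calls Tibble with `genome` and `glb` columns (accepted calls).
#' @return Tibble with `region` (e.g. "sdgb+thb") and `n_genomes`,
#'   covering all 15 regions (zeros included).
#' @export
summarize_venn <- function(calls) {
  regions <- unlist(lapply(1:4, function(k) {
    apply(utils::combn(VENN_SETS, k), 2, paste, collapse = "+")
  }))
  base <- tibble(region = regions, n_genomes = 0L)
  if (nrow(calls) == 0) return(base)
  obs <- calls |>
    filter(.data$glb %in% VENN_SETS) |>
    group_by(.data$genome) |>
    summarise(region = paste(sort(unique(.data$glb)), collapse = "+")) |>
    count(.data$region, name = "n")
  base |>
    left_join(obs, by = "region") |>
    mutate(n_genomes = as.integer(.data$n_genomes + dplyr::coalesce(.data$n, 0L))) |>
    select("region", "n_genomes")
}
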