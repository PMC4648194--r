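# Gene neighborhoods: flanking genes within a +/-5 kb span, tandem-array
# checks, and keyword categorization of neighbor products.

#' Default product keyword map
#'
#' Case-insensitive substring keywords used to tag neighbor products by
#' functional theme (nitrate/nitrite metabolism, chemotaxis, transport,
#' nitrogen-fixation-related nif/fix/nos genes, transcriptional regulators,
#' hypothetical proteins). Untagged products fall into "other".
#'
#' @return Named list: category -> character vector of keywords.
#' @export
product_keyword_map <- function() {
  list(
    `nitrate/nitrite` = c("nitrate", "nitrite"),
    chemotaxis = c("chemotaxis", "chemoreceptor", "che"),
    transport = c("transport", "permease", "transporter", "efflux"),
    `nif/fix/nos` = c("nif", "fix", "nos", "nitrogenase"),
    `transcriptional regulator` = c("transcriptional regulator", "regulator"),
    hypothetical = c("hypothetical", "uncharacterized", "unknown")
  )
}

#' Categorize product labels by keyword
#'
#' @param products Character vector of free-text product labels.
#' @param keyword_map Named list of category -> keywords (default
#'   [product_keyword_map()]).
#' @return List (one element per product) of matching category names;
#'   `"other"` when nothing matches.
#' @export
categorize_products <- function(products, keyword_map = product_keyword_map()) {
  lapply(products, function(p) {
    if (is.na(p)) return("other")
    pl <- tolower(p)
    hits <- names(keyword_map)[vapply(keyword_map, function(kw) {
      any(vapply(kw, function(k) grepl(k, pl, fixed = TRUE), logical(1)))
    }, logical(1))]
    if (length(hits) == 0) "other" else hits
  })
}

# Edge-to-edge gap between two intervals; 0 when they overlap or touch.
interval_gap <- function(s1, e1, s2, e2) {
  if (s2 > e1) s2 - e1 - 1L
  else if (s1 > e2) s1 - e2 - 1L
  else 0L
}

#' Genes flanking a focal gene within a span
#'
#' Neighbors whose nearest edge lies within `span` nt of the focal gene's
#' nearest edge, on the same scaffold, partitioned into upstream and
#' downstream relative to the focal gene's strand (for a - strand focal
#' gene, upstream lies at higher coordinates). Distance is the
#' edge-to-edge gap (0 when overlapping); lists are sorted by |distance|.
#'
#' @param focal One-row data frame (or list) with `gene_id`, `scaffold_id`,
#'   `start`, `end`, `strand`.
#' @param annotation Tibble of annotated genes (`gene_id`, `scaffold_id`,
#'   `start`, `end`, `strand`, `product`).
#' @param span Window in nt (default 5000, "~5 kb up- and downstream").
#' @param keyword_map Passed to [categorize_products()].
#' @return Tibble of neighbors with `side` ("upstream"/"downstream"),
#'   signed `distance` (negative upstream, positive downstream) and
#'   `categories` (list column).
#' @export
flanking_genes <- function(focal, annotation, span = 5000,
                           keyword_map = product_keyword_map()) {
  nb <- annotation |>
    filter(.data$scaffold_id == focal$scaffold_id,
           .data$gene_id != focal$gene_id)
  if (nrow(nb) == 0) {
    return(tibble(focal_id = character(), gene_id = character(),
                  scaffold_id = character(), start = integer(),
                  end = integer(), strand = character(), product = character(),
                  side = character(), distance = integer(),
                  categories = list()))
  }
  gap <- vapply(seq_len(nrow(nb)), function(i) {
    interval_gap(focal$start, focal$end, nb$start[i], nb$end[i])
  }, numeric(1))
  right_of <- nb$start > focal$end
  downstream <- if (focal$strand == "+") right_of else !right_of & nb$end < focal$start
  # overlapping genes: assign by midpoint relative to focal midpoint
  overlap <- gap == 0
  if (any(overlap)) {
    mid_f <- (focal$start + focal$end) / 2
    mid_n <- (nb$start + nb$end) / 2
    right_mid <- mid_n >= mid_f
    downstream[overlap] <- if (focal$strand == "+") right_mid[overlap] else !right_mid[overlap]
  }
  keep <- gap <= span
  nb <- nb[keep, ]
  res <- nb |>
    mutate(
      focal_id = focal$gene_id,
      side = ifelse(downstream[keep], "downstream", "upstream"),
      distance = as.integer(ifelse(downstream[keep], 1, -1) * gap[keep]),
      categories = categorize_products(.data$product, keyword_map)
    ) |>
    arrange(abs(.data$distance)) |>
    select("focal_id", "gene_id", "scaffold_id", "start", "end", "strand",
           "product", "side", "distance", "categories")
  res
}

#' Neighborhood reports for every accepted globin call
#'
#' @param calls Tibble of globin calls with coordinates (`gene_id`,
#'   `scaffold_id`, `start`, `end`, `strand`).
#' @param annotation Annotated gene tibble (e.g. from [read_gff3()] or a
#'   synthetic genome); the globin genes themselves may be present and are
#'   excluded per focal gene.
#' @inheritParams flanking_genes
#' @return Tibble of neighbor records across all focal globins.
#' @export
map_neighborhoods <- function(calls, annotation, span = 5000,
                              keyword_map = product_keyword_map()) {
  bind_rows(lapply(seq_len(nrow(calls)), function(i) {
    flanking_genes(calls[i, ], annotation, span, keyword_map)
  }))
}

#' Check for tandemly arrayed globin copies
#'
#' Pairs of same-type globin calls on one scaffold that are coordinate-
#' adjacent, separated by at most `span` nt, with no intervening annotated
#' gene. An empty result asserts the copies are not tandemly arrayed.
#'
#' @param calls Globin calls on one scaffold (columns `gene_id`,
#'   `scaffold_id`, `start`, `end`, `glb`).
#' @param annotation Annotation used to detect intervening genes.
#' @param span Maximum gap (default 5000 nt).
#' @return Tibble of tandem pairs (`gene_id_1`, `gene_id_2`, `glb`, `gap`).
#' @export
tandem_array_check <- function(calls, annotation = NULL, span = 5000) {
  empty <- tibble(gene_id_1 = character(), gene_id_2 = character(),
                  glb = character(), gap = integer())
  if (nrow(calls) < 2) return(empty)
  out <- list()
  for (scaf in unique(calls$scaffold_id)) {
    cs <- calls |> filter(.data$scaffold_id == scaf) |> arrange(.data$start)
    if (nrow(cs) < 2) next
    for (i in seq_len(nrow(cs) - 1)) {
      a <- cs[i, ]; b <- cs[i + 1, ]
      if (!identical(a$glb, b$glb)) next
      gap <- interval_gap(a$start, a$end, b$start, b$end)
      if (gap > span) next
      if (!is.null(annotation)) {
        between <- annotation |>
          filter(.data$scaffold_id == scaf,
                 !.data$gene_id %in% c(a$gene_id, b$gene_id),
                 .data$start > a$end, .data$end < b$start)
        if (nrow(between) > 0) next
      }
      out[[length(out) + 1]] <- tibble(gene_id_1 = a$gene_id,
                                       gene_id_2 = b$gene_id,
                                       glb = a$glb, gap = as.integer(gap))
    }
  }
  if (length(out) == 0) empty else bind_rows(out)
}
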