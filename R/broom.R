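# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pipeline run into its call table
#'
#' @param x An `rg_run` from [run_pipeline()].
#' @param ... Unused.
#' @return The globin call tibble (one row per classified gene).
#' @export
tidy.rg_run <- function(x, ...) x$calls

#' One-row summary of a pipeline run
#'
#' @param x An `rg_run`.
#' @param ... Unused.
#' @return Tibble with genome/call/acceptance counts and per-type totals.
#' @export
glance.rg_run <- function(x, ...) {
  acc <- x$accepted
  tibble(
    n_genomes = length(unique(x$calls$genome)),
    n_calls = nrow(x$calls),
    n_accepted = nrow(acc),
    n_fhb = sum(acc$glb == "fhb"), n_sdgb = sum(acc$glb == "sdgb"),
    n_gcs = sum(acc$glb == "gcs"), n_thb = sum(acc$glb == "thb"),
    seed = x$config$seed
  )
}

#' Tidy a phenogram into its edge table
#'
#' @param x An `rg_phenogram` from [upgma()] or [phenogram()].
#' @param ... Unused.
#' @return Tibble with `parent`, `node`, `length` and `label` (leaf labels,
#'   NA for internal nodes).
#' @export
tidy.rg_phenogram <- function(x, ...) {
  tr <- x$tree
  tibble(
    parent = tr$edge[, 1], node = tr$edge[, 2],
    length = tr$edge.length,
    label = ifelse(tr$edge[, 2] <= length(tr$tip.label),
                   tr$tip.label[tr$edge[, 2]], NA_character_)
  )
}

#' One-row summary of a phenogram
#'
#' @param x An `rg_phenogram`.
#' @param ... Unused.
#' @return Tibble with leaf count, root height and the maximum deviation
#'   from ultrametricity across leaves.
#' @export
glance.rg_phenogram <- function(x, ...) {
  depths <- ape::node.depth.edgelength(x$tree)
  leaf_depths <- depths[seq_along(x$tree$tip.label)]
  tibble(
    n_leaves = length(x$labels),
    root_height = x$root_height,
    ultrametric_dev = max(leaf_depths) - min(leaf_depths)
  )
}

#' Tidy a pocket-geometry result
#'
#' @param x An `rg_pocket` from [pocket_geometry()].
#' @param ... Unused.
#' @return The per-role geometry tibble.
#' @export
tidy.rg_pocket <- function(x, ...) x$geometry

#' One-row summary of a pocket-geometry result
#'
#' @param x An `rg_pocket`.
#' @param ... Unused.
#' @return Tibble with the coordination call, cutoff and key distances.
#' @export
glance.rg_pocket <- function(x, ...) {
  g <- x$geometry
  val <- function(role) {
    v <- g$distance[g$role == role]
    if (length(v) == 1) v else NA_real_
  }
  tibble(coordination = x$coordination, cutoff = x$cutoff,
         proximal_dist = val("proximal"), distal_dist = val("distal"))
}
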