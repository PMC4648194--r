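# Plotting: ggplot2 autoplot methods for tabular results; the phenogram
# itself is drawn with ape's base plotting, the field's standard.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the globin-type composition of a run
#'
#' Bar chart of accepted calls per genome, filled by globin type.
#'
#' @param object An `rg_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rg_run <- function(object, ...) {
  acc <- object$accepted
  ggplot2::ggplot(acc, ggplot2::aes(x = .data$genome, fill = .data$glb)) +
    ggplot2::geom_bar() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "accepted globin calls", fill = "type") +
    ggplot2::theme_minimal()
}

#' Plot upstream motif hits
#'
#' Hit positions (near offset) per gene and motif over the upstream
#' window, primary hits emphasized.
#'
#' @param object A hit tibble from [scan_promoters()].
#' @param window Window width used in the scan (for the x scale).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_promoter_hits <- function(object, window = 130, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$near, y = .data$gene_id,
                               colour = .data$motif,
                               alpha = .data$primary)) +
    ggplot2::geom_point() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::xlim(-window, 0) +
    ggplot2::labs(x = "offset from start codon (nt)", y = NULL,
                  colour = "element") +
    ggplot2::theme_minimal()
}

#' Plot heme-pocket distances
#'
#' @param object An `rg_pocket`.
#' @param ... Unused.
#' @return A ggplot of Fe-probe distances per role with the coordination
#'   cutoff marked.
#' @export
autoplot.rg_pocket <- function(object, ...) {
  ggplot2::ggplot(object$geometry,
                  ggplot2::aes(x = .data$role, y = .data$distance)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = object$cutoff, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "distance to heme Fe (Å)",
                  subtitle = sprintf("coordination: %s", object$coordination)) +
    ggplot2::theme_minimal()
}

#' Draw a phenogram
#'
#' Thin wrapper over [ape::plot.phylo()]; tip colours can encode globin
#' types.
#'
#' @param x An `rg_phenogram`.
#' @param tip_groups Optional named vector label -> group used to colour
#'   tips.
#' @param ... Passed to [ape::plot.phylo()].
#' @return Invisibly, `x`.
#' @export
plot_phenogram <- function(x, tip_groups = NULL, ...) {
  tree <- x$tree
  col <- "black"
  if (!is.null(tip_groups)) {
    groups <- factor(tip_groups[tree$tip.label])
    pal <- grDevices::hcl.colors(nlevels(groups), "Dark 3")
    col <- pal[as.integer(groups)]
  }
  ape::plot.phylo(tree, tip.color = col, ...)
  invisible(x)
}
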