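# broom-style accessors and ggplot2 views of pipeline results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pipeline run into the long family-status table
#'
#' @param x a `degradome_run`.
#' @param ... unused.
#' @return tibble: `family`, `species`, `copy_count`, `intact_count`,
#'   `status`.
#' @export
tidy.degradome_run <- function(x, ...) x$family_status

#' One-row summary of a pipeline run
#'
#' @param x a `degradome_run`.
#' @param ... unused.
#' @export
glance.degradome_run <- function(x, ...) {
  tibble(
    n_species = length(unique(x$models$species)),
    n_families = length(unique(x$seeds$family)),
    n_models = nrow(x$models),
    n_intact = sum(x$models$status == "intact"),
    n_non_peptidase = sum(x$models$status == "non_peptidase_homolog"),
    n_pseudogene = sum(x$models$status == "pseudogene_fragment"),
    n_hsps = nrow(x$hsps),
    n_rbh_pairs = sum(x$orthology$call == "rbh_orthologue"),
    n_trees = length(x$trees),
    elapsed_s = x$elapsed)
}

#' Family-status matrix as a tile plot
#'
#' The comparative-degradomics view: families on the y axis, species on
#' the x axis, tiles colored by status call.
#'
#' @param object a `degradome_run`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.degradome_run <- function(object, ...) {
  ggplot2::ggplot(object$family_status,
                  ggplot2::aes(x = species, y = family, fill = status)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.4) +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = NULL, fill = "status",
                  title = "Family status across species") +
    ggplot2::theme_minimal()
}

#' Plot HSPs along a contig
#'
#' Each HSP is a horizontal segment at its genomic span, stacked by
#' query, colored by raw score; a quick look at the composite hit report.
#'
#' @param hsps HSP tibble.
#' @param contig_id contig to show (default: the first).
#' @return a ggplot.
#' @export
plot_hsps <- function(hsps, contig_id = NULL) {
  contig_id <- contig_id %||% hsps$contig[1]
  d <- filter(hsps, contig == contig_id)
  ggplot2::ggplot(d, ggplot2::aes(x = gstart, xend = gend,
                                  y = query_id, yend = query_id,
                                  color = score)) +
    ggplot2::geom_segment(linewidth = 2) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::labs(x = paste0(contig_id, " (nt)"), y = NULL, color = "score") +
    ggplot2::theme_minimal()
}

#' Plot a (consensus) tree with bootstrap supports
#'
#' A simple rectangular cladogram; internal nodes show their support
#' labels when present.
#'
#' @param tree a `phylo`.
#' @return a ggplot.
#' @export
plot_tree <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  n <- length(tr$tip.label)
  nn <- n + tr$Nnode
  depth <- numeric(nn)
  for (e in seq_len(nrow(tr$edge)))
    depth[tr$edge[e, 2]] <- depth[tr$edge[e, 1]] + 1
  ypos <- numeric(nn)
  ypos[seq_len(n)] <- seq_len(n)
  tr_post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr_post$edge))) {
    p <- tr_post$edge[e, 1]
    kids <- tr_post$edge[tr_post$edge[, 1] == p, 2]
    ypos[p] <- mean(ypos[kids])
  }
  segs <- tibble(
    x = depth[tr$edge[, 1]], xend = depth[tr$edge[, 2]],
    y = ypos[tr$edge[, 1]], yend = ypos[tr$edge[, 2]])
  tips <- tibble(x = depth[seq_len(n)], y = ypos[seq_len(n)],
                 label = tr$tip.label)
  g <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = x, xend = xend, y = y, yend = yend),
                          linewidth = 0.4) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = x, y = y, label = label),
                       hjust = -0.05, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.3))) +
    ggplot2::theme_void()
  if (!is.null(tr$node.label)) {
    nodes <- tibble(x = depth[(n + 1):nn], y = ypos[(n + 1):nn],
                    label = tr$node.label)
    nodes <- filter(nodes, !is.na(label), nzchar(label))
    g <- g + ggplot2::geom_text(data = nodes,
                                ggplot2::aes(x = x, y = y, label = label),
                                vjust = -0.6, size = 2.7, color = "grey30")
  }
  g
}
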