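#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a co-occurrence network
#'
#' @param x An `ecis_network`.
#' @param ... Unused.
#' @return The edge list as a tibble (`from`, `to`, `weight`).
#' @method tidy ecis_network
#' @export
tidy.ecis_network <- function(x, ...) {
  as_tibble(x$edges)
}

#' One-row network summary
#'
#' @param x An `ecis_network`.
#' @param ... Unused.
#' @return A tibble: node/edge counts, total occurrences, counts per
#'   domain category, and edge density.
#' @method glance ecis_network
#' @export
glance.ecis_network <- function(x, ...) {
  n <- nrow(x$nodes)
  tibble(
    n_nodes = n,
    n_edges = nrow(x$edges),
    total_occurrences = sum(x$nodes$occurrence_count),
    n_ebap = sum(x$nodes$category == "ebap"),
    n_novel = sum(x$nodes$category == "novel"),
    n_pfam = sum(x$nodes$category == "pfam"),
    density = if (n < 2) NA_real_ else nrow(x$edges) / choose(n, 2)
  )
}

#' Tidy a segmentation result
#'
#' @param x An `ecis_segmentation`.
#' @param ... Unused.
#' @return The segment table as a plain tibble.
#' @method tidy ecis_segmentation
#' @export
tidy.ecis_segmentation <- function(x, ...) {
  out <- x
  attr(out, "model") <- NULL
  class(out) <- setdiff(class(out), "ecis_segmentation")
  as_tibble(out)
}

#' @rdname tidy.ecis_segmentation
#' @return `glance()` returns segment count, residue coverage and mean
#'   confidence.
#' @method glance ecis_segmentation
#' @export
glance.ecis_segmentation <- function(x, ...) {
  model <- attr(x, "model")
  tibble(
    n_segments = nrow(x),
    n_residues_covered = sum(x$n_residues),
    n_residues_model = if (is.null(model)) NA_integer_ else nrow(model),
    mean_plddt = if (nrow(x) == 0) NA_real_ else
      stats::weighted.mean(x$mean_plddt, x$n_residues)
  )
}

#' Plot a domain segmentation along the chain
#'
#' Per-residue pLDDT trace with the recovered domain segments shaded.
#'
#' @param object An `ecis_segmentation` from [segment_structure()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecis_segmentation
#' @export
autoplot.ecis_segmentation <- function(object, ...) {
  model <- attr(object, "model")
  segs <- tidy(object)
  p <- ggplot2::ggplot(model,
                       ggplot2::aes(x = .data$residue_number, y = .data$plddt))
  if (nrow(segs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = segs,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$segment_id),
      inherit.aes = FALSE, alpha = 0.25
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "Residue", y = "pLDDT", fill = "Domain") +
    ggplot2::theme_minimal()
}

#' Plot a co-occurrence network's degree/weight profile
#'
#' Occurrence count against node degree, coloured by domain category --
#' a quick structural read of the network without a layout engine.
#'
#' @param object An `ecis_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecis_network
#' @export
autoplot.ecis_network <- function(object, ...) {
  deg <- tibble(domain_id = c(object$edges$from, object$edges$to)) %>%
    count(.data$domain_id, name = "degree")
  df <- object$nodes %>%
    left_join(deg, by = "domain_id") %>%
    mutate(degree = dplyr::coalesce(.data$degree, 0L))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree,
                                   y = .data$occurrence_count,
                                   colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Node degree", y = "Occurrences (hits)",
                  colour = "Category") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
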