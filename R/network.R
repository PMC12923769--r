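#' Filter profile-scan hits for network construction
#'
#' Keeps hits with e-value at most `scan_evalue_max` and bit score at least
#' `scan_bitscore_min` (the 1e-5 / 12-bit screen), then resolves
#' overlapping hits per gene with [resolve_hits()], prioritising higher bit
#' scores where domains compete for the same region.
#'
#' @param hits Hit tibble over any number of genes.
#' @param config Pipeline configuration.
#' @return The retained hits, sorted by gene and alignment start.
#' @export
filter_scan_hits <- function(hits, config = ecis_config()) {
  hits %>%
    filter(.data$e_value <= config$scan_evalue_max,
           .data$bit_score >= config$scan_bitscore_min) %>%
    group_by(.data$gene_id) %>%
    dplyr::group_modify(~ resolve_hits(.x, config$overlap_tolerance)) %>%
    ungroup() %>%
    arrange(.data$gene_id, .data$ali_start)
}

#' Build a domain co-occurrence network
#'
#' Every domain observed on the fiber genes becomes a node; its
#' `occurrence_count` is the total number of retained hits across all
#' genes (multiplicity counts, matching node sizing by occurrence). Per
#' gene, each distinct unordered pair of different domains contributes one
#' unit to the pair's edge weight (presence per gene, so a gene with `k`
#' distinct domains adds `choose(k, 2)` pair increments); repeated hits of
#' one domain on the same gene create no self-edge. The build is invariant
#' to gene and hit order.
#'
#' @param hits Retained hit tibble from [filter_scan_hits()] with columns
#'   `gene_id`, `domain_id`, `source`.
#' @return An object of class `ecis_network`: a list with `nodes`
#'   (`domain_id`, `category` in ebap/novel/pfam, `occurrence_count`) and
#'   `edges` (`from`, `to`, `weight`, with `from < to`).
#' @export
build_cooccurrence <- function(hits) {
  category <- ifelse(startsWith(hits$source, "ebap"), "ebap", hits$source)
  nodes <- tibble(domain_id = hits$domain_id, category = category) %>%
    group_by(.data$domain_id) %>%
    summarise(category = first(.data$category),
              occurrence_count = n(), .groups = "drop") %>%
    arrange(.data$domain_id)
  pair_rows <- hits %>%
    distinct(.data$gene_id, .data$domain_id) %>%
    group_by(.data$gene_id) %>%
    summarise(pairs = list({
      d <- sort(.data$domain_id)
      if (length(d) >= 2) {
        m <- t(combn(d, 2))
        tibble(from = m[, 1], to = m[, 2])
      } else {
        tibble(from = character(), to = character())
      }
    }), .groups = "drop")
  edges <- bind_rows(pair_rows$pairs)
  edges <- if (nrow(edges) == 0) {
    tibble(from = character(), to = character(), weight = integer())
  } else {
    edges %>% count(.data$from, .data$to, name = "weight") %>%
      arrange(.data$from, .data$to)
  }
  structure(list(nodes = nodes, edges = edges), class = "ecis_network")
}

#' @export
print.ecis_network <- function(x, ...) {
  cat(sprintf("<ecis_network: %d domains, %d edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    d = as.data.frame(network$edges),
    directed = FALSE,
    vertices = as.data.frame(network$nodes)
  )
}

#' Export / import a co-occurrence network
#'
#' GraphML (node attributes `category`, `occurrence_count`; edge attribute
#' `weight`) or a TSV pair: `<path>` holds the edge list (`from`, `to`,
#' `weight`) and `<path>.nodes.tsv` the node table. Re-import reproduces
#' the network exactly.
#'
#' @param network An `ecis_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"tsv"`.
#' @return `export_network()` returns `path` invisibly; `import_network()`
#'   returns an `ecis_network`.
#' @export
export_network <- function(network, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else {
    readr::write_tsv(network$edges, path, progress = FALSE)
    readr::write_tsv(network$nodes, paste0(path, ".nodes.tsv"),
                     progress = FALSE)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble(
      domain_id = igraph::V(g)$name,
      category = igraph::V(g)$category,
      occurrence_count = as.integer(igraph::V(g)$occurrence_count)
    ) %>% arrange(.data$domain_id)
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- if (nrow(el) == 0) {
      tibble(from = character(), to = character(), weight = integer())
    } else {
      tibble(
        from = pmin(el$from, el$to),
        to = pmax(el$from, el$to),
        weight = as.integer(el$weight)
      ) %>% arrange(.data$from, .data$to)
    }
  } else {
    edges <- readr::read_tsv(path, col_types = readr::cols(
      from = readr::col_character(), to = readr::col_character(),
      weight = readr::col_integer()
    ), progress = FALSE)
    nodes <- readr::read_tsv(paste0(path, ".nodes.tsv"),
                             col_types = readr::cols(
                               domain_id = readr::col_character(),
                               category = readr::col_character(),
                               occurrence_count = readr::col_integer()
                             ), progress = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "ecis_network")
}
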