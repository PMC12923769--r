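#' Cluster seed genes into candidate loci
#'
#' Seed genes are genes carrying at least one hit whose domain is present
#' in the weight table (eCIS-enriched Pfams). Within each contig, maximal
#' runs of seed genes in which consecutive seeds differ by at most
#' `max_gene_gap` ordinals form one candidate cluster ("max. 5 genes
#' apart": a difference of exactly `max_gene_gap` still merges). Clusters
#' never span contigs.
#'
#' @param genes Gene tibble (see [read_gene_table()]), sorted by ordinal
#'   within contig.
#' @param hits Hit tibble (see [read_hit_table()]).
#' @param weights Weight table, as [default_marker_weights()].
#' @param max_gene_gap Maximum ordinal difference between consecutive
#'   seeds (default 5).
#' @return A tibble with one row per candidate cluster: `genome_id`,
#'   `contig_id`, `cluster_id`, `first_index`, `last_index`,
#'   `seed_indices` (list-column).
#' @export
cluster_genes <- function(genes, hits, weights = default_marker_weights(),
                          max_gene_gap = 5) {
  check_sorted_genes(genes)
  seed_ids <- unique(hits$gene_id[hits$domain_id %in% weights$domain_id])
  seeds <- genes %>% filter(.data$gene_id %in% seed_ids)
  if (nrow(seeds) == 0) {
    return(tibble(
      genome_id = character(), contig_id = character(),
      cluster_id = character(), first_index = integer(),
      last_index = integer(), seed_indices = list()
    ))
  }
  seeds %>%
    group_by(.data$genome_id, .data$contig_id) %>%
    arrange(.data$gene_index, .by_group = TRUE) %>%
    mutate(new_run = c(TRUE, diff(.data$gene_index) > max_gene_gap),
           run = cumsum(.data$new_run)) %>%
    group_by(.data$genome_id, .data$contig_id, .data$run) %>%
    summarise(first_index = min(.data$gene_index),
              last_index = max(.data$gene_index),
              seed_indices = list(sort(.data$gene_index)),
              .groups = "drop") %>%
    arrange(.data$genome_id, .data$contig_id, .data$first_index) %>%
    mutate(cluster_id = sprintf("CL%05d", row_number())) %>%
    select("genome_id", "contig_id", "cluster_id",
           "first_index", "last_index", "seed_indices")
}

check_sorted_genes <- function(genes) {
  ok <- genes %>%
    group_by(.data$genome_id, .data$contig_id) %>%
    summarise(sorted = !is.unsorted(.data$gene_index, strictly = TRUE),
              .groups = "drop")
  if (!all(ok$sorted)) {
    abort("gene records must be sorted by gene_index within contig (see read_gene_table)",
          class = "ecisfiber_integrity_error")
  }
  invisible(genes)
}

#' Score a locus by distinct Pfam presence
#'
#' The score is the sum, over the distinct domain accessions present in the
#' locus, of their configured weights; multiplicity is ignored. Marker
#' Pfams carry elevated weight. Accessions absent from the weight table
#' score 0 and are reported in the `unweighted` set.
#'
#' @param domain_ids Character vector of domain accessions found on the
#'   locus member genes (repeats allowed).
#' @param weights Weight table, as [default_marker_weights()].
#' @return A one-row tibble: `score`, `n_distinct_domains`, `weighted`
#'   (list of scored accessions), `unweighted` (list of accessions with no
#'   configured weight).
#' @examples
#' score_locus(c("DUF4157", "CIS_tube", "Phage_base_V"))
#' @export
score_locus <- function(domain_ids, weights = default_marker_weights()) {
  dom <- unique(domain_ids)
  w <- setNames(weights$weight, weights$domain_id)
  known <- dom[dom %in% names(w)]
  tibble(
    score = sum(w[known]),
    n_distinct_domains = length(known),
    weighted = list(sort(known)),
    unweighted = list(sort(setdiff(dom, known)))
  )
}

#' Expand a locus into its fiber-search window
#'
#' The window pools the locus members plus `window_expand` genes from each
#' edge, clipped at the contig ends ("plus five genes from the two edges").
#'
#' @param genes Gene tibble restricted or not to the contig; only the
#'   locus's contig is used.
#' @param genome_id,contig_id Locus location.
#' @param first_index,last_index Member gene-index interval.
#' @param window_expand Genes to add on each side (default 5).
#' @return The gene tibble rows falling inside the window, in ordinal order.
#' @export
expand_window <- function(genes, genome_id, contig_id,
                          first_index, last_index, window_expand = 5) {
  lo <- first_index - window_expand
  hi <- last_index + window_expand
  g <- genome_id
  ctg <- contig_id
  genes %>%
    filter(.data$genome_id == g, .data$contig_id == ctg,
           .data$gene_index >= lo, .data$gene_index <= hi) %>%
    arrange(.data$gene_index)
}

#' Assign eBAP anchor types to fiber gene candidates
#'
#' Among a gene's hits with source `ebap1`..`ebap5`, e-value at most
#' `scan_evalue_max`, and alignment start within `nterm_window` of the
#' N-terminus, the highest bit score wins; ties break to the smaller
#' alignment start, then to the lexicographically smaller eBAP label. Genes
#' with no qualifying hit get `ebap_type = "none"`. Assignment is invariant
#' to the order of the input rows.
#'
#' @param hits Hit tibble (any number of genes).
#' @param config Pipeline configuration.
#' @param gene_ids Genes to report; defaults to the genes present in
#'   `hits`.
#' @return A tibble with one row per gene: `gene_id`, `ebap_type`
#'   (`"ebap1"`..`"ebap5"` or `"none"`) and the winning hit's `domain_id`,
#'   `ali_start`, `ali_end`, `bit_score`, `e_value` (NA when none).
#' @export
assign_ebap <- function(hits, config = ecis_config(), gene_ids = NULL) {
  gene_ids <- gene_ids %||% unique(hits$gene_id)
  qual <- hits %>%
    filter(.data$source %in% paste0("ebap", 1:5),
           .data$e_value <= config$scan_evalue_max,
           .data$ali_start <= config$nterm_window,
           .data$gene_id %in% gene_ids) %>%
    arrange(dplyr::desc(.data$bit_score), .data$ali_start, .data$source) %>%
    group_by(.data$gene_id) %>%
    slice(1L) %>%
    ungroup() %>%
    mutate(ebap_type = .data$source) %>%
    select("gene_id", "ebap_type", "domain_id",
           "ali_start", "ali_end", "bit_score", "e_value")
  none <- tibble(
    gene_id = setdiff(gene_ids, qual$gene_id),
    ebap_type = "none",
    domain_id = NA_character_,
    ali_start = NA_integer_, ali_end = NA_integer_,
    bit_score = NA_real_, e_value = NA_real_
  )
  bind_rows(qual, none) %>% arrange(match(.data$gene_id, gene_ids))
}

#' Call scored eCIS candidate loci
#'
#' Runs the full locus screen: gap-limited clustering of seed genes,
#' distinct-Pfam scoring, exclusion of clusters containing capsid or T6SS
#' families, window expansion, and eBAP-based fiber detection within the
#' window. A locus is retained iff its score reaches `locus_score_min`, no
#' member gene carries an exclusion-set Pfam, and at least one fiber gene
#' is found in its window. Excluded loci are still emitted for audit with
#' exactly one reason: `capsid` or `t6ss` (exclusion is absolute and takes
#' precedence), else `below_threshold`, else `no_fiber`.
#'
#' @param genes,hits Gene and hit tibbles.
#' @param weights Weight table.
#' @param exclusions Exclusion table with `domain_id`, `category`
#'   (see [default_exclusion_set()]).
#' @param config Pipeline configuration.
#' @return A tibble ordered by (genome, contig, first index), one row per
#'   candidate locus: identifiers, member interval, `seed_indices`,
#'   `score`, `n_ecis_pfams`, `excluded`, `exclusion_reason`
#'   (`NA` when retained), `window_gene_ids` and `fiber_gene_ids`
#'   list-columns.
#' @export
call_loci <- function(genes, hits,
                      weights = default_marker_weights(),
                      exclusions = default_exclusion_set(),
                      config = ecis_config()) {
  clusters <- cluster_genes(genes, hits, weights, config$max_gene_gap)
  if (nrow(clusters) == 0) {
    return(tibble(
      locus_id = character(), genome_id = character(), contig_id = character(),
      first_index = integer(), last_index = integer(), seed_indices = list(),
      score = double(), n_ecis_pfams = integer(),
      excluded = logical(), exclusion_reason = character(),
      window_gene_ids = list(), fiber_gene_ids = list()
    ))
  }
  excl_cat <- setNames(exclusions$category, exclusions$domain_id)
  rows <- purrr::map(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    members <- genes %>%
      filter(.data$genome_id == cl$genome_id,
             .data$contig_id == cl$contig_id,
             .data$gene_index >= cl$first_index,
             .data$gene_index <= cl$last_index)
    member_hits <- hits %>% filter(.data$gene_id %in% members$gene_id)
    sc <- score_locus(member_hits$domain_id, weights)
    window <- expand_window(genes, cl$genome_id, cl$contig_id,
                            cl$first_index, cl$last_index,
                            config$window_expand)
    fib <- assign_ebap(hits, config, gene_ids = window$gene_id) %>%
      filter(.data$ebap_type != "none")
    excl_doms <- intersect(unique(member_hits$domain_id), names(excl_cat))
    reason <- NA_character_
    if (length(excl_doms) > 0) {
      cats <- unique(unname(excl_cat[excl_doms]))
      # a locus with both carries the rarer capsid label first
      reason <- if ("capsid" %in% cats) "capsid" else "t6ss"
    } else if (sc$score < config$locus_score_min) {
      reason <- "below_threshold"
    } else if (nrow(fib) == 0) {
      reason <- "no_fiber"
    }
    tibble(
      genome_id = cl$genome_id, contig_id = cl$contig_id,
      first_index = cl$first_index, last_index = cl$last_index,
      seed_indices = cl$seed_indices,
      score = sc$score, n_ecis_pfams = sc$n_distinct_domains,
      excluded = !is.na(reason), exclusion_reason = reason,
      window_gene_ids = list(window$gene_id),
      fiber_gene_ids = list(fib$gene_id)
    )
  })
  bind_rows(rows) %>%
    arrange(.data$genome_id, .data$contig_id, .data$first_index) %>%
    mutate(locus_id = sprintf("LOCUS%05d", row_number())) %>%
    select("locus_id", dplyr::everything())
}

#' Fiber records linked to retained loci
#'
#' @param loci Locus table from [call_loci()].
#' @param hits Hit tibble.
#' @param config Pipeline configuration.
#' @param retained_only Drop fibers of excluded loci (default TRUE).
#' @return A tibble of fiber records: `gene_id`, `locus_id`, `ebap_type`
#'   and the best eBAP hit columns.
#' @export
locus_fibers <- function(loci, hits, config = ecis_config(),
                         retained_only = TRUE) {
  use <- if (retained_only) loci %>% filter(!.data$excluded) else loci
  if (nrow(use) == 0) {
    return(tibble(gene_id = character(), locus_id = character(),
                  ebap_type = character(), domain_id = character(),
                  ali_start = integer(), ali_end = integer(),
                  bit_score = double(), e_value = double()))
  }
  purrr::map(seq_len(nrow(use)), function(i) {
    ids <- use$fiber_gene_ids[[i]]
    if (length(ids) == 0) return(NULL)
    assign_ebap(hits, config, gene_ids = ids) %>%
      mutate(locus_id = use$locus_id[i])
  }) %>%
    bind_rows() %>%
    select("gene_id", "locus_id", "ebap_type", "domain_id",
           "ali_start", "ali_end", "bit_score", "e_value")
}

#' Multi-fiber statistics over a locus catalogue
#'
#' @param loci Locus table from [call_loci()] (retained loci are used).
#' @param fibers Fiber table from [locus_fibers()].
#' @return A one-row tibble: `n_loci_with_fiber`, `multi_fiber_fraction`
#'   (share of fiber-bearing loci with two or more fibers; `NA` if no
#'   fiber-bearing loci), `max_fibers_per_locus`, and `per_ebap_counts`
#'   (list-column tibble of `ebap_type`, `n`).
#' @export
locus_fiber_stats <- function(loci, fibers) {
  per_locus <- fibers %>% count(.data$locus_id, name = "n_fibers")
  n_with <- nrow(per_locus)
  tibble(
    n_loci_with_fiber = n_with,
    multi_fiber_fraction = if (n_with == 0) NA_real_ else
      sum(per_locus$n_fibers >= 2) / n_with,
    max_fibers_per_locus = if (n_with == 0) NA_integer_ else
      max(per_locus$n_fibers),
    per_ebap_counts = list(fibers %>% count(.data$ebap_type, name = "n"))
  )
}

#' Pfam composition upstream of fiber genes
#'
#' For each fiber of each retained locus, reports the gene immediately
#' upstream in the locus reading direction: the dominant strand is the
#' majority strand among locus member genes (ties resolve to `+` and are
#' recorded); upstream means the previous ordinal for `+`-dominant loci and
#' the next ordinal for `-`-dominant ones. Fibers at a contig edge are
#' reported with an absent neighborhood.
#'
#' @param loci Locus table from [call_loci()].
#' @param fibers Fiber table from [locus_fibers()].
#' @param genes,hits Gene and hit tibbles.
#' @return A tibble with one row per (fiber, upstream domain):
#'   `locus_id`, `fiber_gene_id`, `dominant_strand`, `strand_tie`,
#'   `upstream_gene_id` (`NA` at contig edges) and `upstream_domain`
#'   (`NA` when absent or hitless). Summarise with `dplyr::count()`.
#' @export
upstream_neighborhood <- function(loci, fibers, genes, hits) {
  use <- loci %>% filter(!.data$excluded)
  rows <- purrr::map(seq_len(nrow(use)), function(i) {
    lc <- use[i, ]
    members <- genes %>%
      filter(.data$genome_id == lc$genome_id,
             .data$contig_id == lc$contig_id,
             .data$gene_index >= lc$first_index,
             .data$gene_index <= lc$last_index)
    n_plus <- sum(members$strand == "+")
    n_minus <- sum(members$strand == "-")
    dominant <- if (n_plus >= n_minus) "+" else "-"
    tie <- n_plus == n_minus
    fib <- fibers %>% filter(.data$locus_id == lc$locus_id)
    purrr::map(fib$gene_id, function(fg) {
      fg_idx <- genes$gene_index[genes$gene_id == fg]
      up_idx <- if (dominant == "+") fg_idx - 1L else fg_idx + 1L
      up <- genes %>%
        filter(.data$genome_id == lc$genome_id,
               .data$contig_id == lc$contig_id,
               .data$gene_index == up_idx)
      if (nrow(up) == 0) {
        return(tibble(
          locus_id = lc$locus_id, fiber_gene_id = fg,
          dominant_strand = dominant, strand_tie = tie,
          upstream_gene_id = NA_character_,
          upstream_domain = NA_character_
        ))
      }
      doms <- hits$domain_id[hits$gene_id == up$gene_id]
      tibble(
        locus_id = lc$locus_id, fiber_gene_id = fg,
        dominant_strand = dominant, strand_tie = tie,
        upstream_gene_id = up$gene_id,
        upstream_domain = if (length(doms) == 0) NA_character_ else doms
      )
    }) %>% bind_rows()
  })
  bind_rows(rows)
}
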