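#' Summarise a fiber catalogue
#'
#' Per-eBAP fiber counts (including an explicit `none` bucket so totals are
#' conserved), total fibers, locus count, and multi-fiber statistics.
#'
#' @param fibers Fiber tibble with `gene_id`, `locus_id`, `ebap_type`.
#' @param loci Locus tibble with `locus_id` (retained loci); may be `NULL`
#'   when only fiber counts are wanted.
#' @return A one-row tibble: `total_fibers`, `n_loci`,
#'   `n_loci_with_fiber`, `multi_fiber_fraction`, `max_fibers_per_locus`,
#'   `per_ebap_counts` (list-column tibble `ebap_type`, `n` whose counts
#'   sum to `total_fibers`).
#' @export
summarize_catalogue <- function(fibers, loci = NULL) {
  if (!is.null(loci) && nrow(fibers) > 0) {
    unknown <- setdiff(unique(fibers$locus_id), loci$locus_id)
    if (length(unknown) > 0) {
      abort(sprintf("fiber references unknown locus: %s", unknown[1]),
            class = "ecisfiber_integrity_error")
    }
  }
  stats <- locus_fiber_stats(if (is.null(loci)) tibble() else loci, fibers)
  tibble(
    total_fibers = nrow(fibers),
    n_loci = if (is.null(loci)) NA_integer_ else nrow(loci),
    n_loci_with_fiber = stats$n_loci_with_fiber,
    multi_fiber_fraction = stats$multi_fiber_fraction,
    max_fibers_per_locus = stats$max_fibers_per_locus,
    per_ebap_counts = stats$per_ebap_counts
  )
}

#' False-positive percentage
#'
#' `100 * n_nonfiber / n_total`, rounded half-up to two decimals (so 8
#' clear non-fiber hits among 3445 candidates print as 0.23).
#'
#' @param n_nonfiber Number of non-fiber hits among the candidates.
#' @param n_total Total candidates (> 0).
#' @return The percentage, rounded half-up to 2 decimals.
#' @examples
#' false_positive_rate(8, 3445)
#' @export
false_positive_rate <- function(n_nonfiber, n_total) {
  if (length(n_total) != 1 || n_total <= 0) {
    abort("n_total must be positive", class = "ecisfiber_param_error")
  }
  if (n_nonfiber < 0 || n_nonfiber > n_total) {
    abort("n_nonfiber must lie in [0, n_total]",
          class = "ecisfiber_param_error")
  }
  round_half_up(100 * n_nonfiber / n_total, 2)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Relative domain-position profile per structural cluster
#'
#' For each domain segment, the relative midpoint is
#' `((start + end) / 2) / protein_length`; per cluster the size and mean
#' midpoint are reported (the scatter summary of cluster size against
#' average relative position along the fiber). Invariant to uniform
#' scaling of residue numbering and protein length.
#'
#' @param segments Tibble with `protein_id`, `start`, `end`.
#' @param protein_lengths Tibble with `protein_id`, `protein_length`.
#' @param cluster_assignments Tibble with `protein_id`, `start`, `end`,
#'   `cluster_id` (from external structural clustering), matched by exact
#'   segment identity.
#' @return A tibble `cluster_id`, `cluster_size`,
#'   `mean_relative_midpoint`.
#' @export
domain_position_profile <- function(segments, protein_lengths,
                                    cluster_assignments) {
  df <- segments %>%
    left_join(protein_lengths, by = "protein_id") %>%
    left_join(cluster_assignments, by = c("protein_id", "start", "end"))
  if (anyNA(df$protein_length)) {
    abort("segment protein without a known length",
          class = "ecisfiber_integrity_error")
  }
  if (any(df$end > df$protein_length)) {
    abort("segment extends beyond its protein length",
          class = "ecisfiber_integrity_error")
  }
  df %>%
    mutate(rel_mid = ((.data$start + .data$end) / 2) / .data$protein_length) %>%
    group_by(.data$cluster_id) %>%
    summarise(cluster_size = n(),
              mean_relative_midpoint = mean(.data$rel_mid),
              .groups = "drop") %>%
    arrange(.data$cluster_id)
}
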