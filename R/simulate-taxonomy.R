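#' Simulate per-domain kingdom-count taxonomy tables
#'
#' Emulates the input of the taxonomic-incongruence screen: for each domain
#' a count of family members per kingdom (Bacteria, Archaea, Eukaryota,
#' Viruses). Planted HGT domains draw their non-bacterial fraction
#' uniformly in (0.92, 1.0); non-HGT domains in (0.0, 0.5), so the 0.90
#' screening threshold separates the two bands with margin. Each domain has
#' at least 20 family members. Exactly
#' `round(n_domains * planted_hgt_fraction)` domains are planted as HGT.
#'
#' @param n_domains Number of domains.
#' @param planted_hgt_fraction Fraction of domains planted as HGT
#'   candidates (default 0).
#' @param seed Integer seed.
#' @param path Optional TSV output path (`domain_id`, `bacteria`,
#'   `archaea`, `eukaryota`, `viruses`).
#' @return A list with `taxonomy` (counts tibble) and `truth`
#'   (`domain_id`, `planted_hgt`).
#' @examples
#' sim <- simulate_taxonomy(10, 0.3, seed = 1)
#' sum(sim$truth$planted_hgt)
#' @export
simulate_taxonomy <- function(n_domains, planted_hgt_fraction = 0,
                              seed = 1, path = NULL) {
  if (n_domains < 1) {
    abort("n_domains must be >= 1", class = "ecisfiber_param_error")
  }
  if (planted_hgt_fraction < 0 || planted_hgt_fraction > 1) {
    abort("planted_hgt_fraction must lie in [0, 1]",
          class = "ecisfiber_param_error")
  }
  with_seed(seed, {
    n_hgt <- round(n_domains * planted_hgt_fraction)
    planted <- rep(FALSE, n_domains)
    if (n_hgt > 0) planted[sample.int(n_domains, n_hgt)] <- TRUE

    total <- sample(40:200, n_domains, replace = TRUE)
    frac <- ifelse(planted, runif(n_domains, 0.92, 1.0),
                   runif(n_domains, 0.0, 0.5))
    # ceiling keeps the planted band strictly above the threshold after
    # integer rounding; floor keeps the background band strictly below
    nonbact <- ifelse(planted, ceiling(frac * total), floor(frac * total))
    nonbact <- pmin(nonbact, total)
    bacteria <- total - nonbact

    split3 <- t(vapply(nonbact, function(nb) {
      if (nb == 0) return(c(0, 0, 0))
      p <- runif(3)
      p <- p / sum(p)
      counts <- floor(p * nb)
      counts[1] <- counts[1] + nb - sum(counts)
      counts
    }, numeric(3)))

    taxonomy <- tibble(
      domain_id = sprintf("DOM%04d", seq_len(n_domains)),
      bacteria = as.integer(bacteria),
      archaea = as.integer(split3[, 1]),
      eukaryota = as.integer(split3[, 2]),
      viruses = as.integer(split3[, 3])
    )
    truth <- tibble(domain_id = taxonomy$domain_id, planted_hgt = planted)
    if (!is.null(path)) {
      readr::write_tsv(taxonomy, path, progress = FALSE)
    }
    list(taxonomy = taxonomy, truth = truth)
  })
}

#' Read a per-domain kingdom-count taxonomy table
#'
#' @param path TSV with columns `domain_id`, `bacteria`, `archaea`,
#'   `eukaryota`, `viruses`.
#' @return A tibble of kingdom counts.
#' @export
read_taxonomy_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("taxonomy table not found: %s", path),
          class = "ecisfiber_io_error")
  }
  tax <- readr::read_tsv(path, col_types = readr::cols(
    domain_id = readr::col_character(),
    .default = readr::col_integer()
  ), progress = FALSE)
  need <- c("domain_id", "bacteria", "archaea", "eukaryota", "viruses")
  missing <- setdiff(need, names(tax))
  if (length(missing) > 0) {
    abort(sprintf("taxonomy table is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "ecisfiber_schema_error")
  }
  tax
}
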