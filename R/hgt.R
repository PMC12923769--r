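#' Kingdom-level representation ratios
#'
#' Divides each kingdom's sequence count by the domain's total; fractions
#' sum to 1. Domains with zero total are returned with `screened = FALSE`
#' and NA fractions rather than an error.
#'
#' @param taxonomy Tibble with `domain_id`, `bacteria`, `archaea`,
#'   `eukaryota`, `viruses` (counts).
#' @return The input with added `total`, per-kingdom `frac_*` columns, and
#'   `screened`.
#' @export
kingdom_ratios <- function(taxonomy) {
  taxonomy %>%
    mutate(
      total = .data$bacteria + .data$archaea + .data$eukaryota + .data$viruses,
      screened = .data$total > 0,
      frac_bacteria = if_else(.data$screened, .data$bacteria / .data$total, NA_real_),
      frac_archaea = if_else(.data$screened, .data$archaea / .data$total, NA_real_),
      frac_eukaryota = if_else(.data$screened, .data$eukaryota / .data$total, NA_real_),
      frac_viruses = if_else(.data$screened, .data$viruses / .data$total, NA_real_)
    )
}

#' Flag horizontally transferred domain candidates
#'
#' A domain is flagged when strictly more than `threshold` (default 0.90,
#' the ">90%" rule read literally: a fraction of exactly 0.90 is not
#' flagged) of its family members are non-bacterial. The dominant
#' non-bacterial kingdom is the argmax over Archaea, Eukaryota and Viruses
#' with a documented tie order Eukaryota > Viruses > Archaea. With
#' `archaea_nonbacterial = FALSE` the screen runs in
#' prokaryote-vs-(eukaryote+virus) mode instead.
#'
#' @param taxonomy Kingdom-count tibble (see [kingdom_ratios()]).
#' @param threshold Non-bacterial fraction threshold (default 0.90).
#' @param archaea_nonbacterial Count Archaea as non-bacterial
#'   (default TRUE).
#' @return A tibble `domain_id`, `nonbacterial_fraction`,
#'   `dominant_nonbacterial_kingdom`, `flagged`, `screened`. Scaling all
#'   counts by a positive constant leaves the result unchanged.
#' @examples
#' tax <- tibble::tibble(domain_id = "C1q", bacteria = 5, archaea = 0,
#'                       eukaryota = 95, viruses = 0)
#' flag_hgt(tax)
#' @export
flag_hgt <- function(taxonomy, threshold = 0.90,
                     archaea_nonbacterial = TRUE) {
  r <- kingdom_ratios(taxonomy)
  nonbact <- if (archaea_nonbacterial) {
    1 - r$frac_bacteria
  } else {
    r$frac_eukaryota + r$frac_viruses
  }
  # tie order Eukaryota > Viruses > Archaea
  km <- cbind(eukaryota = r$frac_eukaryota,
              viruses = r$frac_viruses,
              archaea = r$frac_archaea)
  if (!archaea_nonbacterial) km <- km[, c("eukaryota", "viruses"), drop = FALSE]
  dominant <- apply(km, 1, function(v) {
    if (all(is.na(v)) || sum(v, na.rm = TRUE) == 0) return(NA_character_)
    names(v)[which.max(v)]
  })
  tibble(
    domain_id = r$domain_id,
    nonbacterial_fraction = nonbact,
    dominant_nonbacterial_kingdom = dominant,
    flagged = !is.na(nonbact) & nonbact > threshold,
    screened = r$screened
  )
}
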