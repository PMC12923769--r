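#' Pipeline configuration
#'
#' Bundles every tunable threshold of the fiber-discovery pipeline into a
#' single validated list. Defaults are the values used throughout the
#' catalogue analysis: gene-gap clustering at 5 ordinals, all-vs-all pair
#' filtering at e-value 1e-10 with 50% mutual coverage and alignment length
#' in 10--500 residues, gradient clustering at 40/35/30% identity with a
#' minimum cluster size of 5, profile-scan filtering at e-value 1e-5 and
#' bit score 12, an 8 Angstrom C-alpha contact cutoff, and a +-4 residue
#' boundary tolerance for redundant domain parses.
#'
#' @param max_gene_gap Maximum ordinal gap between consecutive seed genes in
#'   one locus (genes; default 5).
#' @param window_expand Genes added on each side of a locus when pooling
#'   fiber candidates (default 5).
#' @param allvsall_evalue_max E-value ceiling for all-vs-all pair hits
#'   (default 1e-10).
#' @param min_pair_coverage Minimum of query/subject coverage for a pair hit
#'   (fraction; default 0.50).
#' @param fragment_range Admissible alignment length interval in residues
#'   (default c(10, 500)).
#' @param gradient_identities Decreasing identity thresholds for gradient
#'   clustering (default c(0.40, 0.35, 0.30)).
#' @param min_cluster_size Clusters below this size are discarded (default 5).
#' @param scan_evalue_max E-value ceiling for profile-scan hits (default 1e-5).
#' @param scan_bitscore_min Bit-score floor for profile-scan hits (default 12).
#' @param ca_cutoff C-alpha distance cutoff for best-friend contacts
#'   (Angstrom; default 8.0).
#' @param boundary_tolerance Residue tolerance for redundant-domain boundary
#'   matching (default 4).
#' @param hgt_fraction_threshold Non-bacterial fraction above which a domain
#'   is flagged as an HGT candidate (strict inequality; default 0.90).
#' @param nterm_window An eBAP anchor hit must start within this many
#'   residues of the N-terminus (default 100).
#' @param min_domain_residues Minimum residues for a structural domain
#'   segment (default 30).
#' @param min_edge_support Minimum number of best-friend relations for an
#'   SSE-pair edge (default 1).
#' @param locus_score_min Minimum marker-weighted score for locus retention
#'   (default 6, i.e. roughly two marker Pfams).
#' @param overlap_tolerance Residues of interval overlap tolerated between
#'   resolved domain hits (default 10).
#' @param neighbor_exclusion Sequence separation at or below which residues
#'   are not best-friend candidates (default 2).
#'
#' @return A validated list of class `ecis_config`.
#' @examples
#' cfg <- ecis_config()
#' cfg$ca_cutoff
#' @export
ecis_config <- function(max_gene_gap = 5,
                        window_expand = 5,
                        allvsall_evalue_max = 1e-10,
                        min_pair_coverage = 0.50,
                        fragment_range = c(10, 500),
                        gradient_identities = c(0.40, 0.35, 0.30),
                        min_cluster_size = 5,
                        scan_evalue_max = 1e-5,
                        scan_bitscore_min = 12,
                        ca_cutoff = 8.0,
                        boundary_tolerance = 4,
                        hgt_fraction_threshold = 0.90,
                        nterm_window = 100,
                        min_domain_residues = 30,
                        min_edge_support = 1,
                        locus_score_min = 6,
                        overlap_tolerance = 10,
                        neighbor_exclusion = 2) {
  cfg <- list(
    max_gene_gap = max_gene_gap,
    window_expand = window_expand,
    allvsall_evalue_max = allvsall_evalue_max,
    min_pair_coverage = min_pair_coverage,
    fragment_range = fragment_range,
    gradient_identities = gradient_identities,
    min_cluster_size = min_cluster_size,
    scan_evalue_max = scan_evalue_max,
    scan_bitscore_min = scan_bitscore_min,
    ca_cutoff = ca_cutoff,
    boundary_tolerance = boundary_tolerance,
    hgt_fraction_threshold = hgt_fraction_threshold,
    nterm_window = nterm_window,
    min_domain_residues = min_domain_residues,
    min_edge_support = min_edge_support,
    locus_score_min = locus_score_min,
    overlap_tolerance = overlap_tolerance,
    neighbor_exclusion = neighbor_exclusion
  )
  validate_ecis_config(cfg)
  structure(cfg, class = "ecis_config")
}

validate_ecis_config <- function(cfg) {
  pos <- c(
    "max_gene_gap", "window_expand", "allvsall_evalue_max", "min_pair_coverage",
    "min_cluster_size", "scan_evalue_max", "ca_cutoff", "boundary_tolerance",
    "hgt_fraction_threshold", "nterm_window", "min_domain_residues",
    "min_edge_support", "locus_score_min"
  )
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("config field '%s' must be a single positive number", f),
            class = "ecisfiber_config_error")
    }
  }
  frac <- c("min_pair_coverage", "hgt_fraction_threshold")
  for (f in frac) {
    if (cfg[[f]] > 1) {
      abort(sprintf("config field '%s' must lie in (0, 1]", f),
            class = "ecisfiber_config_error")
    }
  }
  gi <- cfg$gradient_identities
  if (any(gi <= 0) || any(gi > 1) || is.unsorted(rev(gi), strictly = TRUE)) {
    abort("gradient_identities must be strictly decreasing fractions in (0, 1]",
          class = "ecisfiber_config_error")
  }
  fr <- cfg$fragment_range
  if (length(fr) != 2L || fr[1] <= 0 || fr[1] >= fr[2]) {
    abort("fragment_range must be a positive increasing interval",
          class = "ecisfiber_config_error")
  }
  if (cfg$overlap_tolerance < 0 || cfg$neighbor_exclusion < 0) {
    abort("overlap_tolerance and neighbor_exclusion must be non-negative",
          class = "ecisfiber_config_error")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a JSON file
#'
#' The file holds a flat key-value object whose keys mirror the arguments of
#' [ecis_config()]; absent keys keep their defaults.
#'
#' @param path Path to a JSON configuration file.
#' @return An `ecis_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "ecisfiber_io_error")
  }
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(ecis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
          class = "ecisfiber_config_error")
  }
  do.call(ecis_config, vals)
}

#' Default marker-weight table for eCIS locus scoring
#'
#' Marker Pfams highly distinctive of eCIS operons (DUF4157, Pvc16_N,
#' CIS_tube, DUF6519, Phage_base_V, GPW_gp25, Baseplate_J, Tail_P2_I) carry
#' weight 3; other eCIS-enriched Pfams carry weight 1. The exact per-family
#' weights used for the published catalogue are supplementary configuration,
#' so this table is editable: pass your own tibble with the same columns to
#' any scoring function.
#'
#' @return A tibble with columns `domain_id`, `weight`, `is_marker`.
#' @examples
#' default_marker_weights()
#' @export
default_marker_weights <- function() {
  markers <- c(
    "DUF4157", "Pvc16_N", "CIS_tube", "DUF6519",
    "Phage_base_V", "GPW_gp25", "Baseplate_J", "Tail_P2_I"
  )
  enriched <- c(
    "Phage_sheath_1", "Phage_tube", "VgrG", "Afp2", "Afp5", "LysM",
    "Phage_tail_S", "Phage_GPD", "PAAR_motif", "Pvc15", "AAA_14"
  )
  tibble(
    domain_id = c(markers, enriched),
    weight = c(rep(3, length(markers)), rep(1, length(enriched))),
    is_marker = c(rep(TRUE, length(markers)), rep(FALSE, length(enriched)))
  )
}

#' Default exclusion Pfam table
#'
#' Loci containing any of these families are excluded as likely non-eCIS:
#' T6SS components (membrane-anchored contractile systems that share tube
#' and sheath folds with eCIS) and phage capsid families (true prophages).
#' The `category` column supplies the exclusion reason recorded on the
#' locus call.
#'
#' @return A tibble with columns `domain_id`, `category` (`"t6ss"` or
#'   `"capsid"`).
#' @export
default_exclusion_set <- function() {
  t6ss <- c(
    "T6SS_TssM", "T6SS_TssL", "T6SS_TssJ", "T6SS_TssK", "T6SS_TssF",
    "T6SS_TssG", "T6SS_TssA", "T6SS_TssB", "T6SS_TssC", "T6SS_Vgr",
    "T6SS_HCP", "ImpA_N", "ImpE", "DotU", "IcmF", "EvpB", "VasD", "VasL"
  )
  capsid <- c("Phage_capsid", "HK97", "Phage_cap_E", "Terminase_6")
  tibble(
    domain_id = c(t6ss, capsid),
    category = c(rep("t6ss", length(t6ss)), rep("capsid", length(capsid)))
  )
}
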