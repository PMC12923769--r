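#' Filter all-vs-all pair hits
#'
#' Retains a pair hit iff its e-value is at most `allvsall_evalue_max`, the
#' smaller of query and subject coverage reaches `min_pair_coverage`, and
#' the alignment length falls inside `fragment_range` (10--500 residues by
#' default). Self-hits are removed.
#'
#' @param pairs Tibble of pair hits with columns `query_id`, `subject_id`,
#'   `percent_identity` (fraction), `aln_len`, `q_cov`, `s_cov`,
#'   `bit_score`, `e_value`.
#' @param config Pipeline configuration.
#' @return The retained rows.
#' @export
filter_pair_hits <- function(pairs, config = ecis_config()) {
  pairs %>%
    filter(.data$query_id != .data$subject_id,
           .data$e_value <= config$allvsall_evalue_max,
           pmin(.data$q_cov, .data$s_cov) >= config$min_pair_coverage,
           .data$aln_len >= config$fragment_range[1],
           .data$aln_len <= config$fragment_range[2])
}

seq_kmers <- function(s, k = 4L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Estimated pairwise identity (shared k-mer heuristic)
#'
#' A fast stand-in for alignment-based identity used by the internal
#' clusterer: the fraction of distinct 4-mers of the shorter sequence's
#' 4-mer set shared with the other sequence. Exact duplicates score 1;
#' unrelated random sequences score near 0. This heuristic is a desk-scale
#' surrogate -- production runs plug in external clusterer output instead.
#'
#' @param a,b Protein sequences (character scalars).
#' @param k K-mer size (default 4).
#' @return Estimated identity in [0, 1].
#' @export
seq_identity_est <- function(a, b, k = 4L) {
  ka <- seq_kmers(a, k)
  kb <- seq_kmers(b, k)
  if (length(ka) == 0 || length(kb) == 0) return(0)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Greedy longest-first sequence clustering
#'
#' Deterministic greedy clustering at one identity level: sequences are
#' processed longest first (ties by id, ascending); each sequence joins the
#' earliest-founded representative with estimated identity at least
#' `identity_threshold` and length coverage (shorter/longer) at least
#' `coverage_threshold`, or founds its own cluster.
#'
#' @param seqs Tibble with columns `seq_id`, `sequence`.
#' @param identity_threshold Identity threshold in (0, 1].
#' @param coverage_threshold Mutual length coverage threshold (default 0.5).
#' @return A tibble `cluster_id`, `representative_id`, `member_id`,
#'   `identity_level`.
#' @export
greedy_cluster <- function(seqs, identity_threshold,
                           coverage_threshold = 0.5) {
  if (nrow(seqs) == 0) {
    return(tibble(cluster_id = character(), representative_id = character(),
                  member_id = character(), identity_level = double()))
  }
  ord <- order(-nchar(seqs$sequence), seqs$seq_id)
  ids <- seqs$seq_id[ord]
  ss <- seqs$sequence[ord]
  reps <- integer(0)          # indices into ids/ss
  member_of <- integer(length(ids))
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (r in seq_along(reps)) {
      j <- reps[r]
      lens <- c(nchar(ss[i]), nchar(ss[j]))
      cov <- min(lens) / max(lens)
      if (cov >= coverage_threshold &&
          seq_identity_est(ss[i], ss[j]) >= identity_threshold) {
        member_of[i] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      member_of[i] <- length(reps)
    }
  }
  tibble(
    cluster_id = sprintf("SC%04d", member_of),
    representative_id = ids[reps[member_of]],
    member_id = ids,
    identity_level = identity_threshold
  ) %>% arrange(.data$cluster_id, .data$member_id)
}

#' Gradient-identity clustering with cluster-size filtering
#'
#' Clusters at each threshold of the decreasing gradient (40/35/30% by
#' default) in turn: clusters reaching `min_cluster_size` members are kept
#' and their members removed; the remaining sequences are re-clustered at
#' the next, more permissive, threshold. After the final threshold,
#' sub-size clusters are discarded and their members reported unclustered.
#' Kept members plus unclustered ids always partition the input.
#'
#' @param seqs Tibble with columns `seq_id`, `sequence`.
#' @param config Pipeline configuration (`gradient_identities`,
#'   `min_cluster_size`, `min_pair_coverage`).
#' @return A list with `clusters` (tibble as in [greedy_cluster()], one row
#'   per kept member) and `unclustered` (character vector of seq ids).
#' @export
gradient_cluster <- function(seqs, config = ecis_config()) {
  remaining <- seqs
  kept <- list()
  step <- 0L
  for (thr in config$gradient_identities) {
    if (nrow(remaining) == 0) break
    step <- step + 1L
    cl <- greedy_cluster(remaining, thr, config$min_pair_coverage)
    sizes <- cl %>% count(.data$cluster_id, name = "size")
    big <- sizes$cluster_id[sizes$size >= config$min_cluster_size]
    keep <- cl %>% filter(.data$cluster_id %in% big) %>%
      mutate(cluster_id = sprintf("G%d_%s", step, .data$cluster_id))
    kept[[step]] <- keep
    remaining <- remaining %>% filter(!.data$seq_id %in% keep$member_id)
  }
  clusters <- bind_rows(kept)
  if (nrow(clusters) == 0) {
    clusters <- tibble(cluster_id = character(), representative_id = character(),
                       member_id = character(), identity_level = double())
  }
  list(clusters = clusters, unclustered = remaining$seq_id)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build a per-column residue-frequency profile from an alignment
#'
#' A smoothed position-specific frequency profile (pseudocount 0.01,
#' normalised per column) used as a lightweight scorer for cluster
#' membership checks; production pipelines substitute profile HMMs built by
#' an external engine.
#'
#' @param alignment Character vector of aligned sequences of equal length
#'   (gaps `-` contribute nothing to a column).
#' @param pseudocount Added to every residue count (default 0.01).
#' @return A 20 x L matrix of class `ecis_profile`; each column sums to 1.
#' @export
build_profile <- function(alignment, pseudocount = 0.01) {
  if (length(alignment) == 0) {
    abort("alignment is empty", class = "ecisfiber_param_error")
  }
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    abort("ragged alignment: sequences differ in length",
          class = "ecisfiber_integrity_error")
  }
  L <- lens[1]
  mat <- matrix(pseudocount, nrow = 20, ncol = L, dimnames = list(AA20, NULL))
  chars <- do.call(rbind, strsplit(alignment, ""))
  for (j in seq_len(L)) {
    tab <- table(factor(chars[, j], levels = AA20))
    mat[, j] <- mat[, j] + as.numeric(tab)
  }
  mat <- sweep(mat, 2, colSums(mat), "/")
  class(mat) <- c("ecis_profile", class(mat))
  mat
}

#' Score a sequence against a column profile
#'
#' Sum of log frequencies of the sequence's residues at each column
#' (ungapped; the sequence must have the profile's length). Higher is a
#' better fit; member sequences outscore shuffled ones.
#'
#' @param profile An `ecis_profile` matrix.
#' @param sequence A protein sequence of the profile's length.
#' @return A log-probability score.
#' @export
profile_score <- function(profile, sequence) {
  L <- ncol(profile)
  if (nchar(sequence) != L) {
    abort("sequence length must equal the profile column count",
          class = "ecisfiber_param_error")
  }
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, rownames(profile))
  if (anyNA(idx)) {
    abort("sequence contains residues outside the 20-letter alphabet",
          class = "ecisfiber_param_error")
  }
  sum(log(profile[cbind(idx, seq_len(L))]))
}

#' Resolve overlapping domain hits on one protein
#'
#' Score-prioritised greedy resolution: hits are considered by descending
#' bit score (ties: the longer hit, then the smaller alignment start); a
#' hit is retained iff its interval overlap with every already-retained hit
#' is at most `overlap_tolerance` residues. The output is sorted by
#' alignment start, is pairwise compatible, and is a fixed point of the
#' procedure.
#'
#' @param hits Tibble of hits on a single protein with columns `domain_id`,
#'   `ali_start`, `ali_end`, `bit_score` (other columns pass through).
#' @param overlap_tolerance Residues of overlap tolerated (default 10).
#' @return The retained rows, sorted by `ali_start`.
#' @examples
#' h <- tibble::tibble(domain_id = c("A", "B", "C"),
#'                     ali_start = c(1, 50, 160), ali_end = c(100, 150, 200),
#'                     bit_score = c(50, 60, 10))
#' resolve_hits(h, overlap_tolerance = 0)
#' @export
resolve_hits <- function(hits, overlap_tolerance = 10) {
  if (nrow(hits) <= 1L) {
    return(hits %>% arrange(.data$ali_start))
  }
  len <- hits$ali_end - hits$ali_start + 1L
  ord <- order(-hits$bit_score, -len, hits$ali_start)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      ov <- interval_overlap(hits$ali_start[i], hits$ali_end[i],
                             hits$ali_start[j], hits$ali_end[j])
      if (ov > overlap_tolerance) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  hits[kept, , drop = FALSE] %>% arrange(.data$ali_start)
}
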