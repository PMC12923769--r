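suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# Brute-force reference for resolve_hits: enumerate every pairwise-compatible
# subset and return the one that is lexicographically maximal in the same
# priority order the resolver uses (bit score desc, length desc, start asc).
# Independent of the greedy code path.
resolve_hits_bruteforce <- function(hits, overlap_tolerance = 10) {
  n <- nrow(hits)
  if (n == 0) return(hits)
  len <- hits$ali_end - hits$ali_start + 1L
  prio <- order(-hits$bit_score, -len, hits$ali_start)
  compat <- matrix(TRUE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ov <- max(0, min(hits$ali_end[i], hits$ali_end[j]) -
                max(hits$ali_start[i], hits$ali_start[j]) + 1)
    compat[i, j] <- ov <= overlap_tolerance
  }
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    sel <- prio[bitwAnd(bitwShiftL(1, seq_len(n) - 1L), mask) != 0]
    ok <- TRUE
    if (length(sel) > 1) {
      for (a in seq_along(sel)) for (b in seq_along(sel)) {
        if (a < b && !compat[sel[a], sel[b]]) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    vec <- as.integer(prio %in% sel)   # inclusion vector in priority order
    if (is.null(best) || lex_greater(vec, best$vec)) {
      best <- list(vec = vec, sel = sel)
    }
  }
  hits[sort(best$sel), , drop = FALSE] %>% arrange(ali_start)
}

lex_greater <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] > 0
}

random_hit_set <- function(n, seed) {
  set.seed(seed)
  start <- sample(1:300, n, replace = TRUE)
  tibble(
    domain_id = sprintf("D%02d", seq_len(n)),
    ali_start = start,
    ali_end = start + sample(10:120, n, replace = TRUE),
    bit_score = round(runif(n, 10, 100), 1),
    e_value = 10^runif(n, -30, -6)
  )
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); C <- 1 - c_
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(
    x * x * C + c_,     x * y * C - z * s_, x * z * C + y * s_,
    y * x * C + z * s_, y * y * C + c_,     y * z * C - x * s_,
    z * x * C - y * s_, z * y * C + x * s_, z * z * C + c_
  ), 3, 3, byrow = TRUE)
}

transform_model <- function(model, R, shift = c(0, 0, 0)) {
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(R)
  structure_model(model$residue_number,
                  xyz[, 1] + shift[1], xyz[, 2] + shift[2], xyz[, 3] + shift[3],
                  model$plddt)
}

random_aa_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

shuffle_seq <- function(s, seed) {
  set.seed(seed)
  paste(sample(strsplit(s, "")[[1]]), collapse = "")
}

locus_key <- function(d) paste(d$genome_id, d$contig_id, d$first_index, d$last_index)
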