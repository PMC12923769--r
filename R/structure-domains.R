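#' Assign secondary-structure elements
#'
#' Two modes. `"builtin"` classifies from C-alpha geometry alone (the
#' desk-scale path): residue `i` is helix-like when the `i -> i+3` and
#' `i -> i+4` C-alpha distances fall in [4.5, 6.2] and [5.0, 6.9] Angstrom;
#' runs of at least 4 consecutive helix-like residues are emitted as
#' helices (extended to `i+4` of the last passing residue, where the
#' geometry still holds). A residue is strand-like when its virtual-bond
#' rise, `d(i, i+2) / 2` (the net chain extension per residue, ~3.5 for an
#' extended strand vs ~2.7 for a helix), is at least 3.1 Angstrom; runs of
#' at least 3 yield strands (extended to `i+2`). Helix assignment takes
#' precedence where runs would overlap. `"external"` reads a precomputed
#' per-residue assignment file (TSV: `residue_number`, `code`) using DSSP
#' codes: H/G/I are helix, E/B strand; minimum run lengths 4 (helix) and
#' 3 (strand) apply.
#'
#' @param model An `ecis_structure` (at least 4 residues).
#' @param mode `"builtin"` (default) or `"external"`.
#' @param sse_file Assignment TSV, required for `mode = "external"`.
#' @return A tibble `sse_id`, `type` (`"helix"`/`"strand"`), `start`,
#'   `end` (residue numbers, 1-based inclusive).
#' @export
assign_sse <- function(model, mode = c("builtin", "external"),
                       sse_file = NULL) {
  mode <- match.arg(mode)
  if (nrow(model) < 4) {
    abort("model needs at least 4 residues", class = "ecisfiber_param_error")
  }
  if (mode == "external") {
    if (is.null(sse_file)) {
      abort("mode = 'external' requires sse_file",
            class = "ecisfiber_param_error")
    }
    ass <- readr::read_tsv(sse_file, col_types = readr::cols(
      residue_number = readr::col_integer(),
      code = readr::col_character()
    ), progress = FALSE)
    if (!all(ass$residue_number %in% model$residue_number)) {
      abort("assignment file names residues absent from the model",
            class = "ecisfiber_integrity_error")
    }
    code <- setNames(ass$code, ass$residue_number)[as.character(model$residue_number)]
    state <- ifelse(code %in% c("H", "G", "I"), "helix",
                    ifelse(code %in% c("E", "B"), "strand", "coil"))
    state[is.na(state)] <- "coil"
    return(runs_to_sses(model$residue_number, state, extend = c(0L, 0L)))
  }

  xyz <- as.matrix(model[, c("x", "y", "z")])
  n <- nrow(xyz)
  dist_k <- function(k) {
    i <- 1:(n - k)
    sqrt(rowSums((xyz[i + k, , drop = FALSE] - xyz[i, , drop = FALSE])^2))
  }
  d3 <- dist_k(3L)
  d4 <- dist_k(4L)
  d2 <- dist_k(2L)
  helix_like <- rep(FALSE, n)
  helix_like[1:(n - 4)] <- d3[1:(n - 4)] >= 4.5 & d3[1:(n - 4)] <= 6.2 &
    d4 >= 5.0 & d4 <= 6.9
  strand_like <- rep(FALSE, n)
  strand_like[1:(n - 2)] <- d2 / 2 >= 3.1

  state <- rep("coil", n)
  # helix runs >= 4, emitted over i..last+4
  state <- mark_runs(state, helix_like, min_run = 4L, tail = 4L, label = "helix")
  # strand runs >= 3 on residues not already helix, emitted over i..last+2
  strand_like[state != "coil"] <- FALSE
  state <- mark_runs(state, strand_like, min_run = 3L, tail = 2L,
                     label = "strand", protect = state != "coil")
  runs_to_sses(model$residue_number, state, extend = c(0L, 0L))
}

mark_runs <- function(state, flag, min_run, tail, label, protect = NULL) {
  r <- rle(flag)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= min_run) {
      span <- starts[k]:min(length(state), stops[k] + tail)
      if (!is.null(protect)) span <- span[!protect[span]]
      state[span] <- label
    }
  }
  state
}

runs_to_sses <- function(residue_number, state, extend = c(0L, 0L)) {
  r <- rle(state)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  min_len <- c(helix = 4L, strand = 3L)
  rows <- list()
  for (k in seq_along(r$values)) {
    type <- r$values[k]
    if (type == "coil") next
    if (r$lengths[k] < min_len[[type]]) next
    rows[[length(rows) + 1L]] <- tibble(
      type = type,
      start = residue_number[starts[k]],
      end = residue_number[stops[k]]
    )
  }
  out <- if (length(rows) == 0) {
    tibble(type = character(), start = integer(), end = integer())
  } else {
    bind_rows(rows) %>% arrange(.data$start)
  }
  out %>% mutate(sse_id = sprintf("SSE%03d", row_number())) %>%
    select("sse_id", "type", "start", "end")
}

#' Best-friend contact edges between SSEs
#'
#' For each residue of each SSE, the candidates are residues belonging to a
#' different SSE whose sequence separation exceeds `neighbor_exclusion`
#' positions; the residue's best friend is the candidate at minimal
#' C-alpha distance (ties: the lower residue number). If that distance is
#' within `ca_cutoff`, one support count accrues to the unordered SSE pair.
#' An edge exists iff its support reaches `min_edge_support`. Relations are
#' not required to be reciprocal.
#'
#' @param model An `ecis_structure`.
#' @param sses SSE tibble from [assign_sse()].
#' @param config Pipeline configuration (`ca_cutoff`, `min_edge_support`,
#'   `neighbor_exclusion`).
#' @return A tibble `sse_a`, `sse_b` (with `sse_a < sse_b`), `support`,
#'   restricted to pairs meeting `min_edge_support`.
#' @export
best_friend_edges <- function(model, sses, config = ecis_config()) {
  if (nrow(sses) < 2) {
    return(tibble(sse_a = character(), sse_b = character(),
                  support = integer()))
  }
  sses <- sses %>% arrange(.data$start)
  sse_of <- rep(NA_character_, max(model$residue_number))
  for (i in seq_len(nrow(sses))) {
    sse_of[sses$start[i]:sses$end[i]] <- sses$sse_id[i]
  }
  in_sse <- !is.na(sse_of[model$residue_number])
  res <- model$residue_number[in_sse]
  xyz <- as.matrix(model[in_sse, c("x", "y", "z")])
  lab <- sse_of[res]
  n <- length(res)
  support <- list()
  d2mat <- as.matrix(stats::dist(xyz))^2
  cutoff2 <- config$ca_cutoff^2
  for (i in seq_len(n)) {
    cand <- which(lab != lab[i] & abs(res - res[i]) > config$neighbor_exclusion)
    if (length(cand) == 0) next
    dd <- d2mat[i, cand]
    best <- cand[order(dd, res[cand])][1]
    if (d2mat[i, best] <= cutoff2) {
      key <- paste(sort(c(lab[i], lab[best])), collapse = "|")
      support[[key]] <- (support[[key]] %||% 0L) + 1L
    }
  }
  if (length(support) == 0) {
    return(tibble(sse_a = character(), sse_b = character(),
                  support = integer()))
  }
  parts <- strsplit(names(support), "|", fixed = TRUE)
  tibble(
    sse_a = vapply(parts, `[[`, "", 1L),
    sse_b = vapply(parts, `[[`, "", 2L),
    support = as.integer(unlist(support))
  ) %>%
    filter(.data$support >= config$min_edge_support) %>%
    arrange(.data$sse_a, .data$sse_b)
}

#' Connected components of the SSE contact graph
#'
#' Standard connected components over the best-friend edge set; singleton
#' SSEs form their own component. Components are numbered by their
#' smallest member start position, so output is deterministic and
#' invariant to SSE input order.
#'
#' @param sses SSE tibble.
#' @param edges Edge tibble from [best_friend_edges()].
#' @return A tibble `sse_id`, `component_id` (integer).
#' @export
sse_components <- function(sses, edges) {
  unknown <- setdiff(c(edges$sse_a, edges$sse_b), sses$sse_id)
  if (length(unknown) > 0) {
    abort(sprintf("edges name unknown SSE(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "ecisfiber_integrity_error")
  }
  g <- igraph::graph_from_data_frame(
    d = edges[, c("sse_a", "sse_b")],
    directed = FALSE,
    vertices = data.frame(name = sses$sse_id)
  )
  comp <- igraph::components(g)$membership
  out <- tibble(sse_id = names(comp), component_id = as.integer(comp)) %>%
    left_join(sses[, c("sse_id", "start")], by = "sse_id")
  # renumber components by smallest member start
  ranks <- out %>%
    group_by(.data$component_id) %>%
    summarise(min_start = min(.data$start), .groups = "drop") %>%
    arrange(.data$min_start) %>%
    mutate(new_id = row_number())
  out %>%
    left_join(ranks[, c("component_id", "new_id")], by = "component_id") %>%
    mutate(component_id = .data$new_id) %>%
    arrange(.data$component_id, .data$start) %>%
    select("sse_id", "component_id")
}

#' Turn SSE components into domain segments
#'
#' Each component's provisional segment spans from its first SSE start to
#' its last SSE end. Adjacent segments then partition the chain: the
#' non-SSE residues between two consecutive components are split at the
#' midpoint of the gap between their nearest flanking SSEs (contested
#' residues where spans overlap are assigned by the same midpoint rule, so
#' no residue belongs to two segments). Segments shorter than
#' `min_domain_residues` are dropped. Mean pLDDT is computed over the
#' final span.
#'
#' @param components Tibble from [sse_components()].
#' @param sses SSE tibble.
#' @param model The `ecis_structure` (for pLDDT).
#' @param config Pipeline configuration.
#' @return A tibble `segment_id`, `start`, `end`, `n_residues`,
#'   `n_sses`, `sse_ids` (list), `mean_plddt`, sorted by `start`.
#' @export
components_to_segments <- function(components, sses, model,
                                   config = ecis_config()) {
  if (nrow(components) == 0) {
    return(empty_segments())
  }
  spans <- components %>%
    left_join(sses, by = "sse_id") %>%
    group_by(.data$component_id) %>%
    summarise(span_start = min(.data$start), span_end = max(.data$end),
              sse_ids = list(.data$sse_id), n_sses = n(),
              .groups = "drop") %>%
    arrange(.data$span_start)
  k <- nrow(spans)
  seg_start <- spans$span_start
  seg_end <- spans$span_end
  if (k > 1) {
    for (i in 1:(k - 1)) {
      b <- floor((spans$span_end[i] + spans$span_start[i + 1]) / 2)
      b <- min(max(b, spans$span_start[i]), spans$span_start[i + 1] - 1L)
      seg_end[i] <- b
      seg_start[i + 1] <- b + 1L
    }
  }
  plddt_of <- setNames(model$plddt, model$residue_number)
  out <- tibble(
    start = as.integer(seg_start), end = as.integer(seg_end),
    n_residues = as.integer(seg_end - seg_start + 1L),
    n_sses = spans$n_sses, sse_ids = spans$sse_ids,
    mean_plddt = vapply(seq_len(k), function(i) {
      mean(plddt_of[as.character(seg_start[i]:seg_end[i])], na.rm = TRUE)
    }, 0)
  ) %>%
    filter(.data$n_residues >= config$min_domain_residues)
  if (nrow(out) == 0) return(empty_segments())
  out %>%
    arrange(.data$start) %>%
    mutate(segment_id = sprintf("SEG%03d", row_number())) %>%
    select("segment_id", "start", "end", "n_residues", "n_sses",
           "sse_ids", "mean_plddt")
}

empty_segments <- function() {
  tibble(segment_id = character(), start = integer(), end = integer(),
         n_residues = integer(), n_sses = integer(), sse_ids = list(),
         mean_plddt = double())
}

#' Dissect a structure into domains
#'
#' Runs the full graph-based dissection on one chain: SSE assignment,
#' best-friend edges at the C-alpha cutoff, connected components, and
#' component-to-segment refinement.
#'
#' @param model An `ecis_structure`.
#' @param config Pipeline configuration.
#' @param mode,sse_file Passed to [assign_sse()].
#' @return A segment tibble (see [components_to_segments()]); result of
#'   class `ecis_segmentation` with the model kept as an attribute for
#'   plotting.
#' @export
segment_structure <- function(model, config = ecis_config(),
                              mode = "builtin", sse_file = NULL) {
  sses <- assign_sse(model, mode = mode, sse_file = sse_file)
  if (nrow(sses) == 0) {
    out <- empty_segments()
  } else {
    edges <- best_friend_edges(model, sses, config)
    comps <- sse_components(sses, edges)
    out <- components_to_segments(comps, sses, model, config)
  }
  attr(out, "model") <- model
  class(out) <- c("ecis_segmentation", class(out))
  out
}

#' Filter redundant domain parses
#'
#' Two segments are redundant iff both boundary differences are within
#' `boundary_tolerance` residues. Redundancy groups are closed
#' transitively; within a group the segment with the highest mean pLDDT
#' survives (ties: the longer segment, then the smaller start).
#'
#' @param segments Segment tibble (possibly pooled from multiple parses of
#'   one protein).
#' @param config Pipeline configuration.
#' @return The surviving rows, sorted by `start`.
#' @export
filter_redundant <- function(segments, config = ecis_config()) {
  n <- nrow(segments)
  if (n <= 1) return(segments)
  tol <- config$boundary_tolerance
  pairs <- which(
    outer(segments$start, segments$start, function(a, b) abs(a - b) <= tol) &
      outer(segments$end, segments$end, function(a, b) abs(a - b) <= tol),
    arr.ind = TRUE
  )
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = pairs[, 1], to = pairs[, 2]),
    directed = FALSE, vertices = data.frame(name = seq_len(n))
  )
  grp <- igraph::components(g)$membership[as.character(seq_len(n))]
  keep <- vapply(split(seq_len(n), grp), function(ix) {
    sub <- segments[ix, ]
    len <- sub$end - sub$start + 1L
    ix[order(-sub$mean_plddt, -len, sub$start)][1]
  }, 0L)
  segments[sort(keep), , drop = FALSE] %>% arrange(.data$start)
}

#' Extract a domain segment to a PDB file
#'
#' Writes exactly the residues `start..end` with original numbering, chain
#' identifier, coordinates and pLDDT in the B-factor column.
#'
#' @param model An `ecis_structure`.
#' @param start,end Segment bounds (residue numbers, inclusive), within the
#'   model's residue range.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
extract_segment <- function(model, start, end, path) {
  if (start < min(model$residue_number) || end > max(model$residue_number) ||
      start > end) {
    abort(sprintf("segment %d-%d outside model residue range %d-%d",
                  start, end, min(model$residue_number),
                  max(model$residue_number)),
          class = "ecisfiber_range_error")
  }
  sub <- model %>%
    filter(.data$residue_number >= start, .data$residue_number <= end)
  sub2 <- structure_model(sub$residue_number, sub$x, sub$y, sub$z, sub$plddt,
                          structure_id = attr(model, "structure_id") %||% "model",
                          chain_id = attr(model, "chain_id") %||% "A")
  write_structure(sub2, path)
}

#' Fiber elongation (globularity) metric
#'
#' Ratio of the RMS extent of the C-alpha cloud along its largest principal
#' axis to the mean RMS extent along the two remaining axes. Elongated
#' fibers score high (an ideal straight helix far exceeds 5); globular
#' bundles score below ~2. The ratio is at least 1 by construction and
#' invariant under rigid-body transformation. A near-collinear cloud is
#' reported with `degenerate = TRUE` rather than an error.
#'
#' @param model An `ecis_structure` with at least 3 residues.
#' @return A one-row tibble: `ratio`, `degenerate`.
#' @export
elongation_metric <- function(model) {
  if (nrow(model) < 3) {
    abort("elongation metric needs at least 3 residues",
          class = "ecisfiber_param_error")
  }
  xyz <- as.matrix(model[, c("x", "y", "z")])
  sv <- sort(sqrt(prcomp(xyz, center = TRUE, scale. = FALSE)$sdev^2),
             decreasing = TRUE)
  minor <- mean(sv[2:3])
  degenerate <- minor < 1e-6 * sv[1]
  tibble(
    ratio = if (degenerate) Inf else sv[1] / minor,
    degenerate = degenerate
  )
}
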