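#' Interval conventions
#'
#' Residue intervals are 1-based inclusive throughout (the HMMER and PDB
#' convention); gene ordinals are 0-based. These helpers convert a 1-based
#' inclusive interval to half-open `[start, end)` form and back, and compute
#' overlap lengths; converting to half-open and back is the identity.
#'
#' @param start,end Interval bounds, 1-based inclusive (`end >= start`).
#' @return `interval_to_half_open()` returns `c(start, end + 1)`;
#'   `interval_from_half_open()` returns `c(start, end - 1)`;
#'   `interval_overlap()` returns the number of shared residues (0 if
#'   disjoint).
#' @examples
#' interval_from_half_open(interval_to_half_open(3, 10)[1],
#'                         interval_to_half_open(3, 10)[2])
#' interval_overlap(1, 100, 50, 150)
#' @export
interval_to_half_open <- function(start, end) {
  c(start, end + 1L)
}

#' @rdname interval_to_half_open
#' @export
interval_from_half_open <- function(start, end) {
  c(start, end - 1L)
}

#' @rdname interval_to_half_open
#' @param start2,end2 Second interval, 1-based inclusive.
#' @export
interval_overlap <- function(start, end, start2, end2) {
  pmax(0, pmin(end, end2) - pmax(start, start2) + 1)
}
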