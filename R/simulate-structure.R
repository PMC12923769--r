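#' Build a domain plan for the structure generator
#'
#' A domain plan describes an idealized multi-domain chain: for each domain
#' the secondary-structure type, the number of SSEs and their lengths, and
#' the linker lengths between consecutive domains. Within one domain all
#' SSEs share a type and have matched extents so that packed SSEs satisfy
#' the contact guarantee of [simulate_structure()].
#'
#' @param types Character vector, one of `"helix"`/`"strand"` per domain.
#' @param n_sse Integer vector, SSE count per domain (>= 1).
#' @param sse_len List of integer vectors (lengths per SSE), or `NULL` to
#'   use type defaults (helix 12, strand 7).
#' @param linkers Integer vector of linker lengths between consecutive
#'   domains (length `length(types) - 1`); default 24 residues each.
#' @return A `domain_plan` list.
#' @export
domain_plan <- function(types, n_sse, sse_len = NULL, linkers = NULL) {
  nd <- length(types)
  if (nd < 1 || any(!types %in% c("helix", "strand"))) {
    abort("types must be 'helix' or 'strand'", class = "ecisfiber_param_error")
  }
  if (length(n_sse) != nd || any(n_sse < 1)) {
    abort("domain plan needs at least one SSE per domain",
          class = "ecisfiber_param_error")
  }
  if (is.null(sse_len)) {
    sse_len <- lapply(seq_len(nd), function(d) {
      rep(if (types[d] == "helix") 12L else 7L, n_sse[d])
    })
  }
  if (is.null(linkers)) linkers <- rep(24L, max(0L, nd - 1L))
  if (length(linkers) != nd - 1L) {
    abort("need one linker length per inter-domain gap",
          class = "ecisfiber_param_error")
  }
  structure(list(types = types, n_sse = as.integer(n_sse),
                 sse_len = lapply(sse_len, as.integer),
                 linkers = as.integer(linkers)),
            class = "domain_plan")
}

#' Draw a random domain plan
#'
#' Used by the property suites: 2--4 domains, each of one SSE type with
#' comparable per-SSE z-extents (2--4 helices of 12--14 residues, or 4--6
#' strands of 6--8 residues, so every domain clears the 30-residue domain
#' size floor once half of each flanking linker is attributed to it),
#' linkers of 20--30 residues.
#'
#' @param seed Integer seed.
#' @param n_domains Number of domains, or `NULL` to draw 2--4.
#' @return A `domain_plan`.
#' @export
random_domain_plan <- function(seed, n_domains = NULL) {
  with_seed(seed, {
    nd <- n_domains %||% sample(2:4, 1)
    types <- sample(c("helix", "strand"), nd, replace = TRUE)
    n_sse <- ifelse(types == "helix",
                    sample(2:4, nd, replace = TRUE),
                    sample(4:6, nd, replace = TRUE))
    sse_len <- lapply(seq_len(nd), function(d) {
      if (types[d] == "helix") sample(12:14, n_sse[d], replace = TRUE)
      else sample(6:8, n_sse[d], replace = TRUE)
    })
    linkers <- sample(20:30, max(0L, nd - 1L), replace = TRUE)
    domain_plan(types, n_sse, sse_len, linkers)
  })
}

ideal_helix <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  j <- 0:(n - 1L)
  ang <- j * twist * pi / 180
  cbind(x = radius * cos(ang), y = radius * sin(ang), z = j * rise)
}

ideal_strand <- function(n, rise = 3.5) {
  j <- 0:(n - 1L)
  cbind(x = rep(0, n), y = rep(0, n), z = j * rise)
}

# coil that can never satisfy the SSE criteria: zigzag with 2.5 A net
# advance per residue (below the 3.1 A strand rise) and a d(i, i+3)
# exceeding the helix window
coil_trace <- function(n, origin) {
  j <- 0:(n - 1L)
  cbind(
    x = origin[1] + j * 2.5,
    y = origin[2] + ifelse(j %% 2 == 0, 0, 2.86),
    z = rep(origin[3], n)
  )
}

#' Simulate an idealized multi-domain structure with known boundaries
#'
#' Generates a C-alpha-only chain from a [domain_plan()]: helices as ideal
#' traces (1.5 Angstrom rise and 100 degrees twist per residue, radius
#' 2.3 Angstrom), strands as extended traces (3.5 Angstrom per residue).
#' SSEs within one domain are packed side by side (axes 5.5 Angstrom apart,
#' z-centered, joined by compact 3-residue turns that satisfy neither SSE
#' criterion) so every residue's nearest foreign-SSE C-alpha lies within
#' the 8 Angstrom contact cutoff, while distinct domains are offset so all
#' inter-domain C-alpha distances exceed the cutoff by a wide margin
#' (>= 12 Angstrom). Linkers are placed as non-repetitive coil away from
#' the domain row. pLDDT is drawn around 85 inside domains and 50 in
#' linkers (Gaussian jitter, sd 3, clipped to [0, 100]).
#'
#' Residues are numbered 1..L consecutively: domain 1, linker 1, domain 2,
#' and so on. Identical seeds give identical coordinates.
#'
#' @param plan A `domain_plan`.
#' @param seed Integer seed (pLDDT jitter only; geometry is deterministic).
#' @param path Optional output PDB path.
#' @param structure_id Identifier for the model.
#' @return A list with `model` (an `ecis_structure`) and `truth`, a list of
#'   tibbles `domains` (`domain`, `start`, `end`, `plddt_mean`), `linkers`
#'   (`start`, `end`) and `sses` (`domain`, `type`, `start`, `end`).
#' @examples
#' sim <- simulate_structure(domain_plan("helix", 2), seed = 1)
#' nrow(sim$model)
#' @export
simulate_structure <- function(plan, seed = 1, path = NULL,
                               structure_id = "synthetic") {
  if (!inherits(plan, "domain_plan")) {
    abort("plan must be a domain_plan", class = "ecisfiber_param_error")
  }
  nd <- length(plan$types)
  coords <- list()
  plddt_mu <- numeric(0)
  dom_rows <- list()
  link_rows <- list()
  sse_rows <- list()
  res_next <- 1L
  x_base <- 0
  coil_y <- 40

  turn_len <- 3L
  for (d in seq_len(nd)) {
    lens <- plan$sse_len[[d]]
    spans <- if (plan$types[d] == "helix") (lens - 1) * 1.5 else (lens - 1) * 3.5
    dom_start <- res_next
    dom_xyz <- list()
    for (k in seq_along(lens)) {
      base <- if (plan$types[d] == "helix") ideal_helix(lens[k]) else ideal_strand(lens[k])
      base[, "x"] <- base[, "x"] + x_base + (k - 1) * 5.5
      base[, "z"] <- base[, "z"] - spans[k] / 2    # z-center the SSE
      dom_xyz[[length(dom_xyz) + 1L]] <- base
      sse_rows[[length(sse_rows) + 1L]] <- tibble(
        domain = d, type = plan$types[d],
        start = res_next, end = res_next + lens[k] - 1L
      )
      res_next <- res_next + lens[k]
      if (k < length(lens)) {
        # compact 3-residue turn between packed SSEs: tiny steps, so it can
        # satisfy neither the helix nor the strand geometric criterion, and
        # the flanking SSEs stay separate sequence runs
        tx <- x_base + (k - 0.5) * 5.5
        tz <- max(spans) / 2 + 2
        turn <- cbind(x = tx + (0:(turn_len - 1L)) * 0.8,
                      y = rep(4.6, turn_len),
                      z = rep(tz, turn_len))
        dom_xyz[[length(dom_xyz) + 1L]] <- turn
        res_next <- res_next + turn_len
      }
    }
    dom_end <- res_next - 1L
    dom_rows[[d]] <- tibble(domain = d, start = dom_start, end = dom_end)
    coords[[length(coords) + 1L]] <- do.call(rbind, dom_xyz)
    plddt_mu <- c(plddt_mu, rep(85, dom_end - dom_start + 1L))
    dom_width <- (length(lens) - 1) * 5.5 + 4.6
    x_base <- x_base + dom_width + 20

    if (d < nd) {
      ll <- plan$linkers[d]
      link_rows[[d]] <- tibble(start = res_next, end = res_next + ll - 1L)
      coords[[length(coords) + 1L]] <- coil_trace(ll, c(0, coil_y, 0))
      coil_y <- coil_y + 12
      plddt_mu <- c(plddt_mu, rep(50, ll))
      res_next <- res_next + ll
    }
  }

  xyz <- do.call(rbind, coords)
  n <- nrow(xyz)
  plddt <- with_seed(seed, pmin(100, pmax(0, plddt_mu + rnorm(n, 0, 3))))
  model <- structure_model(seq_len(n), xyz[, "x"], xyz[, "y"], xyz[, "z"],
                           plddt, structure_id = structure_id)
  domains <- bind_rows(dom_rows)
  domains$plddt_mean <- vapply(seq_len(nrow(domains)), function(i) {
    mean(plddt[domains$start[i]:domains$end[i]])
  }, 0)
  truth <- list(
    domains = domains,
    linkers = if (length(link_rows) > 0) bind_rows(link_rows) else
      tibble(start = integer(), end = integer()),
    sses = bind_rows(sse_rows)
  )
  if (!is.null(path)) write_structure(model, path)
  list(model = model, truth = truth)
}
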