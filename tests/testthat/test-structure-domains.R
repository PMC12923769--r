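test_that("builtin SSE assignment recognises ideal helices, strands and coil", {
  helix <- simulate_structure(domain_plan("helix", 1, list(12L)), seed = 1)
  sh <- assign_sse(helix$model)
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$type, "helix")
  expect_gte(sh$end - sh$start + 1L, 8L)

  strand <- simulate_structure(domain_plan("strand", 1, list(8L)), seed = 1)
  ss <- assign_sse(strand$model)
  expect_equal(nrow(ss), 1L)
  expect_equal(ss$type, "strand")

  # seeded random-walk coil: criteria fail everywhere
  set.seed(42)
  steps <- matrix(rnorm(60 * 3), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2)) * 3.8
  # force consecutive-step turns so neither criterion can fire
  for (i in 2:nrow(steps)) {
    if (sum(steps[i, ] * steps[i - 1, ]) > 0) steps[i, ] <- -steps[i, ]
  }
  xyz <- apply(steps, 2, cumsum)
  coil <- structure_model(1:60, xyz[, 1], xyz[, 2], xyz[, 3], rep(50, 60))
  expect_equal(nrow(assign_sse(coil)), 0L)
})

test_that("external SSE assignment reads DSSP-style codes with run minima", {
  helix <- simulate_structure(domain_plan("helix", 1, list(20L)), seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  codes <- c(rep("H", 6), rep("-", 4), rep("E", 4), rep("E", 0), rep("-", 3),
             rep("G", 2), "-")
  readr::write_tsv(tibble(residue_number = 1:20, code = codes), f)
  sse <- assign_sse(helix$model, mode = "external", sse_file = f)
  expect_equal(sse$type, c("helix", "strand"))  # G-run of 2 below minimum
  expect_equal(sse$start, c(1L, 11L))
  expect_equal(sse$end, c(6L, 14L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble(residue_number = 90:95, code = "H"), bad)
  expect_error(assign_sse(helix$model, mode = "external", sse_file = bad),
               class = "ecisfiber_integrity_error")
})

test_that("best-friend edges appear within the cutoff and not beyond", {
  packed <- simulate_structure(domain_plan("helix", 2), seed = 1)
  # one domain with two packed helices: edge present
  sses <- assign_sse(packed$model)
  expect_gte(nrow(sses), 2L)
  e <- best_friend_edges(packed$model, sses)
  expect_gte(nrow(e), 1L)

  # same SSEs moved 12 A apart: no edge at the 8 A cutoff
  two <- simulate_structure(random_domain_plan(seed = 2, n_domains = 2),
                            seed = 2)
  sses2 <- assign_sse(two$model)
  dom1 <- sses2[sses2$end <= two$truth$domains$end[1], ]
  dom2 <- sses2[sses2$start >= two$truth$domains$start[2], ]
  e2 <- best_friend_edges(two$model, sses2)
  cross <- e2 %>%
    filter((sse_a %in% dom1$sse_id & sse_b %in% dom2$sse_id) |
             (sse_a %in% dom2$sse_id & sse_b %in% dom1$sse_id))
  expect_equal(nrow(cross), 0L)

  single <- simulate_structure(domain_plan("helix", 1, list(14L)), seed = 1)
  s1 <- assign_sse(single$model)
  expect_equal(nrow(best_friend_edges(single$model, s1)), 0L)
})

test_that("components are standard and deterministically numbered", {
  sses <- tibble(sse_id = c("a", "b", "c"), type = "helix",
                 start = c(1L, 20L, 40L), end = c(10L, 30L, 50L))
  edges <- tibble(sse_a = "a", sse_b = "b", support = 3L)
  comp <- sse_components(sses, edges)
  expect_equal(comp$component_id[comp$sse_id %in% c("a", "b")], c(1L, 1L))
  expect_equal(comp$component_id[comp$sse_id == "c"], 2L)

  none <- sse_components(sses, edges[0, ])
  expect_equal(sort(unique(none$component_id)), 1:3)

  chain <- tibble(sse_a = c("a", "b"), sse_b = c("b", "c"), support = 1L)
  expect_equal(unique(sse_components(sses, chain)$component_id), 1L)

  bad <- tibble(sse_a = "a", sse_b = "zz", support = 1L)
  expect_error(sse_components(sses, bad), class = "ecisfiber_integrity_error")
})

test_that("segments split contested linkers at the midpoint and size-filter", {
  model <- structure_model(1:140, seq(0, by = 3, length.out = 140),
                           rep(0, 140), rep(0, 140), rep(80, 140))
  sses <- tibble(sse_id = c("a", "b", "c", "d"), type = "helix",
                 start = c(1L, 45L, 85L, 120L), end = c(12L, 60L, 95L, 140L))
  comps <- tibble(sse_id = c("a", "b", "c", "d"),
                  component_id = c(1L, 1L, 2L, 2L))
  seg <- components_to_segments(comps, sses, model)
  # spans 1-60 and 85-140; the 61-84 linker splits at floor((60+85)/2) = 72
  expect_equal(seg$start, c(1L, 73L))
  expect_equal(seg$end, c(72L, 140L))
  expect_equal(seg$n_residues, c(72L, 68L))

  # a 40-residue single component survives the 30-residue floor
  one <- components_to_segments(
    tibble(sse_id = "a", component_id = 1L),
    tibble(sse_id = "a", type = "helix", start = 10L, end = 49L),
    model
  )
  expect_equal(nrow(one), 1L)

  # a 12-residue component is dropped
  tiny <- components_to_segments(
    tibble(sse_id = "a", component_id = 1L),
    tibble(sse_id = "a", type = "helix", start = 10L, end = 21L),
    model
  )
  expect_equal(nrow(tiny), 0L)
})

test_that("planted boundaries are recovered across seeded plans", {
  for (s in 1:20) {
    plan <- random_domain_plan(seed = 300 + s)
    sim <- simulate_structure(plan, seed = s)
    seg <- segment_structure(sim$model)
    nd <- nrow(sim$truth$domains)
    expect_equal(nrow(seg), nd, info = sprintf("plan seed %d", 300 + s))
    if (nd > 1) {
      for (i in 1:(nd - 1)) {
        lk <- sim$truth$linkers[i, ]
        expect_gte(seg$end[i], lk$start - 1L)
        expect_lte(seg$end[i], lk$end)
      }
    }
    # disjoint tiling: no residue in two segments
    expect_true(all(seg$start[-1] > seg$end[-nrow(seg)]))
  }
})

test_that("redundancy filtering keeps the most confident parse per group", {
  segs <- tibble(
    segment_id = c("s1", "s2"),
    start = c(10L, 12L), end = c(110L, 108L),
    n_residues = c(101L, 97L), n_sses = 2L, sse_ids = list("a", "a"),
    mean_plddt = c(80, 90)
  )
  expect_equal(filter_redundant(segs)$segment_id, "s2")

  far <- segs %>% mutate(end = c(110L, 140L), mean_plddt = c(80, 90))
  expect_equal(nrow(filter_redundant(far)), 2L)

  # transitive closure: three mutually-near parses leave one survivor
  three <- tibble(
    segment_id = c("s1", "s2", "s3"),
    start = c(10L, 13L, 16L), end = c(110L, 113L, 116L),
    n_residues = 101L, n_sses = 2L, sse_ids = list("a", "a", "a"),
    mean_plddt = c(70, 95, 80)
  )
  expect_equal(filter_redundant(three)$segment_id, "s2")
})

test_that("segment extraction preserves numbering and round-trips", {
  sim <- simulate_structure(random_domain_plan(seed = 8, n_domains = 2),
                            seed = 8)
  path <- withr::local_tempfile(fileext = ".pdb")
  extract_segment(sim$model, 10, 50, path)
  sub <- read_structure(path)
  expect_equal(sub$residue_number, 10:50)
  expect_equal(nrow(sub), 41L)

  full <- withr::local_tempfile(fileext = ".pdb")
  extract_segment(sim$model, 1, nrow(sim$model), full)
  back <- read_structure(full)
  expect_equal(back$residue_number, sim$model$residue_number)

  expect_error(extract_segment(sim$model, 10, nrow(sim$model) + 10, path),
               class = "ecisfiber_range_error")
})

test_that("elongation separates fibers from bundles and ignores rotations", {
  fiber <- simulate_structure(domain_plan("helix", 1, list(100L)), seed = 1)
  m <- elongation_metric(fiber$model)
  expect_gt(m$ratio, 5)
  expect_false(m$degenerate)

  set.seed(9)
  blob <- structure_model(1:200, rnorm(200, 0, 5), rnorm(200, 0, 5),
                          rnorm(200, 0, 5), rep(80, 200))
  expect_lt(elongation_metric(blob)$ratio, 2)

  R <- rotation_matrix(c(1, 2, 3), 1.1)
  rot <- transform_model(fiber$model, R, shift = c(5, -3, 7))
  expect_equal(elongation_metric(rot)$ratio, m$ratio, tolerance = 1e-6)

  line <- structure_model(1:10, 1:10, rep(0, 10), rep(0, 10), rep(80, 10))
  deg <- elongation_metric(line)
  expect_true(deg$degenerate)
})
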