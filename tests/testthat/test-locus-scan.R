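mk_genes <- function(idx, strand = "+", genome = "G1", contig = "c1") {
  tibble(
    genome_id = genome, contig_id = contig, gene_index = as.integer(idx),
    gene_id = sprintf("%s_g%03d", contig, idx),
    strand = if (length(strand) == 1) rep(strand, length(idx)) else strand,
    protein_length = 500L
  )
}

mk_hit <- function(gene_id, domain_id, source = "pfam", ali_start = 1L,
                   ali_end = 60L, bit_score = 50, e_value = 1e-20) {
  tibble(gene_id = gene_id, domain_id = domain_id, source = source,
         ali_start = as.integer(ali_start), ali_end = as.integer(ali_end),
         bit_score = bit_score, e_value = e_value)
}

test_that("gene clustering obeys the gap rule at and around the boundary", {
  genes <- mk_genes(0:20)
  seeds <- c(3L, 5L, 12L)
  hits <- bind_rows(lapply(genes$gene_id[genes$gene_index %in% seeds],
                           mk_hit, domain_id = "DUF4157"))
  cl <- cluster_genes(genes, hits, max_gene_gap = 5)
  # 12 - 5 = 7 > 5: two clusters
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$first_index, c(3L, 12L))
  expect_equal(cl$last_index, c(5L, 12L))

  seeds2 <- c(1L, 6L, 11L)  # consecutive differences exactly 5: merges
  hits2 <- bind_rows(lapply(genes$gene_id[genes$gene_index %in% seeds2],
                            mk_hit, domain_id = "DUF4157"))
  cl2 <- cluster_genes(genes, hits2, max_gene_gap = 5)
  expect_equal(nrow(cl2), 1L)
  expect_equal(cl2$seed_indices[[1]], seeds2)

  expect_equal(nrow(cluster_genes(genes, mk_hit("none", "BG1")[0, ])), 0L)
  expect_error(cluster_genes(genes[c(2, 1, 3), ], hits),
               class = "ecisfiber_integrity_error")
})

test_that("locus scoring sums distinct-Pfam weights only", {
  w <- tibble(domain_id = c("DUF4157", "CIS_tube", "Phage_base_V"),
              weight = c(3, 3, 1), is_marker = c(TRUE, TRUE, FALSE))
  sc <- score_locus(c("DUF4157", "CIS_tube", "Phage_base_V"), w)
  expect_equal(sc$score, 7)
  # shipped defaults elevate all eight marker families to weight 3
  expect_equal(score_locus(c("DUF4157", "CIS_tube", "Phage_base_V"))$score, 9)
  expect_equal(score_locus(character(0))$score, 0)
  # repeated accession counts once
  expect_equal(score_locus(c("DUF4157", "DUF4157"))$score, 3)
  # unknown accessions score 0 and are reported
  sc2 <- score_locus(c("DUF4157", "MYSTERY1"))
  expect_equal(sc2$score, 3)
  expect_equal(sc2$unweighted[[1]], "MYSTERY1")
  # monotonicity: adding a marker never decreases the score
  base <- c("CIS_tube", "VgrG")
  for (m in c("DUF4157", "Pvc16_N", "DUF6519")) {
    expect_gte(score_locus(c(base, m))$score, score_locus(base)$score)
  }
})

test_that("window expansion clips at contig ends", {
  genes <- mk_genes(0:30)
  w <- expand_window(genes, "G1", "c1", 10, 14, 5)
  expect_equal(range(w$gene_index), c(5L, 19L))
  w2 <- expand_window(genes, "G1", "c1", 0, 2, 5)
  expect_equal(range(w2$gene_index), c(0L, 7L))
  w3 <- expand_window(genes, "G1", "c1", 10, 14, 0)
  expect_equal(w3$gene_index, 10:14)
})

test_that("eBAP assignment picks the best qualifying N-terminal hit", {
  hits <- bind_rows(
    mk_hit("g1", "eBAP3", "ebap3", ali_start = 5, bit_score = 120),
    mk_hit("g1", "PF00001", "pfam", ali_start = 300, bit_score = 500)
  )
  expect_equal(assign_ebap(hits)$ebap_type, "ebap3")

  # highest bit score among qualifying eBAP hits wins
  hits2 <- bind_rows(
    mk_hit("g1", "eBAP1", "ebap1", ali_start = 3, bit_score = 40),
    mk_hit("g1", "eBAP2", "ebap2", ali_start = 6, bit_score = 55)
  )
  expect_equal(assign_ebap(hits2)$ebap_type, "ebap2")

  # no eBAP-source hit at all
  expect_equal(assign_ebap(mk_hit("g1", "PF1"))$ebap_type, "none")

  # hits beyond the N-terminal window or e-value cutoff do not qualify
  far <- mk_hit("g1", "eBAP1", "ebap1", ali_start = 150, bit_score = 99)
  expect_equal(assign_ebap(far)$ebap_type, "none")
  weak <- mk_hit("g1", "eBAP1", "ebap1", ali_start = 5, e_value = 1e-3)
  expect_equal(assign_ebap(weak)$ebap_type, "none")

  # permutation invariance in hit order
  perm <- assign_ebap(hits2[2:1, ])
  expect_equal(perm, assign_ebap(hits2))
})

test_that("locus calling retains planted loci and labels exclusions", {
  sim <- simulate_genomes(6, loci_per_genome = 1, decoy_fraction = 0.5,
                          seed = 19)
  loci <- call_loci(sim$genes, sim$hits)
  retained <- loci %>% filter(!excluded)
  expect_setequal(locus_key(retained),
                  locus_key(sim$truth %>% filter(!is_decoy)))
  dec <- sim$truth %>% filter(is_decoy)
  exc <- loci %>% filter(excluded) %>%
    left_join(dec, by = c("genome_id", "contig_id"),
              suffix = c("", ".t"))
  expect_true(all(exc$exclusion_reason == exc$decoy_type))
  # window containment
  for (i in seq_len(nrow(loci))) {
    span <- loci$last_index[i] - loci$first_index[i] + 1
    expect_lte(length(loci$window_gene_ids[[i]]), span + 10)
    member_ids <- sim$genes$gene_id[
      sim$genes$contig_id == loci$contig_id[i] &
        sim$genes$gene_index >= loci$first_index[i] &
        sim$genes$gene_index <= loci$last_index[i]]
    expect_true(all(member_ids %in% loci$window_gene_ids[[i]]))
  }
})

test_that("weak and fiberless clusters are emitted with the right reason", {
  genes <- mk_genes(0:20)
  # score 2 < 6: below threshold
  weak <- bind_rows(
    mk_hit(genes$gene_id[4], "VgrG"),
    mk_hit(genes$gene_id[5], "LysM")
  )
  lw <- call_loci(genes, weak)
  expect_true(lw$excluded)
  expect_equal(lw$exclusion_reason, "below_threshold")

  # strong score, no eBAP anywhere: no_fiber
  strong <- bind_rows(
    mk_hit(genes$gene_id[4], "DUF4157"),
    mk_hit(genes$gene_id[5], "CIS_tube")
  )
  ls <- call_loci(genes, strong)
  expect_equal(ls$exclusion_reason, "no_fiber")

  # T6SS Pfam kills the locus regardless of score
  t6 <- bind_rows(strong,
                  mk_hit(genes$gene_id[5], "T6SS_TssM"),
                  mk_hit(genes$gene_id[6], "eBAP1", "ebap1", ali_start = 4))
  lt <- call_loci(genes, t6)
  expect_equal(lt$exclusion_reason, "t6ss")
})

test_that("fiber statistics count multi-fiber loci correctly", {
  fibers <- tibble(
    gene_id = sprintf("g%d", 1:5),
    locus_id = c("L1", "L2", "L3", "L3", "L3"),
    ebap_type = c("ebap1", "ebap2", "ebap3", "ebap3", "ebap5")
  )
  st <- locus_fiber_stats(tibble(), fibers)
  expect_equal(st$n_loci_with_fiber, 3L)
  expect_equal(st$multi_fiber_fraction, 1 / 3)
  expect_equal(st$max_fibers_per_locus, 3L)
  expect_equal(sum(st$per_ebap_counts[[1]]$n), nrow(fibers))

  single <- fibers %>% mutate(locus_id = sprintf("L%d", 1:5))
  expect_equal(locus_fiber_stats(tibble(), single)$multi_fiber_fraction, 0)

  none <- fibers[0, ]
  st0 <- locus_fiber_stats(tibble(), none)
  expect_true(is.na(st0$multi_fiber_fraction))
})

test_that("upstream neighborhood follows the dominant strand", {
  cfg <- ecis_config()
  build <- function(strand) {
    genes <- mk_genes(0:20, strand = strand)
    hits <- bind_rows(
      mk_hit(genes$gene_id[6], "DUF4157"),     # index 5
      mk_hit(genes$gene_id[12], "CIS_tube"),   # index 11
      mk_hit(genes$gene_id[9], "eBAP2", "ebap2", ali_start = 4),  # fiber at 8
      mk_hit(genes$gene_id[8], "Baseplate_J"),  # index 7
      mk_hit(genes$gene_id[10], "GPW_gp25")     # index 9
    )
    loci <- call_loci(genes, hits)
    fibers <- locus_fibers(loci, hits)
    upstream_neighborhood(loci, fibers, genes, hits)
  }
  up_plus <- build("+")
  expect_equal(unique(up_plus$upstream_gene_id), "c1_g007")
  up_minus <- build("-")
  expect_equal(unique(up_minus$upstream_gene_id), "c1_g009")

  # planting Baseplate_J upstream of every fiber gives 100% composition
  genes <- mk_genes(0:20, strand = "+")
  hits <- bind_rows(
    mk_hit(genes$gene_id[6], "DUF4157"),
    mk_hit(genes$gene_id[12], "CIS_tube"),
    mk_hit(genes$gene_id[9], "eBAP2", "ebap2", ali_start = 4),
    mk_hit(genes$gene_id[8], "Baseplate_J")
  )
  loci <- call_loci(genes, hits)
  up <- upstream_neighborhood(loci, locus_fibers(loci, hits), genes, hits)
  comp <- up %>% count(upstream_domain)
  expect_equal(comp$upstream_domain, "Baseplate_J")
})
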