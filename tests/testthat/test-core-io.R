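test_that("gene tables round-trip and are sorted by ordinal", {
  genes <- tibble(
    genome_id = "G1", contig_id = "c1",
    gene_index = c(2L, 0L, 1L),
    gene_id = c("g2", "g0", "g1"),
    strand = c("+", "-", "+"),
    protein_length = c(300L, 150L, 220L)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(genes, path)
  back <- read_gene_table(path)
  expect_equal(back$gene_index, 0:2)
  expect_equal(back$gene_id, c("g0", "g1", "g2"))
  # round-trip identity on the sorted form
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(back, path2)
  expect_equal(read_gene_table(path2), back)
})

test_that("gene table reader raises typed errors on bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("genome_id\tcontig_id\tgene_index\tgene_id\tstrand", path)
  expect_error(read_gene_table(path), class = "ecisfiber_schema_error")
  writeLines(c(
    "genome_id\tcontig_id\tgene_index\tgene_id\tstrand\tprotein_length",
    "G1\tc1\t0\tg0\t+\t100",
    "G1\tc1\t0\tg0b\t-\t120"
  ), path)
  expect_error(read_gene_table(path), class = "ecisfiber_integrity_error")
})

test_that("empty gene table with header only parses to zero records", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("genome_id\tcontig_id\tgene_index\tgene_id\tstrand\tprotein_length",
             path)
  expect_equal(nrow(read_gene_table(path)), 0L)
})

test_that("internal hit tables parse, sort per gene, and reject bad coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene_id\tdomain_id\tsource\tali_start\tali_end\tbit_score\te_value",
    "# a comment line",
    "g1\tPF00001\tpfam\t200\t260\t30.5\t1e-8",
    "g1\teBAP3\tebap3\t5\t180\t120\t1e-30"
  ), path)
  hits <- read_hit_table(path)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$ali_start, c(5L, 200L))

  writeLines(c(
    "gene_id\tdomain_id\tsource\tali_start\tali_end\tbit_score\te_value",
    "g1\tPF00001\tpfam\t260\t200\t30.5\t1e-8"
  ), path)
  expect_error(read_hit_table(path), class = "ecisfiber_parse_error")
})

test_that("HMMER domtblout dialect maps fields and classifies sources", {
  path <- withr::local_tempfile(fileext = ".tbl")
  pad <- paste(rep("0", 7), collapse = " ")  # cols 9-15 placeholders
  writeLines(c(
    "# target name  accession tlen query name accession qlen E-value score ...",
    paste("eBAP2 - 120 geneA - 500 1.2e-22 88.4", pad, "1 57 4 60 3 70 0.9 desc"),
    paste("PF00001 - 80 geneA - 500 3e-9 25.1", pad, "1 70 300 370 295 380 0.8 d"),
    paste("NOV0007 - 90 geneB - 400 1e-12 44.0", pad, "1 85 10 95 5 100 0.85 d")
  ), path)
  hits <- read_hit_table(path, dialect = "domtblout")
  expect_equal(nrow(hits), 3L)
  a <- hits[hits$domain_id == "eBAP2", ]
  expect_equal(a$gene_id, "geneA")
  expect_equal(a$source, "ebap2")
  expect_equal(a$ali_start, 4L)
  expect_equal(a$ali_end, 60L)
  expect_equal(a$e_value, 1.2e-22)
  expect_equal(a$bit_score, 88.4)
  expect_equal(hits$source[hits$domain_id == "NOV0007"], "novel")
  expect_equal(hits$source[hits$domain_id == "PF00001"], "pfam")
})

test_that("structure files round-trip through fixed-width PDB fields", {
  sim <- simulate_structure(domain_plan("helix", 2), seed = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sim$model, path)
  back <- read_structure(path)
  expect_equal(nrow(back), nrow(sim$model))
  expect_equal(back$residue_number, sim$model$residue_number)
  expect_lt(max(abs(back$x - sim$model$x)), 1e-3)
  expect_lt(max(abs(back$y - sim$model$y)), 1e-3)
  expect_lt(max(abs(back$z - sim$model$z)), 1e-3)
  # pLDDT survives in the B-factor column at %6.2f precision
  expect_lt(max(abs(back$plddt - sim$model$plddt)), 0.01)
})

test_that("reading a missing chain names the available chains", {
  sim <- simulate_structure(domain_plan("helix", 2), seed = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sim$model, path, chain = "B")
  expect_error(read_structure(path, chain = "Q"), "available chains: B",
               class = "ecisfiber_io_error")
  expect_equal(nrow(read_structure(path, chain = "B")), nrow(sim$model))
})

test_that("interval conversion to half-open and back is the identity", {
  for (iv in list(c(1L, 1L), c(3L, 10L), c(100L, 500L))) {
    ho <- interval_to_half_open(iv[1], iv[2])
    expect_equal(interval_from_half_open(ho[1], ho[2]), iv)
  }
  expect_equal(interval_overlap(1, 100, 50, 150), 51)
  expect_equal(interval_overlap(1, 10, 20, 30), 0)
})

test_that("config validation rejects inconsistent thresholds", {
  expect_s3_class(ecis_config(), "ecis_config")
  expect_error(ecis_config(gradient_identities = c(0.3, 0.4)),
               class = "ecisfiber_config_error")
  expect_error(ecis_config(fragment_range = c(500, 10)),
               class = "ecisfiber_config_error")
  expect_error(ecis_config(min_pair_coverage = 1.5),
               class = "ecisfiber_config_error")
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"ca_cutoff": 6.5, "locus_score_min": 4}', path)
  cfg <- read_config(path)
  expect_equal(cfg$ca_cutoff, 6.5)
  expect_equal(cfg$locus_score_min, 4)
  expect_equal(cfg$max_gene_gap, 5)
  writeLines('{"not_a_field": 1}', path)
  expect_error(read_config(path), class = "ecisfiber_config_error")
})
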