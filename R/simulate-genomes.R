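with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate annotated genomes with planted eCIS loci
#'
#' Generates gene and domain-hit tables in the package's TSV dialects,
#' together with a machine-readable truth table, emulating the substrate of
#' the genome screen: contigs of background genes into which eCIS loci are
#' planted. Every non-decoy locus contains at least two distinct marker
#' Pfams (so it clears the default retention score), one or two fiber genes
#' carrying an eBAP hit that starts within the N-terminal window, and a
#' baseplate gene (`Baseplate_J`) immediately upstream of each fiber in the
#' locus reading direction. Decoy loci mimic T6SS or prophage neighborhoods:
#' they carry marker Pfams plus at least one exclusion-set Pfam and no fiber
#' gene. Background genes carry random non-eCIS hits only.
#'
#' The generator is a pure function of its arguments: identical seeds give
#' byte-identical outputs.
#'
#' @param n_genomes Number of genomes (one contig each).
#' @param loci_per_genome Planted loci per genome (default 1).
#' @param decoy_fraction Fraction of planted loci that are decoys
#'   (default 0); the decoy count is `round(total * decoy_fraction)`.
#' @param seed Integer seed.
#' @param config Pipeline configuration (gap and window sizes are respected
#'   when spacing loci).
#' @param out_dir Optional directory; when given, `genes.tsv`, `hits.tsv`
#'   and `truth.tsv` are written there.
#' @return A list with tibbles `genes`, `hits` and `truth`. Truth columns:
#'   `genome_id`, `contig_id`, `locus_id`, `first_index`, `last_index`
#'   (seed-gene span), `member_indices` (list), `marker_pfams` (list),
#'   `fiber_gene_ids` (list), `fiber_ebap_types` (list), `is_decoy`,
#'   `decoy_type` (`"t6ss"`, `"capsid"` or `NA`).
#' @examples
#' sim <- simulate_genomes(2, seed = 1)
#' sim$truth
#' @export
simulate_genomes <- function(n_genomes,
                             loci_per_genome = 1,
                             decoy_fraction = 0,
                             seed = 1,
                             config = ecis_config(),
                             out_dir = NULL) {
  if (n_genomes < 1) {
    abort("n_genomes must be >= 1", class = "ecisfiber_param_error")
  }
  if (decoy_fraction < 0 || decoy_fraction > 1) {
    abort("decoy_fraction must lie in [0, 1]", class = "ecisfiber_param_error")
  }
  slot <- 22L            # genes reserved per locus
  spacer <- 15L          # background genes between loci (> max_gene_gap)
  contig_len <- loci_per_genome * (slot + spacer) + spacer
  if (loci_per_genome > 40) {
    abort("loci_per_genome exceeds contig capacity",
          class = "ecisfiber_param_error")
  }

  weights <- default_marker_weights()
  markers <- weights$domain_id[weights$is_marker]
  enriched <- weights$domain_id[!weights$is_marker]
  exclusions <- default_exclusion_set()
  background_pool <- sprintf("BG%04d", 1:40)

  n_total <- n_genomes * loci_per_genome
  with_seed(seed, {
    decoy_flags <- rep(FALSE, n_total)
    n_decoys <- round(n_total * decoy_fraction)
    if (n_decoys > 0) {
      decoy_flags[sample.int(n_total, n_decoys)] <- TRUE
    }

    genes_acc <- vector("list", n_genomes)
    hits_acc <- list()
    truth_acc <- list()
    locus_counter <- 0L

    for (g in seq_len(n_genomes)) {
      genome_id <- sprintf("GENOME%03d", g)
      contig_id <- sprintf("%s_c1", genome_id)
      gene_idx <- 0:(contig_len - 1L)
      gene_ids <- sprintf("%s_g%04d", contig_id, gene_idx)
      strands <- sample(c("+", "-"), contig_len, replace = TRUE)
      lengths <- sample(120:600, contig_len, replace = TRUE)
      locus_gene <- rep(FALSE, contig_len)

      for (l in seq_len(loci_per_genome)) {
        locus_counter <- locus_counter + 1L
        is_decoy <- decoy_flags[locus_counter]
        start0 <- (l - 1L) * (slot + spacer) + spacer
        m <- sample(6:9, 1)                       # member genes
        member <- start0 + 0:(m - 1L)
        locus_strand <- sample(c("+", "-"), 1)
        strands[member + 1L] <- locus_strand
        locus_gene[member + 1L] <- TRUE
        locus_id <- sprintf("%s_L%02d", genome_id, l)

        k_markers <- sample(2:4, 1)
        locus_markers <- sample(markers, k_markers)
        locus_enriched <- sample(enriched, sample(1:3, 1))

        # every member carries a weighted hit except up to two planted
        # interior gap genes, so consecutive seeds never exceed the gap
        # limit and the seed span equals the member span
        weighted <- c(locus_markers, locus_enriched)
        n_gaps <- sample(0:2, 1)
        gap_pos <- if (n_gaps > 0) sample(2:(m - 1L), n_gaps) else integer(0)
        carriers <- member[setdiff(seq_len(m), gap_pos)]
        for (i in seq_along(carriers)) {
          gi <- carriers[i] + 1L
          hits_acc[[length(hits_acc) + 1L]] <- tibble(
            gene_id = gene_ids[gi],
            domain_id = weighted[((i - 1L) %% length(weighted)) + 1L],
            source = "pfam",
            ali_start = sample(1:60, 1),
            ali_end = 0L,
            bit_score = round(runif(1, 40, 200), 1),
            e_value = 10^runif(1, -40, -10)
          )
        }

        fiber_ids <- character(0)
        fiber_ebaps <- character(0)
        if (is_decoy) {
          dtype <- sample(c("t6ss", "capsid"), 1)
          excl <- exclusions$domain_id[exclusions$category == dtype]
          for (d in sample(excl, sample(1:2, 1))) {
            gi <- sample(member, 1) + 1L
            hits_acc[[length(hits_acc) + 1L]] <- tibble(
              gene_id = gene_ids[gi],
              domain_id = d,
              source = "pfam",
              ali_start = sample(1:60, 1),
              ali_end = 0L,
              bit_score = round(runif(1, 40, 200), 1),
              e_value = 10^runif(1, -40, -10)
            )
          }
        } else {
          dtype <- NA_character_
          n_fiber <- sample(1:2, 1)
          # interior members (never the edge seeds), spaced so the upstream
          # neighbor inside the locus is free for the baseplate gene
          cand <- member[seq(3L, m - 1L, by = 2L)]
          fiber_members <- sort(sample(cand, min(n_fiber, length(cand))))
          for (fm in fiber_members) {
            gi <- fm + 1L
            lengths[gi] <- sample(400:900, 1)
            ebap <- sample(paste0("ebap", 1:5), 1)
            fiber_ids <- c(fiber_ids, gene_ids[gi])
            fiber_ebaps <- c(fiber_ebaps, ebap)
            a_start <- sample(1:50, 1)
            hits_acc[[length(hits_acc) + 1L]] <- tibble(
              gene_id = gene_ids[gi],
              domain_id = toupper(sub("ebap", "eBAP", ebap)),
              source = ebap,
              ali_start = a_start,
              ali_end = a_start + sample(40:180, 1),
              bit_score = round(runif(1, 60, 250), 1),
              e_value = 10^runif(1, -60, -8)
            )
            upstream <- if (locus_strand == "+") fm - 1L else fm + 1L
            hits_acc[[length(hits_acc) + 1L]] <- tibble(
              gene_id = gene_ids[upstream + 1L],
              domain_id = "Baseplate_J",
              source = "pfam",
              ali_start = sample(1:40, 1),
              ali_end = 0L,
              bit_score = round(runif(1, 60, 200), 1),
              e_value = 10^runif(1, -50, -15)
            )
          }
        }

        truth_acc[[locus_counter]] <- tibble(
          genome_id = genome_id,
          contig_id = contig_id,
          locus_id = locus_id,
          first_index = member[1],
          last_index = member[m],
          member_indices = list(member),
          marker_pfams = list(locus_markers),
          fiber_gene_ids = list(fiber_ids),
          fiber_ebap_types = list(fiber_ebaps),
          is_decoy = is_decoy,
          decoy_type = dtype
        )
      }

      # background hits on non-locus genes
      for (gi in which(!locus_gene)) {
        if (runif(1) < 0.3) {
          for (d in sample(background_pool, sample(1:2, 1))) {
            hits_acc[[length(hits_acc) + 1L]] <- tibble(
              gene_id = gene_ids[gi],
              domain_id = d,
              source = "pfam",
              ali_start = sample(1:80, 1),
              ali_end = 0L,
              bit_score = round(runif(1, 15, 80), 1),
              e_value = 10^runif(1, -20, -6)
            )
          }
        }
      }

      genes_acc[[g]] <- tibble(
        genome_id = genome_id,
        contig_id = contig_id,
        gene_index = gene_idx,
        gene_id = gene_ids,
        strand = strands,
        protein_length = lengths
      )
    }

    genes <- bind_rows(genes_acc)
    hits <- bind_rows(hits_acc)
    # give zero-length placeholder ends a real interval within the protein
    plen <- setNames(genes$protein_length, genes$gene_id)
    fix <- hits$ali_end < hits$ali_start
    hits$ali_end[fix] <- pmin(
      hits$ali_start[fix] + sample(30:120, sum(fix), replace = TRUE),
      unname(plen[hits$gene_id[fix]])
    )
    hits$ali_end <- pmax(hits$ali_end, hits$ali_start)
    hits <- hits %>% arrange(.data$gene_id, .data$ali_start, .data$domain_id)
    truth <- bind_rows(truth_acc)

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_gene_table(genes, file.path(out_dir, "genes.tsv"))
      write_hit_table(hits, file.path(out_dir, "hits.tsv"))
      flat <- truth %>%
        mutate(across(
          c("member_indices", "marker_pfams", "fiber_gene_ids", "fiber_ebap_types"),
          ~ vapply(.x, paste, "", collapse = ",")
        ))
      readr::write_tsv(flat, file.path(out_dir, "truth.tsv"), progress = FALSE)
    }
    list(genes = genes, hits = hits, truth = truth)
  })
}
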