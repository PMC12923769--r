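gene_table_cols <- c(
  "genome_id", "contig_id", "gene_index", "gene_id", "strand", "protein_length"
)

hit_table_cols <- c(
  "gene_id", "domain_id", "source", "ali_start", "ali_end", "bit_score", "e_value"
)

#' Read a per-genome gene annotation table
#'
#' The table is TSV with columns `genome_id`, `contig_id`, `gene_index`
#' (0-based ordinal along the contig), `gene_id`, `strand` (`+`/`-`) and
#' `protein_length` (residues). Records are returned grouped by genome and
#' contig and sorted by gene ordinal. If a hit table is supplied its hits
#' are attached as a nested list-column `hits`.
#'
#' @param path Path to the gene table TSV.
#' @param hits Optional hit tibble from [read_hit_table()] to nest per gene.
#' @return A tibble of gene records sorted by (genome, contig, gene_index).
#' @export
read_gene_table <- function(path, hits = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("gene table not found: %s", path), class = "ecisfiber_io_error")
  }
  genes <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      genome_id = readr::col_character(),
      contig_id = readr::col_character(),
      gene_index = readr::col_integer(),
      gene_id = readr::col_character(),
      strand = readr::col_character(),
      protein_length = readr::col_integer()
    ),
    progress = FALSE
  ))
  missing <- setdiff(gene_table_cols, names(genes))
  if (length(missing) > 0) {
    abort(sprintf("gene table is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "ecisfiber_schema_error")
  }
  dup <- genes %>%
    count(.data$genome_id, .data$contig_id, .data$gene_index) %>%
    filter(n > 1L)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate (contig, gene_index) pairs in gene table, e.g. %s:%d",
                  dup$contig_id[1], dup$gene_index[1]),
          class = "ecisfiber_integrity_error")
  }
  bad_strand <- setdiff(unique(genes$strand), c("+", "-"))
  if (length(bad_strand) > 0) {
    abort(sprintf("strand must be '+' or '-', got: %s",
                  paste(bad_strand, collapse = ", ")),
          class = "ecisfiber_schema_error")
  }
  genes <- genes %>% arrange(.data$genome_id, .data$contig_id, .data$gene_index)
  if (!is.null(hits)) {
    genes$hits <- purrr::map(genes$gene_id, function(g) {
      hits %>% filter(.data$gene_id == g) %>% arrange(.data$ali_start)
    })
  }
  genes
}

#' Write a gene table
#'
#' @param genes Gene tibble (any nested `hits` column is dropped).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(genes[gene_table_cols], path, progress = FALSE)
  invisible(path)
}

#' Read a domain-hit table
#'
#' Two dialects are accepted and never sniffed:
#' * `"tsv"` -- the package's internal schema: `gene_id`, `domain_id`,
#'   `source` (`pfam`, `novel`, or `ebap1`..`ebap5`), `ali_start`,
#'   `ali_end` (1-based inclusive), `bit_score`, `e_value`.
#' * `"domtblout"` -- HMMER's per-domain tabular output from `hmmscan`,
#'   whitespace-delimited with `#` comments. The mapping is gene_id = query
#'   name (column 4), domain_id = target name (column 1), e_value =
#'   full-sequence E-value (column 7), bit_score = full-sequence score
#'   (column 8), alignment coordinates = columns 18--19. The source is
#'   derived from the target name: `eBAP1`..`eBAP5` become `ebap1`..`ebap5`,
#'   `NOV`-prefixed names become `novel`, everything else `pfam`.
#'
#' @param path Path to the hit table.
#' @param dialect `"tsv"` (default) or `"domtblout"`.
#' @return A tibble of hits, sorted by `gene_id` then `ali_start`, with
#'   1-based inclusive coordinates.
#' @export
read_hit_table <- function(path, dialect = c("tsv", "domtblout")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("hit table not found: %s", path), class = "ecisfiber_io_error")
  }
  if (dialect == "tsv") {
    hits <- readr::read_tsv(
      path,
      col_types = readr::cols(
        gene_id = readr::col_character(),
        domain_id = readr::col_character(),
        source = readr::col_character(),
        ali_start = readr::col_integer(),
        ali_end = readr::col_integer(),
        bit_score = readr::col_double(),
        e_value = readr::col_double()
      ),
      comment = "#",
      progress = FALSE
    )
    missing <- setdiff(hit_table_cols, names(hits))
    if (length(missing) > 0) {
      abort(sprintf("hit table is missing column(s): %s",
                    paste(missing, collapse = ", ")),
            class = "ecisfiber_schema_error")
    }
  } else {
    lines <- readLines(path)
    keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
    lines <- lines[keep]
    if (length(lines) == 0) {
      return(tibble(
        gene_id = character(), domain_id = character(), source = character(),
        ali_start = integer(), ali_end = integer(),
        bit_score = double(), e_value = double()
      ))
    }
    fields <- strsplit(lines, "[[:space:]]+")
    short <- which(vapply(fields, length, 1L) < 19L)
    if (length(short) > 0) {
      abort(sprintf("domtblout line %d has fewer than 19 fields", short[1]),
            class = "ecisfiber_schema_error")
    }
    grab <- function(i) vapply(fields, `[[`, "", i)
    hits <- tibble(
      gene_id = grab(4L),
      domain_id = grab(1L),
      ali_start = suppressWarnings(as.integer(grab(18L))),
      ali_end = suppressWarnings(as.integer(grab(19L))),
      bit_score = suppressWarnings(as.numeric(grab(8L))),
      e_value = suppressWarnings(as.numeric(grab(7L)))
    )
    bad <- which(is.na(hits$ali_start) | is.na(hits$ali_end) |
                   is.na(hits$bit_score) | is.na(hits$e_value))
    if (length(bad) > 0) {
      abort(sprintf("unparseable numeric field on domtblout line %d", bad[1]),
            class = "ecisfiber_parse_error")
    }
    hits$source <- classify_domain_source(hits$domain_id)
    hits <- hits[hit_table_cols]
  }
  bad <- which(hits$ali_start > hits$ali_end | hits$ali_start < 1L)
  if (length(bad) > 0) {
    abort(sprintf("invalid alignment coordinates on hit record %d (%s %d-%d)",
                  bad[1], hits$domain_id[bad[1]],
                  hits$ali_start[bad[1]], hits$ali_end[bad[1]]),
          class = "ecisfiber_parse_error")
  }
  if (any(hits$e_value < 0)) {
    abort("negative e-value in hit table", class = "ecisfiber_parse_error")
  }
  hits %>% arrange(.data$gene_id, .data$ali_start)
}

#' @rdname read_hit_table
#' @param hits Hit tibble in the internal schema.
#' @export
write_hit_table <- function(hits, path) {
  readr::write_tsv(hits[hit_table_cols], path, progress = FALSE)
  invisible(path)
}

classify_domain_source <- function(domain_id) {
  out <- rep("pfam", length(domain_id))
  is_ebap <- grepl("^eBAP[1-5]$", domain_id, ignore.case = TRUE)
  out[is_ebap] <- tolower(domain_id[is_ebap])
  out[startsWith(domain_id, "NOV")] <- "novel"
  out
}
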