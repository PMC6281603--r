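#' Parse a Hi-C interaction file in the merged_nodups dialect
#'
#' Each row describes the alignment of one cleaned read pair in 9
#' whitespace-separated columns: read name, strand1, chromosome1, position1,
#' fragment1, strand2, chromosome2, position2, fragment2. Records are tagged
#' with the cell-line and replicate labels of the file they came from.
#'
#' @param path Interaction file (plain text or gzip).
#' @param cell_line,replicate Provenance labels for every record in the file.
#' @param chromosomes Optional character vector of known chromosome names;
#'   when given, records naming any other chromosome raise an error.
#' @return A tibble with columns `read_name`, `strand1`, `chrom1`, `pos1`,
#'   `frag1`, `strand2`, `chrom2`, `pos2`, `frag2`, `cell_line`, `replicate`.
#' @export
read_interactions <- function(path, cell_line, replicate,
                              chromosomes = NULL) {
  stopifnot(length(cell_line) == 1, length(replicate) == 1)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(
      read_name = character(), strand1 = integer(), chrom1 = character(),
      pos1 = integer(), frag1 = integer(), strand2 = integer(),
      chrom2 = character(), pos2 = integer(), frag2 = integer(),
      cell_line = character(), replicate = character()
    ))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf != 9)
  if (length(bad) > 0) {
    stop(sprintf(
      "malformed interaction row(s) in %s: line %s has %d column(s), expected 9",
      path, bad[1], nf[bad[1]]
    ), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  out <- tibble::tibble(
    read_name = m[, 1],
    strand1 = as.integer(m[, 2]),
    chrom1 = m[, 3],
    pos1 = as.integer(m[, 4]),
    frag1 = as.integer(m[, 5]),
    strand2 = as.integer(m[, 6]),
    chrom2 = m[, 7],
    pos2 = as.integer(m[, 8]),
    frag2 = as.integer(m[, 9]),
    cell_line = cell_line,
    replicate = replicate
  )
  if (!is.null(chromosomes)) {
    unknown <- setdiff(unique(c(out$chrom1, out$chrom2)), chromosomes)
    if (length(unknown) > 0) {
      stop("unknown chromosome(s) in ", path, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Read a set of interaction files with provenance
#'
#' @param files Tibble with columns `file`, `cell_line`, `replicate` (one row
#'   per replicate-level interaction file).
#' @inheritParams read_interactions
#' @return All records bound into one tibble.
#' @export
read_interaction_set <- function(files, chromosomes = NULL) {
  check_columns(files, c("file", "cell_line", "replicate"), "files")
  purrr::pmap_dfr(
    files[, c("file", "cell_line", "replicate")],
    function(file, cell_line, replicate) {
      read_interactions(file, cell_line, replicate, chromosomes = chromosomes)
    }
  )
}

# One observation row per (record, SNP-end, gene overlapping the partner
# fragment). Both ends are treated symmetrically; a record whose two ends are
# both SNP fragments contributes to both SNPs, and a partner fragment that
# overlaps k genes contributes one observation to each of the k pairs.
spatial_observations_impl <- function(interactions, snp_map, gene_map) {
  one_end <- function(snp_end) {
    sc <- paste0(c("chrom", "frag"), snp_end)
    gc <- paste0(c("chrom", "frag"), setdiff(1:2, snp_end))
    df <- interactions
    df$snp_chrom <- df[[sc[1]]]
    df$snp_fragment <- df[[sc[2]]]
    df$gene_chrom <- df[[gc[1]]]
    df$gene_fragment <- df[[gc[2]]]
    df %>%
      dplyr::inner_join(
        dplyr::select(snp_map, "rsid",
                      snp_chrom = "chrom", snp_fragment = "fragment"),
        by = c("snp_chrom", "snp_fragment"),
        relationship = "many-to-many"
      ) %>%
      dplyr::inner_join(
        dplyr::select(gene_map, "gene_id",
                      gene_chrom = "chrom", gene_fragment = "fragment"),
        by = c("gene_chrom", "gene_fragment"),
        relationship = "many-to-many"
      ) %>%
      dplyr::select("read_name", "rsid", "gene_id", "snp_chrom",
                    "snp_fragment", "gene_chrom", "gene_fragment",
                    "cell_line", "replicate")
  }
  dplyr::bind_rows(one_end(1L), one_end(2L))
}

#' Identify spatial SNP-gene pairs from interaction records
#'
#' For every SNP whose restriction fragment appears on either end of an
#' interaction record, the fragment at the other end is tested for overlap
#' with a composite gene region. Observations are aggregated per
#' (SNP, gene) pair: the number of distinct (SNP fragment, gene fragment)
#' contact pairs is the pair's fragment interactions, and the number of
#' replicate-level observations is its supporting interactions. All pairs
#' with at least one supporting interaction are retained; thresholds on
#' support can be applied downstream via `min_support`.
#'
#' @param interactions Interaction records from [read_interaction_set()].
#' @param snp_map SNP table with `fragment` column, from
#'   [assign_snps_to_fragments()].
#' @param gene_map Long gene-fragment table from
#'   [assign_genes_to_fragments()].
#' @param min_support Minimum supporting interactions per retained pair
#'   (default 1, i.e. no filtering).
#' @return A tibble with one row per (rsid, gene_id) pair: columns
#'   `fragment_interactions`, `supporting_interactions`, `n_cell_lines` and
#'   `n_replicates` (distinct cell-line/replicate combinations). The
#'   replicate-level observations are attached as the `"observations"`
#'   attribute, retrievable with [spatial_observations()].
#' @export
find_spatial_pairs <- function(interactions, snp_map, gene_map,
                               min_support = 1) {
  check_columns(interactions,
                c("read_name", "chrom1", "frag1", "chrom2", "frag2",
                  "cell_line", "replicate"),
                "interactions")
  check_columns(snp_map, c("rsid", "chrom", "fragment"), "snp_map")
  check_columns(gene_map, c("gene_id", "chrom", "fragment"), "gene_map")
  obs <- spatial_observations_impl(interactions, snp_map, gene_map)
  pairs <- obs %>%
    dplyr::group_by(.data$rsid, .data$gene_id) %>%
    dplyr::summarise(
      fragment_interactions = dplyr::n_distinct(
        paste(.data$snp_chrom, .data$snp_fragment,
              .data$gene_chrom, .data$gene_fragment)
      ),
      supporting_interactions = dplyr::n(),
      n_cell_lines = dplyr::n_distinct(.data$cell_line),
      n_replicates = dplyr::n_distinct(
        paste(.data$cell_line, .data$replicate)
      ),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$supporting_interactions >= min_support) %>%
    dplyr::arrange(.data$rsid, .data$gene_id)
  obs <- dplyr::semi_join(obs, pairs, by = c("rsid", "gene_id"))
  attr(pairs, "observations") <- obs
  pairs
}

#' Replicate-level observations behind a spatial-pair table
#'
#' @param pairs Result of [find_spatial_pairs()].
#' @return The long observation tibble (one row per record, SNP end and
#'   overlapping gene).
#' @export
spatial_observations <- function(pairs) {
  obs <- attr(pairs, "observations")
  if (is.null(obs)) {
    stop("`pairs` carries no observations attribute; ",
         "was it produced by find_spatial_pairs()?", call. = FALSE)
  }
  obs
}

#' Two-proportions Z-test for eQTL enrichment by interaction support
#'
#' Partitions spatial pairs into those supported by more than one
#' replicate-level interaction and those seen exactly once, and tests whether
#' the proportion flagged as eQTL-significant differs between the partitions
#' with a pooled two-proportion Z statistic,
#' \eqn{z = (\hat p_1 - \hat p_2) / \sqrt{\hat p (1 - \hat p)(1/n_1 + 1/n_2)}},
#' with a two-sided normal p-value.
#'
#' @param pairs Spatial-pair tibble (needs `supporting_interactions`).
#' @param significant Logical vector (or bare column name in `pairs`)
#'   flagging each pair as eQTL-significant.
#' @return A one-row tibble: group sizes, significant proportions, `z` and
#'   two-sided `p_value`.
#' @export
support_enrichment_test <- function(pairs, significant) {
  sig <- if (rlang::is_character(significant) && length(significant) == 1) {
    pairs[[significant]]
  } else {
    significant
  }
  stopifnot(is.logical(sig), length(sig) == nrow(pairs))
  multi <- pairs$supporting_interactions > 1
  n1 <- sum(multi)
  n2 <- sum(!multi)
  if (n1 == 0 || n2 == 0) {
    stop("both support partitions (support > 1 and support = 1) must be ",
         "non-empty", call. = FALSE)
  }
  x1 <- sum(sig[multi])
  x2 <- sum(sig[!multi])
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  tibble::tibble(
    n_multi = n1, n_single = n2,
    prop_multi = p1, prop_single = p2,
    z = z,
    p_value = if (z == 0) 1 else 2 * stats::pnorm(-abs(z))
  )
}

#' Write spatial pairs and their observations as TSV
#'
#' @param pairs Result of [find_spatial_pairs()].
#' @param path Output path for the pair summary; observations are written
#'   next to it with suffix `"_observations.tsv"`.
#' @return `path`, invisibly.
#' @export
write_spatial_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  obs <- attr(pairs, "observations")
  if (!is.null(obs)) {
    readr::write_tsv(obs, sub("\\.tsv$", "", path) %>%
                       paste0("_observations.tsv"))
  }
  invisible(path)
}
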