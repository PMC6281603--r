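#' Query an eQTL table for spatial SNP-gene pairs
#'
#' Restricts an eQTL association table (one row per SNP-gene-tissue test) to
#' the rows whose (rsid, gene_id) is a spatial pair. Spatial pairs absent
#' from the table have no eQTL association and are excluded before multiple
#' testing.
#'
#' @param pairs Spatial-pair tibble from [find_spatial_pairs()] (or any
#'   tibble with `rsid` and `gene_id`).
#' @param eqtl_table Tibble with columns `rsid`, `gene_id`, `tissue`,
#'   `p_nominal`, `nes`.
#' @return The matching eQTL rows.
#' @export
query_eqtls <- function(pairs, eqtl_table) {
  check_columns(pairs, c("rsid", "gene_id"), "pairs")
  check_columns(eqtl_table, c("rsid", "gene_id", "tissue", "p_nominal", "nes"),
                "eqtl_table")
  dplyr::semi_join(eqtl_table, pairs, by = c("rsid", "gene_id"))
}

#' Read an eQTL association table
#'
#' TSV with one row per SNP-gene-tissue test: columns `rsid`, `gene_id`,
#' `tissue`, `p_nominal` (nominal association p) and `nes` (normalised
#' effect size, the signed slope of the eQTL regression).
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_eqtl_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(tab, c("rsid", "gene_id", "tissue", "p_nominal", "nes"),
                "eqtl table")
  tab
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order with
#' monotonicity enforced and stable ties.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric", call. = FALSE)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Call spatial eQTL-eGene pairs at an FDR threshold
#'
#' Keeps associations with `p_adjusted <= threshold`. A SNP with at least one
#' retained row is a spatial eQTL; a gene with at least one retained row is a
#' spatial eGene.
#'
#' @param associations Tibble with a `p_adjusted` column (see
#'   [call_spatial_eqtls()]).
#' @param threshold FDR threshold (default 0.05).
#' @return The retained associations.
#' @export
filter_significant <- function(associations, threshold = 0.05) {
  check_columns(associations, "p_adjusted", "associations")
  dplyr::filter(associations, .data$p_adjusted <= threshold)
}

#' Classify associations as cis or trans and compute SNP-gene distance
#'
#' An association is cis when SNP and gene share a chromosome and are
#' separated by less than `cis_window` bp; trans_intra when on the same
#' chromosome at or beyond the window; trans_inter when on different
#' chromosomes. Distance is 0 for a SNP inside the composite gene region,
#' the gap to the nearest region edge otherwise, and `NA` for
#' inter-chromosomal pairs.
#'
#' @param associations Tibble with `rsid` and `gene_id`.
#' @param snps SNP table with `rsid`, `chrom`, `pos` (1-based).
#' @param genes Gene-region table with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param cis_window Cis window in bp (default 1e6).
#' @return `associations` with added `range_class` and `distance` columns.
#' @export
classify_range <- function(associations, snps, genes, cis_window = 1e6) {
  check_columns(associations, c("rsid", "gene_id"), "associations")
  check_columns(snps, c("rsid", "chrom", "pos"), "snps")
  check_columns(genes, c("gene_id", "chrom", "start", "end"), "genes")
  missing_snp <- setdiff(unique(associations$rsid), snps$rsid)
  if (length(missing_snp) > 0) {
    stop("no coordinates for SNP(s): ",
         paste(missing_snp, collapse = ", "), call. = FALSE)
  }
  missing_gene <- setdiff(unique(associations$gene_id), genes$gene_id)
  if (length(missing_gene) > 0) {
    stop("no region for gene(s): ",
         paste(missing_gene, collapse = ", "), call. = FALSE)
  }
  out <- associations %>%
    dplyr::left_join(
      dplyr::select(snps, "rsid", snp_chrom = "chrom", snp_pos = "pos") %>%
        dplyr::distinct(.data$rsid, .keep_all = TRUE),
      by = "rsid"
    ) %>%
    dplyr::left_join(
      dplyr::select(genes, "gene_id", gene_chrom = "chrom",
                    gene_start = "start", gene_end = "end"),
      by = "gene_id"
    ) %>%
    dplyr::mutate(
      distance = dplyr::if_else(
        .data$snp_chrom == .data$gene_chrom,
        pmax(0, .data$gene_start - .data$snp_pos,
             .data$snp_pos - .data$gene_end),
        NA_real_
      ),
      range_class = dplyr::case_when(
        .data$snp_chrom != .data$gene_chrom ~ "trans_inter",
        .data$distance < cis_window ~ "cis",
        TRUE ~ "trans_intra"
      )
    )
  dplyr::select(out, -"snp_chrom", -"snp_pos", -"gene_chrom",
                -"gene_start", -"gene_end")
}

#' Full eQTL stage: query, adjust, flag and classify
#'
#' Convenience wrapper running [query_eqtls()], joint Benjamini-Hochberg
#' adjustment across all surviving SNP-gene-tissue rows, significance
#' flagging at the FDR threshold and, when coordinates are supplied,
#' cis/trans classification.
#'
#' @inheritParams query_eqtls
#' @inheritParams classify_range
#' @param fdr_threshold FDR threshold for the `significant` flag
#'   (default 0.05).
#' @param per_tissue Adjust within each tissue separately instead of jointly
#'   (default `FALSE`, a single family across all rows).
#' @return Association tibble with `p_adjusted`, `significant` and (with
#'   coordinates) `range_class`, `distance`.
#' @export
call_spatial_eqtls <- function(pairs, eqtl_table, snps = NULL, genes = NULL,
                               fdr_threshold = 0.05, cis_window = 1e6,
                               per_tissue = FALSE) {
  assoc <- query_eqtls(pairs, eqtl_table)
  if (nrow(assoc) == 0) {
    assoc$p_adjusted <- numeric(0)
    assoc$significant <- logical(0)
    return(assoc)
  }
  if (per_tissue) {
    assoc <- assoc %>%
      dplyr::group_by(.data$tissue) %>%
      dplyr::mutate(p_adjusted = adjust_bh(.data$p_nominal)) %>%
      dplyr::ungroup()
  } else {
    assoc$p_adjusted <- adjust_bh(assoc$p_nominal)
  }
  assoc$significant <- assoc$p_adjusted <= fdr_threshold
  if (!is.null(snps) && !is.null(genes)) {
    assoc <- classify_range(assoc, snps, genes, cis_window = cis_window)
  }
  assoc
}

#' Compare two association sets
#'
#' Exact set algebra on (rsid, gene_id, tissue) keys: how many associations
#' are shared between a spatially informed set and a distance-based set, and
#' how many are exclusive to each.
#'
#' @param spatial,distance_based Tibbles with columns `rsid`, `gene_id`,
#'   `tissue`.
#' @return A one-row tibble with `shared`, `spatial_only`, `distance_only`.
#' @export
compare_association_sets <- function(spatial, distance_based) {
  key <- function(df) {
    check_columns(df, c("rsid", "gene_id", "tissue"), "association set")
    unique(paste(df$rsid, df$gene_id, df$tissue, sep = "\r"))
  }
  a <- key(spatial)
  b <- key(distance_based)
  tibble::tibble(
    shared = length(intersect(a, b)),
    spatial_only = length(setdiff(a, b)),
    distance_only = length(setdiff(b, a))
  )
}

#' Tissue by cell-line summary of significant associations
#'
#' Joins significant eQTL associations to the replicate-level spatial
#' observations on (rsid, gene_id) and summarises each (tissue, cell line)
#' group: mean nominal eQTL p-value and total supporting interactions.
#' Empty groups are omitted.
#'
#' @param associations Significant association tibble (needs `rsid`,
#'   `gene_id`, `tissue`, `p_nominal`).
#' @param observations Long observation tibble from
#'   [spatial_observations()].
#' @return A tibble with one row per (tissue, cell_line): `mean_p_nominal`
#'   over distinct associations and `supporting_interactions` totals.
#' @export
summarize_tissue_cellline <- function(associations, observations) {
  check_columns(associations, c("rsid", "gene_id", "tissue", "p_nominal"),
                "associations")
  check_columns(observations, c("rsid", "gene_id", "cell_line"),
                "observations")
  support <- observations %>%
    dplyr::count(.data$rsid, .data$gene_id, .data$cell_line,
                 name = "supporting_interactions")
  associations %>%
    dplyr::inner_join(support, by = c("rsid", "gene_id"),
                      relationship = "many-to-many") %>%
    dplyr::group_by(.data$tissue, .data$cell_line) %>%
    dplyr::summarise(
      mean_p_nominal = mean(.data$p_nominal),
      supporting_interactions = sum(.data$supporting_interactions),
      .groups = "drop"
    )
}
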