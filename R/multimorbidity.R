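#' Build phenotype eGene and eQTL sets
#'
#' A phenotype is the trait associated with a SNP in the GWAS table; when one
#' study associates a SNP with several traits simultaneously, those traits
#' form a composite phenotype whose label is the sorted trait names joined by
#' `"|"`. Each (SNP, study) group contributes the SNP's significant eGenes
#' (and the SNP itself) to exactly one phenotype.
#'
#' @param gwas GWAS association tibble (`rsid`, `trait`, `study`, one row per
#'   association), e.g. from [read_gwas()].
#' @param associations Significant spatial eQTL-eGene associations (`rsid`,
#'   `gene_id`), e.g. [filter_significant()] output.
#' @return A tibble with one row per phenotype: `phenotype`, list-columns
#'   `egenes` and `eqtls`, and their sizes `n_egenes`, `n_eqtls`.
#' @export
build_phenotype_sets <- function(gwas, associations) {
  check_columns(gwas, c("rsid", "trait", "study"), "gwas")
  check_columns(associations, c("rsid", "gene_id"), "associations")
  orphan <- setdiff(unique(associations$rsid), gwas$rsid)
  if (length(orphan) > 0) {
    stop("association SNP(s) missing from the GWAS table: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  labels <- gwas %>%
    dplyr::distinct(.data$rsid, .data$study, .data$trait) %>%
    dplyr::group_by(.data$rsid, .data$study) %>%
    dplyr::summarise(
      phenotype = paste(sort(unique(.data$trait)), collapse = "|"),
      .groups = "drop"
    )
  sets <- labels %>%
    dplyr::inner_join(
      dplyr::distinct(associations, .data$rsid, .data$gene_id),
      by = "rsid", relationship = "many-to-many"
    ) %>%
    dplyr::group_by(.data$phenotype) %>%
    dplyr::summarise(
      egenes = list(sort(unique(.data$gene_id))),
      eqtls = list(sort(unique(.data$rsid))),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      n_egenes = lengths(.data$egenes),
      n_eqtls = lengths(.data$eqtls)
    ) %>%
    dplyr::arrange(.data$phenotype)
  sets
}

#' Keep phenotypes with enough eGenes
#'
#' @param sets Phenotype sets from [build_phenotype_sets()].
#' @param min_count Minimum number of eGenes a phenotype must carry to be
#'   kept (default 4).
#' @return The filtered phenotype sets.
#' @export
filter_min_egenes <- function(sets, min_count = 4) {
  check_columns(sets, c("phenotype", "n_egenes"), "sets")
  out <- dplyr::filter(sets, .data$n_egenes >= min_count)
  if (nrow(out) == 0) {
    warning("no phenotype has >= ", min_count, " eGenes", call. = FALSE)
  }
  out
}

#' Pairwise phenotype sharing matrix
#'
#' The asymmetric sharing ratio between phenotypes i and j is the number of
#' their common eGenes (or eQTLs) divided by the number of eGenes of
#' phenotype i:
#' \deqn{a_{ij} = |S_i \cap S_j| / |S_i|.}
#' The diagonal is 1 and \eqn{a_{ij} n_i = a_{ji} n_j} is the integer
#' intersection size.
#'
#' @param sets Phenotype sets from [build_phenotype_sets()].
#' @param mode `"egene"` (default) or `"eqtl"`: which sets populate the
#'   matrix.
#' @return A square numeric matrix with phenotype dimnames, class
#'   `share_matrix`, carrying set sizes in attribute `"n"` and the mode in
#'   attribute `"mode"`.
#' @export
share_matrix <- function(sets, mode = c("egene", "eqtl")) {
  mode <- match.arg(mode)
  col <- if (mode == "egene") "egenes" else "eqtls"
  check_columns(sets, c("phenotype", col), "sets")
  if (nrow(sets) < 2) {
    stop("need at least two phenotypes", call. = FALSE)
  }
  items <- sets[[col]]
  if (any(lengths(items) == 0)) {
    stop("empty ", mode, " set for phenotype(s): ",
         paste(sets$phenotype[lengths(items) == 0], collapse = ", "),
         call. = FALSE)
  }
  universe <- sort(unique(unlist(items)))
  membership <- vapply(items, function(s) universe %in% s,
                       logical(length(universe)))
  counts <- crossprod(membership)  # pairwise intersection sizes
  n <- lengths(items)
  ratios <- sweep(counts, 1, n, "/")
  dimnames(ratios) <- list(sets$phenotype, sets$phenotype)
  structure(ratios, n = n, mode = mode,
            class = c("share_matrix", class(ratios)))
}

#' Mean sharing matrix under the permutation null
#'
#' All eGenes are pooled and randomly reassigned to phenotypes so that each
#' null phenotype keeps the same number of eGenes as its test counterpart
#' (drawn uniformly without replacement within a phenotype, independently
#' across phenotypes). The sharing matrix is computed for each null dataset
#' and the element-wise mean over `n_null` replicates returned.
#'
#' @inheritParams share_matrix
#' @param n_null Number of null datasets (default 1000).
#' @param seed Optional integer seed; the global RNG state is untouched.
#' @return The mean null `share_matrix` (attributes as in [share_matrix()]).
#' @export
null_mean_matrix <- function(sets, n_null = 1000, seed = NULL,
                             mode = c("egene", "eqtl")) {
  mode <- match.arg(mode)
  col <- if (mode == "egene") "egenes" else "eqtls"
  check_columns(sets, c("phenotype", col), "sets")
  items <- sets[[col]]
  pool <- sort(unique(unlist(items)))
  big <- max(lengths(items))
  if (big > length(pool)) {
    stop("a phenotype has more items than the pooled universe", call. = FALSE)
  }
  n <- lengths(items)
  p <- length(items)
  N <- length(pool)
  with_local_seed(seed, {
    acc <- matrix(0, p, p)
    for (r in seq_len(n_null)) {
      membership <- matrix(FALSE, N, p)
      draws <- draw_null_sets(n, N)
      for (j in seq_len(p)) {
        membership[draws[[j]], j] <- TRUE
      }
      counts <- crossprod(membership)
      acc <- acc + sweep(counts, 1, n, "/")
    }
    ratios <- acc / n_null
    dimnames(ratios) <- list(sets$phenotype, sets$phenotype)
    structure(ratios, n = n, mode = mode,
              class = c("share_matrix", class(ratios)))
  })
}

# One null reassignment: each phenotype draws its own number of items
# uniformly without replacement from the pooled universe, independently
# across phenotypes.
draw_null_sets <- function(sizes, N) {
  lapply(sizes, function(n) sample.int(N, n))
}

#' Commonality index of eGenes within a phenotype cluster
#'
#' The commonality index of an eGene is the fraction of phenotypes in the
#' cluster whose eGene set contains it. Genes present in no member are
#' omitted.
#'
#' @param sets Phenotype sets from [build_phenotype_sets()].
#' @param members Character vector of phenotype labels forming the cluster.
#' @return A tibble (`gene_id`, `n_phenotypes`, `commonality`) sorted by
#'   decreasing commonality.
#' @export
commonality_index <- function(sets, members) {
  check_columns(sets, c("phenotype", "egenes"), "sets")
  if (length(members) == 0) {
    stop("cluster has no members", call. = FALSE)
  }
  missing <- setdiff(members, sets$phenotype)
  if (length(missing) > 0) {
    stop("unknown phenotype(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  member_sets <- sets$egenes[match(members, sets$phenotype)]
  tibble::tibble(gene_id = unlist(member_sets)) %>%
    dplyr::count(.data$gene_id, name = "n_phenotypes") %>%
    dplyr::mutate(commonality = .data$n_phenotypes / length(members)) %>%
    dplyr::arrange(dplyr::desc(.data$commonality), .data$gene_id)
}

#' Summarise eGene presence in an OMIM-like gene-phenotype table
#'
#' Reports the fraction of eGenes catalogued in the table and, over the
#' gene-phenotype rows of annotated eGenes, the proportion falling in each
#' gene-phenotype mapping method category: (1) gene associated with the
#' disorder but underlying defect unknown, (2) mapped by linkage only,
#' (3) causal mutation identified in the gene, (4) disorder caused by
#' deletion or duplication of contiguous genes.
#'
#' @param egenes Character vector of spatial eGene ids.
#' @param omim Tibble with columns `gene_id`, `phenotype`, `method_code`
#'   (integer 1-4).
#' @return A list with `fraction_annotated`, `n_annotated`, `n_egenes` and a
#'   `method_distribution` tibble (`method_code`, `n`, `proportion`).
#' @export
omim_summary <- function(egenes, omim) {
  check_columns(omim, c("gene_id", "phenotype", "method_code"), "omim")
  if (!all(omim$method_code %in% 1:4)) {
    stop("OMIM method codes must be integers in 1..4", call. = FALSE)
  }
  egenes <- unique(egenes)
  annotated <- intersect(egenes, omim$gene_id)
  rows <- dplyr::filter(omim, .data$gene_id %in% annotated)
  dist <- rows %>%
    dplyr::count(.data$method_code) %>%
    dplyr::mutate(proportion = .data$n / sum(.data$n))
  list(
    fraction_annotated = if (length(egenes) == 0) NA_real_ else
      length(annotated) / length(egenes),
    n_annotated = length(annotated),
    n_egenes = length(egenes),
    method_distribution = dist
  )
}

#' Read an OMIM-like gene-phenotype table
#'
#' TSV with columns `gene_id`, `phenotype`, `method_code` (integer 1-4).
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_omim <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(tab, c("gene_id", "phenotype", "method_code"), "omim table")
  if (!all(tab$method_code %in% 1:4)) {
    stop("OMIM method codes must be integers in 1..4", call. = FALSE)
  }
  tab
}

#' Write a sharing matrix as TSV with phenotype labels
#'
#' @param x A `share_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_share_matrix <- function(x, path) {
  df <- tibble::as_tibble(unclass(x), rownames = "phenotype")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Long-format view of a sharing matrix
#'
#' @param x A `share_matrix`.
#' @param ... Unused.
#' @return A tibble with `phenotype_i`, `phenotype_j`, `ratio`.
#' @export
tidy.share_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "phenotype_i") %>%
    tidyr::pivot_longer(-"phenotype_i", names_to = "phenotype_j",
                        values_to = "ratio")
}

#' Heatmap of a phenotype sharing matrix
#'
#' @param object A `share_matrix`.
#' @param ... Unused.
#' @return A ggplot heatmap; rows are the reference phenotype i of the
#'   asymmetric ratio.
#' @export
autoplot.share_matrix <- function(object, ...) {
  df <- tidy.share_matrix(object)
  lev <- rownames(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$phenotype_j, levels = lev),
    y = factor(.data$phenotype_i, levels = rev(lev)),
    fill = .data$ratio
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b",
                                 limits = c(0, 1), name = "shared ratio") +
    ggplot2::labs(x = "phenotype j", y = "phenotype i") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
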