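#' In-silico restriction digest of a genome
#'
#' Scans each chromosome for occurrences of a restriction recognition site and
#' cuts at the 5' start of every occurrence (the MboI convention: `^GATC`).
#' Fragments tile each chromosome exactly, in 0-based half-open coordinates,
#' and carry a consecutive per-chromosome ordinal index starting at 0 -- the
#' index referenced by Hi-C interaction records.
#'
#' @param sequences Genome input: a FASTA file path, a named character vector
#'   of sequences, or a [Biostrings::DNAStringSet].
#' @param recognition_site Recognition sequence to cut at (default `"GATC"`,
#'   MboI).
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open)
#'   and `index` (0-based ordinal within the chromosome). Zero-length
#'   fragments arising from a site at the very start of a sequence are
#'   dropped.
#' @examples
#' digest_genome(c(chrA = "AAGATCTTGATCAA"))
#' @export
digest_genome <- function(sequences, recognition_site = "GATC") {
  stopifnot(is.character(recognition_site), nchar(recognition_site) >= 1)
  seqs <- as_dna_stringset(sequences)
  widths <- Biostrings::width(seqs)
  if (any(widths == 0)) {
    stop("empty sequence for chromosome(s): ",
         paste(names(seqs)[widths == 0], collapse = ", "), call. = FALSE)
  }
  hits <- Biostrings::vmatchPattern(recognition_site, seqs)
  purrr::map2_dfr(names(seqs), seq_along(seqs), function(chrom, i) {
    len <- widths[i]
    cuts <- BiocGenerics::start(hits[[i]]) - 1L  # 0-based cut coordinates
    bounds <- sort(unique(c(0L, cuts, len)))
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1]
    keep <- ends > starts
    starts <- starts[keep]
    ends <- ends[keep]
    tibble::tibble(
      chrom = chrom,
      start = as.integer(starts),
      end = as.integer(ends),
      index = seq_along(starts) - 1L
    )
  })
}

#' Collapse transcript isoforms into composite gene regions
#'
#' All isoforms of a gene are collapsed into a single composite region: the
#' union span `[min start, max end)` of its transcripts on its chromosome.
#' Introns and inter-isoform gaps are therefore included in the span.
#'
#' @param annotations A GTF file path, a `GRanges`, or a data frame with
#'   columns `chrom` (or `seqnames`), `start`, `end` and `gene_id` (optionally
#'   `gene_name`). GTF/GRanges coordinates are 1-based inclusive and are
#'   converted; data-frame input is assumed already 0-based half-open.
#' @return A tibble with one row per gene: `gene_id`, `gene_name`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @export
collapse_gene_model <- function(annotations) {
  if (is.character(annotations) && length(annotations) == 1) {
    gr <- rtracklayer::import(annotations, format = "gtf")
    annotations <- tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr) - 1L,  # GTF is 1-based inclusive
      end = BiocGenerics::end(gr),
      gene_id = gr$gene_id,
      gene_name = if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
    )
  } else if (methods::is(annotations, "GRanges")) {
    gr <- annotations
    annotations <- tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr),
      gene_id = gr$gene_id,
      gene_name = if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
    )
  }
  check_columns(annotations, c("chrom", "start", "end", "gene_id"),
                "annotations")
  if (!"gene_name" %in% names(annotations)) {
    annotations$gene_name <- annotations$gene_id
  }
  multi_chrom <- annotations %>%
    dplyr::distinct(.data$gene_id, .data$chrom) %>%
    dplyr::count(.data$gene_id) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(multi_chrom) > 0) {
    stop("gene(s) annotated on more than one chromosome: ",
         paste(multi_chrom$gene_id, collapse = ", "), call. = FALSE)
  }
  annotations %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      gene_name = dplyr::first(.data$gene_name),
      chrom = dplyr::first(.data$chrom),
      start = as.integer(min(.data$start)),
      end = as.integer(max(.data$end)),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$chrom, .data$start)
}

#' Assign SNPs to the restriction fragments harbouring them
#'
#' A SNP position (1-based, the convention of variant input files) is
#' converted to 0-based and mapped to the unique fragment containing it.
#'
#' @param snps Tibble with columns `rsid`, `chrom`, `pos` (1-based).
#' @param fragments Fragment table from [digest_genome()].
#' @return `snps` with an added `fragment` column (the per-chromosome
#'   fragment index).
#' @export
assign_snps_to_fragments <- function(snps, fragments) {
  check_columns(snps, c("rsid", "chrom", "pos"), "snps")
  check_columns(fragments, c("chrom", "start", "end", "index"), "fragments")
  out <- snps
  out$fragment <- NA_integer_
  for (chr in unique(snps$chrom)) {
    frag <- fragments[fragments$chrom == chr, ]
    rows <- which(snps$chrom == chr)
    if (nrow(frag) == 0) {
      stop("no fragments on chromosome ", chr, " for SNP(s): ",
           paste(snps$rsid[rows], collapse = ", "), call. = FALSE)
    }
    frag <- frag[order(frag$start), ]
    pos0 <- snps$pos[rows] - 1L
    hit <- findInterval(pos0, frag$start)
    bad <- hit == 0 | pos0 >= frag$end[pmax(hit, 1L)]
    if (any(bad)) {
      stop("SNP position outside any fragment: ",
           paste(snps$rsid[rows][bad], collapse = ", "), call. = FALSE)
    }
    out$fragment[rows] <- frag$index[hit]
  }
  out
}

#' Assign gene regions to every restriction fragment they overlap
#'
#' A composite gene region maps to each fragment it overlaps by at least 1 bp.
#' No binning or padding is applied around restriction fragments.
#'
#' @param genes Gene-region table from [collapse_gene_model()] (columns
#'   `gene_id`, `chrom`, `start`, `end`; 0-based half-open).
#' @param fragments Fragment table from [digest_genome()].
#' @return A long tibble with one row per (gene, overlapped fragment):
#'   `gene_id`, `chrom`, `fragment`.
#' @export
assign_genes_to_fragments <- function(genes, fragments) {
  check_columns(genes, c("gene_id", "chrom", "start", "end"), "genes")
  check_columns(fragments, c("chrom", "start", "end", "index"), "fragments")
  purrr::map_dfr(unique(genes$chrom), function(chr) {
    g <- genes[genes$chrom == chr, ]
    f <- fragments[fragments$chrom == chr, ]
    if (nrow(f) == 0) {
      stop("no fragments on chromosome ", chr, " for gene(s): ",
           paste(g$gene_id, collapse = ", "), call. = FALSE)
    }
    # 0-based half-open -> IRanges 1-based inclusive
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(g$start + 1L, g$end),
      IRanges::IRanges(f$start + 1L, f$end)
    )
    tibble::tibble(
      gene_id = g$gene_id[S4Vectors::queryHits(hits)],
      chrom = chr,
      fragment = f$index[S4Vectors::subjectHits(hits)]
    )
  }) %>%
    dplyr::arrange(.data$gene_id, .data$fragment)
}

#' Read a GWAS-style SNP-trait association table
#'
#' Reads a TSV with columns `rsid`, `chrom`, `pos`, `trait`, `study`,
#' `gwas_p` (one row per SNP-trait-study association) and applies the
#' suggestive-significance input filter `gwas_p < 5e-6`.
#'
#' @param path TSV file path.
#' @param p_threshold Association p-value cutoff applied at ingest
#'   (default `5e-6`).
#' @return A tibble of retained associations.
#' @export
read_gwas <- function(path, p_threshold = 5e-6) {
  gwas <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(gwas, c("rsid", "chrom", "pos", "trait", "study", "gwas_p"),
                "gwas table")
  dropped <- sum(gwas$gwas_p >= p_threshold)
  if (dropped > 0) {
    message(dropped, " association(s) dropped at p >= ", p_threshold)
  }
  dplyr::filter(gwas, .data$gwas_p < p_threshold)
}

#' Write a fragment table as BED-like TSV
#'
#' @param fragments Fragment table from [digest_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  check_columns(fragments, c("chrom", "start", "end", "index"), "fragments")
  readr::write_tsv(fragments, path)
  invisible(path)
}
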