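# Synthetic-data generator: emits every input the pipeline consumes (genome
# FASTA, transcript GTF, GWAS-style associations, merged_nodups interaction
# files, eQTL table, OMIM-like genemap) with planted ground truth -- trait
# clusters sharing a contiguous core eGene locus plus trait-private eGenes --
# so every downstream stage has a recoverable answer.

#' Configuration for the synthetic dataset
#'
#' Defaults define the study conditions used throughout the package's tests:
#' 12 traits in 3 planted clusters, each cluster sharing a contiguous core
#' locus of 4 adjacent genes plus 2 private eGenes per trait, observed in
#' 2 cell lines with 2 replicates each.
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Chromosome length in bp.
#' @param site_spacing_mean Mean spacing (bp) between planted GATC
#'   recognition sites; controls restriction-fragment density.
#' @param n_genes_per_chromosome Genes placed (without overlap) per
#'   chromosome.
#' @param n_traits Number of traits.
#' @param n_planted_clusters Number of planted trait clusters.
#' @param core_locus_size Adjacent genes forming each cluster's shared core
#'   locus.
#' @param private_egenes_per_trait Trait-private eGenes per trait (drawn
#'   disjointly across traits).
#' @param n_cell_lines,replicates_per_cell_line Hi-C provenance structure.
#' @param background_interactions Total random fragment-pair noise records
#'   across all interaction files.
#' @param true_eqtl_p_scale Scale of the small p-values given to true
#'   eQTL rows (p = scale * Uniform(0,1)); 1 makes every row null.
#' @param n_tissues Number of tissues in the eQTL table.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chromosome_length = 300000L,
                       site_spacing_mean = 1000,
                       n_genes_per_chromosome = 12L,
                       n_traits = 12L,
                       n_planted_clusters = 3L,
                       core_locus_size = 4L,
                       private_egenes_per_trait = 2L,
                       n_cell_lines = 2L,
                       replicates_per_cell_line = 2L,
                       background_interactions = 200L,
                       true_eqtl_p_scale = 1e-8,
                       n_tissues = 3L) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    site_spacing_mean = as.numeric(site_spacing_mean),
    n_genes_per_chromosome = as.integer(n_genes_per_chromosome),
    n_traits = as.integer(n_traits),
    n_planted_clusters = as.integer(n_planted_clusters),
    core_locus_size = as.integer(core_locus_size),
    private_egenes_per_trait = as.integer(private_egenes_per_trait),
    n_cell_lines = as.integer(n_cell_lines),
    replicates_per_cell_line = as.integer(replicates_per_cell_line),
    background_interactions = as.integer(background_interactions),
    true_eqtl_p_scale = as.numeric(true_eqtl_p_scale),
    n_tissues = as.integer(n_tissues)
  )
  counts <- c("n_chromosomes", "chromosome_length",
              "n_genes_per_chromosome", "n_traits", "n_planted_clusters",
              "core_locus_size", "private_egenes_per_trait", "n_cell_lines",
              "replicates_per_cell_line", "n_tissues")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1) {
      stop("`", f, "` must be a count >= 1", call. = FALSE)
    }
  }
  if (cfg$background_interactions < 0) {
    stop("`background_interactions` must be >= 0", call. = FALSE)
  }
  if (cfg$site_spacing_mean <= 0 ||
      cfg$chromosome_length <= 10 * cfg$site_spacing_mean) {
    stop("`chromosome_length` must exceed 10 * `site_spacing_mean`",
         call. = FALSE)
  }
  if (cfg$core_locus_size > cfg$n_genes_per_chromosome) {
    stop("`core_locus_size` cannot exceed `n_genes_per_chromosome`",
         call. = FALSE)
  }
  if (cfg$n_traits < cfg$n_planted_clusters) {
    stop("need at least one trait per planted cluster", call. = FALSE)
  }
  loci_per_chrom <- ceiling(cfg$n_planted_clusters / cfg$n_chromosomes)
  if (loci_per_chrom * cfg$core_locus_size > cfg$n_genes_per_chromosome) {
    stop("core loci do not fit: ", loci_per_chrom, " locus/loci of ",
         cfg$core_locus_size, " genes exceed ", cfg$n_genes_per_chromosome,
         " genes per chromosome", call. = FALSE)
  }
  total_genes <- cfg$n_chromosomes * cfg$n_genes_per_chromosome
  core_genes <- cfg$n_planted_clusters * cfg$core_locus_size
  if (cfg$n_traits * cfg$private_egenes_per_trait > total_genes - core_genes) {
    stop("not enough non-core genes for disjoint private eGenes (",
         cfg$n_traits * cfg$private_egenes_per_trait, " needed, ",
         total_genes - core_genes, " available)", call. = FALSE)
  }
  if (cfg$true_eqtl_p_scale <= 0 || cfg$true_eqtl_p_scale > 1) {
    stop("`true_eqtl_p_scale` must lie in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Sub-seeds so each generator stage is independently deterministic.
stage_seed <- function(config, offset) {
  (config$seed + offset * 10007L) %% .Machine$integer.max
}

#' Generate a synthetic genome with planted recognition sites
#'
#' Each chromosome is random non-GATC background sequence into which GATC
#' recognition sites are injected at stochastic spacings (exponential with
#' mean `site_spacing_mean`, floored at the site length), so the expected
#' restriction-fragment count is `chromosome_length / site_spacing_mean`.
#' Accidental GATC occurrences in the background are rejection-fixed, making
#' the planted site positions the exact digest truth.
#'
#' @param config A [sim_config()].
#' @return A list: `sequences` (named [Biostrings::DNAStringSet]) and
#'   `sites` (per-chromosome integer vectors of 0-based site start
#'   positions).
#' @export
sim_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$chromosome_length
  site <- c("G", "A", "T", "C")
  with_local_seed(stage_seed(config, 0L), {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    sites <- list()
    seqs <- character(config$n_chromosomes)
    for (ci in seq_along(chroms)) {
      n_draw <- ceiling(2.5 * L / config$site_spacing_mean) + 10
      gaps <- pmax(4, round(stats::rexp(n_draw, 1 / config$site_spacing_mean)))
      pos <- cumsum(gaps)
      pos <- pos[pos + 4 <= L]
      chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      # rejection-fix accidental GATC in the background
      repeat {
        s <- paste(chars, collapse = "")
        hits <- gregexpr("GATC", s, fixed = TRUE)[[1]]
        if (hits[1] == -1) break
        chars[hits] <- sample(c("A", "C", "T"), length(hits), replace = TRUE)
      }
      for (k in 0:3) chars[pos + k + 1L] <- site[k + 1L]
      seqs[ci] <- paste(chars, collapse = "")
      sites[[chroms[ci]]] <- as.integer(pos)
    }
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- chroms
    list(sequences = dna, sites = sites)
  })
}

#' Generate gene annotations, GWAS associations and planted ground truth
#'
#' Genes are placed without overlap in equal-width slots along each
#' chromosome; some genes carry two isoforms so that isoform collapsing is
#' exercised. Each planted cluster owns a contiguous core locus of
#' `core_locus_size` adjacent genes shared by all its traits; every trait
#' additionally receives disjoint private eGenes. One SNP per (trait, target
#' gene) is placed inside an intergenic restriction fragment (never on a cut
#' site), with the last private target of each trait on a different
#' chromosome to exercise trans classification; one multi-trait SNP per
#' cluster (its own study) creates a composite phenotype targeting the whole
#' core locus. All emitted GWAS p-values are below 5e-6.
#'
#' @param config A [sim_config()].
#' @param genome Result of [sim_genome()].
#' @return A list: `genes` (isoform-level annotation tibble), `gwas`
#'   (association tibble) and `truth` (ground-truth list: trait and
#'   phenotype cluster labels, true eQTL pairs, core locus genes, SNP and
#'   gene coordinate records).
#' @export
sim_annotations <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  fragments <- digest_genome(genome$sequences)
  L <- config$chromosome_length
  n_genes <- config$n_genes_per_chromosome
  slot <- floor(L / n_genes)
  if (slot < 200) {
    stop("chromosome_length too small to host ", n_genes,
         " genes per chromosome", call. = FALSE)
  }
  with_local_seed(stage_seed(config, 1L), {
    chroms <- names(genome$sequences)
    iso <- list()
    gene_rows <- list()
    for (ci in seq_along(chroms)) {
      for (gi in seq_len(n_genes)) {
        slot_start <- (gi - 1L) * slot
        margin <- round(0.1 * slot)
        gs <- slot_start + margin + sample.int(max(1, round(0.05 * slot)), 1)
        len <- round(stats::runif(1, 0.2, 0.45) * slot)
        gid <- sprintf("G%d.%02d", ci, gi)
        iso1 <- c(gs, gs + len)
        rows <- list(tibble::tibble(
          chrom = chroms[ci], start = iso1[1], end = iso1[2],
          gene_id = gid, gene_name = gid,
          transcript_id = paste0(gid, ".t1")
        ))
        if (gi %% 2 == 0) {  # second isoform extends the union span
          ext <- round(0.15 * slot)
          rows[[2]] <- tibble::tibble(
            chrom = chroms[ci], start = gs + round(0.4 * len),
            end = gs + len + ext,
            gene_id = gid, gene_name = gid,
            transcript_id = paste0(gid, ".t2")
          )
        }
        iso[[gid]] <- dplyr::bind_rows(rows)
        gene_rows[[gid]] <- tibble::tibble(
          gene_id = gid, chrom = chroms[ci],
          start = min(iso[[gid]]$start), end = max(iso[[gid]]$end)
        )
      }
    }
    genes <- dplyr::bind_rows(iso)
    regions <- dplyr::bind_rows(gene_rows)

    # planted cluster structure
    C <- config$n_planted_clusters
    trait_ids <- sprintf("trait%02d", seq_len(config$n_traits))
    trait_cluster <- sort(rep_len(seq_len(C), config$n_traits))
    names(trait_cluster) <- trait_ids
    core <- list()
    for (cl in seq_len(C)) {
      ci <- ((cl - 1L) %% config$n_chromosomes) + 1L
      off <- (cl - 1L) %/% config$n_chromosomes
      idx <- off * config$core_locus_size + seq_len(config$core_locus_size)
      core[[cl]] <- sprintf("G%d.%02d", ci, idx)
    }
    names(core) <- paste0("cluster", seq_len(C))
    non_core <- setdiff(regions$gene_id, unlist(core))
    non_core <- sample(non_core)
    private <- list()
    for (ti in seq_len(config$n_traits)) {
      take <- seq_len(config$private_egenes_per_trait)
      private[[trait_ids[ti]]] <- non_core[take]
      non_core <- non_core[-take]
    }

    # intergenic fragments eligible to host SNPs (width >= 20, no gene)
    gene_frags <- assign_genes_to_fragments(regions, fragments)
    frag_pool <- fragments %>%
      dplyr::anti_join(gene_frags, by = c("chrom", "index" = "fragment")) %>%
      dplyr::filter(.data$end - .data$start >= 20)

    pick_fragment <- function(chrom, near = NA_real_) {
      cand <- frag_pool[frag_pool$chrom == chrom, ]
      if (nrow(cand) == 0) {
        stop("no intergenic fragment left on ", chrom, call. = FALSE)
      }
      row <- if (is.na(near)) {
        cand[sample.int(nrow(cand), 1), ]
      } else {
        cand[which.min(abs((cand$start + cand$end) / 2 - near)), ]
      }
      frag_pool <<- frag_pool[!(frag_pool$chrom == row$chrom &
                                  frag_pool$index == row$index), ]
      row
    }

    snp_rows <- list()
    gwas_rows <- list()
    true_pairs <- list()
    n_snp <- 0L
    new_rsid <- function() {
      n_snp <<- n_snp + 1L
      sprintf("rs%05d", n_snp)
    }
    for (ti in seq_len(config$n_traits)) {
      trait <- trait_ids[ti]
      targets <- c(core[[trait_cluster[ti]]], private[[trait]])
      for (k in seq_along(targets)) {
        gid <- targets[k]
        greg <- regions[regions$gene_id == gid, ]
        # last private target goes cross-chromosome (trans evidence)
        chrom <- if (k == length(targets) && config$n_chromosomes > 1) {
          chroms[(match(greg$chrom, chroms) %% length(chroms)) + 1L]
        } else {
          greg$chrom
        }
        frag <- pick_fragment(chrom,
                              near = if (chrom == greg$chrom) greg$start
                              else NA_real_)
        rsid <- new_rsid()
        pos <- as.integer(floor((frag$start + frag$end) / 2)) + 1L
        snp_rows[[rsid]] <- tibble::tibble(
          rsid = rsid, chrom = chrom, pos = pos, fragment = frag$index
        )
        gwas_rows[[length(gwas_rows) + 1L]] <- tibble::tibble(
          rsid = rsid, chrom = chrom, pos = pos, trait = trait,
          study = "S1", gwas_p = stats::runif(1, 1e-12, 4.9e-6)
        )
        true_pairs[[length(true_pairs) + 1L]] <-
          tibble::tibble(rsid = rsid, gene_id = gid)
      }
    }
    # composite phenotypes: one multi-trait SNP per cluster, own study
    composite_labels <- character(C)
    for (cl in seq_len(C)) {
      members <- trait_ids[trait_cluster == cl]
      pair <- sort(members[seq_len(min(2, length(members)))])
      composite_labels[cl] <- paste(pair, collapse = "|")
      gid1 <- core[[cl]][1]
      greg <- regions[regions$gene_id == gid1, ]
      frag <- pick_fragment(greg$chrom, near = greg$end)
      rsid <- new_rsid()
      pos <- as.integer(floor((frag$start + frag$end) / 2)) + 1L
      snp_rows[[rsid]] <- tibble::tibble(
        rsid = rsid, chrom = greg$chrom, pos = pos, fragment = frag$index
      )
      p <- stats::runif(1, 1e-12, 4.9e-6)
      for (tr in pair) {
        gwas_rows[[length(gwas_rows) + 1L]] <- tibble::tibble(
          rsid = rsid, chrom = greg$chrom, pos = pos, trait = tr,
          study = sprintf("Scomp%d", cl), gwas_p = p
        )
      }
      for (gid in core[[cl]]) {
        true_pairs[[length(true_pairs) + 1L]] <-
          tibble::tibble(rsid = rsid, gene_id = gid)
      }
    }
    snps <- dplyr::bind_rows(snp_rows)
    gwas <- dplyr::bind_rows(gwas_rows)
    pairs <- dplyr::bind_rows(true_pairs)
    tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
    truth <- list(
      trait_to_cluster = trait_cluster,
      phenotype_to_cluster = c(
        trait_cluster,
        stats::setNames(seq_len(C), composite_labels)
      ),
      core_locus_genes = core,
      private_egenes = private,
      true_pairs = pairs,
      true_eqtl_pairs = tidyr::crossing(pairs, tissue = tissues) %>%
        dplyr::arrange(.data$rsid, .data$gene_id, .data$tissue),
      snp_positions = snps,
      gene_regions = regions,
      tissues = tissues,
      sites = genome$sites
    )
    list(genes = genes, gwas = gwas, truth = truth)
  })
}

#' Generate Hi-C interaction files supporting the planted pairs
#'
#' Every planted (SNP, gene) pair receives at least one interaction between
#' the SNP's restriction fragment and a fragment overlapping the gene's
#' composite region, spread stochastically over cell lines and replicates;
#' `background_interactions` random fragment pairs are added as noise. Rows
#' follow the 9-column merged_nodups dialect.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [sim_annotations()].
#' @param fragments Fragment table from [digest_genome()] on the same
#'   genome.
#' @param dir Directory the per-(cell line, replicate) files are written to.
#' @return A tibble (`file`, `cell_line`, `replicate`) naming the written
#'   files, suitable for [read_interaction_set()].
#' @export
sim_interactions <- function(config, truth, fragments, dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gene_frags <- assign_genes_to_fragments(truth$gene_regions, fragments)
  snp_frags <- truth$snp_positions
  bad <- dplyr::anti_join(snp_frags, fragments,
                          by = c("chrom", "fragment" = "index"))
  if (nrow(bad) > 0) {
    stop("fragment indices not present in the digest for SNP(s): ",
         paste(bad$rsid, collapse = ", "), call. = FALSE)
  }
  frag_info <- fragments
  files <- tidyr::crossing(
    cell_line = sprintf("CL%d", seq_len(config$n_cell_lines)),
    replicate = sprintf("R%d", seq_len(config$replicates_per_cell_line))
  )
  with_local_seed(stage_seed(config, 2L), {
    recs <- list()
    rid <- 0L
    add_record <- function(chrom_a, frag_a, chrom_b, frag_b, cl, rep) {
      rid <<- rid + 1L
      fa <- frag_info[frag_info$chrom == chrom_a &
                        frag_info$index == frag_a, ]
      fb <- frag_info[frag_info$chrom == chrom_b &
                        frag_info$index == frag_b, ]
      pos_a <- sample(seq.int(fa$start + 1L, fa$end), 1)
      pos_b <- sample(seq.int(fb$start + 1L, fb$end), 1)
      flip <- stats::runif(1) < 0.5  # SNP end appears as end 1 or end 2
      tibble::tibble(
        read_name = sprintf("read%06d", rid),
        strand1 = sample(c(0L, 16L), 1),
        chrom1 = if (flip) chrom_b else chrom_a,
        pos1 = if (flip) pos_b else pos_a,
        frag1 = if (flip) frag_b else frag_a,
        strand2 = sample(c(0L, 16L), 1),
        chrom2 = if (flip) chrom_a else chrom_b,
        pos2 = if (flip) pos_a else pos_b,
        frag2 = if (flip) frag_a else frag_b,
        cell_line = cl, replicate = rep
      )
    }
    for (i in seq_len(nrow(truth$true_pairs))) {
      rsid <- truth$true_pairs$rsid[i]
      gid <- truth$true_pairs$gene_id[i]
      snp <- snp_frags[snp_frags$rsid == rsid, ]
      gf <- gene_frags[gene_frags$gene_id == gid, ]
      n_obs <- 1L + stats::rpois(1, 1.2)
      for (k in seq_len(n_obs)) {
        file_row <- files[sample.int(nrow(files), 1), ]
        gpick <- gf[sample.int(nrow(gf), 1), ]
        recs[[length(recs) + 1L]] <- add_record(
          snp$chrom, snp$fragment, gpick$chrom, gpick$fragment,
          file_row$cell_line, file_row$replicate
        )
      }
    }
    if (config$background_interactions > 0) {
      for (k in seq_len(config$background_interactions)) {
        ra <- frag_info[sample.int(nrow(frag_info), 1), ]
        rb <- frag_info[sample.int(nrow(frag_info), 1), ]
        file_row <- files[sample.int(nrow(files), 1), ]
        recs[[length(recs) + 1L]] <- add_record(
          ra$chrom, ra$index, rb$chrom, rb$index,
          file_row$cell_line, file_row$replicate
        )
      }
    }
    records <- dplyr::bind_rows(recs)
    files$file <- file.path(dir, sprintf("interactions_%s_%s.txt",
                                         files$cell_line, files$replicate))
    for (i in seq_len(nrow(files))) {
      sub <- records[records$cell_line == files$cell_line[i] &
                       records$replicate == files$replicate[i], ]
      lines <- sprintf("%s %d %s %d %d %d %s %d %d",
                       sub$read_name, sub$strand1, sub$chrom1, sub$pos1,
                       sub$frag1, sub$strand2, sub$chrom2, sub$pos2,
                       sub$frag2)
      writeLines(lines, files$file[i])
    }
    files[, c("file", "cell_line", "replicate")]
  })
}

#' Generate the eQTL association table
#'
#' Every planted (SNP, gene, tissue) triple receives a small p-value
#' (`true_eqtl_p_scale * Uniform(0, 1)`) and a nonzero normalised effect
#' size; an equal number of decoy rows for non-planted SNP-gene pairs carry
#' `Uniform(0, 1)` p-values. Decoy pairs have no planted interaction, so the
#' spatial query step excludes them.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [sim_annotations()].
#' @return The eQTL tibble: `rsid`, `gene_id`, `tissue`, `p_nominal`, `nes`.
#' @export
sim_eqtl_table <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tissues < 1) stop("need at least one tissue", call. = FALSE)
  with_local_seed(stage_seed(config, 3L), {
    true_rows <- truth$true_eqtl_pairs %>%
      dplyr::mutate(
        p_nominal = config$true_eqtl_p_scale * stats::runif(dplyr::n()),
        nes = sample(c(-1, 1), dplyr::n(), replace = TRUE) *
          stats::runif(dplyr::n(), 0.2, 1.5)
      )
    # decoy pairs: non-planted SNP-gene combinations, uniform p
    n_decoy <- nrow(true_rows)
    all_genes <- truth$gene_regions$gene_id
    all_snps <- truth$snp_positions$rsid
    key <- paste(truth$true_pairs$rsid, truth$true_pairs$gene_id)
    decoys <- tibble::tibble(
      rsid = sample(all_snps, 3 * n_decoy, replace = TRUE),
      gene_id = sample(all_genes, 3 * n_decoy, replace = TRUE),
      tissue = sample(truth$tissues, 3 * n_decoy, replace = TRUE)
    ) %>%
      dplyr::filter(!paste(.data$rsid, .data$gene_id) %in% key) %>%
      dplyr::distinct() %>%
      utils::head(n_decoy) %>%
      dplyr::mutate(
        p_nominal = stats::runif(dplyr::n()),
        nes = stats::rnorm(dplyr::n(), 0, 0.2)
      )
    dplyr::bind_rows(true_rows, decoys) %>%
      dplyr::arrange(.data$rsid, .data$gene_id, .data$tissue)
  })
}

#' Generate an OMIM-like gene-phenotype table
#'
#' A synthetic genemap: a random subset of genes receives one or two
#' gene-phenotype rows with mapping-method codes 1-4 drawn with the heavy
#' weight on category 3 (causal mutation identified) seen in curated
#' disease-gene catalogues.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [sim_annotations()].
#' @param coverage Probability a gene is catalogued (default 0.62).
#' @return A tibble `gene_id`, `phenotype`, `method_code`.
#' @export
sim_omim_table <- function(config, truth, coverage = 0.62) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(stage_seed(config, 4L), {
    genes <- truth$gene_regions$gene_id
    included <- genes[stats::runif(length(genes)) < coverage]
    if (length(included) == 0) included <- genes[1]
    rows <- purrr::map_dfr(included, function(g) {
      n <- sample(1:2, 1)
      tibble::tibble(
        gene_id = g,
        phenotype = sprintf("MIM:%s.%d", g, seq_len(n)),
        method_code = sample(1:4, n, replace = TRUE,
                             prob = c(0.008, 0.006, 0.982, 0.004))
      )
    })
    dplyr::arrange(rows, .data$gene_id, .data$phenotype)
  })
}

#' Generate and write the full synthetic dataset
#'
#' Runs every generator stage and writes the pipeline's input files: genome
#' FASTA, transcript GTF, GWAS TSV, fragment table, per-replicate
#' interaction files, eQTL TSV, OMIM-like TSV, plus a JSON echo of the
#' configuration and ground truth. Byte-identical given the same
#' configuration.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return A list: `config`, `truth`, in-memory inputs (`genome`,
#'   `fragments`, `genes`, `gwas`, `eqtl`, `omim`, `interaction_files`) and
#'   `paths` of the written files.
#' @export
sim_dataset <- function(config = sim_config(), dir = tempfile("simdata")) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genome <- sim_genome(config)
  ann <- sim_annotations(config, genome)
  fragments <- digest_genome(genome$sequences)
  files <- sim_interactions(config, ann$truth, fragments, dir)
  eqtl <- sim_eqtl_table(config, ann$truth)
  omim <- sim_omim_table(config, ann$truth)

  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "genes.gtf"),
    gwas = file.path(dir, "gwas.tsv"),
    fragments = file.path(dir, "fragments.tsv"),
    eqtl = file.path(dir, "eqtl.tsv"),
    omim = file.path(dir, "omim.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  Biostrings::writeXStringSet(genome$sequences, paths$fasta)
  writeLines(gtf_lines(ann$genes), paths$gtf)
  readr::write_tsv(ann$gwas, paths$gwas)
  write_fragments(fragments, paths$fragments)
  readr::write_tsv(eqtl, paths$eqtl)
  readr::write_tsv(omim, paths$omim)
  jsonlite::write_json(
    list(
      config = unclass(config),
      trait_to_cluster = as.list(ann$truth$trait_to_cluster),
      phenotype_to_cluster = as.list(ann$truth$phenotype_to_cluster),
      core_locus_genes = ann$truth$core_locus_genes,
      private_egenes = ann$truth$private_egenes,
      true_eqtl_pairs = ann$truth$true_eqtl_pairs,
      snp_positions = ann$truth$snp_positions,
      gene_regions = ann$truth$gene_regions
    ),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  list(
    config = config,
    truth = ann$truth,
    genome = genome,
    fragments = fragments,
    genes = ann$genes,
    gwas = ann$gwas,
    eqtl = eqtl,
    omim = omim,
    interaction_files = files,
    paths = paths
  )
}

# GTF emission: 1-based inclusive coordinates from the internal 0-based
# half-open isoform table.
gtf_lines <- function(genes) {
  sprintf(
    "%s\tsim\ttranscript\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
    genes$chrom, genes$start + 1L, genes$end, genes$gene_id,
    genes$transcript_id, genes$gene_name
  )
}
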