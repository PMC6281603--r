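test_that("configuration invariants are enforced", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_traits = 0), "count")
  expect_error(sim_config(n_tissues = 0), "count")
  expect_error(sim_config(chromosome_length = 1000, site_spacing_mean = 500),
               "chromosome_length")
  expect_error(sim_config(core_locus_size = 99), "core_locus_size")
  expect_error(sim_config(n_genes_per_chromosome = 5, core_locus_size = 4,
                          n_planted_clusters = 4, n_chromosomes = 2),
               "core loci")
  expect_error(sim_config(private_egenes_per_trait = 50), "private")
})

test_that("generation is byte-identical given the same configuration", {
  d1 <- tempfile()
  d2 <- tempfile()
  s1 <- sim_dataset(small_config(), dir = d1)
  s2 <- sim_dataset(small_config(), dir = d2)
  for (p in c("fasta", "gtf", "gwas", "eqtl", "omim")) {
    expect_identical(readLines(s1$paths[[p]]), readLines(s2$paths[[p]]),
                     label = p)
  }
  for (i in seq_len(nrow(s1$interaction_files))) {
    expect_identical(readLines(s1$interaction_files$file[i]),
                     readLines(s2$interaction_files$file[i]))
  }
  # a different seed changes the data
  s3 <- sim_dataset(small_config(seed = 99L), dir = tempfile())
  expect_false(identical(readLines(s1$paths$fasta),
                         readLines(s3$paths$fasta)))
})

test_that("the genome carries the requested chromosomes and site density", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_length = 50000,
                    site_spacing_mean = 500, n_genes_per_chromosome = 6,
                    n_traits = 3, n_planted_clusters = 3,
                    core_locus_size = 2, private_egenes_per_trait = 1)
  g <- sim_genome(cfg)
  expect_equal(length(g$sequences), 2L)
  expect_equal(names(g$sequences), c("chr1", "chr2"))

  frags <- digest_genome(g$sequences)
  per_chrom <- table(frags$chrom)
  # Poisson-spacing expectation: ~100 fragments per chromosome, +-50%
  expect_true(all(per_chrom >= 50 & per_chrom <= 150))
  # the planted sites are exactly the digest's internal cut positions
  chr1 <- frags[frags$chrom == "chr1", ]
  expect_equal(chr1$start[-1], g$sites$chr1)
})

test_that("ground truth matches the emitted annotation and GWAS files", {
  sim <- sim_dataset(small_config(), dir = tempfile())
  truth <- sim$truth

  # 4 traits in 2 clusters of 2
  expect_equal(length(truth$trait_to_cluster), 4L)
  expect_equal(unname(table(truth$trait_to_cluster)), c(2L, 2L),
               ignore_attr = TRUE)
  # collapsed GTF regions equal the recorded gene regions
  collapsed <- collapse_gene_model(sim$paths$gtf)
  want <- dplyr::arrange(truth$gene_regions, chrom, start)
  expect_equal(collapsed$gene_id, want$gene_id)
  expect_equal(collapsed$start, want$start)
  expect_equal(collapsed$end, want$end)
  # every emitted GWAS p-value is below the suggestive threshold
  expect_true(all(sim$gwas$gwas_p < 5e-6))
  # composite rows exist: one SNP, one study, two traits
  multi <- dplyr::count(sim$gwas, rsid, study) %>% dplyr::filter(n > 1)
  expect_gte(nrow(multi), 1L)
  # SNP coordinates in the truth match the emitted GWAS table
  joined <- dplyr::inner_join(
    dplyr::distinct(sim$gwas, rsid, chrom, pos),
    truth$snp_positions, by = "rsid", suffix = c("", ".t")
  )
  expect_equal(joined$pos, joined$pos.t)
  # core-locus genes are adjacent in genomic order
  for (core in truth$core_locus_genes) {
    idx <- match(core, collapsed$gene_id[order(collapsed$chrom,
                                               collapsed$start)])
    expect_equal(diff(sort(idx)), rep(1L, length(core) - 1))
  }
  # each trait appears in exactly one cluster; core genes serve >= 2 traits
  for (cl in seq_along(truth$core_locus_genes)) {
    members <- names(truth$trait_to_cluster[truth$trait_to_cluster == cl])
    expect_gte(length(members), 2L)
  }
})

test_that("dual-isoform genes collapse to the union of their transcripts", {
  sim <- sim_dataset(small_config(), dir = tempfile())
  iso_counts <- dplyr::count(sim$genes, gene_id)
  expect_true(any(iso_counts$n >= 2))
  g2 <- sim$genes[sim$genes$gene_id == iso_counts$gene_id[iso_counts$n == 2][1], ]
  expect_equal(
    collapse_gene_model(g2)$start, min(g2$start)
  )
  expect_equal(collapse_gene_model(g2)$end, max(g2$end))
})

test_that("noise-free interaction files support exactly the planted pairs", {
  cfg <- small_config(background_interactions = 0L)
  sim <- sim_dataset(cfg, dir = tempfile())
  ints <- read_interaction_set(sim$interaction_files)
  genes <- collapse_gene_model(sim$paths$gtf)
  snps <- dplyr::distinct(sim$gwas, rsid, chrom, pos)
  pairs <- find_spatial_pairs(
    ints,
    assign_snps_to_fragments(snps, sim$fragments),
    assign_genes_to_fragments(genes, sim$fragments)
  )
  truth_keys <- with(sim$truth$true_pairs, paste(rsid, gene_id))
  expect_true(all(truth_keys %in% paste(pairs$rsid, pairs$gene_id)))
  # every emitted row supports a planted pair (no background rows)
  expect_equal(nrow(ints), sum(pairs$supporting_interactions))
  # fragment indices in the files all exist in the digest
  valid <- dplyr::bind_rows(
    dplyr::transmute(ints, chrom = chrom1, index = frag1),
    dplyr::transmute(ints, chrom = chrom2, index = frag2)
  ) %>% dplyr::anti_join(sim$fragments, by = c("chrom", "index"))
  expect_equal(nrow(valid), 0L)
})

test_that("interaction generation refuses fragments missing from the digest", {
  cfg <- small_config()
  sim <- sim_dataset(cfg, dir = tempfile())
  tampered <- sim$truth
  tampered$snp_positions$fragment[1] <- 99999L
  expect_error(
    sim_interactions(cfg, tampered, sim$fragments, tempfile()),
    "not present in the digest"
  )
})

test_that("true eQTL rows are small and null rows uniform", {
  cfg <- small_config(true_eqtl_p_scale = 1e-8)
  genome <- sim_genome(cfg)
  ann <- sim_annotations(cfg, genome)
  tab <- sim_eqtl_table(cfg, ann$truth)
  truth_keys <- with(ann$truth$true_eqtl_pairs,
                     paste(rsid, gene_id, tissue))
  is_true <- paste(tab$rsid, tab$gene_id, tab$tissue) %in% truth_keys
  expect_lt(stats::median(tab$p_nominal[is_true]), 1e-6)
  expect_true(all(tab$nes[is_true] != 0))

  # pooled null p-values over 10 seeds pass a KS uniformity check
  null_p <- unlist(lapply(1:10, function(s) {
    cfg_s <- small_config(seed = 300L + s)
    t_s <- sim_eqtl_table(cfg_s, ann$truth)
    null <- !(paste(t_s$rsid, t_s$gene_id, t_s$tissue) %in% truth_keys) &
      !(paste(t_s$rsid, t_s$gene_id) %in%
          with(ann$truth$true_pairs, paste(rsid, gene_id)))
    t_s$p_nominal[null]
  }))
  expect_gt(stats::ks.test(null_p, "punif")$p.value, 0.01)
})

test_that("the full pipeline recovers planted truth exactly when noise-free", {
  cfg <- small_config(background_interactions = 0L)
  run <- run_pipeline(cfg, min_egenes = 2)
  truth_keys <- with(run$sim$truth$true_eqtl_pairs,
                     paste(rsid, gene_id, tissue))
  sig_keys <- with(run$sig, paste(rsid, gene_id, tissue))
  expect_setequal(sig_keys, truth_keys)
})
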