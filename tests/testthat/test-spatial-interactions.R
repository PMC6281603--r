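contact_cartoon_setup <- function() {
  # one SNP fragment, a gene spanning two fragments; the first contact seen
  # once (CL1-R1), the second in CL1-R1, CL1-R2 and CL2-R1
  frags <- tibble::tibble(chrom = "chr1", start = c(0L, 100L, 200L, 300L),
                          end = c(100L, 200L, 300L, 400L), index = 0:3)
  snp_map <- tibble::tibble(rsid = "rs1", chrom = "chr1", pos = 50L,
                            fragment = 0L)
  gene_map <- tibble::tibble(gene_id = "g1", chrom = c("chr1", "chr1"),
                             fragment = c(2L, 3L))
  rec <- function(frag_b, cl, rep, n) tibble::tibble(
    read_name = paste0("r", n), strand1 = 0L, chrom1 = "chr1",
    pos1 = 10L, frag1 = 0L, strand2 = 0L, chrom2 = "chr1",
    pos2 = 250L, frag2 = frag_b, cell_line = cl, replicate = rep
  )
  ints <- dplyr::bind_rows(
    rec(2L, "CL1", "R1", 1),
    rec(3L, "CL1", "R1", 2),
    rec(3L, "CL1", "R2", 3),
    rec(3L, "CL2", "R1", 4)
  )
  list(frags = frags, snp_map = snp_map, gene_map = gene_map, ints = ints)
}

test_that("the worked contact-cartoon example gives 2 fragment and 4 supporting interactions", {
  s <- contact_cartoon_setup()
  pairs <- find_spatial_pairs(s$ints, s$snp_map, s$gene_map)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$fragment_interactions, 2L)
  expect_equal(pairs$supporting_interactions, 4L)
  expect_equal(pairs$n_cell_lines, 2L)
  expect_equal(pairs$n_replicates, 3L)
})

test_that("SNP fragments are detected symmetrically on either record end", {
  s <- contact_cartoon_setup()
  flipped <- s$ints %>%
    dplyr::rename(strand1 = strand2, chrom1 = chrom2, pos1 = pos2,
                  frag1 = frag2, strand2 = strand1, chrom2 = chrom1,
                  pos2 = pos1, frag2 = frag1)
  a <- find_spatial_pairs(s$ints, s$snp_map, s$gene_map)
  b <- find_spatial_pairs(flipped, s$snp_map, s$gene_map)
  expect_equal(
    dplyr::select(a, -dplyr::any_of("observations")),
    dplyr::select(b, -dplyr::any_of("observations")),
    ignore_attr = TRUE
  )
})

test_that("partner fragments overlapping no gene yield no pair", {
  s <- contact_cartoon_setup()
  empty_gene_map <- tibble::tibble(gene_id = character(),
                                   chrom = character(), fragment = integer())
  pairs <- find_spatial_pairs(s$ints, s$snp_map, empty_gene_map)
  expect_equal(nrow(pairs), 0L)
})

test_that("the interaction parser enforces the 9-column dialect", {
  path <- tempfile()
  writeLines(c("r1 0 chr1 10 0 16 chr2 20 3"), path)
  rec <- read_interactions(path, "CL1", "R1")
  expect_equal(rec$read_name, "r1")
  expect_equal(rec$frag2, 3L)
  expect_equal(rec$cell_line, "CL1")

  writeLines(c("r1 0 chr1 10 0 16 chr2 20"), path)
  expect_error(read_interactions(path, "CL1", "R1"), "line 1")

  writeLines(c("r1 0 chr1 10 0 16 chr9 20 3"), path)
  expect_error(read_interactions(path, "CL1", "R1",
                                 chromosomes = c("chr1", "chr2")),
               "chr9")
})

test_that("emitted synthetic files round-trip through the parser", {
  sim <- sim_dataset(small_config(), dir = tempfile())
  ints <- read_interaction_set(sim$interaction_files,
                               chromosomes = paste0("chr", 1:2))
  raw_lines <- sum(vapply(sim$interaction_files$file,
                          function(f) length(readLines(f)), integer(1)))
  expect_equal(nrow(ints), raw_lines)
  # re-emitting parsed rows reproduces the file byte for byte
  f1 <- sim$interaction_files$file[1]
  sub <- read_interactions(f1, "x", "y")
  re_emitted <- sprintf("%s %d %s %d %d %d %s %d %d",
                        sub$read_name, sub$strand1, sub$chrom1, sub$pos1,
                        sub$frag1, sub$strand2, sub$chrom2, sub$pos2,
                        sub$frag2)
  expect_identical(re_emitted, readLines(f1))
})

test_that("supporting-interaction totals match brute-force triple enumeration", {
  set.seed(403)
  for (i in 1:10) {
    frags <- tibble::tibble(
      chrom = rep(c("chr1", "chr2"), each = 5),
      start = rep(seq(0L, 400L, 100L), 2),
      end = rep(seq(100L, 500L, 100L), 2),
      index = rep(0:4, 2)
    )
    snp_map <- tibble::tibble(
      rsid = paste0("rs", 1:3),
      chrom = sample(c("chr1", "chr2"), 3, replace = TRUE),
      fragment = sample(0:4, 3, replace = TRUE)
    )
    gene_map <- tibble::tibble(
      gene_id = sample(paste0("g", 1:3), 6, replace = TRUE),
      chrom = sample(c("chr1", "chr2"), 6, replace = TRUE),
      fragment = sample(0:4, 6, replace = TRUE)
    ) %>% dplyr::distinct()
    ints <- tibble::tibble(
      read_name = paste0("r", 1:30),
      strand1 = 0L,
      chrom1 = sample(c("chr1", "chr2"), 30, replace = TRUE),
      pos1 = 1L, frag1 = sample(0:4, 30, replace = TRUE),
      strand2 = 16L,
      chrom2 = sample(c("chr1", "chr2"), 30, replace = TRUE),
      pos2 = 1L, frag2 = sample(0:4, 30, replace = TRUE),
      cell_line = sample(c("CL1", "CL2"), 30, replace = TRUE),
      replicate = "R1"
    )
    pairs <- find_spatial_pairs(ints, snp_map, gene_map)
    expect_equal(sum(pairs$supporting_interactions),
                 brute_support_total(ints, snp_map, gene_map))
    # provenance counts recomputable from the observations
    obs <- spatial_observations(pairs)
    recount <- obs %>%
      dplyr::group_by(rsid, gene_id) %>%
      dplyr::summarise(ncl = dplyr::n_distinct(cell_line),
                       nrep = dplyr::n_distinct(paste(cell_line, replicate)),
                       .groups = "drop") %>%
      dplyr::arrange(rsid, gene_id)
    expect_equal(pairs$n_cell_lines, recount$ncl)
    expect_equal(pairs$n_replicates, recount$nrep)
    expect_true(all(pairs$fragment_interactions <=
                      pairs$supporting_interactions))
  }
})

test_that("pooled two-proportion Z statistic matches the closed form", {
  pairs <- tibble::tibble(
    supporting_interactions = rep(c(2L, 1L), each = 100)
  )
  sig <- c(rep(TRUE, 50), rep(FALSE, 50), rep(TRUE, 30), rep(FALSE, 70))
  got <- support_enrichment_test(pairs, sig)
  expect_equal(got$z, two_prop_z(50, 100, 30, 100), tolerance = 1e-12)
  expect_equal(got$z, 2.886751, tolerance = 1e-5)
  expect_equal(got$p_value, 0.0038924, tolerance = 1e-4)

  sig45 <- c(rep(TRUE, 40), rep(FALSE, 60), rep(TRUE, 10), rep(FALSE, 90))
  expect_equal(support_enrichment_test(pairs, sig45)$z, 4.89898,
               tolerance = 1e-5)

  same <- c(rep(TRUE, 30), rep(FALSE, 70), rep(TRUE, 30), rep(FALSE, 70))
  got_same <- support_enrichment_test(pairs, same)
  expect_equal(got_same$z, 0)
  expect_equal(got_same$p_value, 1)

  only_multi <- tibble::tibble(supporting_interactions = c(2L, 3L))
  expect_error(support_enrichment_test(only_multi, c(TRUE, FALSE)),
               "partition")
})
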