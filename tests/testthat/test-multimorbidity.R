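toy_gwas <- tibble::tibble(
  rsid = c("s1", "s1", "s2", "s3", "s4"),
  trait = c("X", "Y", "X", "Z", "X"),
  study = c("S1", "S1", "S2", "S2", "S3"),
  chrom = "chr1", pos = 1:5 * 100L, gwas_p = 1e-8
)

toy_assoc <- tibble::tibble(
  rsid = c("s1", "s2", "s3", "s4"),
  gene_id = c("g1", "g2", "g3", "g2")
)

test_that("composite phenotypes form from multi-trait single-study SNPs", {
  sets <- build_phenotype_sets(toy_gwas, toy_assoc)
  expect_setequal(sets$phenotype, c("X|Y", "X", "Z"))
  expect_equal(sets$egenes[[match("X|Y", sets$phenotype)]], "g1")
  # same trait from two studies merges into one phenotype
  expect_setequal(sets$egenes[[match("X", sets$phenotype)]], "g2")
  expect_equal(sets$eqtls[[match("X", sets$phenotype)]], c("s2", "s4"))
  expect_error(
    build_phenotype_sets(toy_gwas,
                         tibble::tibble(rsid = "s9", gene_id = "g1")),
    "s9"
  )
})

test_that("sharing ratios follow the asymmetric common-gene formula", {
  sets <- tibble::tibble(
    phenotype = c("A", "B"),
    egenes = list(paste0("g", 1:4), paste0("g", 3:5)),
    eqtls = list("s1", "s2"),
    n_egenes = c(4L, 3L), n_eqtls = c(1L, 1L)
  )
  M <- share_matrix(sets)
  expect_equal(M["A", "B"], 0.5)
  expect_equal(M["B", "A"], 2 / 3)
  expect_equal(diag(unclass(M)), c(A = 1, B = 1))

  disjoint <- dplyr::mutate(sets, egenes = list(c("g1"), c("g2")))
  expect_true(all(unclass(share_matrix(disjoint))[upper.tri(diag(2))] == 0))

  same <- dplyr::mutate(sets, egenes = list(c("g1", "g2"), c("g1", "g2")))
  expect_true(all(unclass(share_matrix(same)) == 1))

  empty <- dplyr::mutate(sets, egenes = list(character(), "g1"))
  expect_error(share_matrix(empty), "empty")
  expect_error(share_matrix(sets[1, ]), "two phenotypes")
})

test_that("sharing-matrix algebra holds on random sets", {
  set.seed(405)
  for (i in 1:20) {
    p <- sample(3:8, 1)
    pool <- paste0("g", 1:30)
    sets <- tibble::tibble(
      phenotype = paste0("P", seq_len(p)),
      egenes = purrr::map(seq_len(p),
                          ~ sample(pool, sample(2:20, 1))),
      eqtls = purrr::map(seq_len(p), ~ "s1")
    )
    M <- unclass(share_matrix(sets))
    n <- lengths(sets$egenes)
    expect_equal(unname(diag(M)), rep(1, p))
    expect_true(all(M >= 0 & M <= 1))
    for (a in seq_len(p)) {
      for (b in seq_len(p)) {
        common <- M[a, b] * n[a]
        expect_equal(common, round(common), tolerance = 1e-9)
        expect_equal(common, M[b, a] * n[b], tolerance = 1e-9)
        expect_equal(common,
                     length(intersect(sets$egenes[[a]], sets$egenes[[b]])),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("the eGene-count filter keeps phenotypes at the threshold rule", {
  sets <- tibble::tibble(
    phenotype = c("A", "B", "C"),
    n_egenes = c(4L, 3L, 10L)
  )
  expect_equal(filter_min_egenes(sets)$phenotype, c("A", "C"))
  expect_warning(filter_min_egenes(sets, min_count = 99), "no phenotype")
  expect_equal(nrow(filter_min_egenes(sets, min_count = 0)), 3L)
})

test_that("null reassignment preserves per-phenotype counts and the mean law", {
  sets <- tibble::tibble(
    phenotype = c("A", "B"),
    egenes = list(paste0("g", 1:4), paste0("g", 5:9)),
    eqtls = list("s1", "s2")
  )
  # pool N = 9 united genes; expected null ratio a_AB = n_B / N = 5/9
  M0 <- null_mean_matrix(sets, n_null = 1000, seed = 7)
  expect_equal(unname(diag(unclass(M0))), c(1, 1))
  n_a <- 4; n_b <- 5; N <- 9
  exp_ratio <- n_b / N
  var_common <- n_a * (n_b / N) * (1 - n_b / N) * (N - n_a) / (N - 1)
  mc_sigma <- sqrt(var_common / n_a^2) / sqrt(1000)
  expect_lt(abs(M0["A", "B"] - exp_ratio), 3 * mc_sigma)

  # determinism given seed
  expect_equal(unclass(null_mean_matrix(sets, n_null = 50, seed = 11)),
               unclass(null_mean_matrix(sets, n_null = 50, seed = 11)))
  # every replicate preserves the per-phenotype set sizes exactly
  draws <- multimorbid:::draw_null_sets(lengths(sets$egenes), 9)
  expect_equal(lengths(draws), c(4L, 5L))
  expect_true(all(unlist(draws) %in% 1:9))
  expect_false(anyDuplicated(draws[[2]]) > 0)
})

test_that("planted clusters share more than the permutation null", {
  run <- default_pipeline()
  M <- unclass(run$M)
  M0 <- unclass(null_mean_matrix(run$sets, n_null = 200, seed = 3))
  planted <- run$sim$truth$phenotype_to_cluster[rownames(M)]
  within <- outer(planted, planted, "==") & upper.tri(M)
  expect_gt(mean(M[within]), mean(M0[within]))
  expect_gt(mean(M[within]), mean(M[!within & upper.tri(M)]))
})

test_that("commonality index is the fraction of member phenotypes with the gene", {
  sets <- tibble::tibble(
    phenotype = paste0("P", 1:40),
    egenes = c(purrr::map(1:26, ~ c("gCore", paste0("g", .x))),
               purrr::map(27:40, ~ paste0("g", .x)))
  )
  ci <- commonality_index(sets, paste0("P", 1:40))
  expect_equal(ci$commonality[ci$gene_id == "gCore"], 0.65)
  expect_equal(max(ci$commonality[ci$gene_id != "gCore"]), 1 / 40)
  # a gene carried by every member scores 1; absent genes are omitted
  all_in <- commonality_index(sets[1:26, ], paste0("P", 1:26))
  expect_equal(all_in$commonality[all_in$gene_id == "gCore"], 1)
  expect_false("gAbsent" %in% ci$gene_id)
  expect_error(commonality_index(sets, character()), "no members")
})

test_that("OMIM summaries report annotation fraction and method mix", {
  omim <- tibble::tibble(
    gene_id = c("g1", "g3"), phenotype = c("ph1", "ph2"),
    method_code = c(3L, 2L)
  )
  got <- omim_summary(c("g1", "g3", "g5"), omim)
  expect_equal(got$fraction_annotated, 2 / 3)
  expect_equal(got$method_distribution$proportion, c(0.5, 0.5))
  expect_setequal(got$method_distribution$method_code, c(2L, 3L))

  expect_equal(omim_summary("g9", omim)$fraction_annotated, 0)

  all3 <- tibble::tibble(gene_id = c("g1", "g2"), phenotype = "p",
                         method_code = 3L)
  expect_equal(omim_summary(c("g1", "g2"), all3)$method_distribution$proportion,
               1)
  bad <- dplyr::mutate(omim, method_code = c(3L, 7L))
  expect_error(omim_summary("g1", bad), "1..4")
})
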