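make_asvs <- function(identity, abundance) {
  tibble::tibble(
    asv_id = paste0("asv", seq_along(identity)),
    sequence = paste0("S", seq_along(identity)),
    count = as.integer(round(abundance * 1e6)),
    relative_abundance = abundance,
    identity = identity,
    exact_match = identity == 1
  )
}

test_that("the three quality filters fire at their stated thresholds", {
  asvs <- make_asvs(
    identity  = c(0.915, 0.987, 0.995, 0.995, 1.0, 0.999, 0.93),
    abundance = c(0.05, 5e-5, 5e-5, 5e-6, 5e-6, 0.01, 0.001)
  )
  kept <- apply_quality_filters(asvs)
  # rule 1 removes idx 1; rule 2 removes idx 2 (keeps idx 3); rule 3 removes
  # idx 4 (keeps idx 5); idx 6 and 7 survive every rule
  expect_setequal(kept$asv_id, c("asv3", "asv5", "asv6", "asv7"))
  removed <- attr(kept, "filtered_out")
  expect_setequal(removed$asv_id, c("asv1", "asv2", "asv4"))
})

test_that("filters are monotone in identity and abundance", {
  set.seed(41)
  for (trial in 1:200) {
    ident <- runif(1, 0.85, 1)
    ab <- 10^runif(1, -7, -1)
    base_kept <- nrow(apply_quality_filters(make_asvs(ident, ab))) == 1
    worse <- nrow(apply_quality_filters(
      make_asvs(ident - runif(1, 0, 0.05), ab * runif(1, 0.1, 1)))) == 1
    # lowering identity and abundance can never turn "removed" into "kept"
    if (!base_kept) expect_false(worse)
  }
})

test_that("precision/recall accounting matches exact-match counting", {
  truth <- ground_truth(c("A1", "B2", "C3"), c(0.5, 0.3, 0.2))
  filtered <- tibble::tibble(
    sequence = c("A1", "B2", "X9"),
    relative_abundance = c(0.5, 0.3, 0.2),
    identity = c(1, 1, 0.99),
    exact_match = c(TRUE, TRUE, FALSE)
  )
  rep <- score_asvs(filtered, truth)
  expect_equal(rep$true_positives, 2L)
  expect_equal(rep$false_positives, 1L)
  expect_equal(rep$precision, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(rep$recall, 100 * 2 / 3, tolerance = 1e-12)

  empty <- score_asvs(filtered[0, ], truth)
  expect_equal(empty$precision, 0)
  expect_equal(empty$recall, 0)
  expect_true(empty$empty_result)
})

test_that("Bhattacharyya coefficient matches closed forms and invariances", {
  p <- c(0.2, 0.5, 0.3)
  expect_equal(bhattacharyya(p, p), 1)
  expect_equal(bhattacharyya(c(1, 0), c(0, 1)), 0)
  expect_equal(bhattacharyya(c(0.9, 0.1), c(0.1, 0.9)), 0.6)
  # symmetry and rescaling invariance
  q <- c(0.6, 0.1, 0.3)
  expect_equal(bhattacharyya(p, q), bhattacharyya(q, p))
  expect_equal(bhattacharyya(p * 7, q * 130), bhattacharyya(p, q))
  expect_error(bhattacharyya(c(0, 0), c(1, 1)), "all-zero")

  # BC = 1 iff normalized vectors coincide
  expect_lt(bhattacharyya(c(0.5, 0.5), c(0.49, 0.51)), 1)
})

test_that("truth/ASV matching covers the union of supports", {
  truth <- ground_truth(c("AA", "CC"), c(0.7, 0.3))
  asvs <- tibble::tibble(sequence = c("AA", "GG"),
                         relative_abundance = c(0.5, 0.5))
  # shared support only on AA: BC = sqrt(.7*.5)
  expect_equal(bhattacharyya_tables(truth, asvs), sqrt(0.35))
})

test_that("ground truth validates fractions and round-trips TSV", {
  expect_error(ground_truth(c("A", "B"), c(0.5, 0.4)), "sum to 1")
  expect_error(ground_truth(c("A", "A"), c(0.5, 0.5)), "distinct")
  truth <- ground_truth(c("ACGT", "AGGT"), c(0.9, 0.1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(truth, path)
  expect_equal(read_ground_truth(path), truth)
})

test_that("phenotype projection normalizes, logs and projects to 3 PCs", {
  set.seed(42)
  base <- matrix(rpois(6 * 20, 40), 6, 20)
  counts <- rbind(base, base[1, ])  # duplicate sample 1 as sample 7
  rownames(counts) <- paste0("s", 1:7)
  proj <- phenotype_project(counts)
  expect_equal(names(proj), c("sample", "PC1", "PC2", "PC3"))
  # identical samples land on identical coordinates
  expect_equal(unlist(proj[7, -1]), unlist(proj[1, -1]), tolerance = 1e-10)
  # components are orthogonal
  rot <- attr(proj, "rotation")
  expect_equal(unname(crossprod(rot)), diag(3), tolerance = 1e-10)
  # doubling all counts of one sample only changes it through the trimmed-mean
  # scale factor: its normalized profile, hence its projection, is unchanged
  counts2 <- counts
  counts2[3, ] <- counts2[3, ] * 2L
  proj2 <- phenotype_project(counts2)
  expect_equal(unlist(proj2[3, -1]), unlist(proj[3, -1]), tolerance = 1e-8)

  expect_error(phenotype_project(counts[1:3, ]), "at least 4")
  expect_error(phenotype_project(-counts), "non-negative")
})
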