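test_that("reference generation is deterministic and respects the zero-divergence limit", {
  same1 <- generate_reference(20, length = 50, divergence = 3, seed = 5)
  same2 <- generate_reference(20, length = 50, divergence = 3, seed = 5)
  expect_identical(same1, same2)
  other <- generate_reference(20, length = 50, divergence = 3, seed = 6)
  expect_false(identical(same1$aligned_seq, other$aligned_seq))

  frozen <- generate_reference(10, length = 50, divergence = 0, seed = 1)
  expect_equal(length(unique(frozen$aligned_seq)), 1L)
  D <- reference_distance_matrix(frozen)
  expect_true(all(D == 0))
})

test_that("sibling leaves differ by about twice the edge divergence", {
  # with n_seqs = 2 the two leaves are siblings: D ~ sum of two Poisson edges
  div <- 2
  len <- 400  # long frame keeps same-column collisions negligible
  dists <- vapply(1:100, function(s) {
    ref <- generate_reference(2, length = len, divergence = div, seed = s)
    pairwise_distance(ref$aligned_seq[1], ref$aligned_seq[2])
  }, numeric(1))
  expected <- 2 * div
  se <- sqrt(2 * div / 100)
  expect_lt(abs(mean(dists) - expected), 3 * se + 0.1)
})

test_that("mock-community design spaces abundances and separates members", {
  ref <- generate_reference(150, length = 100, divergence = 3, seed = 2)
  mock <- design_mock_community(ref, n_variants = 10, min_edit_sep = 3,
                                seed = 3)
  expect_equal(nrow(mock), 10L)
  expect_equal(sum(mock$true_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(mock$true_fraction) <= 0))
  ed <- utils::adist(mock$sequence)
  expect_true(all(ed[upper.tri(ed)] >= 3))
  # spans orders of magnitude
  expect_gt(mock$true_fraction[1] / mock$true_fraction[10], 100)
})

test_that("error-free reads equal their source variants", {
  ref <- generate_reference(80, length = 60, divergence = 4, seed = 7)
  mock <- design_mock_community(ref, n_variants = 5, seed = 1)
  spec <- mock_community_spec(mock, total_reads = 2000, per_base_error = 0,
                              seed = 4)
  sim <- generate_mock_reads(spec)
  expect_true(all(sim$reads$reads %in% mock$sequence))
  expect_equal(sim$truth$expected_fraction, mock$true_fraction)
})

test_that("per-variant read counts are multinomial-consistent", {
  variants <- tibble::tibble(
    sequence = c(strrep("A", 100), strrep("C", 100), strrep("G", 100)),
    true_fraction = c(0.3, 0.5, 0.2)
  )
  spec <- mock_community_spec(variants, total_reads = 1000,
                              per_base_error = 0, seed = 11)
  sim <- generate_mock_reads(spec)
  n1 <- sum(sim$reads$reads == variants$sequence[1])
  # Binomial(1000, 0.3): 3 standard deviations
  expect_lt(abs(n1 - 300), 3 * sqrt(1000 * 0.3 * 0.7))
})

test_that("the fraction of error-bearing reads matches the closed form", {
  e <- 0.002
  len <- 250
  variants <- tibble::tibble(
    sequence = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    true_fraction = 1
  )
  spec <- mock_community_spec(variants, total_reads = 20000,
                              per_base_error = e, seed = 12)
  sim <- generate_mock_reads(spec)
  frac_err <- mean(sim$reads$reads != variants$sequence)
  expected <- 1 - (1 - e)^len   # ~ 0.394
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(frac_err - expected), 3 * se)
})

test_that("simulation is reproducible under a fixed seed", {
  ref <- generate_reference(60, length = 50, divergence = 4, seed = 9)
  mock <- design_mock_community(ref, n_variants = 4, seed = 2)
  spec <- mock_community_spec(mock, total_reads = 500, per_base_error = 0.01,
                              seed = 8)
  expect_identical(generate_mock_reads(spec)$reads$reads,
                   generate_mock_reads(spec)$reads$reads)
})

test_that("contaminants are carried with intended = FALSE", {
  ref <- generate_reference(120, length = 80, divergence = 4, seed = 13)
  mock <- design_mock_community(ref, n_variants = 5, n_contaminants = 2,
                                seed = 5)
  expect_equal(sum(!mock$intended), 2L)
  expect_equal(sum(mock$true_fraction), 1, tolerance = 1e-12)
  spec <- mock_community_spec(mock[mock$intended, ],
                              contaminants = mock[!mock$intended, ],
                              total_reads = 100, per_base_error = 0, seed = 1)
  sim <- generate_mock_reads(spec)
  expect_equal(sum(sim$truth$intended), 5L)
  expect_equal(sum(sim$truth$expected_fraction[sim$truth$intended]), 1,
               tolerance = 1e-12)
})
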