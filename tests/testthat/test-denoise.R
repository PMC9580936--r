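make_latent_tbl <- function(counts, latent) {
  tbl <- tibble::tibble(
    sequence = paste0("SEQ", seq_along(counts)),
    count = as.integer(counts)
  )
  tbl$latent <- latent
  tbl[order(-tbl$count), ]
}

test_that("candidate parents respect radius, fold and neighbor cap", {
  # child count 10 at origin; neighbors at controlled distances/counts
  latent <- rbind(c(5, 0), c(5, 0.1), c(16, 0), c(0, 0))
  tbl <- make_latent_tbl(c(200, 150, 400, 10), latent)
  params <- denoise_params(max_neighbors = 20, latent_radius = 15,
                           min_fold = 20)
  cands <- find_parent_candidates(tbl, params)
  child <- which(tbl$count == 10)
  got <- cands[[child]]
  # count 200 at distance 5: eligible; count 150 fails the 20-fold rule;
  # count 400 at distance 16 is outside the radius
  expect_equal(tbl$count[got$index], 200L)
  expect_equal(got$latent_dist, 5)

  # neighbor cap: nearest max_neighbors only
  latent2 <- cbind(c(0, seq_len(25)), 0)
  tbl2 <- make_latent_tbl(c(10, rep(500, 25)), latent2)
  small <- find_parent_candidates(tbl2, denoise_params(max_neighbors = 5,
                                                       latent_radius = 15,
                                                       min_fold = 20))
  child2 <- which(tbl2$count == 10)
  expect_equal(nrow(small[[child2]]), 5L)
  expect_equal(small[[child2]]$latent_dist, 1:5)
})

test_that("prefix scan equals a naive brute-force candidate search", {
  params <- denoise_params()
  for (trial in 1:25) {
    set.seed(trial)
    n <- sample(20:120, 1)
    counts <- sort(stats::rpois(n, 50) * sample(c(1L, 40L), n, TRUE) + 2L,
                   decreasing = TRUE)
    latent <- matrix(rnorm(n * 10, sd = 8), n, 10)
    tbl <- make_latent_tbl(counts, latent)
    fast <- find_parent_candidates(tbl, params)
    for (s in seq_len(n)) {
      d <- sqrt(colSums((t(tbl$latent) - tbl$latent[s, ])^2))
      elig <- which(tbl$count >= params$min_fold * tbl$count[s] &
                      d <= params$latent_radius & seq_len(n) != s)
      elig <- elig[order(d[elig])]
      elig <- elig[seq_len(min(length(elig), params$max_neighbors))]
      expect_equal(fast[[s]]$index, elig)
    }
  }
})

test_that("edit-distance confirmation applies the per-base threshold", {
  set.seed(77)
  base <- paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = "")
  with3 <- mutate_seq(base, 3)
  with4 <- mutate_seq(base, 4)
  params <- denoise_params()
  conf <- confirm_by_edit_distance(base, c(with3, with4, base), params)
  # 3/250 = 0.0120 <= 1/64; 4/250 = 0.0160 > 1/64; identical always kept
  expect_equal(conf$edit_distance[3], 0L)
  expect_equal(conf$keep, c(TRUE, FALSE, TRUE))
  expect_equal(conf$error_rate[1], 3 / 250)
  expect_equal(conf$error_rate[2], 4 / 250)
})

test_that("alignment path length includes insertions", {
  # "ACGT" vs "ACGGT": one insertion, path length 5
  conf <- confirm_by_edit_distance("ACGT", "ACGGT", denoise_params())
  expect_equal(conf$edit_distance, 1L)
  expect_equal(conf$align_length, 5L)
})

test_that("parent selection prefers distance, then abundance, then stability", {
  expect_equal(select_parent(tibble::tibble(index = c(7L, 9L),
                                            edit_distance = c(2L, 1L),
                                            count = c(500L, 100L))), 9L)
  expect_equal(select_parent(tibble::tibble(index = c(7L, 9L),
                                            edit_distance = c(1L, 1L),
                                            count = c(100L, 900L))), 9L)
  expect_equal(select_parent(tibble::tibble(index = c(7L, 9L),
                                            edit_distance = c(1L, 1L),
                                            count = c(100L, 100L))), 7L)
  expect_true(is.na(select_parent(tibble::tibble(index = integer(0),
                                                 edit_distance = integer(0),
                                                 count = integer(0)))))
})

test_that("ASV resolution follows chains and conserves abundance", {
  tbl <- tibble::tibble(
    sequence = c("AAA", "CCC", "GGG"),
    count = c(10000L, 200L, 5L)
  )
  links <- tibble::tibble(child = c(3L, 2L), parent = c(2L, 1L),
                          edit_distance = c(1L, 1L))
  asvs <- resolve_asvs(tbl, links)
  expect_equal(nrow(asvs), 1L)
  expect_equal(asvs$count, 10205L)
  expect_equal(sort(asvs$members[[1]]), 1:3)

  # no links: every row is its own ASV
  none <- resolve_asvs(tbl, tibble::tibble(child = integer(0),
                                           parent = integer(0),
                                           edit_distance = integer(0)))
  expect_equal(nrow(none), 3L)
  expect_equal(sum(none$count), sum(tbl$count))

  # two disjoint subtrees conserve the total
  links2 <- tibble::tibble(child = 3L, parent = 2L, edit_distance = 1L)
  two <- resolve_asvs(tbl, links2)
  expect_equal(nrow(two), 2L)
  expect_equal(sum(two$count), sum(tbl$count))

  cyc <- tibble::tibble(child = c(1L, 2L), parent = c(2L, 1L),
                        edit_distance = c(1L, 1L))
  expect_error(resolve_asvs(tbl, cyc), "cycle")
})

test_that("abundance conservation holds on randomized link forests", {
  for (trial in 1:100) {
    set.seed(1000 + trial)
    n <- sample(3:40, 1)
    tbl <- tibble::tibble(
      sequence = paste0("S", seq_len(n)),
      count = sort(sample(2:10000, n), decreasing = TRUE)
    )
    # random forest edges: child -> strictly earlier (more abundant) row
    children <- which(seq_len(n) > 1 & stats::runif(n) < 0.6)
    links <- tibble::tibble(
      child = children,
      parent = vapply(children, function(s) sample.int(s - 1L, 1L), integer(1)),
      edit_distance = 1L
    )
    asvs <- resolve_asvs(tbl, links)
    expect_identical(sum(asvs$count), sum(tbl$count))
    expect_identical(sort(unlist(asvs$members)), seq_len(n))
  }
})

test_that("ASV annotation reports nearest reference, identity and taxonomy", {
  set.seed(31)
  seqs <- c(paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = ""),
            paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = ""))
  ref <- aligned_ref(c("refA", "refB"), seqs,
                     taxonomy = c("Bacteria;X", "Bacteria;Y"))
  space <- structure(
    list(coords = matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE,
                         dimnames = list(ref$id, NULL))),
    class = "latent_space"
  )
  one_off <- mutate_seq(seqs[2], 1)
  asvs <- tibble::tibble(
    asv_id = c("asv1", "asv2"),
    sequence = c(seqs[1], one_off),
    count = c(100L, 50L),
    relative_abundance = c(2 / 3, 1 / 3)
  )
  asvs$latent <- matrix(c(0.1, 0, 9.8, 10.1), 2, 2, byrow = TRUE)
  out <- annotate_asvs(asvs, ref, space)
  expect_equal(out$nearest_reference, c("refA", "refB"))
  expect_equal(out$identity, c(1, 249 / 250))
  expect_equal(out$exact_match, c(TRUE, FALSE))
  expect_equal(out$taxonomy, c("Bacteria;X", "Bacteria;Y"))
})

test_that("external chimera flags remove rows without touching counts", {
  asvs <- tibble::tibble(
    asv_id = paste0("asv", 1:5),
    sequence = paste0("S", 1:5),
    count = c(50L, 40L, 30L, 20L, 10L),
    relative_abundance = c(50, 40, 30, 20, 10) / 150
  )
  class(asvs) <- c("asv_tbl", class(asvs))
  expect_equal(nrow(remove_chimeras_external(asvs, character(0))), 5L)
  out <- remove_chimeras_external(asvs, "asv3")
  expect_equal(nrow(out), 4L)
  expect_equal(out$count, c(50L, 40L, 20L, 10L))
  expect_warning(remove_chimeras_external(asvs, "nope"), "unknown")
})
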