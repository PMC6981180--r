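# Clonotype sharing: pairwise fractions, Venn regions, pool overlap,
# shared/unshared contrasts, CDR3 logos.

test_that("pairwise sharing fractions under all three normalizations", {
  s <- pairwise_sharing(c("x", "y", "z"), c("z", "w"))
  expect_equal(s$fractions$union, 1 / 4)
  expect_equal(s$fractions$mean, 2 / 5)
  expect_equal(unname(s$fractions$per_set), c(1 / 3, 1 / 2))
  same <- pairwise_sharing(c("a", "b"), c("a", "b"))
  expect_equal(same$fractions$union, 1)
  disj <- pairwise_sharing(c("a"), c("b"))
  expect_equal(disj$fractions$union, 0)
  expect_equal(disj$fractions$mean, 0)
  expect_error(pairwise_sharing(character(0), "a"), "empty")
})

test_that("sharing is symmetric in union and mean modes and ignores duplicates", {
  a <- c("a", "b", "c", "c"); b <- c("b", "d")
  ab <- pairwise_sharing(a, b); ba <- pairwise_sharing(b, a)
  expect_equal(ab$fractions$union, ba$fractions$union)
  expect_equal(ab$fractions$mean, ba$fractions$mean)
  expect_equal(ab$set_sizes[["a"]], 3)  # set semantics
})

test_that("multiway Venn regions match brute-force enumeration on random sets", {
  set.seed(8)
  for (i in 1:10) {
    sets <- lapply(1:3, function(j) sample(sprintf("k%03d", 1:100), sample(20:60, 1)))
    names(sets) <- c("A", "B", "C")
    mw <- multiway_sharing(sets)
    # brute force: classify every key of the union by its membership pattern
    all_keys <- unique(unlist(sets))
    pat <- vapply(all_keys, function(k) {
      paste(names(sets)[vapply(sets, function(s) k %in% s, logical(1))],
            collapse = "&")
    }, character(1))
    brute <- table(pat)
    expect_equal(sum(mw$regions$size), length(all_keys))
    for (r in seq_len(nrow(mw$regions))) {
      expect_equal(mw$regions$size[r],
                   unname(brute[[mw$regions$pattern[r]]]))
    }
    expect_equal(mw$all_shared_fraction,
                 length(Reduce(intersect, sets)) / length(all_keys))
  }
})

test_that("degenerate multiway cases: identical sets and no triple overlap", {
  same <- multiway_sharing(list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y")))
  expect_equal(same$all_shared_fraction, 1)
  none <- multiway_sharing(list(A = c("x", "y"), B = c("y", "z"), C = c("z", "x")))
  expect_equal(none$all_shared_fraction, 0)
})

test_that("pool overlap fractions per subject and combined", {
  q <- list(S1 = c("a", "b"), S2 = c("b", "c"))
  expect_equal(pool_overlap(q, c("a", "b", "c", "d"))$fraction_in_pool,
               c(1, 1, 1))
  expect_equal(pool_overlap(q, c("zzz"))$fraction_in_pool, c(0, 0, 0))
  po <- pool_overlap(q, c("a", "c"))
  expect_equal(po$fraction_in_pool[po$subject == "combined"], 2 / 3)
  expect_error(pool_overlap(list(S1 = character(0)), "a"), "empty query")
  expect_error(pool_overlap(q, character(0)), "empty pool")
})

test_that("clonotypes from the same preset share more than across presets", {
  sets <- lapply(c(or1 = 71, or2 = 72, hu1 = 73), function(s) {
    cfg <- simulator_config(if (s < 73) "omnirat_like" else "human_like",
                            n_clones = 3000, n_reads_per_compartment = 6000,
                            shm_rate_igm = 0, shm_rate_igg = 0, seed = s)
    sim <- simulate_repertoire(cfg)
    unique(c(assign_clonotypes(sim$lymph_node)$key,
             assign_clonotypes(sim$spleen)$key))
  })
  intra <- pairwise_sharing(sets$or1, sets$or2)$fractions$union
  inter <- pairwise_sharing(sets$or1, sets$hu1)$fractions$union
  expect_gt(intra, inter)
})

test_that("planted shorter shared CDRH3s are recovered by the shared/unshared contrast", {
  mk <- function(lens, tag) {
    tibble::tibble(
      key = sprintf("%s%03d", tag, seq_along(lens)),
      v_gene = "IGHV1-2", j_gene = "IGHJ4",
      cdr3_aa = vapply(lens, function(L) strrep("A", L), character(1)),
      cdr3_length = lens, n_reads = 1L
    )
  }
  shared <- mk(rep(c(8, 9, 10), 20), "s")
  unshared <- mk(rep(c(13, 14, 15), 20), "u")
  animal <- dplyr::bind_rows(shared, unshared)
  pool <- shared$key
  cmp <- compare_shared_unshared(animal, pool)
  expect_equal(cmp$n_shared, 60)
  expect_lt(cmp$shared$mean_length, cmp$unshared$mean_length)
  expect_equal(sum(cmp$shared$length_table$frequency), 1, tolerance = 1e-9)
  expect_equal(sum(cmp$unshared$v_family$frequency), 1, tolerance = 1e-9)
  # pool covering everything leaves the unshared side empty with a warning
  expect_warning(all_in <- compare_shared_unshared(animal, animal$key), "empty")
  expect_null(all_in$unshared)
})

test_that("CDR3 logos are column-normalized with category partition and torso flags", {
  ct <- tibble::tibble(
    key = c("k1", "k2"), v_gene = "IGHV1-2", j_gene = "IGHJ4",
    cdr3_aa = c("ARDYSTAG", "GRDYSTAG"), cdr3_length = 8L, n_reads = 1L
  )
  logo <- cdr3_logo(ct, 8)
  expect_equal(unname(colSums(logo$pfm)), rep(1, 8), tolerance = 1e-12)
  expect_equal(unname(logo$pfm["A", 1]), 0.5)
  expect_equal(unname(logo$pfm["G", 1]), 0.5)
  expect_equal(max(logo$pfm[, 2]), 1)  # one-hot beyond position 1
  expect_equal(sort(unique(unname(logo$categories))),
               c("acidic", "basic", "hydrophobic", "polar"))
  expect_equal(sum(lengths(split(names(logo$categories), logo$categories))), 20)
  expect_equal(logo$torso, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_error(cdr3_logo(ct, 13), "length 13")
  one <- cdr3_logo(ct[1, ], 8)
  expect_true(all(apply(one$pfm, 2, max) == 1))  # one-hot columns
})
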