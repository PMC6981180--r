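# CDR3/junction statistics: length distributions, tails, family co-usage,
# isotype and mutation summaries.

test_that("length distributions are normalized with consistent means", {
  rep12 <- hand_repertoire(rep(paste0("C", strrep("A", 12), "W"), 5))
  d <- length_distribution(rep12, "cdr3_length")
  expect_equal(d$table$frequency[d$table$value == 12], 1)
  expect_equal(d$mean, 12)
  mixed <- hand_repertoire(c(paste0("C", strrep("A", 10), "W"),
                             paste0("C", strrep("A", 14), "W")))
  d2 <- length_distribution(mixed, "cdr3_length")
  expect_equal(d2$mean, 12)
  expect_equal(sum(d2$table$frequency), 1, tolerance = 1e-9)
  expect_equal(sum(d2$table$frequency * d2$table$value), d2$mean, tolerance = 1e-9)
})

test_that("a point-mass insertion model yields a point-mass n1 histogram", {
  m <- species_preset("human_like")$igh_model
  m$p_n1 <- setNames(as.numeric(0:15 == 5), as.character(0:15))
  rep_ <- generate(m, 800, seed = 51)
  d <- length_distribution(rep_, "n1_length")
  expect_equal(d$table$frequency[d$table$value == 5], 1)
  expect_equal(d$mean, 5)
})

test_that("tail frequency is monotone, starts at 1 and equals 1 - CDF", {
  lens <- c(10, 12, 14)
  rep_ <- hand_repertoire(vapply(lens, function(L) paste0("C", strrep("A", L), "W"),
                                 character(1)))
  tail <- cdr3_tail_frequency(rep_)
  expect_equal(tail$tail_frequency[tail$length == 11], 2 / 3)
  expect_equal(tail$tail_frequency[1], 1)
  expect_true(all(diff(tail$tail_frequency) <= 1e-12))
  d <- length_distribution(rep_, "cdr3_length")
  cdf <- cumsum(d$table$frequency)
  expect_equal(tail$tail_frequency, 1 - c(0, cdf[-length(cdf)]), tolerance = 1e-12)
})

test_that("family pair frequency counts matching D/J families, duplicate-weighted", {
  recs <- hand_records(rep("CARDYW", 12),
                       d = c(rep("IGHD3-10*01", 2), rep("IGHD3-3*01", 1),
                             rep("IGHD1-1*01", 9)),
                       j = c(rep("IGHJ6*01", 3), rep("IGHJ4*01", 9)))
  rep_ <- repertoire(recs, locus = "IGH")
  expect_equal(family_pair_frequency(rep_, "IGHD3", "IGHJ6"), 0.25)
  expect_equal(family_pair_frequency(rep_, "IGHD2", "IGHJ6"), 0)
  expect_error(family_pair_frequency(hand_repertoire("CQQYNSF", locus = "IGK")),
               "IGH")
})

test_that("co-usage frequency matches the model's joint D,J mass within 3 SE", {
  m <- species_preset("human_like")$igh_model
  rep_ <- generate(m, 20000, seed = 52)
  p <- sum(m$p_dj[gene_family(rownames(m$p_dj)) == "IGHD3",
                  gene_family(colnames(m$p_dj)) == "IGHJ6"])
  obs <- family_pair_frequency(repertoire(rep_$records, locus = "IGH"),
                               "IGHD3", "IGHJ6")
  # productivity filtering perturbs the raw event mass slightly; compare on
  # all records where the joint law is exact
  obs_all <- {
    r <- rep_$records
    sum((gene_family(r$d_gene) == "IGHD3") & (gene_family(r$j_gene) == "IGHJ6")) / nrow(r)
  }
  se <- sqrt(p * (1 - p) / n_records(rep_))
  expect_lt(abs(obs_all - p), 3 * se)
  expect_lt(abs(obs - p), 0.01)
})

test_that("short CDRL3 fractions are computed on kappa repertoires only", {
  k5 <- paste0("C", strrep("Q", 5), "F")
  k9 <- paste0("C", strrep("Q", 9), "F")
  rep_ <- hand_repertoire(c(k5, rep(k9, 199)), locus = "IGK")
  expect_equal(short_cdrl3_fraction(rep_), 1 / 200)
  expect_equal(short_cdrl3_fraction(rep_, k = 9), 199 / 200)
  expect_error(short_cdrl3_fraction(hand_repertoire("CARDYW")), "IGK")
})

test_that("isotype frequencies sum to one and match simulator settings within 3 SE", {
  rep_ <- hand_repertoire(rep("CARDYW", 100),
                          isotype = c(rep("IgG", 15), rep("IgM", 85)))
  iso <- isotype_frequencies(rep_)
  expect_equal(iso$frequency[iso$isotype == "IgG"], 0.15)
  expect_equal(sum(iso$frequency), 1)
  cfg <- simulator_config("omnirat_like", n_clones = 500,
                          n_reads_per_compartment = 20000, seed = 53)
  sim <- simulate_repertoire(cfg)
  obs <- isotype_frequencies(sim$lymph_node)
  p <- 0.15
  se <- sqrt(p * (1 - p) / 20000)
  expect_lt(abs(obs$frequency[obs$isotype == "IgG"] - p), 3 * se + 0.005)
})

test_that("mutation summaries recover isotype-specific SHM rates and boundary cases", {
  rep0 <- hand_repertoire(rep("CARDYW", 5))
  ms0 <- mutation_summary(rep0)
  expect_equal(ms0$mean_mutations, 0)
  cfg <- simulator_config("omnirat_like", n_clones = 500,
                          n_reads_per_compartment = 15000,
                          shm_rate_igm = 2, shm_rate_igg = 10, seed = 54)
  sim <- simulate_repertoire(cfg)
  ms <- mutation_summary(sim$lymph_node)
  igg <- ms[ms$group == "IgG", ]; igm <- ms[ms$group == "IgM", ]
  expect_gt(igg$mean_mutations, igm$mean_mutations)
  expect_lt(abs(igm$mean_mutations - 2), 3 * sqrt(2 / igm$n))
  expect_lt(abs(igg$mean_mutations - 10), 3 * sqrt(10 / igg$n))
  # single-record group flagged with SEM 0
  one <- hand_records("CARDYW", isotype = "IgG")
  one$v_mutation_count <- 4L
  ms1 <- mutation_summary(repertoire(one, locus = "IGH"))
  expect_true(ms1$single_record)
  expect_equal(ms1$sem, 0)
})
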