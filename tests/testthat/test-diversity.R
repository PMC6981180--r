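# Clonotype collapsing, incidence, Chao estimators, rarefaction.

test_that("clonotype keys collapse on (V gene, J gene, CDR3 aa)", {
  rep_ <- hand_repertoire(rep("CARDYW", 5))
  ct <- assign_clonotypes(rep_)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$n_reads, 5)
  recs <- hand_records(rep("CARDYW", 2), j = c("IGHJ4*01", "IGHJ6*01"))
  ct2 <- assign_clonotypes(repertoire(recs, locus = "IGH"))
  expect_equal(nrow(ct2), 2)  # same CDR3, different J
  # allele differences do not split clonotypes
  recs3 <- hand_records(rep("CARDYW", 2), v = c("IGHV1-2*01", "IGHV1-2*02"))
  expect_equal(nrow(assign_clonotypes(repertoire(recs3, locus = "IGH"))), 1)
})

test_that("incidence table counts singletons and repeats; union is conserved", {
  inc <- build_incidence(c("a", "b"), c("b", "c"))
  expect_equal(inc$S_obs, 3)
  expect_equal(inc$Q1, 2)
  expect_equal(inc$Q2, 1)
  expect_equal(inc$Q1 + inc$Q2, inc$S_obs)
  disjoint <- build_incidence(c("a", "b"), c("c"))
  expect_equal(disjoint$Q2, 0)
  expect_error(build_incidence(character(0), character(0)), "empty")
})

test_that("chao2 matches hand formula evaluation and respects the S_obs floor", {
  inc <- build_incidence(c("a", "b"), c("b", "c"))
  est <- chao2(inc)
  expect_equal(est$estimate, 3 + (1 / 2) * 4 / 2)  # 4.0
  expect_equal(est$estimate, 4.0)
  # Q1 = 0 -> estimate = S_obs
  inc0 <- build_incidence(c("a", "b"), c("a", "b"))
  expect_equal(chao2(inc0)$estimate, inc0$S_obs)
  # Q2 = 0 switches to the bias-corrected form (finite)
  incq2 <- build_incidence(c("a", "b", "c"), c("d"))
  est2 <- chao2(incq2)
  expect_equal(est2$estimator, "chao2_bias_corrected")
  expect_equal(est2$estimate, 4 + 0.5 * 4 * 3 / 2)
  expect_gte(est2$estimate, incq2$S_obs)
})

test_that("chao2 agrees with vegan's incidence-based chao on random tables", {
  skip_if_not_installed("vegan")
  set.seed(3)
  for (i in 1:10) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    inc <- build_incidence(a, b)
    mat <- rbind(as.integer(union(a, b) %in% a), as.integer(union(a, b) %in% b))
    colnames(mat) <- union(a, b)
    vg <- vegan::specpool(mat)$chao
    ours <- if (inc$Q2 > 0) chao2(inc)$estimate else chao2(inc, bias_corrected = TRUE)$estimate
    expect_equal(ours, vg, tolerance = 1e-9)
  }
})

test_that("chao1 matches hand formula and F1 = F2 = 0 handling", {
  expect_equal(chao1(c(4, 3, 5))$estimate, 3)  # no singles/doubles
  est <- chao1(c(rep(1, 4), rep(2, 2), rep(5, 4)))
  expect_equal(est$estimate, 10 + 16 / 4)  # 14
  expect_error(chao1(integer(0)), "empty")
  expect_gte(chao1(c(1, 1, 3))$estimate, 3)
})

test_that("chao2 recovers true richness within a factor of 2 on simulated data", {
  cfg <- simulator_config("omnirat_like", n_clones = 1000,
                          n_reads_per_compartment = 10000,
                          shm_rate_igm = 0, shm_rate_igg = 0, seed = 61)
  sim <- simulate_repertoire(cfg)
  inc <- build_incidence(assign_clonotypes(sim$lymph_node),
                         assign_clonotypes(sim$spleen))
  est <- chao2(inc)
  expect_gte(est$estimate, inc$S_obs)
  expect_gt(est$estimate, 1000 / 2)
  expect_lt(est$estimate, 1000 * 2)
})

test_that("rarefaction is diagonal for all-unique reads, flat for one clonotype, and S_obs at f = 1", {
  uniq <- sprintf("C%sW", vapply(1:200, function(i)
    paste(sample(c("A","R","D","G","S","T","Y"), 8, TRUE), collapse = ""), character(1)))
  uniq <- unique(uniq)
  rep_u <- hand_repertoire(uniq)
  cur <- rarefaction(rep_u, fractions = c(0.25, 0.5, 1), seed = 2)
  expect_equal(cur$mean_unique, cur$n_reads)  # on the diagonal
  rep_1 <- hand_repertoire(rep("CARDYW", 50))
  cur1 <- rarefaction(rep_1, fractions = c(0.2, 0.6, 1), seed = 2)
  expect_true(all(cur1$mean_unique == 1))
  ct <- assign_clonotypes(rep_u)
  expect_equal(cur$mean_unique[cur$fraction == 1], nrow(ct))
  expect_error(rarefaction(rep_u, fractions = c(0, 0.5)), "\\(0, 1\\]")
})

test_that("rarefaction means are monotone and bounded by the diagonal", {
  cfg <- simulator_config("omnirat_like", n_clones = 300,
                          n_reads_per_compartment = 3000, seed = 62)
  sim <- simulate_repertoire(cfg)
  cur <- rarefaction(sim$lymph_node, seed = 3)
  expect_true(all(diff(cur$mean_unique) >= 0))
  expect_true(all(cur$mean_unique <= cur$n_reads))
  expect_true(all(cur$mean_unique >= 1))
})

test_that("diversity_vs_fraction at f = 1 equals the full-data estimator; sequence >= clonotype", {
  cfg <- simulator_config("omnirat_like", n_clones = 400,
                          n_reads_per_compartment = 3000, seed = 63)
  sim <- simulate_repertoire(cfg)
  dv <- diversity_vs_fraction(sim$lymph_node, sim$spleen,
                              fractions = c(0.3, 0.6, 1), seed = 4)
  full <- chao2(build_incidence(assign_clonotypes(sim$lymph_node),
                                assign_clonotypes(sim$spleen)))$estimate
  expect_equal(dv$mean_estimate[dv$fraction == 1], full)
  dv_seq <- diversity_vs_fraction(sim$lymph_node, sim$spleen,
                                  fractions = 1, unit = "sequence", seed = 4)
  expect_gte(dv_seq$mean_estimate, full)
})
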