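# Usage profiles, z-score clustering and pairwise regressions.

test_that("usage frequencies are duplicate-weighted fractions over the gene universe", {
  rep1 <- hand_repertoire(rep("CARDYW", 10))
  u <- gene_usage(rep1, "V")
  expect_equal(u$frequency[u$gene == "IGHV1-2"], 1)
  recs <- hand_records(rep("CARDYW", 4), v = c(rep("IGHV1-2*01", 3), "IGHV3-23*01"))
  u2 <- gene_usage(repertoire(recs, locus = "IGH"), "V")
  expect_equal(sort(u2$frequency, decreasing = TRUE)[1:2], c(0.75, 0.25))
  expect_equal(sum(u2$frequency), 1, tolerance = 1e-9)
  # unobserved germline genes appear with frequency zero
  g <- toy_germline_set("human_like", "IGH")
  u3 <- gene_usage(repertoire(recs, locus = "IGH", germline = g), "V")
  expect_equal(nrow(u3), 12)
  expect_equal(sum(u3$frequency == 0), 10)
})

test_that("simulated usage matches generating probabilities within 3 binomial SE", {
  m <- species_preset("human_like")$igh_model
  rep_ <- generate(m, 20000, seed = 21)
  u <- gene_usage(rep_, "V", productive_only = FALSE)
  n <- n_records(rep_)
  for (gname in names(m$p_v)) {
    p <- m$p_v[[gname]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(u$frequency[u$gene == gname] - p), 3 * se + 1e-6)
  }
})

test_that("z-scored rows have mean 0 and unit population sd; identical columns give zero z", {
  m <- species_preset("human_like")$igh_model
  profs <- lapply(c(a = 22, b = 23, c = 24), function(s) gene_usage(generate(m, 3000, seed = s), "V"))
  mat <- usage_matrix(profs)
  z <- zscore_and_cluster(mat)$z
  active <- apply(mat, 1, function(r) stats::sd(r) > 0)
  expect_equal(unname(rowMeans(z[active, ])), rep(0, sum(active)), tolerance = 1e-9)
  expect_equal(unname(apply(z[active, ], 1, function(r) sqrt(mean((r - mean(r))^2)))),
               rep(1, sum(active)), tolerance = 1e-9)
  mat2 <- cbind(x = mat[, 1], y = mat[, 1])
  z2 <- zscore_and_cluster(mat2)
  expect_true(all(z2$z == 0))
  expect_equal(z2$col_hclust$height, 0)
  expect_error(zscore_and_cluster(mat[, 1, drop = FALSE]), "at least 2")
})

test_that("repertoires simulated from different presets split into two species clusters", {
  reps <- list()
  for (i in 1:3) {
    cfg <- simulator_config("omnirat_like", n_clones = 5000,
                            n_reads_per_compartment = 5000, seed = 30 + i,
                            subject_id = paste0("OR", i))
    reps[[paste0("OR", i)]] <- simulate_repertoire(cfg)$lymph_node
  }
  for (i in 1:3) {
    cfg <- simulator_config("human_like", n_clones = 5000,
                            n_reads_per_compartment = 5000, seed = 40 + i,
                            subject_id = paste0("HU", i))
    reps[[paste0("HU", i)]] <- simulate_repertoire(cfg)$lymph_node
  }
  mat <- usage_matrix(lapply(reps, gene_usage, segment = "V"))
  hc <- zscore_and_cluster(mat)$col_hclust
  groups <- stats::cutree(hc, k = 2)
  expect_equal(length(unique(groups[paste0("OR", 1:3)])), 1)
  expect_equal(length(unique(groups[paste0("HU", 1:3)])), 1)
  expect_false(groups[["OR1"]] == groups[["HU1"]])
})

test_that("self-regression is exact and matches closed-form OLS on a hand triple", {
  recs <- hand_records(rep("CARDYW", 10),
                       v = c(rep("IGHV1-2*01", 2), rep("IGHV3-23*01", 3),
                             rep("IGHV4-34*01", 5)))
  u <- gene_usage(repertoire(recs, locus = "IGH"), "V")
  fit <- suppressWarnings(usage_regression(u, u))  # lm warns on a perfect fit
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  # hand OLS for x = (.2,.3,.5), y = (.3,.2,.5)
  u2 <- u; u2$frequency <- c(0.3, 0.2, 0.5)
  fit2 <- usage_regression(u, u2)
  x <- c(0.2, 0.3, 0.5); y <- c(0.3, 0.2, 0.5)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit2$slope, beta, tolerance = 1e-12)
  expect_equal(fit2$intercept, mean(y) - beta * mean(x), tolerance = 1e-12)
  expect_equal(fit2$r_squared, stats::cor(x, y)^2, tolerance = 1e-12)
})

test_that("regression of a permuted profile over many genes has low R-squared", {
  set.seed(99)
  genes <- sprintf("IGHV%d-%d", rep(1:7, each = 8), 1:8)[1:50]
  f <- stats::runif(50); f <- f / sum(f)
  a <- tibble::tibble(gene = genes, frequency = f)
  attr(a, "segment") <- "V"
  r2 <- replicate(20, {
    b <- tibble::tibble(gene = genes, frequency = sample(f))
    attr(b, "segment") <- "V"
    usage_regression(a, b)$r_squared
  })
  expect_lt(median(r2), 0.2)
})
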