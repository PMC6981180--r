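# Generative simulator: determinism, degenerate models, event-frequency
# oracles, junction assembly invariants, SHM behaviour.

degenerate_model <- function() {
  g <- tiny_germline()[c(1, 3, 5), ]  # one V, one D, one J
  sup0 <- "0"
  recomb_model(
    locus = "IGH", germline = g,
    p_v = setNames(1, g$gene[g$segment == "V"]),
    p_dj = matrix(1, 1, 1, dimnames = list(g$gene[g$segment == "D"],
                                           g$gene[g$segment == "J"])),
    p_v_trim = matrix(1, 1, 1, dimnames = list(g$gene[g$segment == "V"], sup0)),
    p_d_trim = array(1, c(1, 1, 1), dimnames = list(g$gene[g$segment == "D"], sup0, sup0)),
    p_j_trim = matrix(1, 1, 1, dimnames = list(g$gene[g$segment == "J"], sup0)),
    p_n1 = setNames(1, "0"), p_n2 = setNames(1, "0"),
    markov_init = setNames(rep(0.25, 4), c("A", "C", "G", "T")),
    markov_trans = matrix(0.25, 4, 4, dimnames = list(c("A","C","G","T"),
                                                      c("A","C","G","T"))),
    p_nucleotides = FALSE
  )
}

test_that("a fully degenerate model yields the deterministic concatenation", {
  m <- degenerate_model()
  g <- m$germline
  r1 <- simulate_rearrangement(m, 5, seed = 1)
  r2 <- simulate_rearrangement(m, 5, seed = 99)
  expect_equal(unique(r1$junction), unique(r2$junction))
  v <- g[g$segment == "V", ]; d <- g[g$segment == "D", ]; j <- g[g$segment == "J", ]
  expected <- paste0(substr(v$sequence, v$anchor, nchar(v$sequence)),
                     d$sequence,
                     substr(j$sequence, 1, j$anchor + 2))
  expect_equal(unique(r1$junction), expected)
})

test_that("point-mass insertion distributions fix both insertion lengths", {
  m <- tiny_model()
  m$p_n1 <- setNames(c(0, 0, 0, 0, 0, 1), as.character(0:5))
  m$p_n2 <- m$p_n1
  r <- simulate_rearrangement(m, 200, seed = 2)
  expect_true(all(r$n1_length == 5))
  expect_true(all(r$n2_length == 5))
  expect_true(all(nchar(r$n1_sequence) == 5))
})

test_that("observed gene usage converges to model probabilities (binomial SE)", {
  m <- species_preset("human_like")$igh_model
  n <- 10000
  r <- simulate_rearrangement(m, n, seed = 3)
  pj <- colSums(m$p_dj)
  for (jg in c("IGHJ6", "IGHJ4")) {
    obs <- mean(r$j_gene == jg)
    se <- sqrt(pj[jg] * (1 - pj[jg]) / n)
    expect_lt(abs(obs - pj[jg]), 3 * se)
  }
})

test_that("junction length decomposes exactly into kept segments, insertions and P additions", {
  m <- species_preset("omnirat_like")$igh_model
  r <- simulate_rearrangement(m, 2000, seed = 4)
  g <- m$germline
  dlen <- nchar(g$sequence)[match(r$d_gene, g$gene)]
  janch <- g$anchor[match(r$j_gene, g$gene)]
  d_kept <- pmax(0L, dlen - r$d_trim5 - r$d_trim3)
  p_len <- 2L * ((r$v_trim3 == 0) + (r$j_trim5 == 0) +
                   (d_kept > 0 & r$d_trim5 == 0) + (d_kept > 0 & r$d_trim3 == 0))
  v_after_cys <- 12L  # CYS codon + 9-nt CDR3 stub
  expect_equal(nchar(r$junction),
               (v_after_cys - r$v_trim3) + r$n1_length + d_kept + r$n2_length +
                 (janch + 2L - r$j_trim5) + p_len)
})

test_that("unnormalized models are rejected", {
  m <- tiny_model()
  m$p_v <- m$p_v * 2
  expect_error(simulate_rearrangement(m, 1, seed = 1), "sum to 1")
})

test_that("same config gives byte-identical AIRR output; reads are conserved", {
  cfg <- simulator_config("omnirat_like", n_clones = 150,
                          n_reads_per_compartment = 400, seed = 77)
  s1 <- simulate_repertoire(cfg)
  s2 <- simulate_repertoire(cfg)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_airr(s1$lymph_node, f1)
  write_airr(s2$lymph_node, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(n_records(s1$lymph_node) + n_records(s1$spleen), 2 * 400)
})

test_that("zero tissue overlap gives cross-compartment sharing bounded by key collisions", {
  cfg <- simulator_config("omnirat_like", n_clones = 400,
                          n_reads_per_compartment = 2000,
                          tissue_overlap_prob = 0,
                          shm_rate_igm = 0, shm_rate_igg = 0, seed = 5)
  sim <- simulate_repertoire(cfg)
  tr <- sim$truth$clones
  key <- paste(tr$v_gene, tr$j_gene, tr$cdr3_aa)
  # brute-force collision bound: keys produced by clones on both sides
  collision_bound <- length(intersect(key[tr$in_lymph_node], key[tr$in_spleen]))
  inc <- build_incidence(assign_clonotypes(sim$lymph_node),
                         assign_clonotypes(sim$spleen))
  expect_lte(inc$Q2, collision_bound)
})

test_that("full tissue overlap with deep sampling approaches complete recapture", {
  cfg <- simulator_config("omnirat_like", n_clones = 100,
                          n_reads_per_compartment = 5000,
                          tissue_overlap_prob = 1,
                          shm_rate_igm = 0, shm_rate_igg = 0, seed = 6)
  sim <- simulate_repertoire(cfg)
  inc <- build_incidence(assign_clonotypes(sim$lymph_node),
                         assign_clonotypes(sim$spleen))
  expect_gt(inc$Q2 / inc$S_obs, 0.9)
})

test_that("every emitted record's clonotype key maps to a true clone (no SHM)", {
  cfg <- simulator_config("omnirat_like", n_clones = 200,
                          n_reads_per_compartment = 1000,
                          shm_rate_igm = 0, shm_rate_igg = 0, seed = 8)
  sim <- simulate_repertoire(cfg)
  truth_keys <- paste(sim$truth$clones$v_gene, sim$truth$clones$j_gene,
                      sim$truth$clones$cdr3_aa, sep = "|")
  ct <- assign_clonotypes(sim$lymph_node)
  expect_true(all(ct$key %in% truth_keys))
})

test_that("SHM leaves records untouched at mean 0 and matches the Poisson mean", {
  m <- species_preset("human_like")$igh_model
  r <- simulate_rearrangement(m, 3000, seed = 9)
  r0 <- apply_shm(r, 0, seed = 1)
  expect_identical(r0$sequence, r$sequence)
  expect_true(all(r0$v_mutation_count == 0))
  r5 <- apply_shm(r, 5, seed = 2)
  se <- sqrt(5 / nrow(r))
  expect_lt(abs(mean(r5$v_mutation_count) - 5), 3 * se)
  # mutated sequences differ from germline-assembled ones
  expect_gt(mean(r5$sequence != r$sequence), 0.95)
})

test_that("mutation counts are capped at the V-region length with a warning", {
  m <- species_preset("human_like")$igh_model
  r <- simulate_rearrangement(m, 3, seed = 10)
  expect_warning(out <- apply_shm(r, 5000, seed = 3), "capped")
  expect_true(all(out$v_mutation_count <= r$v_sequence_length))
})

test_that("species presets expose the spec'd germline sizes and normalized insertions", {
  for (nm in c("omnirat_like", "human_like")) {
    pr <- species_preset(nm)
    g <- pr$igh_model$germline
    expect_gte(sum(g$segment == "V"), 10)
    expect_gte(sum(g$segment == "D"), 8)
    expect_equal(sum(g$segment == "J"), 6)
    gk <- pr$igk_model$germline
    expect_gte(sum(gk$segment == "V"), 10)
    expect_equal(sum(gk$segment == "J"), 5)
    expect_equal(sum(pr$igh_model$p_n1), 1, tolerance = 1e-12)
    expect_equal(sum(pr$igh_model$p_n2), 1, tolerance = 1e-12)
  }
  expect_error(species_preset("mouse_like"))
})
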