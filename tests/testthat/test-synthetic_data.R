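test_that("generated networks pass validation across sizes and seeds", {
  for (seed in 1:6) {
    spec <- synthetic_spec(n_plants = sample(5:20, 1),
                           n_pollinators = sample(6:30, 1),
                           target_connectance = runif(1, 0.15, 0.4),
                           nestedness_strength = runif(1, 0, 2),
                           quantitative = seed %% 2 == 0)
    net <- generate_network(spec, rng_seed = seed)
    expect_silent(validate_network(net))
    expect_identical(generate_network(spec, rng_seed = seed)$weights,
                     net$weights)   # pure function of (spec, seed)
  }
  expect_error(generate_network(synthetic_spec(n_plants = 30,
                                               n_pollinators = 30,
                                               target_connectance = 0.02)),
               "infeasible")
})

test_that("realized connectance tracks the target at 30x60", {
  spec <- synthetic_spec(n_plants = 30, n_pollinators = 60,
                         target_connectance = 0.15)
  set.seed(55)
  conn <- replicate(50, {
    sz <- network_size(generate_network(spec))
    sz$L / (sz$P * sz$A)
  })
  expect_lt(abs(mean(conn) - 0.15) / 0.15, 0.2)
})

test_that("nestedness_strength drives relative nestedness", {
  # homogeneous case needs large networks: the averaged-fill null slightly
  # flattens small degree sequences, biasing small-network N* upward
  flat <- synthetic_spec(n_plants = 25, n_pollinators = 50,
                         target_connectance = 0.2, nestedness_strength = 0)
  steep <- synthetic_spec(n_plants = 25, n_pollinators = 50,
                          target_connectance = 0.2, nestedness_strength = 1.5)
  set.seed(66)
  star <- function(spec) replicate(50, {
    relative_nestedness(generate_network(spec), n_reps = 60)$N_star
  })
  s_flat <- star(flat)
  s_steep <- star(steep)
  # the degree-conditioned null leaves a small residual bias (measured
  # ~ -0.07 here) even in the homogeneous world; the planted contrast with
  # the heterogeneous world is an order of magnitude larger
  expect_lt(abs(mean(s_flat)), 0.1)
  expect_gt(mean(s_steep), 0.05)
  expect_gt(mean(s_steep), mean(s_flat) + 0.3)
})

test_that("exotic attachment is uniform when beta = gamma = delta = 0", {
  # 8x8 circulant with row degree 3: every column keeps >= 2 links after a
  # single-plant rewiring, so no pollinator can be stranded
  m <- matrix(0, 8, 8, dimnames = list(paste0("p", 1:8), paste0("a", 1:8)))
  for (i in 1:8) m[i, ((i + 0:2 - 1) %% 8) + 1] <- 1
  net <- bipartite_network(m)
  set.seed(88)
  counts <- numeric(8)
  n_draw <- 10000
  for (i in seq_len(n_draw)) {
    r <- plant_exotic_attachment(net, c(-1, 0, 0, 0), 1 / 8)
    counts <- counts + unname(r$weights[r$exotic, ])
  }
  freq <- counts / n_draw
  se <- sqrt(3 / 8 * 5 / 8 / n_draw)
  expect_true(all(abs(freq - 3 / 8) < 4 * se))

  expect_error(plant_exotic_attachment(net, c(0, 0, 0, 0), 0.01),
               "selects no plant")
})

test_that("positive degree preference concentrates exotic links on hubs", {
  spec <- synthetic_spec(n_plants = 12, n_pollinators = 16,
                         target_connectance = 0.3, nestedness_strength = 1)
  base <- generate_network(spec, rng_seed = 4)
  k <- rank_normalize(colSums(binary_structure(base)))
  set.seed(99)
  gain <- numeric(ncol(base$weights))
  for (i in 1:400) {
    r <- plant_exotic_attachment(base, c(-2, 6, 0, 0), 1 / 12)
    b <- binary_structure(r)
    ex <- b[r$exotic[rownames(b)], , drop = FALSE]
    gain[match(colnames(b), colnames(base$weights))] <-
      gain[match(colnames(b), colnames(base$weights))] + colSums(ex)
  }
  top <- k >= quantile(k, 0.75)
  expect_gt(mean(gain[top]), 2 * mean(gain[!top]))
})

test_that("generated phylogenies are ultrametric and reproducible", {
  tr <- generate_phylogeny(12, rng_seed = 3, depth = 100)
  depths <- ape::node.depth.edgelength(tr)[1:12]
  expect_equal(depths, rep(100, 12), tolerance = 1e-9)
  expect_true(ape::is.ultrametric(tr))
  tr2 <- generate_phylogeny(12, rng_seed = 3, depth = 100)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  expect_equal(phylogenetic_diversity(tr, tr$tip.label), 100,
               tolerance = 1e-9)
})

test_that("study sets have the requested design shape", {
  ss <- suppressWarnings(generate_study_set(
    n_invaded = 4, n_uninvaded = 5,
    template = synthetic_spec(n_plants = 10, n_pollinators = 14,
                              target_connectance = 0.3,
                              attachment_coeffs = c(-1, 0, 0, 0)),
    rng_seed = 12))
  expect_length(ss$networks, 9)
  n_ex <- vapply(ss$networks, function(n) sum(n$exotic), 0L)
  expect_true(all(n_ex[ss$manifest$invaded] >= 1))
  expect_true(all(n_ex[!ss$manifest$invaded] == 0))
  for (net in ss$networks) expect_silent(validate_network(net))
})

test_that("planted richness shifts give the group test power", {
  # scaled-down twin of the power example (+50% richness, fewer sets)
  set.seed(202)
  null_spec <- synthetic_spec(n_plants = 12, n_pollinators = 24,
                              target_connectance = 0.25,
                              attachment_coeffs = c(-1, 0, 0, 0))
  reject <- replicate(50, {
    ss <- suppressWarnings(generate_study_set(
      10, 13, template = null_spec, richness_shift = 0.5,
      rng_seed = sample.int(2^30, 1)))
    S <- vapply(ss$networks, function(n) network_size(n)$S, 0)
    kruskal_wallis(S, ss$manifest$invaded)$p_value < 0.05
  })
  expect_gt(mean(reject), 0.6)
})

test_that("simulate_attachment_table matches the logistic generative law", {
  tab <- simulate_attachment_table(n_networks = 5, n_pollinators = 10,
                                   rng_seed = 2)
  expect_equal(nrow(tab), 5 * 10 * 2)
  expect_setequal(unique(tab$is_random), c(0L, 1L))
  expect_true(all(tab$y %in% 0:1))
  # high-probability corner: alpha large positive forces y = 1
  tab1 <- simulate_attachment_table(n_networks = 2, n_pollinators = 20,
                                    coeffs = c(20, 0, 0, 0), ranef_sd = 0,
                                    rng_seed = 3)
  expect_true(all(tab1$y == 1))
})
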