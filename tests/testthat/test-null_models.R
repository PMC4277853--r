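test_that("cell probabilities follow the averaged-fill formula", {
  # links {(1,1),(1,2),(2,1)}: p11 = (2/2 + 2/2)/2 = 1, p22 = (1/2 + 1/2)/2
  m <- lmat(c(1, 1, 1, 0), 2)
  p <- cell_probabilities(bipartite_network(m))
  expect_equal(unname(p$probs["p1", "a1"]), 1.0)
  expect_equal(unname(p$probs["p2", "a2"]), 0.5)
  expect_equal(sum(p$probs), 3)   # conservation: sum p = L

  full <- bipartite_network(lmat(rep(1, 12), 3))
  expect_true(all(cell_probabilities(full)$probs == 1))
})

test_that("sum of cell probabilities equals L on random networks", {
  set.seed(101)
  for (i in 1:50) {
    m <- random_binary(sample(3:9, 1), sample(3:9, 1), runif(1, 0.3, 0.8))
    net <- bipartite_network(m)
    expect_equal(sum(cell_probabilities(net)$probs), sum(m), tolerance = 1e-12)
  }
})

test_that("cell-model sampling is deterministic and respects p = 1", {
  full <- bipartite_network(lmat(rep(1, 6), 2))
  p <- cell_probabilities(full)
  expect_identical(sample_cell_model(p, 7)$weights, full$weights)

  net <- bipartite_network(random_binary(5, 6))
  pr <- cell_probabilities(net)
  r1 <- sample_cell_model(pr, 11)
  r2 <- sample_cell_model(pr, 11)
  expect_identical(r1$weights, r2$weights)
})

test_that("cell-model mean fill matches the exact conditional expectation", {
  # All p = 0.5 on 2x2. Conditioning on no empty row/column (the sampler's
  # rejection rule) gives mean fill 20/7 by exhaustive enumeration of the 16
  # configurations: valid fills are {2,2,3,3,3,3,4} with probability 1/7
  # each at fill weights (2 x fill2, 4 x fill3, 1 x fill4).
  probs <- structure(list(
    probs = matrix(0.5, 2, 2, dimnames = list(c("p1", "p2"), c("a1", "a2"))),
    network_id = "halves"), class = "cell_probability_matrix")
  set.seed(13)
  fills <- replicate(10000, sum(sample_cell_model(probs)$weights))
  expected <- 20 / 7
  se <- sd(fills) / sqrt(length(fills))
  expect_lt(abs(mean(fills) - expected), 3 * se)
})

test_that("focal randomization preserves everything but the focal species", {
  m <- lmat(c(1, 1, 0, 1, 0, 1, 1, 1, 0), 3)
  net <- bipartite_network(m)
  r <- randomize_focal_species(net, "p2", rng_seed = 3)
  b <- binary_structure(r)
  expect_identical(b[c("p1", "p3"), ], binary_structure(net)[c("p1", "p3"), ])
  expect_equal(sum(b["p2", ]), sum(m["p2", ]))   # degree preserved

  # focal connected to every partner: only one subset exists
  full_row <- bipartite_network(lmat(c(1, 1, 1, 1, 0, 1), 2))
  expect_identical(binary_structure(randomize_focal_species(full_row, "p1", 5)),
                   binary_structure(full_row))
  expect_error(randomize_focal_species(net, "nope"), "unknown species")
})

test_that("focal rewiring follows the weighted-sampling law", {
  # plant_1 degree 1; eligible cells have p = (0.75, 0.5) so partner a1
  # should be drawn with frequency 0.75/1.25 = 0.6
  m <- lmat(c(1, 0, 1, 1), 2)
  net <- bipartite_network(m)
  p <- cell_probabilities(net)
  expect_equal(unname(p$probs["p1", ]), c(0.75, 0.5))
  set.seed(29)
  n_draw <- 20000
  hits <- 0
  for (i in seq_len(n_draw)) {
    r <- randomize_focal_species(net, "p1", probs = p)
    hits <- hits + (r$weights["p1", "a1"] == 1)
  }
  se <- sqrt(0.6 * 0.4 / n_draw)
  expect_lt(abs(hits / n_draw - 0.6), 3 * se)
})

test_that("swap randomization preserves marginals and handles degeneracy", {
  id2 <- bipartite_network(lmat(c(1, 0, 0, 1), 2))
  flipped <- swap_randomize(id2, rng_seed = 1, n_attempts = 1)
  expect_identical(unname(binary_structure(flipped)),
                   matrix(c(0, 1, 1, 0), 2))

  tri <- lmat(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3)   # nested triangle
  expect_warning(out <- swap_randomize(bipartite_network(tri), 2),
                 "degenerate")
  expect_identical(unname(binary_structure(out)), unname(tri))

  set.seed(57)
  for (i in 1:30) {
    m <- random_binary(sample(4:10, 1), sample(4:10, 1))
    net <- bipartite_network(m)
    sw <- swap_randomize(net)
    expect_identical(rowSums(binary_structure(sw)), rowSums(m))
    expect_identical(colSums(binary_structure(sw)), colSums(m))
  }
})

test_that("ensembles are reproducible and carry provenance", {
  net <- bipartite_network(random_binary(6, 8))
  e1 <- build_ensemble(net, "swap", n_reps = 20, rng_seed = 5)
  e2 <- build_ensemble(net, "swap", n_reps = 20, rng_seed = 5)
  expect_equal(e1$n_reps, 20)
  expect_identical(lapply(e1$replicates, `[[`, "weights"),
                   lapply(e2$replicates, `[[`, "weights"))
  for (r in e1$replicates) {
    expect_identical(rowSums(binary_structure(r)),
                     rowSums(binary_structure(net)))
  }
  e3 <- build_ensemble(net, "swap", n_reps = 20, rng_seed = 6)
  same <- mapply(function(a, b) identical(a$weights, b$weights),
                 e1$replicates, e3$replicates)
  expect_false(all(same))   # different seeds explore different states

  ec <- build_ensemble(net, "cell_model", n_reps = 5, rng_seed = 9)
  expect_length(ec$replicates, 5)
  ef <- build_ensemble(net, "focal_species", n_reps = 5, rng_seed = 9,
                       focal = rownames(net$weights)[1])
  others <- rownames(net$weights)[-1]
  for (r in ef$replicates) {
    expect_identical(binary_structure(r)[others, ],
                     binary_structure(net)[others, ])
  }
})

test_that("ensemble serialization writes replicates plus manifest", {
  net <- bipartite_network(random_binary(4, 5))
  ens <- build_ensemble(net, "swap", n_reps = 3, rng_seed = 2)
  dir <- withr::local_tempdir()
  write_ensemble(ens, dir)
  expect_length(list.files(dir, pattern = "replicate_.*tsv"), 3)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$method, "swap")
  expect_equal(man$n_reps, 3)
  expect_equal(man$seed, 2)
})
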