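test_that("kruskal_wallis reproduces the closed-form H", {
  # tie-free closed form: 12/(n(n+1)) * sum n_g (rbar_g - rbar)^2
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(kw$chi_sq, 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2),
               tolerance = 1e-12)
  expect_equal(kw$df, 1)

  same <- kruskal_wallis(c(1, 2, 3, 1, 2, 3),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(same$chi_sq, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  # rank statistic: invariant under strictly monotone transforms
  v <- c(0.3, 2.5, 1.1, 4.2, 0.9, 3.3)
  g <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(kruskal_wallis(exp(v), g)$chi_sq,
               kruskal_wallis(v, g)$chi_sq, tolerance = 1e-12)

  expect_error(kruskal_wallis(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
})

test_that("kruskal_wallis p-value tracks the exact permutation law", {
  # chi-squared reference vs exhaustive permutation over all group
  # assignments; agreement is approximate at n = 8 (the chi-squared law is
  # asymptotic), so the bound is loose
  set.seed(23)
  for (i in 1:5) {
    v <- rnorm(8)
    g <- c(rep(TRUE, 4), rep(FALSE, 4))
    h_obs <- kruskal_wallis(v, g)$chi_sq
    combos <- combn(8, 4)
    h_all <- apply(combos, 2, function(ix) {
      kruskal_wallis(v, seq_len(8) %in% ix)$chi_sq
    })
    p_perm <- mean(h_all >= h_obs - 1e-12)
    # observed discrepancies reach ~0.12 at this sample size
    expect_lt(abs(kruskal_wallis(v, g)$p_value - p_perm), 0.15)
  }
})

test_that("exotic_prevalence_trends detects monotone structure", {
  S <- c(10, 20, 30, 40, 50)
  P <- c(5, 10, 15, 20, 25)
  A <- S - P
  n_ex <- c(5, 4, 3, 2, 1)   # proportion inversely ordered with richness
  tr <- exotic_prevalence_trends(S, P, A, n_ex)
  row <- tr[tr$comparison == "exotic_proportion_vs_S", ]
  expect_equal(row$sign, -1)
  expect_lt(row$p_value, 0.05)

  # permutation null: with plant richness held constant the proportion is
  # proportional to the count, so permuted counts are independent of S and
  # the association averages to zero
  set.seed(41)
  S0 <- seq(20, 56, by = 4)
  P0 <- rep(10, 10)
  A0 <- S0 - P0
  ne0 <- rep(1:5, 2)
  rhos <- replicate(60, {
    exotic_prevalence_trends(S0, P0, A0, sample(ne0))$rho[2]
  })
  expect_lt(abs(mean(rhos)), 0.15)

  expect_error(exotic_prevalence_trends(1:2, 1:2, 1:2, c(1, 1)), ">= 3")
})

test_that("dependence regression recovers planted shifts in direction", {
  set.seed(5)
  n <- 400
  exotic <- rep(c(TRUE, FALSE), each = n)
  base <- rbeta(2 * n, 2, 4)
  d_plant <- ifelse(exotic, base / 2, base)   # exotic dependences halved
  rec <- data.frame(d_plant = d_plant, d_pollinator = rev(d_plant),
                    plant_exotic = exotic)
  fit <- dependence_regression(rec, "plant")
  expect_lt(fit$coefficient, 0)
  expect_lt(fit$p_value, 0.01)

  # identical distributions: coefficient near zero
  rec0 <- data.frame(d_plant = rep(base[1:n], 2), d_pollinator = 0.5,
                     plant_exotic = exotic)
  fit0 <- dependence_regression(rec0, "plant")
  expect_lt(abs(fit0$z), 2)

  # all dependences 1: degenerate, flagged
  rec1 <- data.frame(d_plant = 1, d_pollinator = 1, plant_exotic = exotic)
  expect_true(dependence_regression(rec1, "plant")$degenerate)

  expect_error(dependence_regression(
    data.frame(d_plant = 0.5, d_pollinator = 0.5, plant_exotic = TRUE),
    "plant"), "both")
})

test_that("preference regression recovers a planted log-shift within 2 SE", {
  set.seed(9)
  n <- 500
  exotic <- rep(c(TRUE, FALSE), each = n)
  lg <- rnorm(2 * n, 0, 1) + ifelse(exotic, 0.5, 0)
  rec <- data.frame(gamma = exp(lg), plant_exotic = exotic)
  fit <- preference_regression(rec)
  se <- 2 * sqrt(2 / n)   # conservative 2 SE of a two-sample mean difference
  expect_lt(abs(fit$coefficient - 0.5), se)
  expect_lt(fit$p_value, 0.01)

  flat <- data.frame(gamma = 1, plant_exotic = exotic)
  expect_true(preference_regression(flat)$undefined)
})

test_that("exotic_link_indicator marks pollinators touching exotic plants", {
  m <- lmat(c(1, 1, 0,
              0, 1, 1), 2)
  net <- bipartite_network(m, exotic = "p2")
  ind <- exotic_link_indicator(net)
  expect_identical(unname(ind), c(FALSE, TRUE, TRUE))

  all_ex <- bipartite_network(m, exotic = c("p1", "p2"))
  expect_true(all(exotic_link_indicator(all_ex)))

  none <- bipartite_network(m)
  expect_error(exotic_link_indicator(none), "no exotic plants")
})

test_that("assemble_model_table has the exact stacked layout", {
  set.seed(77)
  nets <- lapply(1:2, function(i) {
    m <- random_binary(6, 5, 0.5)
    bipartite_network(m, exotic = "p1", network_id = paste0("n", i))
  })
  tab <- assemble_model_table(nets, n_reps = 4, c_reps = 10, rng_seed = 3)
  expect_equal(nrow(tab), 2 * 5 * (1 + 4))
  # k constant within pollinator per network (swap preserves degrees)
  for (nid in c("n1", "n2")) {
    sub <- tab[tab$network == nid, ]
    expect_true(all(tapply(sub$k, sub$pollinator,
                           function(v) length(unique(v))) == 1))
    expect_equal(sum(sub$is_random == 0), 5)   # one empirical row per pollinator
  }
  expect_true(all(tab$c >= 0 & tab$c <= 1))
})

test_that("the attachment model recovers planted coefficients and nulls", {
  planted <- c(-3.69, 1.86, -3.69, 5.60)
  tab <- simulate_attachment_table(n_networks = 80, n_pollinators = 40,
                                   coeffs = planted, rng_seed = 15)
  fit <- fit_exotic_link_model(tab)
  cf <- fit$coefficients
  base <- cf[cf$parameter %in% c("alpha", "beta", "gamma", "delta"), ]
  expect_true(all(abs(base$estimate - planted) < 3 * base$std_error))
  expect_true(all(sign(base$estimate) == sign(planted)))
  stars <- cf[grepl("_star", cf$parameter), ]
  expect_true(all(abs(stars$estimate) < 3 * stars$std_error))

  # reconstruction identity: Random rows are sums of base + starred terms
  expect_equal(fit$random_table$estimate, base$estimate + stars$estimate,
               tolerance = 1e-12)

  # intercept identity for the prediction function
  expect_equal(unname(predict_attachment(fit, 0, 0, "empirical")),
               unname(plogis(base$estimate[1])), tolerance = 1e-12)

  # null table: y independent of k and c
  tab0 <- simulate_attachment_table(n_networks = 60, n_pollinators = 30,
                                    coeffs = c(-2, 0, 0, 0), rng_seed = 19)
  fit0 <- fit_exotic_link_model(tab0)
  slopes <- fit0$coefficients[fit0$coefficients$parameter %in%
                                c("beta", "gamma", "delta"), ]
  expect_true(all(abs(slopes$estimate) < 3 * slopes$std_error))
})

test_that("relative_probability evaluates the two printed intercept curves", {
  # direct evaluation oracle on a hand-built result object
  fake <- structure(list(coefficients = data.frame(
    parameter = c("alpha", "beta", "gamma", "delta",
                  "alpha_star", "beta_star", "gamma_star", "delta_star"),
    estimate = c(-3.69, 1.86, -3.69, 5.60,
                 -4.44 - (-3.69), 2.67 - 1.86, -1.49 - (-3.69), 3.17 - 5.60),
    stringsAsFactors = FALSE)), class = "exotic_link_model")
  expect_equal(relative_probability(fake, 0, 0),
               plogis(-3.69) / plogis(-4.44), tolerance = 1e-12)
  grid <- expand.grid(k = seq(0, 1, 0.25), c = seq(0, 1, 0.25))
  rp <- relative_probability(fake, grid$k, grid$c)
  expect_true(all(is.finite(rp) & rp > 0))

  # zero contrasts: ratio identically one
  null_fake <- fake
  null_fake$coefficients$estimate[5:8] <- 0
  expect_equal(relative_probability(null_fake, grid$k, grid$c),
               rep(1, nrow(grid)), tolerance = 1e-12)
})
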