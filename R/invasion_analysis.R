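# The statistical surface: Kruskal-Wallis group comparisons across invaded /
# uninvaded networks, prevalence trends, interaction-level regressions, and
# the empirical-vs-randomized mixed-effects logistic contrast of which
# pollinators attach to exotic plants.

#' Kruskal-Wallis comparison of a property between two groups
#'
#' Rank-sum H statistic with tie correction, referred to a chi-squared
#' distribution with 1 degree of freedom (two groups).
#'
#' @param values numeric property values, one per network (or species).
#' @param invaded_flags logical group membership, same length.
#' @return list with `property_n` (group sizes), `chi_sq`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, invaded_flags) {
  stopifnot(length(values) == length(invaded_flags))
  ok <- !is.na(values)
  values <- values[ok]; invaded_flags <- invaded_flags[ok]
  if (sum(invaded_flags) == 0 || sum(!invaded_flags) == 0) {
    stop("both groups must be non-empty")
  }
  kt <- kruskal.test(values, factor(invaded_flags))
  list(group_sizes = c(invaded = sum(invaded_flags), uninvaded = sum(!invaded_flags)),
       chi_sq = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Exotic-prevalence trends across networks
#'
#' Rank-correlation (Spearman) tests of (a) endemic plant richness against
#' the number of exotic plants, and (b) the exotic proportion of the plant
#' community against total richness S, plant richness P and pollinator
#' richness A.
#'
#' @param S,P,A per-network richness values.
#' @param n_exotic per-network exotic plant counts.
#' @return `data.frame` with one row per test: comparison, rho, p_value,
#'   sign, undefined.
#' @export
exotic_prevalence_trends <- function(S, P, A, n_exotic) {
  n <- length(n_exotic)
  stopifnot(length(S) == n, length(P) == n, length(A) == n)
  invaded <- n_exotic > 0
  if (sum(invaded) < 3) stop("prevalence trends need >= 3 invaded networks")
  endemic <- P - n_exotic
  prop_exotic <- n_exotic / P
  one <- function(label, x, y) {
    if (length(unique(x)) < 2 || length(unique(y)) < 2) {
      return(data.frame(comparison = label, rho = NA_real_, p_value = NA_real_,
                        sign = NA_integer_, undefined = TRUE))
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    data.frame(comparison = label, rho = unname(ct$estimate),
               p_value = ct$p.value, sign = sign(unname(ct$estimate)),
               undefined = FALSE)
  }
  rbind(
    one("endemic_richness_vs_n_exotic", endemic[invaded], n_exotic[invaded]),
    one("exotic_proportion_vs_S", S[invaded], prop_exotic[invaded]),
    one("exotic_proportion_vs_P", P[invaded], prop_exotic[invaded]),
    one("exotic_proportion_vs_A", A[invaded], prop_exotic[invaded]))
}

#' Binomial regression of dependences on exotic status
#'
#' Logit-link binomial model of the dependence proportion on the exotic
#' indicator. `side = "plant"` regresses each plant's dependence on its own
#' status (the paper-direction result is a negative coefficient: exotic
#' plants spread their visits more evenly). `side = "pollinator"` regresses
#' the pollinator's dependence on the partner plant's status.
#'
#' @param records an interaction table from [dependences()] or
#'   [interaction_table()] (possibly several networks row-bound).
#' @param side `"plant"` or `"pollinator"`.
#' @return list with `coefficient` (log-odds difference, exotic vs native),
#'   `z`, `p_value`, `n`, `degenerate`.
#' @export
dependence_regression <- function(records, side = c("plant", "pollinator")) {
  side <- match.arg(side)
  y <- if (side == "plant") records$d_plant else records$d_pollinator
  x <- records$plant_exotic
  if (length(unique(x)) < 2) stop("both exotic and native links are required")
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  s <- summary(fit)$coefficients
  degenerate <- nrow(s) < 2 || !is.finite(s["xTRUE", "Std. Error"]) ||
    s["xTRUE", "Std. Error"] > 1e3 || var(y) == 0
  list(coefficient = unname(coef(fit)["xTRUE"]),
       z = if (degenerate) NA_real_ else unname(s["xTRUE", "z value"]),
       p_value = if (degenerate) NA_real_ else unname(s["xTRUE", "Pr(>|z|)"]),
       n = length(y), degenerate = degenerate)
}

#' Linear regression of log-preferences on exotic status
#'
#' Ordinary least squares of log(Gamma) on the exotic indicator with a
#' two-sided t test on the slope.
#'
#' @param records an interaction table from [interaction_table()].
#' @return list with `coefficient`, `t`, `p_value`, `n`, `undefined`.
#' @export
preference_regression <- function(records) {
  y <- log(records$gamma)
  x <- records$plant_exotic
  if (length(unique(x)) < 2) stop("both exotic and native links are required")
  if (var(y) == 0) {
    return(list(coefficient = 0, t = NA_real_, p_value = NA_real_,
                n = length(y), undefined = TRUE))
  }
  fit <- lm(y ~ x)
  s <- summary(fit)$coefficients
  list(coefficient = unname(coef(fit)["xTRUE"]),
       t = unname(s["xTRUE", "t value"]),
       p_value = unname(s["xTRUE", "Pr(>|t|)"]),
       n = length(y), undefined = FALSE)
}

#' Which pollinators touch an exotic plant
#'
#' @param net a `bipartite_network` with at least one exotic plant.
#' @return named logical vector over pollinators: `TRUE` iff the pollinator
#'   has a positive-weight link to an exotic plant.
#' @export
exotic_link_indicator <- function(net) {
  if (!any(net$exotic)) {
    stop("network '", net$network_id, "' has no exotic plants; ",
         "exclude it from the attachment analysis")
  }
  b <- binary_structure(net)
  colSums(b[net$exotic, , drop = FALSE]) > 0
}

# Pollinator-level predictors for one network instance: ranked degree k and
# ranked nestedness-contribution c (rank of the z-score), plus the exotic
# link indicator. c_reps controls the focal-randomization ensemble size.
pollinator_predictors <- function(net, c_reps = 100, rng_seed = 1L) {
  b <- binary_structure(net)
  polls <- colnames(b)
  k <- rank_normalize(colSums(b))
  z <- contribution_zscores(net, polls, n_reps = c_reps, rng_seed = rng_seed)
  c_rank <- rank_normalize(z)
  data.frame(pollinator = polls, k = k, c = c_rank, z = unname(z),
             stringsAsFactors = FALSE)
}

#' Assemble the stacked observation table for the attachment model
#'
#' One row per pollinator per network instance (1 empirical + n_reps swap
#' replicates per invaded network), with the exotic-link indicator y, ranked
#' degree k, ranked nestedness contribution c, the is_random dummy, the
#' network id and the replicate index. Swap replicates preserve degrees, so
#' k is identical across instances of a network; c is recomputed per
#' replicate (with a reduced contribution ensemble, `c_reps`, for runtime).
#'
#' @param networks list of invaded `bipartite_network`s.
#' @param n_reps swap replicates per network (the contrast uses 100).
#' @param c_reps focal-randomization ensemble size behind each c (default
#'   25; reduced relative to the empirical default to keep runtime linear).
#' @param rng_seed master seed.
#' @return `data.frame` with columns y, k, c, is_random, network, replicate,
#'   pollinator.
#' @export
assemble_model_table <- function(networks, n_reps = 100, c_reps = 25,
                                 rng_seed = 1L) {
  stopifnot(length(networks) >= 1)
  set.seed(rng_seed)
  rows <- list()
  for (net in networks) {
    if (!any(net$exotic)) {
      stop("network '", net$network_id, "' has no exotic plants")
    }
    seeds <- sample.int(.Machine$integer.max, n_reps + 1)
    emp <- pollinator_predictors(net, c_reps = c_reps, rng_seed = seeds[1])
    rows[[length(rows) + 1]] <- data.frame(
      y = as.integer(unname(exotic_link_indicator(net))),
      k = emp$k, c = emp$c, is_random = 0L,
      network = net$network_id, replicate = 0L,
      pollinator = emp$pollinator, stringsAsFactors = FALSE)
    ens <- build_ensemble(net, "swap", n_reps = n_reps, rng_seed = seeds[1])
    for (r in seq_len(n_reps)) {
      rep_net <- ens$replicates[[r]]
      rp <- pollinator_predictors(rep_net, c_reps = c_reps, rng_seed = seeds[r + 1])
      rows[[length(rows) + 1]] <- data.frame(
        y = as.integer(unname(exotic_link_indicator(rep_net))),
        k = rp$k, c = rp$c, is_random = 1L,
        network = net$network_id, replicate = r,
        pollinator = rp$pollinator, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (anyNA(out$c)) stop("undefined nestedness contribution for some pollinator")
  rownames(out) <- NULL
  out
}

#' Fit the mixed-effects logistic model of exotic-plant attachment
#'
#' Logistic regression of the probability that a pollinator interacts with
#' an exotic plant,
#' \deqn{\mathrm{logit}(p) = \alpha + \beta k + \gamma c + \delta k c + n,}
#' with a random intercept n per network identity, fitted jointly on the
#' empirical and randomized instances via is_random dummies. The starred
#' coefficients (the is_random interactions) measure how the randomized
#' ensemble differs from the empirical networks; the randomized-network
#' coefficients are reconstructed as sums (alpha + alpha*, ...).
#'
#' @param table a stacked table from [assemble_model_table()] (columns y, k,
#'   c, is_random, network).
#' @return an `exotic_link_model`: list with `fit` (the `lme4::glmer`
#'   object), `coefficients` (8-row data.frame: parameter, estimate,
#'   std_error, z, p_value), `random_table` (the reconstructed
#'   randomized-network rows), `converged`, `separation`.
#' @export
fit_exotic_link_model <- function(table) {
  stopifnot(all(c("y", "k", "c", "is_random", "network") %in% names(table)))
  if (length(unique(table$is_random)) < 2) {
    stop("both empirical and randomized instances are required")
  }
  if (length(unique(table$network)) < 2) {
    stop("the network random intercept needs >= 2 networks")
  }
  fit <- lme4::glmer(y ~ k * c * is_random + (1 | network),
                     data = table, family = binomial(),
                     control = lme4::glmerControl(calc.derivs = FALSE))
  sm <- summary(fit)$coefficients
  map <- c("(Intercept)" = "alpha", "k" = "beta", "c" = "gamma",
           "k:c" = "delta", "is_random" = "alpha_star",
           "k:is_random" = "beta_star", "c:is_random" = "gamma_star",
           "k:c:is_random" = "delta_star")
  ord <- names(map)
  if (!all(ord %in% rownames(sm))) stop("unexpected fixed-effect layout: ",
                                        paste(rownames(sm), collapse = ", "))
  coefs <- data.frame(parameter = unname(map),
                      estimate = sm[ord, "Estimate"],
                      std_error = sm[ord, "Std. Error"],
                      z = sm[ord, "z value"],
                      p_value = sm[ord, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  # Randomized-network rows of the report are sums of base + starred terms,
  # with standard errors from the fixed-effect covariance.
  V <- as.matrix(vcov(fit))
  base <- c("(Intercept)", "k", "c", "k:c")
  star <- c("is_random", "k:is_random", "c:is_random", "k:c:is_random")
  rnd <- data.frame(
    parameter = c("alpha+alpha_star", "beta+beta_star", "gamma+gamma_star",
                  "delta+delta_star"),
    estimate = sm[base, "Estimate"] + sm[star, "Estimate"],
    std_error = sqrt(diag(V)[base] + diag(V)[star] +
                       2 * V[cbind(base, star)]),
    row.names = NULL, stringsAsFactors = FALSE)
  rnd$z <- rnd$estimate / rnd$std_error
  rnd$p_value <- 2 * stats::pnorm(-abs(rnd$z))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  sep <- any(abs(sm[, "Estimate"]) > 15)
  structure(list(fit = fit, coefficients = coefs, random_table = rnd,
                 converged = conv, separation = sep,
                 ranef_var = unname(as.data.frame(lme4::VarCorr(fit))$vcov[1]),
                 n = nrow(table)),
            class = "exotic_link_model")
}

#' @export
print.exotic_link_model <- function(x, ...) {
  cat("Mixed-effects logistic model of exotic-plant attachment\n")
  cat(sprintf("  n = %d observations; random-intercept variance = %.4g\n",
              x$n, x$ranef_var))
  print(x$coefficients, digits = 4)
  cat("Randomized-network (reconstructed) rows:\n")
  print(x$random_table, digits = 4)
  invisible(x)
}

model_coef <- function(result, which) {
  cf <- result$coefficients
  setNames(cf$estimate, cf$parameter)[which]
}

#' Predicted attachment probability
#'
#' Fixed-effect prediction (random intercept at 0) of the probability that a
#' pollinator with ranked degree k and ranked contribution c links to an
#' exotic plant.
#'
#' @param result an `exotic_link_model`.
#' @param k,c values in [0, 1] (vectorized).
#' @param type `"empirical"` or `"random"`.
#' @return predicted probabilities.
#' @export
predict_attachment <- function(result, k, c, type = c("empirical", "random")) {
  type <- match.arg(type)
  e <- model_coef(result, c("alpha", "beta", "gamma", "delta"))
  if (type == "random") {
    e <- e + model_coef(result, c("alpha_star", "beta_star", "gamma_star",
                                  "delta_star"))
  }
  plogis(e[1] + e[2] * k + e[3] * c + e[4] * k * c)
}

#' Relative attachment probability (empirical vs randomized)
#'
#' The ratio between the predicted probability for the empirical data and
#' the predicted probability for the randomized data, at the same (k, c)
#' and with the random effect at 0. A ratio above 1 means the pollinator
#' class links to exotic plants more often than expected by chance.
#'
#' @param result an `exotic_link_model`.
#' @param k,c values in [0, 1] (vectorized).
#' @return positive ratio(s).
#' @export
relative_probability <- function(result, k, c) {
  unname(predict_attachment(result, k, c, "empirical") /
           predict_attachment(result, k, c, "random"))
}
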