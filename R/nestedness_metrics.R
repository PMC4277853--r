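# Network-level structure: connectance family, NODF nestedness, relative
# nestedness against the averaged-fill null, and per-species nestedness
# contribution z-scores.

#' NODF nestedness of a bipartite network
#'
#' Nestedness based on overlap and decreasing fill. For every ordered pair of
#' rows (u, v) with degree(u) > degree(v) > 0 the paired term is
#' 100 * |shared partners| / degree(v); pairs with equal degrees (or an empty
#' lower member) contribute 0. The same is computed over column pairs, and
#' \deqn{N = \frac{\sum \mathrm{paired\ terms}}{P(P-1)/2 + A(A-1)/2}}
#' giving a value in [0, 100]. Quantitative weights are binarized at
#' weight > 0: NODF is a binary-structure metric.
#'
#' @param net a `bipartite_network` or a binary matrix.
#' @return NODF in [0, 100].
#' @export
nodf <- function(net) {
  b <- if (inherits(net, "bipartite_network")) binary_structure(net) else (as.matrix(net) > 0) * 1
  if (nrow(b) < 2 || ncol(b) < 2) {
    stop("NODF is undefined for fewer than 2 rows or 2 columns")
  }
  (nodf_half(b) + nodf_half(t(b))) /
    (choose(nrow(b), 2) + choose(ncol(b), 2))
}

# Sum of paired NODF terms over the row pairs of b (call on t(b) for columns).
# shared[u, v] = |partners of u AND v| via tcrossprod; the decreasing-fill
# condition k_u > k_v selects which ordering of each unordered pair counts.
nodf_half <- function(b) {
  k <- rowSums(b)
  shared <- tcrossprod(b)
  ku <- outer(k, k, ">")          # TRUE where row u strictly fills more than v
  denom <- matrix(k, nrow(b), nrow(b), byrow = TRUE)  # degree of v
  terms <- ifelse(ku & denom > 0, 100 * shared / ifelse(denom > 0, denom, 1), 0)
  sum(terms)
}

#' Relative nestedness
#'
#' \eqn{N^* = (N - \bar N) / \bar N}, where \eqn{\bar N} is the mean NODF over
#' an averaged-fill (cell model) ensemble: the degree to which nestedness
#' exceeds the amount expected at random.
#'
#' @param net a connected `bipartite_network`.
#' @param n_reps ensemble size (default 1000).
#' @param rng_seed integer seed.
#' @return list with `N`, `N_star` (NA with `undefined = TRUE` when the
#'   ensemble mean is 0), `null_mean`, `null_sd`, `n_reps`, `seed`.
#' @export
relative_nestedness <- function(net, n_reps = 1000, rng_seed = 1L) {
  stopifnot(n_reps >= 2)
  N <- nodf(net)
  ens <- build_ensemble(net, "cell_model", n_reps = n_reps, rng_seed = rng_seed)
  null_N <- vapply(ens$replicates, nodf, 0)
  nbar <- mean(null_N)
  list(N = N,
       N_star = if (nbar > 0) (N - nbar) / nbar else NA_real_,
       undefined = !(nbar > 0),
       null_mean = nbar, null_sd = sd(null_N),
       n_reps = n_reps, seed = rng_seed)
}

#' Per-species nestedness contribution
#'
#' The degree to which the observed nestedness of the network changes when
#' randomizing just the interactions of the focal species: the z-score
#' \eqn{z_i = (N - \mu_i)/\sigma_i} of observed NODF against an ensemble in
#' which only the focal species' links are redrawn under the averaged-fill
#' model. Positive z means the species' observed links raise nestedness above
#' its random rewiring (a strong contributor).
#'
#' @param net a connected `bipartite_network`.
#' @param species a plant or pollinator label.
#' @param n_reps focal-randomization ensemble size (default 100).
#' @param rng_seed integer seed.
#' @param probs optional precomputed [cell_probabilities()].
#' @return list with `species`, `guild`, `observed_N`, `mu`, `sigma`, `z`
#'   (NA with `undefined = TRUE` when sigma is 0), `n_reps`, `seed`.
#' @export
nestedness_contribution <- function(net, species, n_reps = 100, rng_seed = 1L,
                                    probs = NULL) {
  stopifnot(n_reps >= 2)
  validate_network(net)
  N <- nodf(net)
  if (is.null(probs)) probs <- cell_probabilities(net)
  set.seed(rng_seed)
  null_N <- vapply(seq_len(n_reps), function(r) {
    nodf(randomize_focal_species(net, species, probs = probs))
  }, 0)
  mu <- mean(null_N)
  sigma <- sd(null_N)
  guild <- if (species %in% rownames(net$weights)) "plant" else "pollinator"
  list(species = species, guild = guild, observed_N = N, mu = mu, sigma = sigma,
       z = if (sigma > 0) (N - mu) / sigma else NA_real_,
       undefined = !(sigma > 0), n_reps = n_reps, seed = rng_seed)
}

# Contribution z-scores for many species sharing one cell-probability matrix.
# Returns a named vector (NA where sigma = 0).
contribution_zscores <- function(net, species, n_reps = 100, rng_seed = NULL) {
  probs <- cell_probabilities(net)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  vapply(species, function(s) {
    nestedness_contribution_stream(net, s, n_reps, probs)
  }, 0)
}

# Internal: like nestedness_contribution but consuming the ambient RNG stream
# (no reseed per species) so a whole table derives from one seed.
nestedness_contribution_stream <- function(net, species, n_reps, probs) {
  N <- nodf(net)
  null_N <- vapply(seq_len(n_reps), function(r) {
    nodf(randomize_focal_species(net, species, probs = probs))
  }, 0)
  sigma <- sd(null_N)
  if (sigma > 0) (N - mean(null_N)) / sigma else NA_real_
}

#' Rank-normalize a vector to [0, 1]
#'
#' Average ranks are assigned to ties, then affinely mapped so the smallest
#' value is 0 and the largest is 1. A constant vector (or a single value)
#' maps to 0.5 by convention. `NA`s propagate.
#'
#' @param values numeric vector (length >= 1).
#' @return numeric vector in [0, 1].
#' @export
rank_normalize <- function(values) {
  if (length(values) == 0) stop("rank_normalize needs at least one value")
  ok <- !is.na(values)
  r <- rank(values[ok], ties.method = "average")
  out <- rep(NA_real_, length(values))
  if (sum(ok) == 0) return(out)
  if (max(r) == min(r)) {
    out[ok] <- 0.5
  } else {
    out[ok] <- (r - min(r)) / (max(r) - min(r))
  }
  out
}

#' Network-level metric row
#'
#' Computes the full network-level property set: S, P, A, R, L, connectance
#' C = L/(PA), links per plant C_P = L/P, links per pollinator C_A = L/A,
#' NODF N and relative nestedness N*.
#'
#' @param net a connected `bipartite_network`.
#' @param n_null_reps ensemble size behind N* (default 1000).
#' @param rng_seed integer seed for the N* ensemble.
#' @return one-row `data.frame` with columns network_id, S, P, A, R, L, C,
#'   C_P, C_A, N, N_star, null_mean_N, null_sd_N, n_reps, seed.
#' @export
network_metrics <- function(net, n_null_reps = 1000, rng_seed = 1L) {
  sz <- network_size(net)
  rn <- relative_nestedness(net, n_reps = n_null_reps, rng_seed = rng_seed)
  data.frame(network_id = net$network_id, S = sz$S, P = sz$P, A = sz$A,
             R = sz$R, L = sz$L, C = sz$L / (sz$P * sz$A),
             C_P = sz$L / sz$P, C_A = sz$L / sz$A,
             N = rn$N, N_star = rn$N_star,
             null_mean_N = rn$null_mean, null_sd_N = rn$null_sd,
             n_reps = n_null_reps, seed = rng_seed,
             stringsAsFactors = FALSE)
}
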