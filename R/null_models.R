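# Null models: the probabilistic averaged-fill cell model (used for relative
# nestedness and nestedness contributions) and degree-preserving checkerboard
# swaps (used for the pollinator-level contrast). All samplers are pure
# functions of (input, seed).

#' Averaged-fill cell probabilities
#'
#' For each cell of the binary structure, the interaction probability is the
#' average of the row fill and the column fill:
#' \deqn{p_{ij} = \frac{1}{2}\left(\frac{k_i}{A} + \frac{k_j}{P}\right)}
#' where \eqn{k_i} is plant i's degree, \eqn{k_j} pollinator j's degree,
#' and P, A the guild sizes. The total \eqn{\sum_{ij} p_{ij} = L} exactly.
#'
#' @param net a connected `bipartite_network`.
#' @return a `cell_probability_matrix`: list with `probs` (P x A matrix in
#'   [0, 1]) and `network_id`.
#' @export
cell_probabilities <- function(net) {
  validate_network(net)
  b <- binary_structure(net)
  P <- nrow(b); A <- ncol(b)
  p <- 0.5 * (outer(rowSums(b) / A, colSums(b) / P, "+"))
  dimnames(p) <- dimnames(b)
  structure(list(probs = p, network_id = net$network_id),
            class = "cell_probability_matrix")
}

#' Sample one replicate from the cell model
#'
#' Each cell is an independent Bernoulli draw with the averaged-fill
#' probability. Draws producing an empty row or column are rejected and
#' redrawn, because nestedness is ill-defined on empty guild members.
#'
#' @param probs a `cell_probability_matrix` from [cell_probabilities()].
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @param max_retries rejection budget for empty rows/columns.
#' @return a qualitative `bipartite_network` replicate.
#' @export
sample_cell_model <- function(probs, rng_seed = NULL, max_retries = 1000) {
  stopifnot(inherits(probs, "cell_probability_matrix"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  p <- probs$probs
  for (i in seq_len(max_retries)) {
    draw <- matrix(rbinom(length(p), 1, p), nrow(p), ncol(p), dimnames = dimnames(p))
    if (all(rowSums(draw) > 0) && all(colSums(draw) > 0)) {
      return(bipartite_network(draw, quantitative = FALSE,
                               network_id = paste0(probs$network_id, "_cellnull")))
    }
  }
  stop("degenerate null for network '", probs$network_id,
       "': no connected replicate in ", max_retries, " draws")
}

#' Randomize the links of a single focal species
#'
#' Redraws the focal species' k links as a weighted sample (without
#' replacement) of k distinct partners, with selection probability
#' proportional to the averaged-fill cell probability for that species' row
#' (or column). Everything else is untouched; the focal degree is preserved.
#' This is the elementary move behind per-species nestedness contributions.
#'
#' @param net a connected `bipartite_network`.
#' @param focal label of a plant or pollinator.
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @param probs optional precomputed [cell_probabilities()] result.
#' @return a `bipartite_network` with only the focal row/column changed.
#' @export
randomize_focal_species <- function(net, focal, rng_seed = NULL, probs = NULL) {
  validate_network(net)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(probs)) probs <- cell_probabilities(net)
  b <- binary_structure(net)
  is_plant <- focal %in% rownames(b)
  is_poll <- focal %in% colnames(b)
  if (!is_plant && !is_poll) stop("unknown species label: ", focal)
  if (is_plant) {
    k <- sum(b[focal, ])
    new_partners <- sample(ncol(b), k, prob = probs$probs[focal, ])
    b[focal, ] <- 0
    b[focal, new_partners] <- 1
  } else {
    k <- sum(b[, focal])
    new_partners <- sample(nrow(b), k, prob = probs$probs[, focal])
    b[, focal] <- 0
    b[new_partners, focal] <- 1
  }
  net2 <- bipartite_network(b, quantitative = FALSE, exotic = net$exotic,
                            location = net$location,
                            network_id = net$network_id, validate = FALSE)
  # the focal rewiring may strand a partner; downstream metrics tolerate it
  net2
}

#' Degree-preserving swap randomization
#'
#' Runs a chain of attempted checkerboard swaps (2x2 submatrices
#' `[[1,0],[0,1]] <-> [[0,1],[1,0]]`) on the binary structure. Row and
#' column degree sequences, and hence connectance, are preserved exactly.
#' Weights of quantitative networks are not randomized: the pollinator-level
#' analysis uses only link presence.
#'
#' @param net a `bipartite_network` with >= 2 plants and >= 2 pollinators.
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @param n_attempts attempted swaps; default 10 x L (common mixing
#'   heuristic; the literature source of the method names no chain length).
#' @return a qualitative `bipartite_network`; if no swappable checkerboard
#'   exists the source structure is returned unchanged with a warning.
#' @export
swap_randomize <- function(net, rng_seed = NULL, n_attempts = NULL) {
  validate_network(net)
  b <- binary_structure(net)
  if (nrow(b) < 2 || ncol(b) < 2) stop("swap null needs >= 2 rows and >= 2 columns")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(n_attempts)) n_attempts <- 10L * sum(b)
  if (!has_checkerboard(mode_int(b))) {
    warning("no swappable checkerboard in network '", net$network_id,
            "': swap null is degenerate, returning source unchanged")
    out <- b
  } else {
    out <- swap_chain(mode_int(b), as.integer(n_attempts))
    attr(out, "accepted") <- NULL
    dimnames(out) <- dimnames(b)
  }
  bipartite_network(out * 1, quantitative = FALSE, exotic = net$exotic,
                    location = net$location,
                    network_id = paste0(net$network_id, "_swap"))
}

mode_int <- function(m) {
  storage.mode(m) <- "integer"
  m
}

#' Build an ensemble of randomized networks
#'
#' @param net source `bipartite_network`.
#' @param method one of `"cell_model"`, `"swap"`, `"focal_species"`.
#' @param n_reps number of replicates (the pollinator-level contrast uses
#'   100 swap replicates).
#' @param rng_seed integer master seed; per-replicate seeds are derived from
#'   it so the ensemble is reproducible.
#' @param focal focal species label (required for `method = "focal_species"`).
#' @param thin for `method = "swap"`: attempted swaps between successive
#'   replicates of the single chain (default 10 x L, also used as burn-in).
#' @return a `random_ensemble`: list with `replicates`, `method`, `n_reps`,
#'   `seed`, `network_id`.
#' @export
build_ensemble <- function(net, method = c("cell_model", "swap", "focal_species"),
                           n_reps = 100, rng_seed = 1L, focal = NULL, thin = NULL) {
  method <- match.arg(method)
  stopifnot(n_reps >= 1)
  validate_network(net)
  set.seed(rng_seed)
  reps <- vector("list", n_reps)
  if (method == "swap") {
    # one thinned chain: burn-in of `thin` attempts, then a replicate every
    # `thin` further attempts
    b <- binary_structure(net)
    if (is.null(thin)) thin <- 10L * sum(b)
    if (!has_checkerboard(mode_int(b))) {
      warning("no swappable checkerboard in network '", net$network_id,
              "': swap ensemble replicates equal the source")
      reps <- replicate(n_reps, swap_strip(net, b), simplify = FALSE)
    } else {
      cur <- mode_int(b)
      for (r in seq_len(n_reps)) {
        cur <- swap_chain(cur, as.integer(thin))
        attr(cur, "accepted") <- NULL
        dimnames(cur) <- dimnames(b)
        reps[[r]] <- swap_strip(net, cur)
      }
    }
  } else if (method == "cell_model") {
    probs <- cell_probabilities(net)
    for (r in seq_len(n_reps)) reps[[r]] <- sample_cell_model(probs)
  } else {
    if (is.null(focal)) stop("focal species label required for focal_species ensemble")
    probs <- cell_probabilities(net)
    for (r in seq_len(n_reps)) {
      reps[[r]] <- randomize_focal_species(net, focal, probs = probs)
    }
  }
  structure(list(replicates = reps, method = method, n_reps = n_reps,
                 seed = rng_seed, focal = focal, network_id = net$network_id),
            class = "random_ensemble")
}

swap_strip <- function(net, b) {
  bipartite_network(b * 1, quantitative = FALSE, exotic = net$exotic,
                    location = net$location,
                    network_id = paste0(net$network_id, "_swap"),
                    validate = FALSE)
}

#' @export
print.random_ensemble <- function(x, ...) {
  cat(sprintf("<random_ensemble> %s: %d replicates of '%s' (method = %s, seed = %s)\n",
              x$method, x$n_reps, x$network_id, x$method, x$seed))
  invisible(x)
}

#' Serialize an ensemble to a directory of matrix files plus a manifest
#'
#' @param ensemble a `random_ensemble`.
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "random_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(ensemble$replicates)) {
    write_network(ensemble$replicates[[r]],
                  file.path(dir, sprintf("replicate_%04d.tsv", r)))
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(network_id = ensemble$network_id, method = ensemble$method,
         n_reps = ensemble$n_reps, seed = ensemble$seed,
         focal = ensemble$focal),
    manifest, auto_unbox = TRUE, null = "null")
  invisible(manifest)
}
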