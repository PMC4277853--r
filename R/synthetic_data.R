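# Synthetic networks, phylogenies and multi-network study sets with the
# statistical structure the analysis assumes: heterogeneous degrees with
# tunable nestedness, averaged-fill link formation, overdispersed mass-action
# weights, and a planted logistic rule attaching exotic plants to pollinators
# by degree and nestedness contribution.

#' Specification for one synthetic network
#'
#' @param n_plants,n_pollinators guild sizes (>= 2).
#' @param target_connectance expected fraction of realized links, in (0, 1).
#' @param nestedness_strength degree-heterogeneity exponent (>= 0). 0 gives
#'   homogeneous expected degrees (relative nestedness ~ 0); larger values
#'   give power-law-like expected degrees and increasingly nested structure.
#' @param quantitative draw visit counts on observed links?
#' @param weight_dispersion overdispersion of visit counts (> 0); the count
#'   part is negative binomial with size = 1/weight_dispersion (geometric at
#'   1).
#' @param exotic_fraction fraction of plants to flag and rewire as exotic.
#' @param attachment_coeffs planted logistic attachment rule (alpha, beta,
#'   gamma, delta) on ranked pollinator degree k and contribution c.
#' @param mean_visits mean visit count per observed link (> 1).
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_plants = 15, n_pollinators = 30,
                           target_connectance = 0.15,
                           nestedness_strength = 1,
                           quantitative = FALSE,
                           weight_dispersion = 1,
                           exotic_fraction = 0,
                           attachment_coeffs = c(alpha = -3.69, beta = 1.86,
                                                 gamma = -3.69, delta = 5.60),
                           mean_visits = 4) {
  stopifnot(n_plants >= 2, n_pollinators >= 2,
            target_connectance > 0, target_connectance < 1,
            nestedness_strength >= 0, weight_dispersion > 0,
            exotic_fraction >= 0, exotic_fraction < 1,
            length(attachment_coeffs) == 4, mean_visits > 1)
  structure(list(n_plants = n_plants, n_pollinators = n_pollinators,
                 target_connectance = target_connectance,
                 nestedness_strength = nestedness_strength,
                 quantitative = quantitative,
                 weight_dispersion = weight_dispersion,
                 exotic_fraction = exotic_fraction,
                 attachment_coeffs = attachment_coeffs,
                 mean_visits = mean_visits),
            class = "synthetic_spec")
}

# Expected degrees proportional to rank^(-eta), rescaled to sum to L and
# clamped to the feasible range (0, kmax].
expected_degrees <- function(n, eta, L, kmax) {
  x <- seq_len(n)^(-eta)
  k <- L * x / sum(x)
  for (it in 1:50) {
    k <- pmin(k, kmax)
    excess <- L - sum(k)
    if (abs(excess) < 1e-9) break
    free <- k < kmax
    if (!any(free)) break
    k[free] <- k[free] * (1 + excess / sum(k[free]))
    k <- pmax(k, 1e-6)
  }
  pmin(k, kmax)
}

#' Generate one synthetic bipartite network
#'
#' Draws power-law-like expected degrees for both guilds (exponent =
#' `nestedness_strength`), forms links as independent Bernoulli draws from
#' the averaged-fill cell probabilities of those expected degrees, and
#' rejects draws with empty rows or columns. Quantitative weights on
#' observed links are 1 plus an overdispersed count whose mean is the
#' product of lognormal plant and pollinator abundance factors (a rank-one
#' mass-action structure, so planted preferences are neutral).
#'
#' @param spec a [synthetic_spec()].
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @param network_id label for the result.
#' @param max_retries rejection budget for empty rows/columns.
#' @return a validated `bipartite_network` (exotic plants planted when
#'   `spec$exotic_fraction > 0`, via [plant_exotic_attachment()]).
#' @export
generate_network <- function(spec, rng_seed = NULL, network_id = "synthetic",
                             max_retries = 1000) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  P <- spec$n_plants; A <- spec$n_pollinators
  L <- spec$target_connectance * P * A
  if (L < max(P, A) + 1) {
    stop("infeasible spec: expected links (", round(L, 1),
         ") cannot connect ", P, " plants and ", A, " pollinators")
  }
  kp <- expected_degrees(P, spec$nestedness_strength, L, A)
  ka <- expected_degrees(A, spec$nestedness_strength, L, P)
  p <- 0.5 * outer(kp / A, ka / P, "+")
  p <- pmin(pmax(p, 0), 1)
  b <- matrix(rbinom(length(p), 1, p), P, A)
  # Empty rows/columns are rejected and redrawn line-wise from the same cell
  # probabilities (redrawing whole matrices almost surely fails at realistic
  # pollination sparsity); a line whose probabilities are too small to
  # connect in `max_retries` redraws gets a single link placed proportional
  # to its cell probabilities.
  redraw_line <- function(pv) {
    for (i in seq_len(max_retries)) {
      d <- rbinom(length(pv), 1, pv)
      if (sum(d) > 0) return(d)
    }
    d <- numeric(length(pv))
    d[sample(length(pv), 1, prob = pmax(pv, 1e-12))] <- 1
    d
  }
  for (pass in seq_len(max_retries)) {
    er <- which(rowSums(b) == 0); ec <- which(colSums(b) == 0)
    if (length(er) == 0 && length(ec) == 0) break
    for (i in er) b[i, ] <- redraw_line(p[i, ])
    for (j in ec) b[, j] <- redraw_line(p[, j])
    if (pass == max_retries) {
      stop("infeasible spec: could not connect all species in ",
           max_retries, " passes")
    }
  }
  dimnames(b) <- list(paste0("plant_", seq_len(P)),
                      paste0("poll_", seq_len(A)))
  w <- b
  if (spec$quantitative) {
    u <- rlnorm(P, 0, 0.5); v <- rlnorm(A, 0, 0.5)
    mu <- spec$mean_visits * outer(u, v) / mean(outer(u, v))
    idx <- which(b > 0)
    w[idx] <- 1 + rnbinom(length(idx), size = 1 / spec$weight_dispersion,
                          mu = pmax(mu[idx] - 1, 0.1))
  }
  net <- bipartite_network(w, quantitative = spec$quantitative,
                           network_id = network_id)
  if (spec$exotic_fraction > 0) {
    net <- plant_exotic_attachment(net, spec$attachment_coeffs,
                                   spec$exotic_fraction)
  }
  net
}

#' Plant exotic labels with a logistic attachment rule
#'
#' Flags a random subset of plants as exotic and rewires each exotic plant's
#' links so that pollinator j is chosen with probability proportional to
#' \eqn{\mathrm{logistic}(\alpha + \beta k_j + \gamma c_j + \delta k_j c_j)},
#' holding the plant's degree fixed (weighted sampling without replacement).
#' Pollinator ranked degree k and ranked nestedness contribution c are
#' computed on the network before any rewiring; native plants' links are
#' untouched. For quantitative networks, the rewired plant's positive
#' weights are permuted onto its new partners so its total visitation is
#' preserved.
#'
#' @param net a connected `bipartite_network`.
#' @param coeffs numeric (alpha, beta, gamma, delta).
#' @param exotic_fraction fraction of plants to flag; must yield >= 1 plant.
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @param c_reps contribution ensemble size behind c (default 25). Skipped
#'   entirely when gamma = delta = 0, where c cannot affect attachment.
#' @param max_retries redraw budget should a rewiring strand a pollinator.
#' @return a `bipartite_network` with exotic flags and rewired exotic links.
#' @export
plant_exotic_attachment <- function(net, coeffs, exotic_fraction,
                                    rng_seed = NULL, c_reps = 25,
                                    max_retries = 25) {
  validate_network(net)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  coeffs <- unname(coeffs)
  P <- nrow(net$weights); A <- ncol(net$weights)
  n_exotic <- floor(exotic_fraction * P)
  if (n_exotic < 1) {
    stop("exotic_fraction ", exotic_fraction, " selects no plant out of ", P)
  }
  exotic_plants <- sample(rownames(net$weights), n_exotic)
  b <- binary_structure(net)
  k <- rank_normalize(colSums(b))
  if (coeffs[3] == 0 && coeffs[4] == 0) {
    cc <- rep(0.5, A)   # c cannot affect attachment; skip the costly ensemble
  } else {
    z <- contribution_zscores(net, colnames(b), n_reps = c_reps)
    cc <- rank_normalize(z)
    cc[is.na(cc)] <- 0.5
  }
  prob <- plogis(coeffs[1] + coeffs[2] * k + coeffs[3] * cc +
                   coeffs[4] * k * cc)
  for (attempt in seq_len(max_retries)) {
    w <- net$weights
    for (pl in exotic_plants) {
      deg <- sum(w[pl, ] > 0)
      if (deg > A) stop("degree exceeds eligible pollinators for ", pl)
      old_w <- w[pl, w[pl, ] > 0]
      partners <- sample(A, deg, prob = prob)
      w[pl, ] <- 0
      w[pl, partners] <- unname(old_w)[sample.int(length(old_w))]
    }
    if (all(colSums(w) > 0)) break
    if (attempt == max_retries) {
      # pollinators whose only links came from rewired plants leave the
      # observed community; keep the last draw and drop them
      warning(sum(colSums(w) == 0), " pollinator(s) stranded by exotic ",
              "rewiring were dropped from network '", net$network_id, "'")
    }
  }
  out <- bipartite_network(w, quantitative = net$quantitative,
                           exotic = rownames(w) %in% exotic_plants,
                           location = net$location,
                           network_id = net$network_id, validate = FALSE)
  drop_unconnected(out)
}

#' Generate an ultrametric plant phylogeny
#'
#' Pure-birth (Yule) tree rescaled to a fixed depth, so all tips are
#' equidistant from the root (clock-like dating in arbitrary time units,
#' default 100, a Myr-scale community depth).
#'
#' @param n_taxa number of tips (>= 2).
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @param depth root-to-tip distance after rescaling.
#' @param tip_labels optional labels (default `plant_1..n`, matching
#'   [generate_network()] plant ids).
#' @return an ape `phylo` object.
#' @export
generate_phylogeny <- function(n_taxa, rng_seed = NULL, depth = 100,
                               tip_labels = NULL) {
  stopifnot(n_taxa >= 2)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  cur <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * depth / cur
  tree$tip.label <- if (is.null(tip_labels)) paste0("plant_", seq_len(n_taxa)) else tip_labels
  tree
}

#' Generate a multi-network study set
#'
#' Emulates the design of a global collection of pollination networks:
#' `n_invaded` networks carry exotic plants (planted by
#' [plant_exotic_attachment()]) and `n_uninvaded` carry none. Guild sizes
#' vary across networks (Poisson around the template means, floored at 5);
#' the invaded group's mean sizes can be shifted by `richness_shift` and its
#' degree heterogeneity by `nestedness_shift`, planting group differences
#' for the community-level comparisons. A fraction of networks
#' (`prob_quantitative`) receive quantitative weights.
#'
#' @param n_invaded,n_uninvaded group sizes (>= 1; the emulated design is
#'   25 invaded + 34 uninvaded).
#' @param template a [synthetic_spec()] giving the baseline parameters;
#'   its `exotic_fraction` (or 0.1 if unset) sets the invaded-group exotic
#'   fraction.
#' @param richness_shift relative shift of invaded-group mean sizes
#'   (0.5 = +50\% richness).
#' @param nestedness_shift additive shift of invaded-group
#'   `nestedness_strength`.
#' @param prob_quantitative probability a network is quantitative (default
#'   20/59, the emulated data set's split).
#' @param rng_seed integer seed.
#' @return list with `networks` (list of `bipartite_network`), and
#'   `manifest` (data.frame of per-network parameters and seeds).
#' @export
generate_study_set <- function(n_invaded = 25, n_uninvaded = 34,
                               template = synthetic_spec(),
                               richness_shift = 0, nestedness_shift = 0,
                               prob_quantitative = 20 / 59, rng_seed = 1L) {
  stopifnot(n_invaded >= 1, n_uninvaded >= 1)
  set.seed(rng_seed)
  n_total <- n_invaded + n_uninvaded
  invaded <- c(rep(TRUE, n_invaded), rep(FALSE, n_uninvaded))
  frac <- if (template$exotic_fraction > 0) template$exotic_fraction else 0.1
  nets <- vector("list", n_total)
  man <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    mult <- if (invaded[i]) 1 + richness_shift else 1
    np <- max(5L, rpois(1, template$n_plants * mult))
    na <- max(5L, rpois(1, template$n_pollinators * mult))
    sp <- template
    sp$n_plants <- np
    sp$n_pollinators <- na
    # small or skewed networks need higher connectance to stay connectable
    # (empirically, connectance falls with network size but is bounded below
    # by roughly one link per species)
    sp$target_connectance <- min(0.9, max(template$target_connectance,
                                          1.3 * max(np, na) / (np * na)))
    sp$nestedness_strength <- template$nestedness_strength +
      if (invaded[i]) nestedness_shift else 0
    sp$quantitative <- runif(1) < prob_quantitative
    sp$exotic_fraction <- if (invaded[i]) max(frac, 1 / np + 1e-9) else 0
    seed_i <- sample.int(.Machine$integer.max, 1)
    id <- sprintf("net_%02d_%s", i, if (invaded[i]) "inv" else "nat")
    nets[[i]] <- generate_network(sp, rng_seed = seed_i, network_id = id)
    man[[i]] <- data.frame(network_id = id, invaded = invaded[i],
                           n_plants = np, n_pollinators = na,
                           quantitative = sp$quantitative,
                           exotic_fraction = sp$exotic_fraction,
                           nestedness_strength = sp$nestedness_strength,
                           seed = seed_i, stringsAsFactors = FALSE)
  }
  list(networks = nets, manifest = do.call(rbind, man))
}

#' Simulate a stacked attachment-model table from the logistic rule
#'
#' Generates the observation table of [fit_exotic_link_model()] directly
#' from the attachment model: for each network, pollinator ranks k and c are
#' independent rank-normalized uniforms, a network intercept is drawn
#' N(0, ranef_sd), and the exotic-link indicator is Bernoulli with
#' probability logistic(alpha + beta k + gamma c + delta k c + intercept),
#' with the starred contrasts added for the randomized instances. Used for
#' coefficient-recovery checks of the fitting stage.
#'
#' @param n_networks,n_pollinators design size.
#' @param coeffs planted (alpha, beta, gamma, delta).
#' @param star_coeffs planted contrasts (default all 0: randomized instances
#'   follow the same rule).
#' @param ranef_sd standard deviation of the network random intercept.
#' @param n_random randomized instances per network (default 1).
#' @param rng_seed integer seed.
#' @return a `data.frame` accepted by [fit_exotic_link_model()].
#' @export
simulate_attachment_table <- function(n_networks = 200, n_pollinators = 50,
                                      coeffs = c(-3.69, 1.86, -3.69, 5.60),
                                      star_coeffs = c(0, 0, 0, 0),
                                      ranef_sd = 0.5, n_random = 1,
                                      rng_seed = 1L) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  coeffs <- unname(coeffs); star_coeffs <- unname(star_coeffs)
  rows <- vector("list", n_networks * (1 + n_random))
  idx <- 0
  for (g in seq_len(n_networks)) {
    b0 <- stats::rnorm(1, 0, ranef_sd)
    for (inst in 0:n_random) {
      k <- rank_normalize(runif(n_pollinators))
      cc <- rank_normalize(runif(n_pollinators))
      is_random <- as.integer(inst > 0)
      cf <- coeffs + is_random * star_coeffs
      eta <- b0 + cf[1] + cf[2] * k + cf[3] * cc + cf[4] * k * cc
      idx <- idx + 1
      rows[[idx]] <- data.frame(
        y = rbinom(n_pollinators, 1, plogis(eta)),
        k = k, c = cc, is_random = is_random,
        network = sprintf("net_%03d", g), replicate = inst,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
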