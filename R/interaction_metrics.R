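# Interaction-level metrics for quantitative networks: mutual dependences
# (proportional visitation) and mass-action interaction preferences.

require_quantitative <- function(net) {
  if (!net$quantitative) {
    stop("interaction-level metrics are restricted to quantitative networks; ",
         "network '", net$network_id, "' is qualitative")
  }
  invisible(net)
}

#' Mutual dependences of observed interactions
#'
#' For each observed link (w > 0), the dependence of plant i on pollinator j
#' is the proportion of all visits to i carried by j,
#' \eqn{d^P_{ij} = w_{ij} / \sum_{j'} w_{ij'}}, and symmetrically the
#' dependence of the pollinator on the plant,
#' \eqn{d^A_{ij} = w_{ij} / \sum_{i'} w_{i'j}}. Dependences sum to 1 within
#' each species and are generally asymmetric between partners.
#'
#' @param net a quantitative `bipartite_network`.
#' @return `data.frame` with one row per observed link: network_id, plant,
#'   pollinator, weight, d_plant, d_pollinator, plant_exotic.
#' @export
dependences <- function(net) {
  validate_network(net)
  require_quantitative(net)
  w <- net$weights
  idx <- which(w > 0, arr.ind = TRUE)
  data.frame(
    network_id = net$network_id,
    plant = rownames(w)[idx[, 1]],
    pollinator = colnames(w)[idx[, 2]],
    weight = w[idx],
    d_plant = w[idx] / rowSums(w)[idx[, 1]],
    d_pollinator = w[idx] / colSums(w)[idx[, 2]],
    plant_exotic = unname(net$exotic[idx[, 1]]),
    stringsAsFactors = FALSE)
}

#' Mass-action interaction preferences
#'
#' Quantifies how much each observed interaction deviates from a
#' random-encounter (mass-action) expectation. The visit counts are modelled
#' on the log scale by an additive species-effect decomposition over the
#' observed cells only,
#' \deqn{\log w_{ij} = m + a_i + b_j + \log\Gamma_{ij},}
#' fitted by least squares with sum-to-zero constraints on the plant effects
#' \eqn{a_i} and pollinator effects \eqn{b_j}. The preference
#' \eqn{\Gamma_{ij}} is the exponentiated residual: \eqn{\Gamma > 1} means
#' the interaction occurs more often than mass action predicts, \eqn{\Gamma
#' < 1} less often. The intercept absorbs total sampling effort, so the
#' geometric mean of \eqn{\Gamma} over observed links is exactly 1 and
#' preferences are invariant to rescaling any row or column.
#'
#' Residuals at cells with leverage ~1 (e.g. a species whose single link
#' makes its effect unidentifiable apart from the residual) are forced to 0;
#' those links are flagged `gamma_unreliable`.
#'
#' @param net a quantitative `bipartite_network` with >= 2 plants and >= 2
#'   pollinators.
#' @return the [dependences()] table with `gamma` and `gamma_unreliable`
#'   columns added.
#' @export
preferences <- function(net) {
  validate_network(net)
  require_quantitative(net)
  if (nrow(net$weights) < 2 || ncol(net$weights) < 2) {
    stop("preferences need >= 2 plants and >= 2 pollinators")
  }
  rec <- dependences(net)
  df <- data.frame(logw = log(rec$weight),
                   plant = factor(rec$plant),
                   pollinator = factor(rec$pollinator))
  fit <- lm(logw ~ plant + pollinator, data = df,
            contrasts = list(plant = "contr.sum", pollinator = "contr.sum"))
  h <- hatvalues(fit)
  rec$gamma <- exp(stats::residuals(fit))
  rec$gamma_unreliable <- h > 1 - 1e-8
  rec
}

#' Full interaction table for one network
#'
#' Dependences plus preferences in the layout of the interaction TSV report.
#'
#' @param net a quantitative `bipartite_network`.
#' @return `data.frame` with columns network_id, plant, pollinator, weight,
#'   d_plant, d_pollinator, gamma, gamma_unreliable, plant_exotic.
#' @export
interaction_table <- function(net) {
  rec <- preferences(net)
  rec[, c("network_id", "plant", "pollinator", "weight", "d_plant",
          "d_pollinator", "gamma", "gamma_unreliable", "plant_exotic")]
}
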