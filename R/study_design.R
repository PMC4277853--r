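# Parsers and summaries for the study-design tables shipped with the
# package: the exotic-species inventory (which species, where exotic, and
# in how many networks each was observed), the per-network exotic-count
# distribution, and the qualitative/quantitative network split.

#' Read the exotic species inventory table
#'
#' @param path TSV with columns species, location_where_exotic, n_networks;
#'   defaults to the copy shipped under `inst/extdata`.
#' @return `data.frame` of the table.
#' @export
read_exotic_species_table <- function(path = system.file(
  "extdata", "exotic_species_table.tsv", package = "exoticnets")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "location_where_exotic", "n_networks") %in% names(tab)))
  tab
}

#' Summarize an exotic species inventory
#'
#' @param tab table from [read_exotic_species_table()].
#' @return list: `n_records` (species-by-location rows), `n_distinct_species`
#'   (taxonomically unique names) and `total_network_records` (sum of the
#'   per-row network counts, i.e. exotic plant records across networks).
#' @export
summarize_exotic_species <- function(tab = read_exotic_species_table()) {
  list(n_records = nrow(tab),
       n_distinct_species = length(unique(tab$species)),
       total_network_records = sum(tab$n_networks))
}

#' Read the per-network exotic-count distribution
#'
#' @param path TSV with columns n_exotic_per_network, n_networks.
#' @return `data.frame` of the distribution.
#' @export
read_exotic_count_distribution <- function(path = system.file(
  "extdata", "exotic_count_distribution.tsv", package = "exoticnets")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("n_exotic_per_network", "n_networks") %in% names(tab)))
  tab
}

#' Summarize a per-network exotic-count distribution
#'
#' @param tab table from [read_exotic_count_distribution()].
#' @return list: `n_invaded_networks` (networks with >= 1 exotic plant) and
#'   `total_exotic_records` (exotic plant records summed over networks).
#' @export
summarize_exotic_counts <- function(tab = read_exotic_count_distribution()) {
  list(n_invaded_networks = sum(tab$n_networks),
       total_exotic_records = sum(tab$n_exotic_per_network * tab$n_networks))
}

#' Read the qualitative/quantitative study split
#'
#' @param path TSV with columns network_kind, n_networks.
#' @return list: `n_qualitative`, `n_quantitative`, `n_total`.
#' @export
read_study_design <- function(path = system.file(
  "extdata", "study_design.tsv", package = "exoticnets")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("network_kind", "n_networks") %in% names(tab)))
  list(n_qualitative = tab$n_networks[tab$network_kind == "qualitative"],
       n_quantitative = tab$n_networks[tab$network_kind == "quantitative"],
       n_total = sum(tab$n_networks))
}
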