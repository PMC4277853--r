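# Phylogeny-derived community metrics: plant phylogenetic diversity (mean
# distance from each plant to the plant set's most recent common ancestor)
# and per-plant phylogenetic uniqueness (mean patristic distance to the
# other plants in the same community).

resolve_taxa <- function(tree, taxa, context = "metric") {
  hit <- taxa %in% tree$tip.label
  if (!all(hit)) {
    warning("taxa not on the tree excluded from ", context, ": ",
            paste(taxa[!hit], collapse = ", "))
  }
  taxa[hit]
}

#' Phylogenetic diversity of a plant community
#'
#' Mean, over the given taxa, of the path length from each tip to the most
#' recent common ancestor of the whole taxon set. On an ultrametric (dated)
#' tree this equals the age of that ancestor.
#'
#' @param tree a `phylo` object with branch lengths (see [read_phylogeny()]).
#' @param taxa plant labels; taxa absent from the tree are excluded with a
#'   warning rather than given fabricated distances.
#' @return mean tip-to-MRCA distance, in the tree's time units.
#' @export
phylogenetic_diversity <- function(tree, taxa) {
  check_phylogeny(tree)
  taxa <- resolve_taxa(tree, unique(taxa), "phylogenetic_diversity")
  if (length(taxa) < 2) stop("phylogenetic diversity needs >= 2 resolvable taxa")
  depths <- ape::node.depth.edgelength(tree)   # distance from root
  tips <- match(taxa, tree$tip.label)
  mrca <- ape::getMRCA(tree, taxa)
  mean(depths[tips] - depths[mrca])
}

#' Phylogenetic uniqueness of a focal plant
#'
#' Arithmetic mean of the patristic distances from the focal plant to every
#' other plant in its community.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param focal focal plant label (must resolve on the tree).
#' @param others labels of the other plants in the community.
#' @return mean patristic distance, in the tree's time units.
#' @export
phylogenetic_uniqueness <- function(tree, focal, others) {
  check_phylogeny(tree)
  if (!(focal %in% tree$tip.label)) stop("focal taxon not on tree: ", focal)
  others <- setdiff(unique(others), focal)
  others <- resolve_taxa(tree, others, "phylogenetic_uniqueness")
  if (length(others) < 1) stop("phylogenetic uniqueness needs >= 1 other resolvable taxon")
  d <- patristic_distances(tree)
  mean(d[focal, others])
}

# Full patristic (tip-to-tip path length) matrix.
patristic_distances <- function(tree) {
  stats::cophenetic(tree)
}

#' Per-plant uniqueness for a whole network
#'
#' @param tree a `phylo` object.
#' @param net a `bipartite_network`; uniqueness is computed among the plants
#'   of this network only ("in its community").
#' @return named numeric vector over plants (NA for plants not on the tree).
#' @export
community_uniqueness <- function(tree, net) {
  check_phylogeny(tree)
  plants <- rownames(net$weights)
  on_tree <- plants[plants %in% tree$tip.label]
  out <- setNames(rep(NA_real_, length(plants)), plants)
  if (length(on_tree) >= 2) {
    d <- patristic_distances(tree)[on_tree, on_tree, drop = FALSE]
    out[on_tree] <- rowSums(d) / (length(on_tree) - 1)
  }
  if (length(on_tree) < length(plants)) {
    warning("plants absent from the tree get NA uniqueness: ",
            paste(setdiff(plants, on_tree), collapse = ", "))
  }
  out
}
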