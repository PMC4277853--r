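#' @useDynLib exoticnets, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef kruskal.test lm plogis qlogis quantile rbinom
#'   rnbinom rpois runif sd setNames vcov cor.test glm binomial predict
#'   hatvalues rlnorm pchisq
#' @importFrom utils read.delim write.table read.csv
"_PACKAGE"

#' Construct a bipartite plant-pollinator network
#'
#' The canonical container used by every stage of the analysis: a labelled
#' plants-by-pollinators weight matrix, a qualitative/quantitative flag,
#' per-plant exotic annotations and free-text metadata.
#'
#' @param weights numeric matrix, plants as rows, pollinators as columns,
#'   non-negative visit counts (0/1 when `quantitative = FALSE`). Must carry
#'   unique row and column names.
#' @param quantitative logical; `TRUE` when cells are visit counts.
#' @param exotic character vector of plant (row) labels flagged as exotic,
#'   or a logical vector of length `nrow(weights)`.
#' @param location free-text location metadata.
#' @param network_id unique label for the network.
#' @param validate check invariants (default `TRUE`).
#' @return an object of class `bipartite_network`.
#' @export
bipartite_network <- function(weights, quantitative = FALSE, exotic = character(),
                              location = NA_character_, network_id = "net",
                              validate = TRUE) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (is.null(rownames(weights)) || is.null(colnames(weights))) {
    stop("weights must carry plant row names and pollinator column names; ",
         "unlabelled tables are ambiguous (orientation cannot be checked)")
  }
  if (is.logical(exotic)) {
    if (length(exotic) != nrow(weights)) {
      stop("logical exotic flags must have one entry per plant row")
    }
    exotic_flags <- exotic
  } else {
    exotic_flags <- match_exotic_labels(rownames(weights), exotic)
  }
  names(exotic_flags) <- rownames(weights)
  net <- structure(
    list(weights = weights,
         quantitative = isTRUE(quantitative),
         exotic = exotic_flags,
         location = location,
         network_id = network_id),
    class = "bipartite_network")
  if (validate) validate_network(net)
  net
}

# Case-insensitive, whitespace-normalized matching of exotic labels to rows.
# Labels that match no row trigger a warning, never an error: mirrors the
# conservative rule that unresolvable plants are never considered exotic.
match_exotic_labels <- function(plant_ids, exotic_labels) {
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  flags <- norm(plant_ids) %in% norm(exotic_labels)
  missing <- exotic_labels[!(norm(exotic_labels) %in% norm(plant_ids))]
  if (length(missing) > 0) {
    warning("exotic plant label(s) not found among rows (ignored): ",
            paste(missing, collapse = ", "))
  }
  flags
}

#' Validate a bipartite network
#'
#' Checks the class invariants: unique labels within each guild, non-negative
#' weights, 0/1 weights for qualitative networks, one exotic flag per plant,
#' and every species retaining at least one positive-weight link.
#'
#' @param net a `bipartite_network`.
#' @return the network, invisibly.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  w <- net$weights
  if (anyDuplicated(rownames(w))) stop("duplicate plant labels")
  if (anyDuplicated(colnames(w))) stop("duplicate pollinator labels")
  if (anyNA(w)) stop("missing values in weight matrix")
  if (any(w < 0)) stop("negative weights are invalid")
  if (!net$quantitative && !all(w %in% c(0, 1))) {
    stop("qualitative network contains weights outside {0, 1}")
  }
  if (length(net$exotic) != nrow(w)) {
    stop("number of exotic flags must equal number of plants")
  }
  if (any(rowSums(w) == 0) || any(colSums(w) == 0)) {
    stop("every plant and pollinator must keep at least one link; ",
         "use drop_unconnected() first")
  }
  invisible(net)
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> %s: %d plants x %d pollinators, L = %d, %s\n",
              x$network_id, nrow(x$weights), ncol(x$weights),
              sum(x$weights > 0),
              if (x$quantitative) "quantitative" else "qualitative"))
  n_ex <- sum(x$exotic)
  if (n_ex > 0) {
    cat(sprintf("  exotic plants (%d): %s\n", n_ex,
                paste(names(x$exotic)[x$exotic], collapse = ", ")))
  }
  invisible(x)
}

#' Read a bipartite network from a matrix file plus metadata sidecar
#'
#' The matrix file is a labelled CSV/TSV table with plants as rows and
#' pollinators as columns (the Web of Life convention). The metadata sidecar
#' is a key-value text file declaring `network_id`, `location`,
#' `quantitative` (true/false) and `exotic_plants` (comma-separated row
#' labels).
#'
#' @param matrix_path path to the interaction matrix (CSV or TSV by
#'   extension; anything not ending in `.csv` is read as tab-separated).
#' @param metadata_path path to the key-value sidecar; `NULL` for a
#'   qualitative network with no exotic plants.
#' @return a validated `bipartite_network`.
#' @export
read_network <- function(matrix_path, metadata_path = NULL) {
  sep <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else "\t"
  tab <- read.delim(matrix_path, sep = sep, header = TRUE, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("matrix file must have a label column plus >= 1 pollinator column")
  plant_ids <- as.character(tab[[1]])
  if (anyDuplicated(plant_ids)) stop("duplicate plant labels in matrix file")
  w <- as.matrix(tab[, -1, drop = FALSE])
  if (anyDuplicated(colnames(w))) stop("duplicate pollinator labels in matrix file")
  suppressWarnings(storage.mode(w) <- "double")
  if (anyNA(w)) stop("non-numeric or missing cells in matrix file")
  rownames(w) <- plant_ids

  meta <- list(network_id = basename(matrix_path), location = NA_character_,
               quantitative = FALSE, exotic_plants = character())
  if (!is.null(metadata_path)) meta <- modifyList(meta, read_network_metadata(metadata_path))
  bipartite_network(w,
                    quantitative = meta$quantitative,
                    exotic = meta$exotic_plants,
                    location = meta$location,
                    network_id = meta$network_id)
}

read_network_metadata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^=:]+?)\\s*[=:]\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad) > 0) stop("malformed metadata line(s): ", paste(bad, collapse = "; "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  out <- list()
  for (i in seq_along(keys)) {
    key <- tolower(keys[i])
    if (key == "quantitative") {
      out$quantitative <- tolower(trimws(vals[i])) %in% c("true", "yes", "1")
    } else if (key == "exotic_plants") {
      v <- trimws(strsplit(vals[i], ",")[[1]])
      out$exotic_plants <- v[nzchar(v)]
    } else {
      out[[key]] <- trimws(vals[i])
    }
  }
  out
}

#' Write a bipartite network to a matrix file plus metadata sidecar
#'
#' Inverse of [read_network()]: round-tripping reproduces weights, labels and
#' exotic flags exactly.
#'
#' @param net a `bipartite_network`.
#' @param matrix_path output matrix path (`.csv` for comma-separated,
#'   otherwise tab-separated).
#' @param metadata_path output sidecar path; `NULL` to skip.
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, matrix_path, metadata_path = NULL) {
  validate_network(net)
  sep <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else "\t"
  tab <- data.frame(plant = rownames(net$weights), net$weights,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, matrix_path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(metadata_path)) {
    writeLines(c(
      paste0("network_id = ", net$network_id),
      paste0("location = ", ifelse(is.na(net$location), "", net$location)),
      paste0("quantitative = ", tolower(as.character(net$quantitative))),
      paste0("exotic_plants = ",
             paste(names(net$exotic)[net$exotic], collapse = ", "))
    ), metadata_path)
  }
  invisible(c(matrix_path, metadata_path))
}

#' Drop unconnected species from a network
#'
#' Removes plants and pollinators with zero total weight. Removal is a single
#' pass (a species unconnected after removal of others cannot arise in a
#' bipartite matrix: deleting a zero row never zeroes a column) and therefore
#' idempotent.
#'
#' @param net a `bipartite_network` (possibly violating the connectivity
#'   invariant).
#' @return a validated, connected `bipartite_network`.
#' @export
drop_unconnected <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  w <- net$weights
  keep_r <- rowSums(w) > 0
  keep_c <- colSums(w) > 0
  if (!any(keep_r) || !any(keep_c)) {
    stop("empty network: no connected plants or pollinators remain")
  }
  bipartite_network(w[keep_r, keep_c, drop = FALSE],
                    quantitative = net$quantitative,
                    exotic = net$exotic[keep_r],
                    location = net$location,
                    network_id = net$network_id)
}

#' Read a dated plant phylogeny from Newick text
#'
#' Wraps [ape::read.tree()] and enforces the requirements of the downstream
#' phylogenetic metrics: branch lengths must be present (node dating is
#' required, never defaulted) and non-negative, and tip labels must be unique.
#'
#' @param tree_path path to a Newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_phylogeny <- function(tree_path) {
  tree <- tryCatch(ape::read.tree(tree_path),
                   error = function(e) stop("unparseable Newick: ", conditionMessage(e)))
  if (is.null(tree)) stop("unparseable Newick text in ", tree_path)
  check_phylogeny(tree)
}

check_phylogeny <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop("phylogeny has no branch lengths; dated trees are required")
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("phylogeny has missing or negative branch lengths")
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in phylogeny")
  tree
}

# Helpers shared across modules ------------------------------------------

binary_structure <- function(net) {
  (net$weights > 0) * 1
}

#' Basic size descriptors of a network
#'
#' @param net a `bipartite_network`.
#' @return named list with P (plants), A (pollinators), S = P + A,
#'   R = A / P and L (number of observed links).
#' @export
network_size <- function(net) {
  b <- binary_structure(net)
  P <- nrow(b); A <- ncol(b)
  list(P = P, A = A, S = P + A, R = A / P, L = sum(b))
}
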