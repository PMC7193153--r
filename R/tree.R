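#' Read / write rooted trees in newick format
#'
#' Wrappers over \pkg{ape} enforcing this package's contracts: a single rooted
#' tree, unique tip labels, nonnegative branch lengths, and deterministic
#' internal-node labels (unlabelled internal nodes are auto-labelled
#' \code{N<preorder index>} with a warning). Multifurcations are preserved:
#' the composite opsin phylogeny and the rate lineages contain trifurcations.
#'
#' @param path File path.
#' @return \code{read_newick}: an \pkg{ape} \code{phylo} object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) stop("expected a single tree, found several")
  if (is.null(tr)) stop("could not parse newick in ", path)
  validate_tree(tr)
}

#' @rdname read_newick
#' @param tree A \code{phylo} object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Validate and canonicalize a phylo object
#'
#' @param tree A \code{phylo}.
#' @param require_lengths Require branch lengths to be present.
#' @return The validated tree, with internal nodes labelled.
#' @export
validate_tree <- function(tree, require_lengths = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed")
  }
  if (require_lengths && is.null(tree$edge.length)) {
    stop("tree has no branch lengths")
  }
  ensure_node_labels(tree)
}

# deterministic auto-labels for unlabelled internal nodes (preorder index)
ensure_node_labels <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n_int)
  missing <- is.na(lab) | lab == ""
  if (any(missing)) {
    warning(sum(missing), " unlabelled internal node(s) auto-labelled by preorder index")
    lab[missing] <- paste0("N", which(missing))
  }
  if (anyDuplicated(lab)) stop("duplicate internal-node labels")
  tree$node.label <- lab
  tree
}

# all node labels in ape numbering order (tips 1..n, then internals)
node_labels <- function(tree) c(tree$tip.label, tree$node.label)

# children of every node, as a list indexed by ape node number
children_list <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    kids[[p]] <- c(kids[[p]], e)  # store edge indices
  }
  kids
}

# internal nodes in postorder (every child before its parent)
postorder_nodes <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  unique(po$edge[, 1L])
}

root_node <- function(tree) length(tree$tip.label) + 1L

#' Attach lambda-max annotations to a tree
#'
#' Stores per-node wavelengths of maximal absorption (nm) on the tree, keyed
#' by tip / internal-node label. Nodes without a value stay unannotated; the
#' shift census skips branches with an unannotated endpoint.
#'
#' @param tree A labelled \code{phylo}.
#' @param lambda Named numeric vector (names are node labels, values nm).
#' @return The tree with a \code{lambda_max} element.
#' @export
set_lambda_max <- function(tree, lambda) {
  tree <- validate_tree(tree)
  labs <- node_labels(tree)
  unknown <- setdiff(names(lambda), labs)
  if (length(unknown)) {
    stop("lambda_max names not in tree: ", paste(unknown, collapse = ", "))
  }
  tree$lambda_max <- lambda
  tree
}

#' Attach node ages to a tree
#'
#' @param tree A labelled \code{phylo}.
#' @param ages Named numeric vector, million years before present; must be
#'   nonincreasing from root to tips.
#' @return The tree with a \code{node_ages} element.
#' @export
set_node_ages <- function(tree, ages) {
  tree <- validate_tree(tree)
  labs <- node_labels(tree)
  unknown <- setdiff(names(ages), labs)
  if (length(unknown)) stop("age names not in tree: ", paste(unknown, collapse = ", "))
  for (e in seq_len(nrow(tree$edge))) {
    pl <- labs[tree$edge[e, 1L]]; cl <- labs[tree$edge[e, 2L]]
    if (pl %in% names(ages) && cl %in% names(ages) &&
        ages[[cl]] > ages[[pl]] + 1e-9) {
      stop("node ages increase from '", pl, "' to '", cl, "'")
    }
  }
  tree$node_ages <- ages
  tree
}
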