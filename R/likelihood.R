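# Encode the retained alignment columns as an integer matrix of state indices
# (rows = tips in the tree's tip order; NA = gap/X, treated as missing data).
encode_tips <- function(tree, aln, columns = retained_columns(aln)) {
  idx <- match(tree$tip.label, aln$names)
  if (anyNA(idx)) {
    stop("tip(s) without a sequence: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  }
  m <- aln_matrix(aln)[idx, columns, drop = FALSE]
  X <- matrix(aa_index(m), nrow = nrow(m))
  rownames(X) <- tree$tip.label
  X
}

# partial likelihood matrix (20 x S) for one tip
tip_partials <- function(states, S) {
  L <- matrix(0, 20L, S)
  obs <- !is.na(states)
  L[cbind(states[obs], which(obs))] <- 1
  L[, !obs] <- 1
  L
}

# Felsenstein pruning: post-order ("down") partials for every node.
# Returns list(down = list of 20xS matrices indexed by ape node number,
#              logscale = numeric vector per node of length S,
#              P = list of per-edge transition matrices).
pruning_down <- function(tree, X, Q) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  S <- ncol(X)
  Pe <- lapply(tree$edge.length, function(t) transition_probabilities(Q, t))
  kids <- children_list(tree)
  down <- vector("list", n_all)
  logscale <- vector("list", n_all)
  for (i in seq_len(n_tip)) {
    down[[i]] <- tip_partials(X[i, ], S)
    logscale[[i]] <- numeric(S)
  }
  for (p in postorder_nodes(tree)) {
    acc <- NULL
    ls <- numeric(S)
    for (e in kids[[p]]) {
      ch <- tree$edge[e, 2L]
      m <- Pe[[e]] %*% down[[ch]]
      acc <- if (is.null(acc)) m else acc * m
      ls <- ls + logscale[[ch]]
    }
    sc <- colSums(acc)
    if (any(sc <= 0)) stop("zero partial likelihood at an internal node")
    down[[p]] <- acc / rep(sc, each = 20L)
    logscale[[p]] <- ls + log(sc)
  }
  list(down = down, logscale = logscale, P = Pe)
}

# per-site natural-log likelihoods over the retained columns
site_logliks <- function(tree, X, Q) {
  d <- pruning_down(tree, X, Q)
  r <- root_node(tree)
  log(colSums(d$down[[r]] * Q$pi)) + d$logscale[[r]]
}

#' Site log-likelihood under the pruning algorithm
#'
#' Natural-log likelihood of one alignment column on a rooted tree with branch
#' lengths, computed by Felsenstein pruning with per-node rescaling (underflow
#' safe). Gaps and \code{'X'} at tips are treated as missing data
#' (marginalized), and the root is combined with the stationary frequencies.
#'
#' @param tree Rooted \code{phylo} with branch lengths; tips covered by
#'   \code{aln}.
#' @param aln An \code{aa_alignment}.
#' @param Q A \code{rate_matrix}.
#' @param site_index Column index among the alignment's retained columns.
#' @return Natural-log likelihood (scalar).
#' @export
site_log_likelihood <- function(tree, aln, Q, site_index) {
  tree <- validate_tree(tree, require_lengths = TRUE)
  cols <- retained_columns(aln)
  if (site_index < 1L || site_index > length(cols)) {
    stop("site_index out of range (1..", length(cols), ")")
  }
  X <- encode_tips(tree, aln, cols[site_index])
  as.numeric(site_logliks(tree, X, Q))
}

#' Tree log-likelihood
#'
#' Sum of \code{\link{site_log_likelihood}} over the alignment's retained
#' columns (all columns, or the reference-numbered window when one is set).
#'
#' @inheritParams site_log_likelihood
#' @return Natural-log likelihood (scalar).
#' @export
tree_log_likelihood <- function(tree, aln, Q) {
  tree <- validate_tree(tree, require_lengths = TRUE)
  cols <- retained_columns(aln)
  if (length(cols) == 0L) stop("empty alignment window")
  X <- encode_tips(tree, aln, cols)
  sum(site_logliks(tree, X, Q))
}

# pre-order ("up") partials: up[[root]] = pi; for child c of p,
# up[[c]] = t(P_c) %*% (up[[p]] * prod over siblings s of (P_s down[[s]])).
# Columns are renormalized (sum 1) at each node; only ratios are used
# downstream, so the scale factors are not tracked.
pruning_up <- function(tree, d, Q) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  S <- ncol(d$down[[1L]])
  kids <- children_list(tree)
  up <- vector("list", n_all)
  r <- root_node(tree)
  up[[r]] <- matrix(Q$pi, 20L, S)
  for (p in rev(postorder_nodes(tree))) {   # preorder over internal nodes
    edges <- kids[[p]]
    msgs <- lapply(edges, function(e) d$P[[e]] %*% d$down[[tree$edge[e, 2L]]])
    for (k in seq_along(edges)) {
      e <- edges[k]
      ch <- tree$edge[e, 2L]
      acc <- up[[p]]
      for (j in seq_along(edges)) if (j != k) acc <- acc * msgs[[j]]
      u <- crossprod(d$P[[e]], acc)
      cs <- colSums(u)
      cs[cs <= 0] <- 1
      up[[ch]] <- u / rep(cs, each = 20L)
    }
  }
  up
}
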