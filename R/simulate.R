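#' Simulate amino-acid sequence evolution along a tree
#'
#' Evolves sequences under a reversible empirical model on a fixed rooted tree
#' with branch lengths: the root sequence is drawn site-independently from the
#' stationary frequencies, and each branch evolves each site by sampling from
#' the row of P(branch length) given the parent state. All internal-node
#' states are recorded, so reconstruction accuracy can be scored against
#' truth. Replaying the same seed reproduces the output bit-exactly.
#'
#' @param tree Rooted labelled \code{phylo} with branch lengths.
#' @param Q A \code{rate_matrix}.
#' @param n_sites Number of sites (>= 1).
#' @param seed Integer seed.
#' @return A \code{simulation_truth}: \code{tree}, \code{tip_alignment}
#'   (an \code{aa_alignment}), \code{ancestral_sequences} (named character
#'   vector over internal-node labels), \code{model}, \code{seed}.
#' @export
simulate_alignment <- function(tree, Q, n_sites, seed) {
  tree <- validate_tree(tree, require_lengths = TRUE)
  if (anyNA(tree$edge.length)) stop("unset branch length")
  stopifnot(n_sites >= 1L)
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  states <- matrix(NA_integer_, n_all, n_sites)
  r <- root_node(tree)
  states[r, ] <- sample.int(20L, n_sites, replace = TRUE, prob = Q$pi)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in rev(seq_len(nrow(po)))) {        # preorder: parents before children
    e <- match(po[i, 2L], tree$edge[, 2L])
    P <- transition_probabilities(Q, tree$edge.length[e])
    parent <- states[tree$edge[e, 1L], ]
    child <- integer(n_sites)
    for (a in unique(parent)) {
      idx <- which(parent == a)
      child[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = P[a, ])
    }
    states[tree$edge[e, 2L], ] <- child
  }
  labs <- node_labels(tree)
  seqs <- apply(states, 1L, function(s) paste(aa_states()[s], collapse = ""))
  structure(list(
    tree = tree,
    tip_alignment = aa_alignment(labs[seq_len(n_tip)], seqs[seq_len(n_tip)]),
    ancestral_sequences = stats::setNames(seqs[(n_tip + 1L):n_all],
                                          labs[(n_tip + 1L):n_all]),
    model = Q$name, seed = seed
  ), class = "simulation_truth")
}

#' Random bifurcating tree with exponential branch lengths
#'
#' Yule-style random topology (via \code{ape::rtree}) with i.i.d. exponential
#' branch lengths; adequate for property tests, with no biological claim.
#'
#' @param n_tips Number of tips.
#' @param mean_branch Mean branch length (expected substitutions/site).
#' @param seed Integer seed.
#' @return A labelled rooted \code{phylo}.
#' @export
random_tree <- function(n_tips, mean_branch = 0.1, seed = 1L) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, br = function(n) stats::rexp(n, rate = 1 / mean_branch))
  tr$node.label <- paste0("N", seq_len(tr$Nnode))
  tr
}

#' Simulate a lambda-max-annotated tree with planted shifts
#'
#' Generates a random bifurcating tree and walks a lambda-max value from the
#' root to the tips: each branch receives, with probability \code{shift_prob},
#' a planted signed shift of magnitude uniform in \code{shift_range} nm;
#' otherwise a small integer-nm jitter (normal with sd \code{jitter_sd},
#' rounded). Values accumulate root-to-tip, and the planted branches are
#' returned so shift detection can be scored against truth.
#'
#' @param n_tips Number of tips.
#' @param root_lambda Root lambda-max in nm (default 503).
#' @param shift_prob Per-branch probability of a planted shift.
#' @param shift_range Length-2 numeric, nm magnitudes (low >= 10).
#' @param jitter_sd SD of the non-shift jitter in nm (default 1).
#' @param seed Integer seed.
#' @return List: \code{tree} (with \code{lambda_max} set on every node),
#'   \code{planted} data frame (ancestor, descendant, shift_nm).
#' @export
simulate_annotated_tree <- function(n_tips, root_lambda = 503, shift_prob = 0.15,
                                    shift_range = c(10, 35), jitter_sd = 1,
                                    seed = 1L) {
  stopifnot(shift_prob >= 0, shift_prob <= 1)
  if (length(shift_range) != 2L || shift_range[1L] < 10 ||
      shift_range[2L] < shift_range[1L]) {
    stop("shift_range must be (low >= 10, high >= low) in nm")
  }
  tree <- random_tree(n_tips, seed = seed)
  set.seed(seed + 1L)
  labs <- node_labels(tree)
  lam <- stats::setNames(rep(NA_real_, length(labs)), labs)
  lam[labs[root_node(tree)]] <- root_lambda
  po <- ape::reorder.phylo(tree, "postorder")$edge
  planted <- list()
  for (i in rev(seq_len(nrow(po)))) {
    p <- po[i, 1L]; ch <- po[i, 2L]
    if (stats::runif(1L) < shift_prob) {
      shift <- round(sample(c(-1, 1), 1L) *
                       stats::runif(1L, shift_range[1L], shift_range[2L]))
      planted[[length(planted) + 1L]] <-
        data.frame(ancestor = labs[p], descendant = labs[ch], shift_nm = shift)
    } else {
      shift <- round(stats::rnorm(1L, 0, jitter_sd))
    }
    lam[labs[ch]] <- lam[labs[p]] + shift
  }
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(ancestor = character(), descendant = character(),
               shift_nm = numeric())
  list(tree = set_lambda_max(tree, lam), planted = planted)
}
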