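# Independent oracles used across the suite. All of these deliberately avoid
# the package's pruning/eigendecomposition code paths: likelihoods are
# computed by exhaustive enumeration over internal-state assignments, and the
# matrix exponential by truncated series / Matrix::expm.

jtt_Q <- function() build_rate_matrix(load_model("JTT"))

# exhaustive-enumeration log-likelihood of one site (trees up to ~4 tips)
brute_site_loglik <- function(tree, aln, Q, site) {
  aa <- aa_states()
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  P <- lapply(tree$edge.length, function(t) transition_probabilities(Q, t))
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  m <- m[match(tree$tip.label, aln$names), site]
  tipstate <- match(m, aa)             # NA for '-'/'X'
  ints <- (n_tip + 1L):n_all
  grid <- as.matrix(expand.grid(rep(list(1:20), length(ints))))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(n_all)
    st[seq_len(n_tip)] <- tipstate
    st[ints] <- grid[g, ]
    pr <- Q$pi[st[n_tip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      ch <- st[tree$edge[e, 2L]]
      pr <- pr * (if (is.na(ch)) 1 else P[[e]][st[tree$edge[e, 1L]], ch])
    }
    tot <- tot + pr
  }
  log(unname(tot))
}

# clamp-and-renormalize posterior oracle for one internal node and site
clamp_pp_oracle <- function(tree, aln, Q, node_label, site) {
  aa <- aa_states()
  labs <- c(tree$tip.label, tree$node.label)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  P <- lapply(tree$edge.length, function(t) transition_probabilities(Q, t))
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  m <- m[match(tree$tip.label, aln$names), site]
  tipstate <- match(m, aa)
  k <- match(node_label, labs)
  ints <- setdiff((n_tip + 1L):n_all, k)
  grid <- if (length(ints)) as.matrix(expand.grid(rep(list(1:20), length(ints))))
          else matrix(0L, 1L, 0L)
  lik <- numeric(20L)
  for (a in 1:20) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      st <- integer(n_all)
      st[seq_len(n_tip)] <- tipstate
      st[k] <- a
      if (length(ints)) st[ints] <- grid[g, ]
      pr <- Q$pi[st[n_tip + 1L]]
      for (e in seq_len(nrow(tree$edge))) {
        ch <- st[tree$edge[e, 2L]]
        pr <- pr * (if (is.na(ch)) 1 else P[[e]][st[tree$edge[e, 1L]], ch])
      }
      tot <- tot + pr
    }
    lik[a] <- unname(tot)
  }
  lik / sum(lik)
}

# truncated-series matrix exponential, I + Qt + (Qt)^2/2 + (Qt)^3/6
series_expm <- function(Q, t, order = 3L) {
  A <- unname(Q$Q) * t
  term <- diag(20L)
  out <- term
  for (k in seq_len(order)) {
    term <- term %*% A / k
    out <- out + term
  }
  out
}

# a random rooted tree whose root is a trifurcation, so every branch length
# is identifiable (a bifurcating root's two child edges are only jointly so)
random_trifurcating_tree <- function(n_tips, mean_branch = 0.15, seed = 1L) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, rooted = FALSE,
                   br = function(n) stats::rexp(n, rate = 1 / mean_branch))
  tr$node.label <- paste0("N", seq_len(tr$Nnode))
  tr
}

# hand-built reconstruction object (for concordance unit tests)
fake_reconstruction <- function(node, map_states, pps, sites = seq_along(map_states)) {
  pp <- matrix((1 - rep(pps, each = 20L)) / 19, 20L, length(map_states))
  rownames(pp) <- aa_states()
  for (s in seq_along(map_states)) pp[map_states[s], s] <- pps[s]
  structure(list(
    node_ids = node,
    pp = stats::setNames(list(pp), node),
    map_sequence = stats::setNames(paste(map_states, collapse = ""), node),
    site_numbers = sites,
    ties = matrix(FALSE, 1L, length(map_states), dimnames = list(node, NULL)),
    provenance = "fake"
  ), class = "reconstruction")
}
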