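#' Marginal ancestral-state reconstruction
#'
#' For every internal node k and retained alignment site s, the posterior
#' probability of ancestral state a is proportional to the likelihood of the
#' tip data with node k clamped to a, normalized over the 20 states. It is
#' computed in one post-order and one pre-order pass per site (the
#' outside-inside decomposition), which is algebraically identical to the
#' clamp-and-renormalize definition; the test suite verifies the equivalence
#' against exhaustive enumeration on small trees. The maximum-a-posteriori
#' (MAP) sequence is extracted per node, ties broken by canonical
#' \code{\link{aa_states}} order and flagged.
#'
#' @param tree Rooted \code{phylo} with branch lengths (optimized or given).
#' @param aln An \code{aa_alignment}; when it carries a reference and window,
#'   site numbers are reported in reference (bovine-RH1) coordinates.
#' @param Q A \code{rate_matrix}.
#' @param provenance Free-text tag recorded with the result (e.g.
#'   \code{"JTT/24-seq"}).
#' @return A \code{reconstruction} object: \code{node_ids}, \code{pp} (list of
#'   20 x n_sites posterior matrices per node), \code{map_sequence} (named
#'   character vector), \code{site_numbers}, \code{ties} (logical matrix),
#'   \code{provenance}.
#' @export
marginal_reconstruction <- function(tree, aln, Q, provenance = Q$name) {
  tree <- validate_tree(tree, require_lengths = TRUE)
  cols <- retained_columns(aln)
  if (length(cols) == 0L) stop("empty alignment window")
  site_numbers <- if (!is.null(aln$reference_name) && !is.null(aln$site_window)) {
    map_reference_numbering(aln)$position
  } else {
    cols
  }
  X <- encode_tips(tree, aln, cols)
  d <- pruning_down(tree, X, Q)
  up <- pruning_up(tree, d, Q)
  n_tip <- length(tree$tip.label)
  internals <- (n_tip + 1L):(n_tip + tree$Nnode)
  labs <- node_labels(tree)
  pp <- vector("list", length(internals))
  map_seq <- character(length(internals))
  ties <- matrix(FALSE, length(internals), length(cols))
  for (i in seq_along(internals)) {
    k <- internals[i]
    w <- d$down[[k]] * up[[k]]
    w <- w / rep(colSums(w), each = 20L)
    rownames(w) <- aa_states()
    pp[[i]] <- w
    top <- apply(w, 2L, max)
    idx <- apply(w, 2L, which.max)
    ties[i, ] <- apply(w, 2L, function(v) sum(abs(v - max(v)) < 1e-12) > 1L)
    map_seq[i] <- paste(aa_states()[idx], collapse = "")
  }
  node_ids <- labs[internals]
  names(pp) <- node_ids
  names(map_seq) <- node_ids
  rownames(ties) <- node_ids
  structure(list(node_ids = node_ids, pp = pp, map_sequence = map_seq,
                 site_numbers = site_numbers, ties = ties,
                 provenance = provenance),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("reconstruction [", x$provenance, "]: ", length(x$node_ids),
      " internal nodes x ", length(x$site_numbers), " sites\n", sep = "")
  invisible(x)
}

#' Concordance between two reconstructions at a node
#'
#' Per-site comparison of the MAP states of the same ancestral node under two
#' reconstructions (e.g. two substitution models, or two taxon sets). Sites
#' with identical MAP states are binned by the smaller of the two posterior
#' probabilities: \code{identical_high} (min PP >= \code{high}),
#' \code{identical_mid} (\code{mid} <= min PP < \code{high}),
#' \code{identical_low} (min PP < \code{mid}); disagreeing sites are counted
#' as \code{different}.
#'
#' @param a,b \code{reconstruction} objects sharing \code{site_numbers}.
#' @param node Internal-node label present in both.
#' @param high,mid Posterior-probability thresholds (defaults 0.95, 0.70).
#' @return A \code{concordance_summary}: counts plus a per-site detail table.
#' @export
concordance <- function(a, b, node, high = 0.95, mid = 0.70) {
  stopifnot(inherits(a, "reconstruction"), inherits(b, "reconstruction"))
  if (!identical(a$site_numbers, b$site_numbers)) {
    stop("reconstructions cover different site windows")
  }
  if (!(node %in% a$node_ids) || !(node %in% b$node_ids)) {
    stop("node '", node, "' absent from one of the reconstructions")
  }
  pa <- a$pp[[node]]; pb <- b$pp[[node]]
  sa <- strsplit(a$map_sequence[[node]], "")[[1L]]
  sb <- strsplit(b$map_sequence[[node]], "")[[1L]]
  ppa <- pa[cbind(match(sa, aa_states()), seq_along(sa))]
  ppb <- pb[cbind(match(sb, aa_states()), seq_along(sb))]
  minpp <- pmin(ppa, ppb)
  same <- sa == sb
  cls <- ifelse(!same, "different",
         ifelse(minpp >= high, "identical_high",
         ifelse(minpp >= mid, "identical_mid", "identical_low")))
  detail <- data.frame(site = a$site_numbers, state_a = sa, state_b = sb,
                       pp_a = ppa, pp_b = ppb, min_pp = minpp, class = cls)
  structure(list(
    node = node,
    n_sites = length(sa),
    n_identical_high = sum(cls == "identical_high"),
    n_identical_mid = sum(cls == "identical_mid"),
    n_identical_low = sum(cls == "identical_low"),
    n_different = sum(cls == "different"),
    thresholds = c(high = high, mid = mid),
    detail = detail
  ), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("concordance at node '", x$node, "' over ", x$n_sites, " sites:\n",
      "  identical, min PP >= ", x$thresholds[["high"]], ": ",
      x$n_identical_high, "\n",
      "  identical, ", x$thresholds[["mid"]], " <= min PP < ",
      x$thresholds[["high"]], ": ", x$n_identical_mid, "\n",
      "  identical, min PP < ", x$thresholds[["mid"]], ": ",
      x$n_identical_low, "\n",
      "  different: ", x$n_different, "\n", sep = "")
  invisible(x)
}

#' Report MAP states and posteriors at chosen sites
#'
#' Audit table for reference positions of interest (the spectral-tuning
#' critical sites 122, 207 and 292 by default usage): for every internal node
#' and queried site, the MAP state and its posterior probability. Sites
#' outside the reconstruction's window are listed with \code{NA} rather than
#' raising an error.
#'
#' @param recon A \code{reconstruction}.
#' @param sites Reference positions to report.
#' @return Data frame (node, site, state, pp, tie) sorted by node then site.
#' @export
site_state_report <- function(recon, sites) {
  stopifnot(inherits(recon, "reconstruction"))
  rows <- expand.grid(site = as.integer(sites), node = recon$node_ids,
                      stringsAsFactors = FALSE)[, c("node", "site")]
  rows <- rows[order(match(rows$node, recon$node_ids), rows$site), ]
  col <- match(rows$site, recon$site_numbers)
  state <- rep(NA_character_, nrow(rows))
  pp <- rep(NA_real_, nrow(rows))
  tie <- rep(NA, nrow(rows))
  ok <- !is.na(col)
  for (i in which(ok)) {
    nd <- rows$node[i]
    v <- recon$pp[[nd]][, col[i]]
    state[i] <- substr(recon$map_sequence[[nd]], col[i], col[i])
    pp[i] <- v[[state[i]]]
    tie[i] <- recon$ties[nd, col[i]]
  }
  out <- data.frame(node = rows$node, site = rows$site, state = state,
                    pp = pp, tie = tie)
  rownames(out) <- NULL
  out
}

#' Export a reconstruction
#'
#' Writes the full posterior table as TSV (node, site, 20 per-state posterior
#' columns, MAP state) and, optionally, the MAP sequences as FASTA.
#'
#' @param recon A \code{reconstruction}.
#' @param tsv_path Output TSV path.
#' @param fasta_path Optional FASTA path for the MAP sequences.
#' @return Invisibly, the TSV path.
#' @export
write_reconstruction <- function(recon, tsv_path, fasta_path = NULL) {
  stopifnot(inherits(recon, "reconstruction"))
  rows <- do.call(rbind, lapply(recon$node_ids, function(nd) {
    w <- t(recon$pp[[nd]])
    data.frame(node = nd, site = recon$site_numbers,
               round(w, 6),
               map = strsplit(recon$map_sequence[[nd]], "")[[1L]])
  }))
  utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fasta_path)) {
    write_fasta(aa_alignment(recon$node_ids, unname(recon$map_sequence)),
                fasta_path)
  }
  invisible(tsv_path)
}
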