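#' Sequentially averaged depth of a focal ancestor
#'
#' Expected substitutions per site from a focal ancestor to the present,
#' computed by recursive bottom-up averaging: tips have depth 0, and an
#' internal node's depth is the unweighted mean over its children (two or
#' three, at multifurcations) of child branch length plus child depth. On an
#' ultrametric (clock) tree this equals every root-to-tip path length.
#'
#' @param tree Rooted \code{phylo} with branch lengths below the focal node.
#' @param focal_node Label of the focal ancestor (tip labels give depth 0).
#' @return Depth in expected substitutions per site.
#' @export
sequential_average_depth <- function(tree, focal_node) {
  tree <- validate_tree(tree)
  labs <- node_labels(tree)
  k <- match(focal_node, labs)
  if (is.na(k)) stop("no node labelled '", focal_node, "'")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("missing branch length below focal node")
  kids <- children_list(tree)
  depth_of <- function(node) {
    if (is.null(kids[[node]])) return(0)
    mean(vapply(kids[[node]], function(e) {
      tree$edge.length[e] + depth_of(tree$edge[e, 2L])
    }, numeric(1L)))
  }
  depth_of(k)
}

#' Substitution rate of a lineage
#'
#' @param depth Sequentially averaged depth (substitutions/site).
#' @param origin_time_years Age of the lineage's origin in years (> 0).
#' @return Rate in substitutions per site per year.
#' @export
lineage_rate <- function(depth, origin_time_years) {
  if (!is.numeric(origin_time_years) || origin_time_years <= 0) {
    stop("origin time must be positive")
  }
  depth / origin_time_years
}

#' Bootstrap standard error of a lineage rate
#'
#' Nonparametric bootstrap over alignment columns: columns are resampled with
#' replacement, branch lengths are re-optimized on the fixed topology, the
#' sequentially averaged depth and rate are recomputed, and the SE is the
#' standard deviation of the bootstrap rates. Degenerate resamples (e.g.
#' all-constant columns, or failed optimizations) are skipped; fewer than 10
#' successful replicates is an error.
#'
#' @param tree Rooted \code{phylo} with (initial) branch lengths.
#' @param focal_node Label of the lineage's focal ancestor.
#' @param aln An \code{aa_alignment} covering the tips.
#' @param Q A \code{rate_matrix}.
#' @param origin_time_years Lineage origin in years.
#' @param n_boot Number of bootstrap replicates (>= 50, default 100).
#' @param seed Integer seed; replicates are reproducible given the seed.
#' @param tol Optimizer tolerance per replicate (default 1e-4; the rate is a
#'   smooth functional of the branch lengths, so replicate-level optimization
#'   can be looser than the point estimate's).
#' @return List: \code{se}, \code{rates} (successful bootstrap rates),
#'   \code{n_success}.
#' @export
rate_se <- function(tree, focal_node, aln, Q, origin_time_years,
                    n_boot = 100L, seed = 1L, tol = 1e-4) {
  if (n_boot < 50L) stop("n_boot must be at least 50")
  tree <- validate_tree(tree, require_lengths = TRUE)
  cols <- retained_columns(aln)
  m <- aln_matrix(aln)[, cols, drop = FALSE]
  set.seed(seed)
  rates <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    pick <- sample.int(length(cols), length(cols), replace = TRUE)
    baln <- aa_alignment(aln$names, apply(m[, pick, drop = FALSE], 1L, paste,
                                          collapse = ""))
    fit <- tryCatch(
      optimize_branch_lengths(tree, baln, Q, tol = tol, max_cycles = 50L),
      error = function(e) NULL)
    if (is.null(fit)) next
    d <- sequential_average_depth(fit, focal_node)
    rates[b] <- lineage_rate(d, origin_time_years)
  }
  ok <- rates[!is.na(rates)]
  if (length(ok) < 10L) stop("fewer than 10 successful bootstrap replicates")
  list(se = stats::sd(ok), rates = ok, n_success = length(ok))
}

#' Assemble a lineage-rate record
#'
#' @param lineage_id Short identifier (e.g. "a", "b", "c").
#' @param depth Substitutions/site from \code{\link{sequential_average_depth}}.
#' @param origin_time_years Lineage origin in years.
#' @param se Standard error of the rate (same units as the rate), >= 0.
#' @return A \code{lineage_rate_record}.
#' @export
lineage_rate_record <- function(lineage_id, depth, origin_time_years, se = NA_real_) {
  if (!is.na(se) && se < 0) stop("se must be nonnegative")
  structure(list(lineage_id = lineage_id, depth = depth,
                 origin_time = origin_time_years,
                 rate = lineage_rate(depth, origin_time_years), se = se),
            class = "lineage_rate_record")
}

#' Compare two lineage rates
#'
#' Two-sample Z statistic with pooled standard errors:
#' Z = |r1 - r2| / sqrt(se1^2 + se2^2), with a two-sided normal p-value and
#' significance flags at the 5 and 1 percent levels. Note this pooled-SE
#' construction is the package's documented choice; other Z constructions for
#' the same rates exist and give different values.
#'
#' @param r1,r2 \code{lineage_rate_record}s with positive SEs.
#' @return List: \code{z}, \code{p_value}, \code{significant_5pct},
#'   \code{significant_1pct}.
#' @export
compare_rates <- function(r1, r2) {
  stopifnot(inherits(r1, "lineage_rate_record"),
            inherits(r2, "lineage_rate_record"))
  pooled <- sqrt(r1$se^2 + r2$se^2)
  if (!is.finite(pooled) || pooled <= 0) {
    stop("zero pooled standard error: rates cannot be compared")
  }
  z <- abs(r1$rate - r2$rate) / pooled
  p <- 2 * stats::pnorm(-z)
  list(z = z, p_value = p,
       significant_5pct = p < 0.05, significant_1pct = p < 0.01)
}
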