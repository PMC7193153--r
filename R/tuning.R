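#' Per-branch lambda-max shifts
#'
#' One record per parent-to-child branch whose two endpoints both carry a
#' lambda-max annotation; branches with an unannotated endpoint are skipped
#' and listed in \code{attr(, "skipped")}. The shift is signed
#' descendant minus ancestor, so a positive delta is a red shift. Output is in
#' deterministic preorder.
#'
#' @param tree A \code{phylo} with a \code{lambda_max} annotation (see
#'   \code{\link{set_lambda_max}}).
#' @param significance Absolute shift (nm) called significant (default 10).
#' @param large Absolute shift (nm) called large (default 30).
#' @return Data frame of class \code{shift_records}: ancestor, descendant,
#'   lambda_anc, lambda_desc, delta, significant, large.
#' @export
branch_shifts <- function(tree, significance = 10, large = 30) {
  tree <- validate_tree(tree)
  lam <- tree$lambda_max
  if (is.null(lam) || length(lam) == 0L) {
    stop("tree carries no lambda_max annotations")
  }
  labs <- node_labels(tree)
  po <- rev(ape::reorder.phylo(tree, "postorder")$edge[, 2L])  # preorder children
  ord <- match(po, tree$edge[, 2L])
  anc <- labs[tree$edge[ord, 1L]]
  des <- labs[tree$edge[ord, 2L]]
  has <- anc %in% names(lam) & des %in% names(lam)
  skipped <- data.frame(ancestor = anc[!has], descendant = des[!has])
  la <- unname(lam[anc[has]])
  ld <- unname(lam[des[has]])
  delta <- ld - la
  out <- data.frame(ancestor = anc[has], descendant = des[has],
                    lambda_anc = la, lambda_desc = ld, delta = delta,
                    significant = abs(delta) >= significance,
                    large = abs(delta) >= large)
  attr(out, "skipped") <- skipped
  class(out) <- c("shift_records", "data.frame")
  out
}

#' Census of significant and large shifts
#'
#' @param records Shift records from \code{\link{branch_shifts}} (thresholds
#'   are re-applied here, so any thresholds used there are irrelevant).
#' @param significance Absolute-shift threshold in nm for significance
#'   (default 10).
#' @param large Absolute-shift threshold in nm for "large" (default 30).
#' @return List: \code{n_significant}, \code{n_large}, and \code{listing} of
#'   significant branches sorted by |delta| descending then input (preorder)
#'   order.
#' @export
count_shifts <- function(records, significance = 10, large = 30) {
  if (is.null(records) || nrow(records) == 0L) {
    return(list(n_significant = 0L, n_large = 0L,
                listing = records[integer(0), , drop = FALSE]))
  }
  sig <- abs(records$delta) >= significance
  lrg <- abs(records$delta) >= large
  listing <- records[sig, , drop = FALSE]
  listing <- listing[order(-abs(listing$delta), seq_len(nrow(listing))), ,
                     drop = FALSE]
  rownames(listing) <- NULL
  list(n_significant = sum(sig), n_large = sum(lrg), listing = listing)
}

#' Parse a mutation label
#'
#' Labels follow the vision-science convention
#' \code{<from><site><to>} in bovine-RH1 numbering, e.g. \code{E122Q};
#' multiple mutations are joined by \code{"/"}.
#'
#' @param label Character vector of single-mutation labels.
#' @return Data frame with \code{from}, \code{site}, \code{to}.
#' @export
parse_mutation <- function(label) {
  m <- regmatches(label, regexec("^([A-Z])([0-9]+)([A-Z])$", label))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("unparseable mutation label(s): ",
                     paste(label[bad], collapse = ", "))
  out <- data.frame(
    from = vapply(m, `[`, "", 2L),
    site = as.integer(vapply(m, `[`, "", 3L)),
    to = vapply(m, `[`, "", 4L)
  )
  if (any(out$site < 1L | out$site > 354L)) {
    stop("mutation site outside bovine-RH1 range 1..354")
  }
  if (any(out$from == out$to)) stop("mutation with identical from/to state")
  out
}

#' Classify mutagenesis assays as fully explaining a shift
#'
#' An assay row records an engineered ancestral pigment, the substitutions
#' introduced, the mutant's measured lambda-max, and the descendant pigment
#' the branch leads to. The mutation(s) fully explain the branch's shift when
#' the mutant lands within \code{tolerance} nm of the descendant:
#' |mutant lambda - descendant lambda| <= tolerance (default 4 nm). Rows with
#' a missing lambda are reported unevaluable and excluded from counts.
#'
#' @param assays Data frame with columns \code{ancestor},
#'   \code{ancestor_lambda}, \code{mutations} (slash-joined labels),
#'   \code{mutant_lambda}, \code{descendant}, \code{descendant_lambda}.
#' @param tolerance nm (default 4).
#' @return List: \code{verdicts} (the input plus \code{n_mutations},
#'   \code{residual}, \code{explained}, \code{evaluable}),
#'   \code{n_explained}, \code{n_explained_single}, \code{n_explained_multi},
#'   \code{n_evaluable}.
#' @export
classify_explained <- function(assays, tolerance = 4) {
  need <- c("ancestor", "ancestor_lambda", "mutations", "mutant_lambda",
            "descendant", "descendant_lambda")
  if (!all(need %in% names(assays))) {
    stop("assay table must have columns: ", paste(need, collapse = ", "))
  }
  for (mm in assays$mutations) parse_mutation(strsplit(mm, "/")[[1L]])
  evaluable <- !is.na(assays$mutant_lambda) & !is.na(assays$descendant_lambda)
  residual <- assays$mutant_lambda - assays$descendant_lambda
  explained <- evaluable & abs(residual) <= tolerance
  n_mut <- vapply(strsplit(assays$mutations, "/"), length, 1L)
  verdicts <- cbind(assays,
                    n_mutations = n_mut,
                    residual = ifelse(evaluable, residual, NA_real_),
                    explained = ifelse(evaluable, explained, NA),
                    evaluable = evaluable)
  list(verdicts = verdicts,
       n_explained = sum(explained),
       n_explained_single = sum(explained & n_mut == 1L),
       n_explained_multi = sum(explained & n_mut > 1L),
       n_evaluable = sum(evaluable))
}

#' Fraction of a branch's shift explained by a mutant
#'
#' The contribution of the engineered mutation(s) is the mutant's lambda-max
#' minus the ancestor's (nm, signed); the percent explained is
#' 100 * contribution / (descendant - ancestor), rounded half-away-from-zero
#' to the nearest integer (so 15/35 of a shift reports 43 percent).
#'
#' @param lambda_anc,lambda_mutant,lambda_desc Wavelengths in nm.
#' @return List: \code{contribution_nm}, \code{percent}.
#' @export
fraction_explained <- function(lambda_anc, lambda_mutant, lambda_desc) {
  if (lambda_desc == lambda_anc) {
    stop("zero total shift: fraction explained is undefined")
  }
  contribution <- lambda_mutant - lambda_anc
  pct <- 100 * contribution / (lambda_desc - lambda_anc)
  list(contribution_nm = contribution,
       percent = round_half_away(pct))
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Trace substitutions at chosen sites over a tree
#'
#' Emits one event per branch and site where the parent's and child's amino
#' acids differ, labelled \code{<from><site><to>}, and counts events per
#' label. Branches where either endpoint lacks a state at a queried site are
#' skipped and reported.
#'
#' @param tree A labelled \code{phylo}.
#' @param node_states Data frame or matrix: rows named by node label, one
#'   column per queried site (column names are the site numbers), entries
#'   single amino-acid letters (or NA).
#' @param sites Sites to trace; defaults to all columns of
#'   \code{node_states}.
#' @return List: \code{events} (data frame ancestor, descendant, site, from,
#'   to, label), \code{counts} (named integer vector per label),
#'   \code{skipped}.
#' @export
trace_site_substitutions <- function(tree, node_states,
                                     sites = colnames(node_states)) {
  tree <- validate_tree(tree)
  node_states <- as.matrix(node_states)
  sites <- as.character(sites)
  missing_sites <- setdiff(sites, colnames(node_states))
  if (length(missing_sites)) {
    stop("no states for site(s): ", paste(missing_sites, collapse = ", "))
  }
  vals <- node_states[, sites, drop = FALSE]
  ok <- is.na(vals) | vals %in% aa_states()
  if (!all(ok)) {
    stop("invalid amino-acid state(s): ",
         paste(unique(vals[!ok]), collapse = ", "))
  }
  labs <- node_labels(tree)
  po <- rev(ape::reorder.phylo(tree, "postorder")$edge[, 2L])
  ord <- match(po, tree$edge[, 2L])
  anc <- labs[tree$edge[ord, 1L]]
  des <- labs[tree$edge[ord, 2L]]
  events <- list()
  skipped <- list()
  for (i in seq_along(anc)) {
    for (s in sites) {
      fa <- if (anc[i] %in% rownames(vals)) vals[anc[i], s] else NA
      ta <- if (des[i] %in% rownames(vals)) vals[des[i], s] else NA
      if (is.na(fa) || is.na(ta)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(ancestor = anc[i], descendant = des[i], site = s)
      } else if (fa != ta) {
        events[[length(events) + 1L]] <- data.frame(
          ancestor = anc[i], descendant = des[i], site = as.integer(s),
          from = fa, to = ta, label = paste0(fa, s, ta))
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(ancestor = character(), descendant = character(),
               site = integer(), from = character(), to = character(),
               label = character())
  counts <- if (nrow(events)) table(events$label) else table(character())
  list(events = events,
       counts = stats::setNames(as.integer(counts), names(counts)),
       skipped = if (length(skipped)) do.call(rbind, unique(skipped)) else NULL)
}

#' Polymorphic / monomorphic site classification
#'
#' Over a set of aligned, reference-numbered pigment sequences, a site is
#' polymorphic when at least two distinct non-missing amino acids occur. The
#' adaptive fraction is the share of polymorphic sites that are
#' spectral-tuning critical sites, as a percent with one decimal.
#'
#' @param aln An \code{aa_alignment} with reference and window set (default
#'   window 31..311).
#' @param critical_sites Reference positions known to shift lambda-max
#'   (default 122, 207, 292).
#' @return List: \code{n_polymorphic}, \code{n_monomorphic},
#'   \code{adaptive_fraction} (percent, one decimal), \code{per_site} data
#'   frame (site, n_states, polymorphic, critical).
#' @export
classify_sites <- function(aln, critical_sites = c(122L, 207L, 292L)) {
  if (length(aln$names) < 2L) stop("need at least two sequences")
  map <- map_reference_numbering(aln)
  if (nrow(map) == 0L) stop("empty site window")
  m <- aln_matrix(aln)[, map$column, drop = FALSE]
  n_states <- apply(m, 2L, function(col) {
    length(unique(col[col %in% aa_states()]))
  })
  poly <- n_states >= 2L
  crit <- map$position %in% critical_sites
  per_site <- data.frame(site = map$position, n_states = n_states,
                         polymorphic = poly, critical = crit)
  n_poly <- sum(poly)
  frac <- if (n_poly > 0L) round(100 * sum(poly & crit) / n_poly, 1L) else NA_real_
  list(n_polymorphic = n_poly, n_monomorphic = sum(!poly),
       adaptive_fraction = frac, per_site = per_site)
}
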