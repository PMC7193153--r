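#' Assemble and validate a run configuration
#'
#' One declarative object carries everything a pipeline run needs: input
#' paths, the substitution model, the reference window, the thresholds used
#' by the shift and reconstruction summaries, lineage definitions for the
#' rate analysis, bootstrap size and seed, and the output directory. Defaults
#' follow the package's study conventions: window 31..311 in bovine-RH1
#' numbering, significance 10 nm, large 30 nm, explained tolerance 4 nm,
#' posterior thresholds 0.95/0.70.
#'
#' @param model Model name ("JTT", "WAG" or "Dayhoff").
#' @param alignment Path to a FASTA alignment (reconstruction/rates stages).
#' @param tree Path to a newick tree.
#' @param reference_name Numbering reference sequence name, or NULL for plain
#'   column numbering.
#' @param site_window Inclusive reference window (default c(31, 311); ignored
#'   without a reference).
#' @param empirical_frequencies Use alignment ("+F") frequencies instead of
#'   the model's published ones.
#' @param significance,large,explained_tolerance Shift thresholds in nm.
#' @param pp_high,pp_mid Posterior-probability thresholds.
#' @param lineages Named list for the rate stage: each element is
#'   \code{list(focal = <node label>, origin_years = <years>)}.
#' @param n_boot Bootstrap replicates for rate SEs.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return A validated \code{run_config} list.
#' @export
run_config <- function(model = "JTT", alignment = NULL, tree = NULL,
                       reference_name = NULL, site_window = c(31L, 311L),
                       empirical_frequencies = FALSE,
                       significance = 10, large = 30, explained_tolerance = 4,
                       pp_high = 0.95, pp_mid = 0.70,
                       lineages = NULL, n_boot = 100L, seed = 1L,
                       out_dir = tempfile("opsinshift_run_")) {
  stopifnot(model %in% c("JTT", "WAG", "Dayhoff"))
  if (any(c(significance, large, explained_tolerance) <= 0)) {
    stop("all nm thresholds must be positive")
  }
  if (!(pp_mid > 0 && pp_high < 1 && pp_mid < pp_high)) {
    stop("posterior thresholds must satisfy 0 < mid < high < 1")
  }
  if (!is.null(lineages)) {
    ok <- vapply(lineages, function(l) {
      is.list(l) && !is.null(l$focal) && !is.null(l$origin_years) &&
        l$origin_years > 0
    }, logical(1L))
    if (!all(ok)) {
      stop("each lineage needs a focal node and a positive origin_years",
           " (missing for: ", paste(names(lineages)[!ok], collapse = ", "), ")")
    }
  }
  structure(list(model = model, alignment = alignment, tree = tree,
                 reference_name = reference_name, site_window = site_window,
                 empirical_frequencies = empirical_frequencies,
                 significance = significance, large = large,
                 explained_tolerance = explained_tolerance,
                 pp_high = pp_high, pp_mid = pp_mid,
                 lineages = lineages, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# write a reproducibility manifest (DCF: machine-readable, base-R round-trip)
write_manifest <- function(config, stage, inputs, out_dir) {
  sums <- if (length(inputs)) {
    paste(basename(inputs), unname(tools::md5sum(inputs)),
          sep = ":", collapse = " ")
  } else ""
  dcf <- data.frame(
    stage = stage,
    package_version = as.character(utils::packageVersion("opsinshift")),
    seed = config$seed, model = config$model,
    input_md5 = sums,
    config = paste(utils::capture.output(utils::str(unclass(config))),
                   collapse = " "))
  write.dcf(dcf, file.path(out_dir, paste0(stage, "_manifest.dcf")))
}

stage_run <- function(stage, out_dir, expr) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  before <- list.files(out_dir, full.names = TRUE)
  tryCatch(expr, error = function(e) {
    made <- setdiff(list.files(out_dir, full.names = TRUE), before)
    unlink(made)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the ancestral-reconstruction stage
#'
#' Reads the configured alignment and tree, builds the rate matrix, optimizes
#' branch lengths on the fixed topology, performs the marginal
#' reconstruction, and writes: the posterior table (TSV), MAP sequences
#' (FASTA), the optimized tree (newick), a branch-length optimization log
#' (TSV), and a manifest. Rerunning the same config reproduces the outputs.
#'
#' @param config A \code{run_config} with \code{alignment} and \code{tree}
#'   set.
#' @return Invisibly, a list with the \code{reconstruction}, the optimized
#'   \code{tree}, and output \code{paths}.
#' @export
run_reconstruct <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$alignment) || !file.exists(config$alignment)) {
    stop("config validation: alignment path missing or nonexistent")
  }
  if (is.null(config$tree) || !file.exists(config$tree)) {
    stop("config validation: tree path missing or nonexistent")
  }
  stage_run("reconstruct", config$out_dir, {
    aln <- read_fasta(config$alignment,
                      reference_name = config$reference_name,
                      site_window = if (!is.null(config$reference_name))
                        config$site_window)
    tree <- read_newick(config$tree)
    model <- load_model(config$model)
    Q <- build_rate_matrix(model,
      frequencies = if (config$empirical_frequencies)
        empirical_frequencies(aln))
    fitted <- optimize_branch_lengths(tree, aln, Q)
    recon <- marginal_reconstruction(fitted, aln, Q,
      provenance = paste0(config$model, "/", length(aln$names), "-seq"))
    paths <- list(
      posteriors = file.path(config$out_dir, "reconstruction.tsv"),
      map_fasta = file.path(config$out_dir, "map_sequences.fasta"),
      tree = file.path(config$out_dir, "optimized_tree.nwk"),
      optlog = file.path(config$out_dir, "branch_lengths.tsv"))
    write_reconstruction(recon, paths$posteriors, paths$map_fasta)
    write_newick(fitted, paths$tree)
    utils::write.table(attr(fitted, "convergence")$branches, paths$optlog,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(config, "reconstruct", c(config$alignment, config$tree),
                   config$out_dir)
    invisible(list(reconstruction = recon, tree = fitted, paths = paths))
  })
}

#' Run the spectral-shift stage
#'
#' Computes the per-branch lambda-max shift table and census on an annotated
#' tree, classifies the mutagenesis assays as fully explaining their branch
#' or not, and reports the fraction of the shift explained for every assay on
#' a significantly shifted branch. Defaults to the packaged composite-tree
#' and assay fixtures.
#'
#' @param config A \code{run_config}.
#' @param annotated_tree A \code{phylo} with \code{lambda_max}; default the
#'   packaged composite tree.
#' @param assays Assay data frame; default \code{\link{rh2_mutation_assays}()}.
#'   Pass an empty data frame to skip explanation analysis (a warning is
#'   issued and shifts are still reported).
#' @return Invisibly, a list: \code{shifts}, \code{census},
#'   \code{explained}, \code{fractions}, \code{paths}.
#' @export
run_shifts <- function(config, annotated_tree = NULL, assays = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage_run("shifts", config$out_dir, {
    if (is.null(annotated_tree)) annotated_tree <- rh2_annotated_tree()$tree
    if (is.null(assays)) assays <- rh2_mutation_assays()
    shifts <- branch_shifts(annotated_tree, significance = config$significance,
                            large = config$large)
    census <- count_shifts(shifts, significance = config$significance,
                           large = config$large)
    if (nrow(assays) == 0L) {
      warning("empty assay table: explanation section skipped")
      explained <- NULL
      fractions <- NULL
    } else {
      explained <- classify_explained(assays,
                                      tolerance = config$explained_tolerance)
      sig_key <- paste(shifts$ancestor[shifts$significant],
                       shifts$descendant[shifts$significant])
      on_sig <- paste(assays$ancestor, assays$descendant) %in% sig_key
      fractions <- do.call(rbind, lapply(which(on_sig), function(i) {
        fe <- fraction_explained(assays$ancestor_lambda[i],
                                 assays$mutant_lambda[i],
                                 assays$descendant_lambda[i])
        data.frame(ancestor = assays$ancestor[i],
                   descendant = assays$descendant[i],
                   mutations = assays$mutations[i],
                   contribution_nm = fe$contribution_nm,
                   percent = fe$percent)
      }))
    }
    paths <- list(shifts = file.path(config$out_dir, "shift_report.tsv"),
                  explained = file.path(config$out_dir, "explained.tsv"),
                  fractions = file.path(config$out_dir, "fraction_explained.tsv"))
    utils::write.table(as.data.frame(shifts), paths$shifts, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(explained)) {
      utils::write.table(explained$verdicts, paths$explained, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(fractions)) {
      utils::write.table(fractions, paths$fractions, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    write_manifest(config, "shifts", character(), config$out_dir)
    invisible(list(shifts = shifts, census = census, explained = explained,
                   fractions = fractions, paths = paths))
  })
}

#' Run the lineage-rate stage
#'
#' For every configured lineage (focal node + origin time), computes the
#' sequentially averaged depth on the optimized tree, the substitution rate
#' per site per year, a bootstrap SE over alignment columns, and all pairwise
#' Z comparisons.
#'
#' @param config A \code{run_config} with \code{alignment}, \code{tree} and
#'   \code{lineages} set.
#' @param tree Optional pre-optimized \code{phylo}; when NULL the configured
#'   tree is read and its branch lengths optimized against the alignment.
#' @return Invisibly, a list: \code{rates} (data frame),
#'   \code{comparisons} (data frame), \code{paths}.
#' @export
run_rates <- function(config, tree = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$lineages) || length(config$lineages) < 1L) {
    stop("config validation: no lineages configured")
  }
  if (is.null(config$alignment) || !file.exists(config$alignment)) {
    stop("config validation: alignment path missing or nonexistent")
  }
  stage_run("rates", config$out_dir, {
    aln <- read_fasta(config$alignment)
    if (is.null(tree)) {
      if (is.null(config$tree) || !file.exists(config$tree)) {
        stop("config validation: tree path missing or nonexistent")
      }
      tree <- optimize_branch_lengths(read_newick(config$tree), aln,
                                      build_rate_matrix(load_model(config$model)))
    }
    Q <- build_rate_matrix(load_model(config$model))
    labs <- node_labels(tree)
    kids <- children_list(tree)
    recs <- list()
    for (nm in names(config$lineages)) {
      l <- config$lineages[[nm]]
      k <- match(l$focal, labs)
      if (is.na(k)) stop("lineage '", nm, "': no node labelled '", l$focal, "'")
      n_desc <- length(ape::extract.clade(tree, k)$tip.label)
      if (!is.null(kids[[k]]) && n_desc < 2L) {
        stop("lineage '", nm, "' has fewer than 2 tips")
      }
      depth <- sequential_average_depth(tree, l$focal)
      se <- rate_se(tree, l$focal, aln, Q, l$origin_years,
                    n_boot = config$n_boot, seed = config$seed)
      recs[[nm]] <- lineage_rate_record(nm, depth, l$origin_years, se$se)
    }
    rates <- do.call(rbind, lapply(recs, function(r) {
      data.frame(lineage = r$lineage_id, depth = r$depth,
                 origin_MYA = r$origin_time / 1e6, rate = r$rate, se = r$se,
                 n_boot = config$n_boot, seed = config$seed)
    }))
    pairs <- if (length(recs) >= 2L) utils::combn(names(recs), 2L) else NULL
    comparisons <- if (!is.null(pairs)) {
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        cmp <- compare_rates(recs[[pairs[1L, j]]], recs[[pairs[2L, j]]])
        data.frame(lineage_1 = pairs[1L, j], lineage_2 = pairs[2L, j],
                   z = cmp$z, p_value = cmp$p_value,
                   significant_5pct = cmp$significant_5pct,
                   significant_1pct = cmp$significant_1pct)
      }))
    }
    paths <- list(rates = file.path(config$out_dir, "lineage_rates.tsv"),
                  comparisons = file.path(config$out_dir, "rate_comparisons.tsv"))
    utils::write.table(rates, paths$rates, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(comparisons)) {
      utils::write.table(comparisons, paths$comparisons, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    write_manifest(config, "rates",
                   c(config$alignment,
                     if (!is.null(config$tree) && file.exists(config$tree))
                       config$tree),
                   config$out_dir)
    invisible(list(rates = rates, comparisons = comparisons, paths = paths))
  })
}
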