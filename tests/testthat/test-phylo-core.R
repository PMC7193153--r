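test_that("FASTA round-trips, normalizes case and gaps, and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "mnpq.", ">s2", "MN-GT"), f)
  aln <- read_fasta(f)
  expect_length(aln$names, 2)
  expect_identical(aln$seqs, c("MNPQ-", "MN-GT"))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(aln, f2)
  expect_identical(read_fasta(f2)[c("names", "seqs")], aln[c("names", "seqs")])
  writeLines(c(">a", "MNP", ">a", "MNP"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">a", "MNP", ">b", "MNPQ"), f)
  expect_error(read_fasta(f), "ragged")
})

test_that("newick parsing keeps topology, multifurcations and lengths", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:0.1,B:0.2):0.05,C:0.3);", f)
  tr <- suppressWarnings(read_newick(f))
  expect_length(tr$tip.label, 3)
  expect_identical(tr$Nnode, 2L)
  writeLines("(A:0.1,B:0.1,C:0.1);", f)
  tr3 <- suppressWarnings(read_newick(f))
  expect_identical(tr3$Nnode, 1L)               # trifurcation preserved
  big <- random_tree(37, seed = 5)
  f3 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(big, f3)
  back <- read_newick(f3)
  expect_identical(back$tip.label, big$tip.label)
  expect_equal(back$edge.length, big$edge.length, tolerance = 1e-9)
  expect_identical(ape::write.tree(back), ape::write.tree(big))
  writeLines("((A:1,B:1", f)
  expect_error(suppressWarnings(read_newick(f)))
  writeLines("((A:1,A:1):1,C:1);", f)
  expect_error(read_newick(f), "duplicate")
})

test_that("reference numbering maps columns, gaps and windows correctly", {
  aln <- aa_alignment(c("ref", "x"), c("MN-GT", "MNPGT"), reference_name = "ref")
  map <- map_reference_numbering(aln)
  expect_identical(map$position, c(1L, 2L, NA, 3L, 4L))
  aln2 <- aa_alignment(c("ref", "x"), c("MN-GT", "MNPGT"),
                       reference_name = "ref", site_window = c(2, 3))
  expect_identical(map_reference_numbering(aln2)$column, c(2L, 4L))
  expect_warning(map_reference_numbering(aln, window = c(40, 50)), "no alignment columns")
  expect_error(map_reference_numbering(aln, reference_name = "zz"), "absent")
})

test_that("a 354-residue reference windowed at 31..311 retains 281 numbered sites", {
  set.seed(8)
  ref <- paste(sample(aa_states(), 354, replace = TRUE), collapse = "")
  aln <- aa_alignment(c("bovineRH1", "q"), c(ref, ref),
                      reference_name = "bovineRH1", site_window = c(31, 311))
  expect_identical(nrow(map_reference_numbering(aln)), 281L)
  expect_length(retained_columns(aln), 281L)
})

test_that("degenerate two-tip likelihood equals the stationary log-frequency", {
  Q <- jtt_Q()
  tr <- ape::read.tree(text = "(A:0,B:0)R;")
  aln <- aa_alignment(c("A", "B"), c("L", "L"))
  expect_equal(site_log_likelihood(tr, aln, Q, 1), log(Q$pi[["L"]]))
})

test_that("pruning equals the exhaustive-enumeration oracle on small trees", {
  Q <- jtt_Q()
  for (rep in 1:8) {
    n <- sample(3:4, 1)
    tr <- random_tree(n, seed = 100 + rep)
    sim <- simulate_alignment(tr, Q, 3, seed = 200 + rep)
    for (s in 1:3) {
      expect_equal(site_log_likelihood(tr, sim$tip_alignment, Q, s),
                   brute_site_loglik(tr, sim$tip_alignment, Q, s),
                   tolerance = 1e-10)
    }
  }
})

test_that("gap and X tips are marginalized as missing data", {
  Q <- jtt_Q()
  tr <- random_tree(3, seed = 3)
  aln <- aa_alignment(tr$tip.label, c("L", "-", "X"))
  expect_equal(site_log_likelihood(tr, aln, Q, 1),
               brute_site_loglik(tr, aln, Q, 1), tolerance = 1e-10)
})

test_that("tree log-likelihood sums sites and ignores column order", {
  Q <- jtt_Q()
  tr <- random_tree(4, seed = 6)
  sim <- simulate_alignment(tr, Q, 10, seed = 7)
  aln <- sim$tip_alignment
  total <- tree_log_likelihood(tr, aln, Q)
  expect_equal(total, sum(vapply(1:10, function(s)
    site_log_likelihood(tr, aln, Q, s), numeric(1))), tolerance = 1e-10)
  single <- aa_alignment(aln$names, substr(aln$seqs, 1, 1))
  expect_equal(tree_log_likelihood(tr, single, Q),
               site_log_likelihood(tr, aln, Q, 1))
  set.seed(9)
  perm <- sample(10)
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  shuffled <- aa_alignment(aln$names, apply(m[, perm], 1, paste, collapse = ""))
  expect_equal(tree_log_likelihood(tr, shuffled, Q), total, tolerance = 1e-12)
  expect_error(tree_log_likelihood(tr, aa_alignment("A", "L"), Q), "without a sequence")
})

test_that("likelihood matches phangorn and obeys the pulley principle", {
  skip_if_not_installed("phangorn")
  Q <- jtt_Q()
  tr <- random_tree(6, seed = 31)
  sim <- simulate_alignment(tr, Q, 40, seed = 32)
  pd <- phangorn::phyDat(stats::setNames(strsplit(sim$tip_alignment$seqs, ""),
                                         sim$tip_alignment$names), type = "AA")
  fit <- phangorn::pml(tr, pd, model = "JTT")
  expect_equal(tree_log_likelihood(tr, sim$tip_alignment, Q), fit$logLik,
               tolerance = 1e-6)
  # sliding the root along its edge must not change the likelihood
  t1 <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,C:0.30)R;")
  t2 <- ape::read.tree(text = "((A:0.1,B:0.2):0.25,C:0.10)R;")
  aln <- aa_alignment(c("A", "B", "C"), c("L", "I", "V"))
  expect_equal(suppressWarnings(site_log_likelihood(t1, aln, Q, 1)),
               suppressWarnings(site_log_likelihood(t2, aln, Q, 1)),
               tolerance = 1e-8)
})

test_that("likelihood stays finite on a 40-taxon, 281-site alignment", {
  Q <- jtt_Q()
  tr <- random_tree(40, mean_branch = 0.08, seed = 21)
  sim <- simulate_alignment(tr, Q, 281, seed = 22)
  ll <- tree_log_likelihood(tr, sim$tip_alignment, Q)
  expect_true(is.finite(ll))
  expect_lt(ll, 0)
})

test_that("identical sequences drive branch lengths to the lower bound", {
  Q <- jtt_Q()
  tr <- ape::read.tree(text = "(A:0.3,B:0.4)R;")
  aln <- aa_alignment(c("A", "B"), strrep("LIVMARN", 2)[c(1, 1)])
  fit <- optimize_branch_lengths(tr, aln, Q)
  expect_true(all(fit$edge.length < 1e-6))
  conv <- attr(fit, "convergence")
  expect_gte(conv$loglik, tree_log_likelihood(tr, aln, Q))
})

test_that("an identical-state site is more likely than a two-state site", {
  Q <- jtt_Q()
  tr <- ape::read.tree(text = "(A:0.05,B:0.05)R;")
  same <- aa_alignment(c("A", "B"), c("L", "L"))
  diff <- aa_alignment(c("A", "B"), c("L", "I"))
  expect_gt(site_log_likelihood(tr, same, Q, 1),
            site_log_likelihood(tr, diff, Q, 1))
})
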