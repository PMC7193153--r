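fx <- rh2_annotated_tree()

test_that("branch shifts are signed descendant minus ancestor with flags", {
  sh <- branch_shifts(fx$tree)
  expect_true(all(sh$delta == sh$lambda_desc - sh$lambda_anc))
  jf <- sh[sh$ancestor == "AncAgnatha" & sh$descendant == "AncJawedFish", ]
  expect_identical(jf$delta, -15L)
  expect_true(jf$significant); expect_false(jf$large)
  e4 <- sh[sh$ancestor == "AncEuteleost2" & sh$descendant == "AncEuteleost4", ]
  expect_identical(e4$delta, 35L)
  expect_true(e4$significant && e4$large)
  expect_true(all(sh$significant[sh$large]))     # large implies significant
  tp <- sh[sh$ancestor == "AncJawedFish" & sh$descendant == "AncTetrapod", ]
  expect_identical(tp$delta, 0L)
  expect_false(tp$significant)
  bare <- random_tree(4, seed = 1)
  expect_error(branch_shifts(bare), "no lambda_max")
})

test_that("unannotated endpoints are skipped and reported", {
  tr <- suppressWarnings(validate_tree(ape::read.tree(text = "((A:1,B:1):1,C:1)R;")))
  tr <- set_lambda_max(tr, c(R = 500, A = 510, C = 490))
  sh <- branch_shifts(tr)
  expect_identical(nrow(sh), 1L)                 # only R->C has both endpoints
  expect_identical(sh$descendant, "C")
  expect_identical(nrow(attr(sh, "skipped")), 3L)
})

test_that("the shift census counts significant and large branches", {
  sh <- branch_shifts(fx$tree)
  cs <- count_shifts(sh)
  expect_identical(cs$n_significant, 16L)
  expect_identical(cs$n_large, 3L)
  expect_identical(cs$listing$delta[1], 35L)      # sorted by |delta| descending
  empty <- count_shifts(sh[0, ])
  expect_identical(empty$n_significant, 0L)
  expect_identical(empty$n_large, 0L)
  # monotone nonincreasing in the threshold
  ns <- vapply(c(5, 10, 20, 30, 40), function(th)
    count_shifts(sh, significance = th)$n_significant, integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("significant branches equal the fixture's thick-branch flags", {
  sh <- branch_shifts(fx$tree)
  thick <- fx$annotations$node_label[fx$annotations$thick_branch]
  expect_setequal(sh$descendant[sh$significant], thick)
})

test_that("deltas telescope along every root-to-tip path", {
  sim <- simulate_annotated_tree(20, shift_prob = 0.2, seed = 6)
  sh <- branch_shifts(sim$tree)
  lam <- sim$tree$lambda_max
  root <- "N1"
  for (tip in sim$tree$tip.label) {
    total <- 0
    node <- tip
    while (node != root) {
      row <- sh[sh$descendant == node, ]
      total <- total + row$delta
      node <- row$ancestor
    }
    expect_identical(total, lam[[tip]] - lam[[root]])
  }
})

test_that("assays are classified by the mutant-descendant residual", {
  assays <- rh2_mutation_assays()
  out <- classify_explained(assays)
  expect_identical(out$n_evaluable, 16L)
  expect_identical(out$n_explained, 8L)
  v <- out$verdicts
  expect_true(v$explained[v$ancestor == "AncAgnatha" & v$mutations == "E122Q"])
  expect_false(v$explained[v$descendant == "loosejaw"])   # |480-468| = 12 > 4
  expect_false(v$explained[v$mutations == "D83N"])
  # exact-match row is explained at any tolerance including zero
  exact <- data.frame(ancestor = "x", ancestor_lambda = 500, mutations = "E122Q",
                      mutant_lambda = 488, descendant = "y", descendant_lambda = 488)
  expect_true(classify_explained(exact, tolerance = 0)$verdicts$explained)
  expect_identical(classify_explained(assays, tolerance = 0)$n_explained, 0L)
  expect_identical(classify_explained(assays, tolerance = Inf)$n_explained, 16L)
  # incomplete rows are unevaluable, not errors
  assays$mutant_lambda[3] <- NA
  out2 <- classify_explained(assays)
  expect_identical(out2$n_evaluable, 15L)
  expect_true(is.na(out2$verdicts$explained[3]))
})

test_that("fraction explained uses half-away-from-zero integer rounding", {
  expect_identical(fraction_explained(489, 504, 524),
                   list(contribution_nm = 15, percent = 43))
  expect_identical(fraction_explained(489, 509, 524)$percent, 57)
  expect_identical(fraction_explained(489, 510, 524)$percent, 60)
  expect_identical(fraction_explained(489, 489, 524)$percent, 0)
  expect_identical(fraction_explained(500, 495, 490)$percent, 50)
  expect_error(fraction_explained(488, 490, 488), "undefined")
})

test_that("mutation labels parse and invalid ones are rejected", {
  m <- parse_mutation(c("E122Q", "A292S"))
  expect_identical(m$site, c(122L, 292L))
  expect_identical(m$from, c("E", "A"))
  expect_error(parse_mutation("E122"), "unparseable")
  expect_error(parse_mutation("E999Q"), "354")
  expect_error(parse_mutation("E122E"), "identical")
})

test_that("critical-site substitutions are traced and counted", {
  tra <- trace_site_substitutions(fx$tree, fx$critical_states)
  expect_identical(tra$counts[c("E122Q", "Q122E", "M207L", "A292S")],
                   c(E122Q = 3L, Q122E = 4L, M207L = 2L, A292S = 1L))
  expect_identical(sum(tra$counts), 10L)         # no unreported events
  # two-node toy
  tr <- ape::read.tree(text = "(A:1,B:1)R;")
  st <- matrix(c("E", "Q", "E"), 3, 1, dimnames = list(c("R", "A", "B"), "122"))
  ev <- trace_site_substitutions(tr, st)
  expect_identical(ev$events$label, "E122Q")
  same <- trace_site_substitutions(tr, matrix("E", 3, 1,
            dimnames = list(c("R", "A", "B"), "122")))
  expect_identical(nrow(same$events), 0L)
  bad <- matrix(c("E", "Z", "E"), 3, 1, dimnames = list(c("R", "A", "B"), "122"))
  expect_error(trace_site_substitutions(tr, bad), "invalid")
})

test_that("polymorphic sites and the adaptive fraction are counted", {
  ref <- paste(rep("A", 130), collapse = "")
  s1 <- ref
  s2 <- ref; substr(s2, 122, 122) <- "Q"         # critical polymorphic
  substr(s2, 40, 40) <- "S"; substr(s2, 50, 50) <- "T"; substr(s2, 60, 60) <- "V"
  aln <- aa_alignment(c("bovineRH1", "p1", "p2"), c(ref, s1, s2),
                      reference_name = "bovineRH1", site_window = c(31, 130))
  out <- classify_sites(aln)
  expect_identical(out$n_polymorphic, 4L)
  expect_identical(out$adaptive_fraction, 25.0)
  expect_identical(out$n_polymorphic + out$n_monomorphic, 100L)
  same <- aa_alignment(c("bovineRH1", "p"), c(ref, ref),
                       reference_name = "bovineRH1", site_window = c(31, 130))
  expect_identical(classify_sites(same)$n_polymorphic, 0L)
  expect_error(classify_sites(aa_alignment("only", ref)), "at least two")
})
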