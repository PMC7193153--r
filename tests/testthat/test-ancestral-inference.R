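test_that("a concordant star tree reconstructs its root state with high confidence", {
  Q <- jtt_Q()
  tr <- ape::read.tree(text = "(A:0.01,B:0.01,C:0.01)R;")
  aln <- aa_alignment(c("A", "B", "C"), c("E", "E", "E"))
  rec <- marginal_reconstruction(tr, aln, Q)
  expect_identical(rec$map_sequence[["R"]], "E")
  expect_gt(rec$pp[["R"]]["E", 1], 0.99)
  expect_lt(abs(sum(rec$pp[["R"]][, 1]) - 1), 1e-9)
})

test_that("posteriors equal the clamp-and-renormalize oracle on small trees", {
  Q <- build_rate_matrix(load_model("WAG"))
  for (rep in 1:6) {
    tr <- random_tree(sample(3:4, 1), seed = 13 * rep)
    sim <- simulate_alignment(tr, Q, 2, seed = 17 * rep)
    rec <- marginal_reconstruction(tr, sim$tip_alignment, Q)
    for (nd in rec$node_ids) {
      for (s in 1:2) {
        oracle <- clamp_pp_oracle(tr, sim$tip_alignment, Q, nd, s)
        expect_equal(unname(rec$pp[[nd]][, s]), oracle, tolerance = 1e-9)
      }
    }
  }
})

test_that("every posterior vector sums to one and MAP states are argmaxes", {
  Q <- jtt_Q()
  tr <- random_tree(10, seed = 44)
  sim <- simulate_alignment(tr, Q, 30, seed = 45)
  rec <- marginal_reconstruction(tr, sim$tip_alignment, Q)
  for (nd in rec$node_ids) {
    expect_lt(max(abs(colSums(rec$pp[[nd]]) - 1)), 1e-9)
    map <- strsplit(rec$map_sequence[[nd]], "")[[1]]
    idx <- apply(rec$pp[[nd]], 2, which.max)
    expect_identical(map, aa_states()[idx])
  }
})

test_that("reconstruction is invariant to tip input order", {
  Q <- jtt_Q()
  tr <- random_tree(6, seed = 51)
  sim <- simulate_alignment(tr, Q, 20, seed = 52)
  aln <- sim$tip_alignment
  set.seed(53)
  perm <- sample(length(aln$names))
  shuffled <- aa_alignment(aln$names[perm], aln$seqs[perm])
  a <- marginal_reconstruction(tr, aln, Q)
  b <- marginal_reconstruction(tr, shuffled, Q)
  expect_identical(a$map_sequence, b$map_sequence)
  expect_equal(a$pp, b$pp, tolerance = 1e-12)
})

test_that("high-posterior sites recover the simulated ancestral truth", {
  Q <- jtt_Q()
  tr <- random_tree(40, mean_branch = 0.08, seed = 21)
  sim <- simulate_alignment(tr, Q, 281, seed = 22)
  rec <- marginal_reconstruction(tr, sim$tip_alignment, Q)
  hits_hi <- c(); hits_mid <- c()
  for (nd in rec$node_ids) {
    map <- strsplit(rec$map_sequence[[nd]], "")[[1]]
    tru <- strsplit(sim$ancestral_sequences[[nd]], "")[[1]]
    pp <- rec$pp[[nd]][cbind(match(map, aa_states()), seq_along(map))]
    hits_hi <- c(hits_hi, (map == tru)[pp >= 0.95])
    hits_mid <- c(hits_mid, (map == tru)[pp >= 0.70 & pp < 0.95])
  }
  expect_gt(length(hits_hi), 1000)
  expect_gte(mean(hits_hi), 0.90)         # calibration at the high-PP bin
  expect_gte(mean(hits_mid), 0.60)        # mid bin brackets its nominal range
})

test_that("concordance bins agree with hand-enumerated fixtures", {
  a <- fake_reconstruction("root", c("E", "L", "Q", "M", "V"),
                           c(0.99, 0.97, 0.80, 0.98, 0.99))
  b <- fake_reconstruction("root", c("E", "L", "Q", "M", "A"),
                           c(0.98, 0.96, 0.75, 0.99, 0.97))
  cs <- concordance(a, b, "root")
  expect_identical(c(cs$n_identical_high, cs$n_identical_mid,
                     cs$n_identical_low, cs$n_different),
                   c(3L, 1L, 0L, 1L))
  expect_identical(cs$n_identical_high + cs$n_identical_mid +
                     cs$n_identical_low + cs$n_different, cs$n_sites)
  same <- concordance(a, a, "root")
  expect_identical(same$n_identical_high, 4L)   # one site sits below 0.95
  expect_identical(same$n_different, 0L)
  b2 <- fake_reconstruction("root", c("E", "L"), c(0.9, 0.9), sites = 1:2)
  expect_error(concordance(a, b2, "root"), "different site windows")
  expect_error(concordance(a, b, "nope"), "absent")
})

test_that("site state reports are deterministic lookups into the posteriors", {
  Q <- jtt_Q()
  tr <- random_tree(8, seed = 61)
  sim <- simulate_alignment(tr, Q, 300, seed = 62)
  aln <- sim$tip_alignment
  rec <- marginal_reconstruction(tr, aln, Q)
  rep3 <- site_state_report(rec, c(122, 207, 292))
  expect_identical(nrow(rep3), 3L * length(rec$node_ids))
  for (i in seq_len(nrow(rep3))) {
    v <- rec$pp[[rep3$node[i]]][, rep3$site[i]]
    expect_identical(rep3$state[i], aa_states()[which.max(v)])
    expect_equal(rep3$pp[i], max(v))
  }
  outside <- site_state_report(rec, 9999)
  expect_true(all(is.na(outside$state)))        # absent, not an error
})

test_that("reconstructions export to TSV and FASTA", {
  Q <- jtt_Q()
  tr <- random_tree(4, seed = 71)
  sim <- simulate_alignment(tr, Q, 12, seed = 72)
  rec <- marginal_reconstruction(tr, sim$tip_alignment, Q)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_reconstruction(rec, tsv, fa)
  tab <- read.delim(tsv)
  expect_identical(nrow(tab), length(rec$node_ids) * 12L)
  expect_lt(max(abs(rowSums(tab[, aa_states()]) - 1)), 1e-5)
  expect_identical(read_fasta(fa)$seqs, unname(rec$map_sequence))
})
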