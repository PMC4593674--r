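test_that("branch-site parameter class proportions are a valid mixture", {
  p <- branch_site_params(2, 0.3, 4, 0.5, 0.3)
  pr <- class_proportions(p)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_true(all(pr >= 0))
  expect_equal(unname(pr["p2a"] / pr["p2b"]), 0.5 / 0.3, tolerance = 1e-12)
  expect_error(branch_site_params(2, 1.2, 4, 0.5, 0.3))
  expect_error(branch_site_params(2, 0.3, 0.5, 0.5, 0.3))
})

test_that("pruning equals exhaustive enumeration on 3- and 4-tip trees", {
  set.seed(21)
  trees <- list(
    parse_newick("((A:0.2,B:0.3)#1:0.15,C:0.4);"),
    parse_newick("((A:0.15,B:0.25):0.1,(C:0.3,D:0.2)#1:0.12);"),
    parse_newick("(((A:0.1,B:0.2)#1:0.1,C:0.25):0.15,D:0.3);"))
  for (tr in trees) {
    ntip <- ape::Ntip(tr)
    for (rep in 1:2) {
      pars <- branch_site_params(runif(1, 1, 4), runif(1, 0.05, 0.9),
                                 1 + rexp(1, 0.5),
                                 p0 = runif(1, 0.2, 0.6),
                                 p1 = runif(1, 0.1, 0.3))
      pi <- omegascan:::.regularize_pi(rgamma(61, 2))
      aln <- h_random_aln(tr$tip.label, 3, seed = rep * 100 + ntip,
                          miss_prob = 0.15)
      lnL <- gene_log_likelihood(aln, tr, pars, pi)
      oracle <- oracle_exhaustive_loglik(aln, tr, pars, pi)
      expect_equal(as.numeric(lnL), oracle, tolerance = 1e-10)
    }
  }
})

test_that("zero-length trees recover the stationary log-probability", {
  tr <- parse_newick("((A:0,B:0)#1:0,C:0);")
  pi <- h_pi_skew()
  pars <- h_params_null()
  st <- matrix(rep(c(5L, 17L, 60L), each = 3), nrow = 3,
               dimnames = list(c("A", "B", "C"), NULL))
  aln <- codon_alignment(st)
  lnL <- gene_log_likelihood(aln, tr, pars, pi)
  expect_equal(as.numeric(lnL), sum(log(as.numeric(pi)[c(5, 17, 60)])),
               tolerance = 1e-10)
  # conflicting states on a zero-length tree are impossible
  st2 <- st; st2["A", 2] <- 6L
  expect_identical(as.numeric(gene_log_likelihood(codon_alignment(st2),
                                                  tr, pars, pi)), -Inf)
})

test_that("likelihood is invariant to column order, taxon order and
           all-missing taxa", {
  tr <- h_tree6()
  pi <- h_pi_skew()
  pars <- branch_site_params(2.2, 0.25, 3, 0.5, 0.3)
  sim <- simulate_gene(tr, pars, pi, L = 60, seed = 8)
  aln <- sim$alignment
  base <- as.numeric(gene_log_likelihood(aln, tr, pars, pi))

  perm_cols <- codon_alignment(aln$states[, sample(60)])
  expect_equal(as.numeric(gene_log_likelihood(perm_cols, tr, pars, pi)),
               base, tolerance = 1e-10)

  perm_taxa <- codon_alignment(aln$states[sample(nrow(aln$states)), ])
  expect_equal(as.numeric(gene_log_likelihood(perm_taxa, tr, pars, pi)),
               base, tolerance = 1e-10)

  # an extra all-missing taxon, with its tip pruned, changes nothing;
  # equivalently: masking one taxon to all-missing equals pruning that tip
  aln_mask <- aln$states
  aln_mask["camel", ] <- NA_integer_
  lnl_mask <- as.numeric(gene_log_likelihood(codon_alignment(aln_mask),
                                             tr, pars, pi))
  tr_drop <- prune_to_taxa(tr, setdiff(tr$tip.label, "camel"))
  aln_drop <- codon_alignment(aln$states[tr_drop$tip.label, ])
  lnl_drop <- as.numeric(gene_log_likelihood(aln_drop, tr_drop, pars, pi))
  expect_equal(lnl_mask, lnl_drop, tolerance = 1e-8)
})

test_that("pattern collapsing matches the uncollapsed computation", {
  tr <- h_tree6()
  pi <- uniform_codon_frequencies()
  pars <- h_params_sel(4)
  sim <- simulate_gene(tr, pars, pi, L = 40, seed = 13)
  aln <- sim$alignment
  # duplicate every column; lnL must double exactly
  dup <- codon_alignment(aln$states[, rep(1:40, 2)])
  l1 <- as.numeric(gene_log_likelihood(aln, tr, pars, pi))
  l2 <- as.numeric(gene_log_likelihood(dup, tr, pars, pi))
  expect_equal(l2, 2 * l1, tolerance = 1e-9)
})

test_that("likelihood requires a foreground flag and matching taxa", {
  tr <- h_tree6(NULL)
  aln <- h_random_aln(tr$tip.label, 5, seed = 1)
  expect_error(gene_log_likelihood(aln, tr, h_params_null(),
                                   uniform_codon_frequencies()),
               "foreground")
  tr2 <- h_tree6()
  aln2 <- h_random_aln(c("dolphin", "whale", "hippo"), 5, seed = 1)
  expect_error(gene_log_likelihood(aln2, tr2, h_params_null(),
                                   uniform_codon_frequencies()),
               "absent")
})
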