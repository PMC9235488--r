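test_that("two-rate parameters follow the printed construction", {
  r <- derive_rates(0.3, 0.3, 0.04)
  expect_equal(r$tau1, 0.246939, tolerance = 1e-5)
  expect_equal(r$tau2, 0.753061, tolerance = 1e-5)
  expect_equal(r$mu_s, 0.04)
  expect_equal(r$mu_l, 1.09289, tolerance = 1e-5)
  for (d in c(0.05, 0.3, 2))
    expect_equal(derive_rates(d, 0.3, 0.04)$tau1 +
                   derive_rates(d, 0.3, 0.04)$tau2, 1)
  # long branch not longer than the scaled short branch
  expect_error(derive_rates(0.3, 0.02, 0.04), "invalid")
  # tau1 collapses for huge d: mu_l explodes past the guard
  expect_error(derive_rates(45, 0.3, 0.04), "1e6")
})

test_that("coalescent gene trees are valid ultrametric binary trees", {
  set.seed(51)
  sp <- felsenstein_species_tree(0.3)
  g <- msc_gene_trees(sp, 10)
  for (tr in g) {
    expect_s3_class(tr, "phylo")
    expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
    expect_equal(tr$Nnode, 3L)
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    expect_true(all(tr$edge.length >= 0))
  }
  expect_error(msc_gene_trees(ape::read.tree(text = "((A:1,B:2):1,C:3);"), 1),
               "ultrametric")
})

test_that("gene-tree topology frequencies match the coalescent law", {
  set.seed(52)
  n <- 3e4
  sm <- msc_quartet_summary(felsenstein_species_tree(0.3), n)
  expect_lt(abs(sm$freq[1] - (1 - (2 / 3) * exp(-0.3))), 0.012)
  expect_lt(abs(sm$freq[2] - (1 / 3) * exp(-0.3)), 0.012)

  # star species tree: all three topologies equally likely
  star <- ape::read.tree(text = "((A:1,B:1):0,(C:1,D:1):0);")
  sm0 <- msc_quartet_summary(star, n)
  expect_true(all(abs(sm0$freq - 1 / 3) < 0.012))
})

test_that("mean terminal extension above speciation follows the lemma", {
  set.seed(53)
  n <- 3e4
  # d = 0: exactly 2/3
  star <- ape::read.tree(text = "((A:1,B:1):0,(C:1,D:1):0);")
  expect_lt(abs(msc_quartet_summary(star, n)$mean_extension - 2 / 3), 0.02)
  for (d in c(0.1, 0.3)) {
    sm <- msc_quartet_summary(felsenstein_species_tree(d), n)
    expect_lt(abs(sm$mean_extension - (1 - exp(-d) / 3)), 0.02)
  }
})

test_that("the two-rate map multiplies segments by their species-branch rate", {
  cond <- felsenstein_condition(0.3, 0.3, 0.04, seq_len = 100, n_genes = 1)
  tau1 <- cond$tau1
  # gene tree congruent with the species tree, cherries at the root age:
  # every pendant spans its terminal species branch then short-rate branches
  root_age <- tau1 + 0.3 / 2
  h <- 1.0   # cherry height, above the species root
  gt <- ape::read.tree(text = sprintf(
    "((A:%.10f,B:%.10f):%.10f,(C:%.10f,D:%.10f):%.10f);",
    h, h, 0.2, h, h, 0.2))
  mapped <- apply_two_rate_map(gt, cond)
  pl <- pendant_lengths(mapped)
  expect_equal(unname(pl["A"]), cond$mu_l * tau1 + cond$mu_s * (h - tau1),
               tolerance = 1e-9)
  expect_equal(unname(pl["B"]), cond$mu_s * h, tolerance = 1e-9)

  # homogeneity: doubling both rates doubles every branch
  cond2 <- list(species_tree = cond$species_tree,
                rates = rep(2 * cond$mu_s, 7),
                above_root_rate = 2 * cond$mu_s)
  cond1 <- list(species_tree = cond$species_tree,
                rates = rep(cond$mu_s, 7),
                above_root_rate = cond$mu_s)
  m1 <- apply_two_rate_map(gt, cond1)
  m2 <- apply_two_rate_map(gt, cond2)
  expect_equal(m2$edge.length, 2 * m1$edge.length, tolerance = 1e-12)
})

test_that("mapped terminal branches have expected lengths l and s", {
  set.seed(54)
  cond <- felsenstein_condition(0.3, 0.3, 0.04, n_genes = 1)
  n <- 1e4
  tot <- c(A = 0, B = 0, C = 0, D = 0)
  for (i in 1:n) {
    gt <- msc_gene_trees(cond$species_tree, 1)
    tot <- tot + pendant_lengths(apply_two_rate_map(gt, cond))[names(tot)]
  }
  avg <- tot / n
  expect_lt(abs(avg[["A"]] / 0.3 - 1), 0.03)
  expect_lt(abs(avg[["C"]] / 0.3 - 1), 0.03)
  expect_lt(abs(avg[["B"]] / 0.04 - 1), 0.03)
  expect_lt(abs(avg[["D"]] / 0.04 - 1), 0.03)
})

test_that("the relaxed clock draws Gamma multipliers with mean 1, var 1/5", {
  set.seed(55)
  base <- ape::rtree(1000, br = function(n) rep(1, n))
  mult <- unlist(lapply(1:50, function(i)
    gamma_clock_map(base, overall_rate = 1, shape = 5,
                    scale = 1 / 5)$edge.length))
  expect_lt(abs(mean(mult) - 1), 0.01)
  expect_lt(abs(stats::var(mult) - 0.2), 0.01)

  z <- gamma_clock_map(base, overall_rate = 0)
  expect_true(all(z$edge.length == 0))

  set.seed(56); a <- gamma_clock_map(base, 0.02)
  set.seed(56); b <- gamma_clock_map(base, 0.02)
  expect_identical(a$edge.length, b$edge.length)
})

test_that("JC69 simulation matches the pairwise difference formula", {
  set.seed(57)
  two <- ape::read.tree(text = "(A:0.05,B:0.05);")
  aln <- simulate_jc69(two, 1e5)
  expect_lt(abs(mean(aln[1, ] != aln[2, ]) - 0.75 * (1 - exp(-0.4 / 3))),
            0.005)

  zero <- ape::read.tree(text = "(A:0,B:0);")
  az <- simulate_jc69(zero, 1000)
  expect_identical(az[1, ], az[2, ])

  sat <- ape::read.tree(text = "(A:15,B:15);")
  as_ <- simulate_jc69(sat, 1e5)
  expect_lt(abs(mean(as_[1, ] != as_[2, ]) - 0.75), 0.01)

  neg <- ape::read.tree(text = "(A:-1,B:1);")
  expect_error(simulate_jc69(neg, 10), "negative")
})

test_that("quartet likelihoods are symmetric on constant alignments", {
  aln <- matrix("A", 4, 50, dimnames = list(c("A", "B", "C", "D"), NULL))
  ll <- quartet_loglik_table(aln)
  expect_lt(max(ll) - min(ll), 1e-6)
})

test_that("the likelihood engine identifies the generating topology", {
  set.seed(58)
  gen <- ape::read.tree(text = "((A:0.1,B:0.1):0.25,(C:0.1,D:0.1):0.25);")
  aln <- simulate_jc69(gen, 1e4)
  ll <- quartet_loglik_table(aln)
  expect_equal(which.max(ll), 1L)
  P <- build_P_from_loglik(matrix(ll, 3, 1), KEY4)
  expect_gt(P$P[1, 1], 0.99)
})

test_that("pruning equals the exhaustive 16-state sum and a grid oracle", {
  set.seed(59)
  gen <- ape::read.tree(text = "((A:0.2,B:0.1):0.15,(C:0.05,D:0.3):0.15);")
  aln <- simulate_jc69(gen, 20)
  pat <- quartetco:::.aln_patterns(aln)
  for (j in 1:3) {
    for (rep in 1:3) {
      b <- runif(5, 0.01, 1)
      mine <- quartet_topology_loglik(aln, j, branch_lengths = b)
      brute <- sum(pat$counts * log(vapply(seq_along(pat$counts), function(i)
        bruteforce_jc_site(pat$states[, i], quartetco:::.topology_pairs[[j]],
                           b), numeric(1))))
      expect_equal(mine, brute, tolerance = 1e-10)
    }
    opt <- quartet_topology_loglik(aln, j)
    oracle <- coordinate_descent_ll(function(b)
      quartet_topology_loglik(aln, j, branch_lengths = b))
    expect_equal(opt, oracle$ll, tolerance = 1e-4)
  }
})

test_that("the fixed-lengths likelihood agrees with phangorn", {
  skip_if_not_installed("phangorn")
  set.seed(60)
  gen <- ape::read.tree(text = "((A:0.1,B:0.1):0.25,(C:0.1,D:0.1):0.25);")
  aln <- simulate_jc69(gen, 2000)
  b <- c(0.1, 0.12, 0.09, 0.11, 0.3)
  mine <- quartet_topology_loglik(aln, 1, branch_lengths = b)
  dat <- phangorn::phyDat(aln, type = "DNA")
  tr <- ape::read.tree(text = "((A:0.1,B:0.12):0.3,C:0.09,D:0.11);")
  expect_equal(mine, phangorn::pml(tr, dat)$logLik, tolerance = 1e-6)
})

test_that("replicate simulation is reproducible and correctly shaped", {
  cond <- felsenstein_condition(0.3, 0.3, 0.04, seq_len = 120, n_genes = 4,
                                seed = 61)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_condition(cond, d1)
  simulate_condition(cond, d2)
  fastas <- list.files(d1, pattern = "\\.fasta$")
  expect_length(fastas, 4)
  a <- read_fasta(file.path(d1, fastas[1]))
  expect_equal(dim(a), c(4L, 120L))
  expect_setequal(rownames(a), c("A", "B", "C", "D"))
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  coal <- ape::read.tree(file.path(d1, "gene_trees_coalescent.nwk"))
  expect_length(coal, 4)
  expect_true(file.exists(file.path(d1, "manifest.tsv")))

  # per-gene stream reproducibility in isolation
  g3a <- simulate_gene(cond, 3)
  g3b <- simulate_gene(cond, 3)
  expect_identical(g3a$alignment, g3b$alignment)
  expect_identical(write_newick(g3a$coal_tree), write_newick(g3b$coal_tree))

  an <- anomaly_condition(n_genes = 2, seq_len = 600, seed = 62)
  ga <- simulate_gene(an, 1)
  expect_equal(dim(ga$alignment), c(6L, 600L))
  expect_true(ape::is.ultrametric(an$species_tree))
})
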