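test_that("all_quartets enumerates exactly choose(n, 4) canonical keys", {
  expect_length(all_quartets(paste0("t", 1:6)), 15)
  expect_length(all_quartets(paste0("t", 1:4)), 1)
  for (n in 4:12)
    expect_length(all_quartets(paste0("s", sprintf("%02d", 1:n))),
                  choose(n, 4))
  qs <- all_quartets(c("d", "c", "b", "a", "e"))
  expect_true(all(vapply(qs, function(k)
    identical(unclass(k), sort(unclass(k))), logical(1))))
  expect_length(unique(vapply(qs, paste, character(1), collapse = "|")), 5)
  expect_error(all_quartets(c("a", "b", "c")), "at least 4")
})

test_that("leaf walks favor leaves near the polytomy by the product rule", {
  # side ((L1,L2),L3) hanging off a degree-3 polytomy fixture
  guide <- ape::read.tree(text = "(((L1,L2),L3),A,B);")
  ua <- quartetco:::.unrooted_adjacency(guide)
  root <- length(guide$tip.label) + 1L
  side <- setdiff(ua$adj[[root]], match(c("A", "B"), guide$tip.label))
  # single-leaf side is returned with probability 1
  expect_equal(sample_leaf_from_side(guide, root,
                                     match("A", guide$tip.label)), "A")
  set.seed(41)
  draws <- vapply(1:100000, function(i)
    quartetco:::.leaf_walk(ua$adj, ua$ntip, side, root, guide$tip.label),
    character(1))
  freq <- table(draws) / length(draws)
  expect_equal(unname(freq[["L3"]]), 0.5, tolerance = 0.02)
  expect_equal(unname(freq[["L1"]]), 0.25, tolerance = 0.04)
  expect_equal(unname(freq[["L2"]]), 0.25, tolerance = 0.04)
})

test_that("polytomy sampling respects rounds, caps and side-distinctness", {
  # degree 4: clades hanging off a star root; 300 rounds of 1 quartet
  g4 <- ape::read.tree(text = "((A1,A2),(B1,B2),(C1,C2),(D1,D2));")
  set.seed(42)
  qs <- sample_quartets_around_polytomy(g4, 9L, quartet_budget(1200))
  expect_lte(length(qs), 300)
  expect_gt(length(qs), 1)
  sides <- list(c("A1", "A2"), c("B1", "B2"), c("C1", "C2"), c("D1", "D2"))
  for (q in qs) {
    membership <- vapply(q, function(leaf)
      which(vapply(sides, function(s) leaf %in% s, logical(1))), integer(1))
    expect_length(unique(membership), 4)
  }

  # degree 6 star of leaves: every round emits all C(6,4) quartets
  g6 <- ape::read.tree(text = "(a,b,c,d,e,f);")
  set.seed(43)
  qs6 <- sample_quartets_around_polytomy(g6, 7L, quartet_budget(1200))
  expect_length(qs6, 15)

  # degree 19 with the 12-side cap: at most floor(1200/19) * C(12,4) quartets
  g19 <- ape::read.tree(text = paste0("(", paste(paste0("x", 1:19),
                                                 collapse = ","), ");"))
  set.seed(44)
  qs19 <- sample_quartets_around_polytomy(g19, 20L, quartet_budget(1200))
  expect_lte(length(qs19), 63 * 495)
  expect_gt(length(qs19), 495)
  expect_true(all(vapply(qs19, function(q) length(unique(q)) == 4,
                         logical(1))))

  g3 <- ape::read.tree(text = "(p,q,r);")
  expect_warning(empty <- sample_quartets_around_polytomy(
    g3, 4L, quartet_budget(1200)), "degree")
  expect_length(empty, 0)
})

test_that("quartet selection contracts the guide and samples its polytomies", {
  # star guide: every quartet is eventually sampled
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  sel <- select_quartets(star, quartet_budget(seed = 45))
  expect_length(sel$quartets, 5)

  # fully supported resolved guide: nothing to refine
  resolved <- ape::read.tree(text = "(((A,B)1.0,C)1.0,((D,E)1.0,F)1.0);")
  expect_message(sel2 <- select_quartets(resolved, quartet_budget(seed = 46)),
                 "fully resolved")
  expect_length(sel2$quartets, 0)
  expect_true(ape::all.equal.phylo(sel2$guide, resolved))

  # one weak branch: all sampled quartets have one leaf per polytomy side
  g8 <- ape::read.tree(text =
    "((((A,B)1.0,(C,D)1.0)0.5,(E,F)1.0)1.0,(G,H)1.0);")
  sel3 <- select_quartets(g8, quartet_budget(seed = 47))
  sides <- list(c("A", "B"), c("C", "D"), c("E", "F"), c("G", "H"))
  expect_gt(length(sel3$quartets), 0)
  for (q in sel3$quartets) {
    membership <- vapply(q, function(leaf)
      which(vapply(sides, function(s) leaf %in% s, logical(1))), integer(1))
    expect_length(unique(membership), 4)
  }
})

test_that("exact supertree recovers compatible inputs and takes majorities", {
  tru <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  qt <- lapply(all_quartets(LETTERS[1:5]), function(k)
    topology_newick(k, induced_quartet_topology(tru, k)))
  st <- exact_supertree(qt, LETTERS[1:5])
  expect_equal(attr(st, "score"), 5L)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tru), st)), 0)

  # majority on conflict: two AB|CD beat one AC|BD
  maj <- exact_supertree(list("((A,B),(C,D));", "((A,C),(B,D));",
                              "((A,B),(C,D));"), LETTERS[1:4])
  expect_equal(induced_quartet_topology(maj, KEY4), 1L)
  expect_equal(attr(maj, "score"), 2L)

  # search-space size: (2n-5)!! unrooted topologies
  st6 <- exact_supertree(list("((A,B),(C,D));"), LETTERS[1:6])
  expect_equal(attr(st6, "n_candidates"), 105L)
  expect_error(exact_supertree(list("((A,B),(C,D));"), paste0("t", 1:9)),
               "capped")
})

test_that("the enumerator visits every unrooted topology exactly once", {
  cands <- quartetco:::.enumerate_unrooted(6)
  expect_length(cands, 105)
  # canonical signature: sorted non-trivial bipartitions, each oriented to
  # contain leaf 1
  sig <- vapply(cands, function(tr) {
    masks <- quartetco:::.edge_bipartitions(tr$edges, 6L)
    paste(sort(vapply(masks, function(m) {
      if (!m[1]) m <- !m
      paste(as.integer(m), collapse = "")
    }, character(1))), collapse = "|")
  }, character(1))
  expect_length(unique(sig), 105)
  # independent cardinality check against phangorn
  skip_if_not_installed("phangorn")
  expect_length(phangorn::allTrees(6), 105)
})

test_that("the supertree respects a multifurcating constraint", {
  cons <- ape::read.tree(text = "((A,B),C,D,(E,F));")
  qt <- list("((A,C),(E,F));", "((A,D),(E,C));")   # second conflicts w/ cons
  st <- exact_supertree(qt, LETTERS[1:6], constraint = cons)
  bip <- ape::prop.part(st)
  # the constrained clades {A,B} and {E,F} must appear in the result
  has_clade <- function(phy, labs) {
    pp <- ape::prop.part(phy)
    any(vapply(pp, function(p)
      setequal(attr(pp, "labels")[p], labs), logical(1)))
  }
  rooted <- ape::root(st, "A", resolve.root = TRUE)
  expect_true(has_clade(rooted, c("E", "F")) ||
                has_clade(rooted, setdiff(LETTERS[1:6], c("E", "F"))))
})

test_that("amalgamation export writes clean quartet files", {
  r1 <- ml_quartet(onehot_P(c(51, 29, 20)))
  r2 <- ml_quartet(onehot_P(c(5, 90, 5), quartet_key(c("C", "D", "E", "F"))))
  rt <- ml_quartet(quartet_posterior(quartet_key(c("A", "B", "E", "F")),
                                     matrix(1 / 3, 3, 6)))  # tied
  prefix <- file.path(withr::local_tempdir(), "run")
  expect_message(files <- export_for_amalgamation(list(r1, r2, rt), prefix,
                                                  guide = NULL),
                 "1 tie-flagged")
  lines <- readLines(paste0(prefix, "_quartets.nwk"))
  expect_length(lines, 2)
  trs <- lapply(lines, function(s) ape::read.tree(text = s))
  expect_equal(induced_quartet_topology(trs[[1]], r1$key), r1$t_hat)
  expect_equal(trs[[1]]$edge.length[!is.na(trs[[1]]$edge.length)][1] > 0, TRUE)

  guide <- ape::read.tree(text = "((A,B),C,D,(E,F));")
  files2 <- export_for_amalgamation(list(r1, r2), prefix, guide = guide)
  expect_true(file.exists(paste0(prefix, "_guide.nwk")))
  g2 <- ape::read.tree(paste0(prefix, "_guide.nwk"))
  expect_true(ape::all.equal.phylo(g2, guide))
})

test_that("six-taxon pipeline recovers the species tree from hard posteriors", {
  set.seed(48)
  # long internal branches => strong signal; one gene-tree sample per gene
  cond <- anomaly_condition(n_genes = 300, internal = 1.0, seed = 48)
  trees <- msc_gene_trees(cond$species_tree, 300)
  forests <- lapply(seq_along(trees), function(i)
    make_forest(write_newick(trees[[i]]), id = paste0("g", i)))
  inf <- infer_quartet_trees(forests, update = FALSE)
  st <- species_tree_from_quartets(inf$results)
  expect_equal(as.numeric(ape::dist.topo(st, ape::unroot(cond$species_tree))),
               0)
})
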