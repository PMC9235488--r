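# In-code fixtures shared across test files.

# Wrap newick strings as a gene_forest (no burn-in).
make_forest <- function(newicks, id = "g") {
  trees <- lapply(newicks, function(s) ape::read.tree(text = s))
  class(trees) <- "multiPhylo"
  structure(list(id = id, trees = trees, n_total = length(trees),
                 n_retained = length(trees), burnin_frac = 0,
                 taxa = sort(unique(unlist(lapply(trees, `[[`,
                                                  "tip.label"))))),
            class = "gene_forest")
}

KEY4 <- quartet_key(c("A", "B", "C", "D"))

# newick for topology j of a key (no branch lengths)
topology_newick <- function(key, j) {
  pr <- quartet_topologies(key)[[j]]
  sprintf("((%s,%s),(%s,%s));", pr[1, 1], pr[1, 2], pr[2, 1], pr[2, 2])
}

# One-hot posterior matrix with the given per-topology gene counts.
onehot_P <- function(counts, key = KEY4) {
  cols <- do.call(cbind, lapply(1:3, function(j) {
    m <- matrix(0, 3, counts[j])
    if (counts[j] > 0) m[j, ] <- 1
    m
  }))
  quartet_posterior(key, cols)
}

# Random soft posterior matrix (columns on the simplex).
random_P <- function(k, key = KEY4) {
  m <- matrix(rexp(3 * k), 3, k)
  quartet_posterior(key, sweep(m, 2, colSums(m), `/`))
}

# Closed-form profile log-likelihood for one-hot columns: n_match genes have
# P[t,i] = 1, the rest 0 (pre-regularization limit).
onehot_loglik <- function(n_match, n_total, d) {
  n_match * log(1 - (2 / 3) * exp(-d)) +
    (n_total - n_match) * log((1 / 3) * exp(-d))
}

# Dense-grid maximizer of the profile log-likelihood, vectorized
# independently of quartet_loglik()'s implementation.
grid_profile_max <- function(t, P, npts = 2e5) {
  p <- P$P[t, !P$missing]
  dseq <- seq(0, D_MAX, length.out = npts)
  A <- outer(1 / 3 - p, exp(-dseq)) + p
  ll <- colSums(log(A))
  i <- which.max(ll)
  list(d = dseq[i], loglik = ll[i])
}

# Brute-force JC69 site likelihood summing over the 16 internal state pairs.
# pairs: 2x2 position matrix; b: 5 branch lengths (terminals in key position
# order, internal last); states: length-4 site states in key position order.
bruteforce_jc_site <- function(states, pairs, b) {
  pmat <- function(blen) {
    E <- exp(-4 * blen / 3)
    m <- matrix((1 - E) / 4, 4, 4)
    diag(m) <- (1 - E) / 4 + E
    m
  }
  Pt <- lapply(1:4, function(pos) pmat(b[pos]))
  Pi <- pmat(b[5])
  tot <- 0
  for (x in 1:4) for (y in 1:4) {
    tot <- tot + 0.25 *
      Pt[[pairs[1, 1]]][x, states[pairs[1, 1]]] *
      Pt[[pairs[1, 2]]][x, states[pairs[1, 2]]] *
      Pi[x, y] *
      Pt[[pairs[2, 1]]][y, states[pairs[2, 1]]] *
      Pt[[pairs[2, 2]]][y, states[pairs[2, 2]]]
  }
  tot
}

# Cyclic coordinate-descent optimizer over the 5 branch lengths, built on
# stats::optimize only (independent of the package's L-BFGS-B route).
coordinate_descent_ll <- function(fn, b0 = rep(0.1, 5), iters = 40) {
  b <- b0
  for (it in seq_len(iters)) {
    for (i in 1:5) {
      o <- optimize(function(v) { bb <- b; bb[i] <- v; fn(bb) },
                    c(1e-9, 10), maximum = TRUE, tol = 1e-10)
      b[i] <- o$maximum
    }
  }
  list(b = b, ll = fn(b))
}

# Unrooted pendant edge lengths of a tree, named by leaf.
pendant_lengths <- function(phy) {
  u <- ape::unroot(phy)
  ntip <- length(u$tip.label)
  idx <- match(seq_len(ntip), u$edge[, 2])
  setNames(u$edge.length[idx], u$tip.label)
}

# Most-frequent-MAP-topology baseline (summary-method surrogate): each gene
# votes its MAP topology; the plurality topology wins.
map_frequency_baseline <- function(P) {
  maps <- apply(P$P[, !P$missing, drop = FALSE], 2, which.max)
  which.max(tabulate(maps, 3))
}
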