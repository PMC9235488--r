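#' Two-rate parameters for the long-branch-attraction quartet simulation
#'
#' For a balanced quartet species tree with total internal branch length `d`
#' (two internal branches of `d/2` each, coalescent units), computes the
#' terminal-branch length `tau1`, the expected gene-tree terminal extension
#' above the speciation nodes `tau2 = 1 - (1/3) exp(-d)`, and the two
#' mutation rates `mu_s`, `mu_l` such that the expected substitution-unit
#' lengths are `l` for the two long (non-sister) terminals, and `s` for the
#' other terminals and the internal branch.  Setting
#' `tau1 = 1 - tau2 = exp(-d)/3` makes the expected internal branch length
#' `s` as well, which is the long-branch-attraction regime when `l/s` is
#' large.
#'
#' @param d total coalescent-unit internal branch length, `> 0`.
#' @param l expected substitution-unit length of the two long terminals.
#' @param s expected substitution-unit length of the short branches.
#' @return list with `tau1`, `tau2`, `mu_s`, `mu_l`.
#' @examples
#' derive_rates(0.3, 0.3, 0.04)
#' @export
derive_rates <- function(d, l, s) {
  stopifnot(d > 0, l > 0, s > 0)
  tau2 <- 1 - exp(-d) / 3
  tau1 <- 1 - tau2
  mu_s <- s / (tau1 + tau2)          # tau1 + tau2 = 1 by construction
  mu_l <- (l - tau2 * mu_s) / tau1
  if (mu_l <= 0)
    stop("invalid condition: l <= tau2 * s, long branch not longer than ",
         "the scaled short branch")
  if (mu_l > 1e6)
    stop("invalid condition: mu_l exceeds 1e6 (tau1 too small for this d)")
  list(tau1 = tau1, tau2 = tau2, mu_s = mu_s, mu_l = mu_l)
}

#' Balanced quartet species tree of the long-branch-attraction simulation
#'
#' Topology `((A,B),(C,D))` with terminal branches `tau1 = exp(-d)/3` and two
#' internal branches of `d/2`, all in coalescent units.  Taxa `A` and `C`
#' (non-sisters) carry the long mutation rate.
#'
#' @param d total internal branch length in coalescent units.
#' @return a `phylo`.
#' @export
felsenstein_species_tree <- function(d) {
  tau1 <- exp(-d) / 3
  ape::read.tree(text = sprintf(
    "((A:%.12g,B:%.12g):%.12g,(C:%.12g,D:%.12g):%.12g);",
    tau1, tau1, d / 2, tau1, tau1, d / 2))
}

#' Felsenstein-zone simulation condition
#'
#' Bundles the parameters of one long-branch-attraction model condition:
#' gene trees are simulated under the multispecies coalescent on the
#' balanced quartet of [felsenstein_species_tree()], branch lengths are
#' converted to substitution units with the two-rate map of
#' [derive_rates()], and JC69 sequences of length `seq_len` are simulated.
#'
#' @param d coalescent-unit internal branch length (total across the two
#'   internal branches).
#' @param l,s expected substitution-unit lengths of long/short branches.
#' @param seq_len sites per gene alignment (default 1600).
#' @param n_genes number of genes (default 200).
#' @param seed master seed; per-gene streams are derived from it by counter.
#' @return object of class `"felsenstein_condition"`.
#' @export
felsenstein_condition <- function(d, l, s, seq_len = 1600, n_genes = 200,
                                  seed = 1) {
  rates <- derive_rates(d, l, s)
  sp <- felsenstein_species_tree(d)
  structure(c(list(d = d, l = l, s = s, seq_len = as.integer(seq_len),
                   n_genes = as.integer(n_genes), seed = as.integer(seed),
                   species_tree = sp, long_taxa = c("A", "C")),
              rates),
            class = "felsenstein_condition")
}

#' Anomaly-zone simulation condition
#'
#' A 6-taxon caterpillar species tree with short internal branches (default
#' 0.1 coalescent units each, inside published anomaly-zone bounds for
#' caterpillars), built ultrametric with the cherry at depth `cherry_depth`.
#' Gene trees are simulated under the multispecies coalescent; substitution
#' branch lengths are coalescent lengths times `overall_rate` times an
#' independent Gamma rate multiplier per branch (shape 5, scale 1/5: mean 1,
#' variance 1/5), creating deviations from ultrametricity.
#'
#' @param n_genes number of genes.
#' @param seq_len sites per gene (default 600).
#' @param seed master seed.
#' @param internal internal branch length in coalescent units (default 0.1).
#' @param cherry_depth age of the shallowest speciation (default 1.0).
#' @param overall_rate substitution rate per coalescent unit (default 0.02).
#' @param shape,scale Gamma rate-multiplier parameters (default 5 and 1/5).
#' @return object of class `"anomaly_condition"`.
#' @export
anomaly_condition <- function(n_genes = 200, seq_len = 600, seed = 1,
                              internal = 0.1, cherry_depth = 1.0,
                              overall_rate = 0.02, shape = 5, scale = 1 / 5) {
  taxa <- paste0("t", 1:6)
  ages <- cherry_depth + internal * (0:4)   # cherry, then 4 stacked nodes
  nwk <- sprintf(
    "(((((%s:%.12g,%s:%.12g):%.12g,%s:%.12g):%.12g,%s:%.12g):%.12g,%s:%.12g):%.12g,%s:%.12g);",
    taxa[1], ages[1], taxa[2], ages[1], internal, taxa[3], ages[2],
    internal, taxa[4], ages[3], internal, taxa[5], ages[4], internal,
    taxa[6], ages[5])
  structure(list(n_genes = as.integer(n_genes), seq_len = as.integer(seq_len),
                 seed = as.integer(seed), internal = internal,
                 cherry_depth = cherry_depth, overall_rate = overall_rate,
                 shape = shape, scale = scale,
                 species_tree = ape::read.tree(text = nwk)),
            class = "anomaly_condition")
}

# --- censored multispecies coalescent ---------------------------------------

# Preprocess an ultrametric species tree for coalescent simulation.
.species_prep <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  parent <- integer(nn)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  children <- vector("list", nn)
  for (r in seq_len(nrow(phy$edge)))
    children[[phy$edge[r, 1]]] <- c(children[[phy$edge[r, 1]]], phy$edge[r, 2])
  elen <- numeric(nn)
  elen[phy$edge[, 2]] <- phy$edge.length
  age <- rep(NA_real_, nn)
  age[seq_len(ntip)] <- 0
  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (r in seq_len(nrow(po))) {
    v <- po[r, 1]; c_ <- po[r, 2]
    a <- age[c_] + elen[c_]
    if (is.na(age[v])) age[v] <- a
    else if (abs(age[v] - a) > 1e-8 * max(1, a))
      stop("species tree must be ultrametric in coalescent units")
  }
  root <- ntip + 1L
  # bottom-up order (children before parents); robust to zero-length branches
  bottom_up <- unique(po[, 1])
  list(ntip = ntip, nn = nn, root = root, parent = parent,
       children = children, age = age, elen = elen,
       internal_by_age = bottom_up,
       tip_labels = phy$tip.label)
}

# One censored-coalescent simulation: within each species-tree branch, pairs
# of lineages coalesce at rate 1 per pair per coalescent unit; survivors
# enter the parent branch; all remaining lineages coalesce above the root.
# Returns the n-1 merge events (ages, the two merged lineage ids, hosting
# species node). Lineage ids: tips 1..ntip, event i creates ntip + i.
.msc_sim <- function(prep) {
  ntip <- prep$ntip
  sets <- vector("list", prep$nn)
  for (tip in seq_len(ntip)) sets[[tip]] <- tip
  ne <- 0L
  ev_age <- numeric(ntip - 1L)
  ev_l <- integer(ntip - 1L)
  ev_r <- integer(ntip - 1L)
  ev_host <- integer(ntip - 1L)
  for (v in prep$internal_by_age) {
    lin <- unlist(sets[prep$children[[v]]], use.names = FALSE)
    t <- prep$age[v]
    top <- if (v == prep$root) Inf else prep$age[prep$parent[v]]
    m <- length(lin)
    while (m >= 2L) {
      t <- t + rexp(1L, m * (m - 1L) / 2)
      if (t >= top) break
      pr <- sample.int(m, 2L)
      ne <- ne + 1L
      ev_age[ne] <- t
      ev_l[ne] <- lin[pr[1]]
      ev_r[ne] <- lin[pr[2]]
      ev_host[ne] <- v
      lin <- c(lin[-pr], ntip + ne)
      m <- m - 1L
    }
    sets[[v]] <- lin
  }
  list(age = ev_age, left = ev_l, right = ev_r, host = ev_host)
}

# Assemble a rooted binary phylo (coalescent-unit branch lengths) from the
# event stream of .msc_sim.
.events_to_phylo <- function(ev, ntip, tip_labels) {
  n_ev <- ntip - 1L
  creation <- c(rep(0, ntip), ev$age)              # by lineage id
  root_lin <- ntip + n_ev
  new_id <- integer(ntip + n_ev)
  new_id[seq_len(ntip)] <- seq_len(ntip)
  edge <- matrix(0L, 2L * n_ev, 2L)
  elen <- numeric(2L * n_ev)
  counter <- ntip
  k <- 0L
  rec <- function(lin) {
    counter <<- counter + 1L
    new_id[lin] <<- counter
    i <- lin - ntip
    for (child in c(ev$left[i], ev$right[i])) {
      k <<- k + 1L
      row <- k
      if (child > ntip) rec(child)
      edge[row, ] <<- c(new_id[lin], new_id[child])
      elen[row] <<- ev$age[i] - creation[child]
    }
  }
  rec(root_lin)
  phy <- list(edge = edge, edge.length = elen, tip.label = tip_labels,
              Nnode = n_ev)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate a gene tree under the multispecies coalescent
#'
#' Standard censored coalescent within the branches of an ultrametric
#' species tree (coalescent units), one sampled lineage per species: within
#' each species-tree branch, each pair of lineages coalesces at rate 1 per
#' coalescent unit; surviving lineages enter the parent branch, and all
#' remaining lineages coalesce above the root.
#'
#' @param species_tree ultrametric `phylo` with coalescent-unit branch
#'   lengths (e.g. [felsenstein_species_tree()]).
#' @param n number of gene trees.
#' @return a `phylo` (`n = 1`) or `multiPhylo`, rooted, branch lengths in
#'   coalescent units.
#' @export
msc_gene_trees <- function(species_tree, n = 1) {
  prep <- .species_prep(species_tree)
  out <- lapply(seq_len(n), function(i)
    .events_to_phylo(.msc_sim(prep), prep$ntip, prep$tip_labels))
  if (n == 1) return(out[[1]])
  class(out) <- "multiPhylo"
  out
}

#' Quartet summaries of many coalescent gene trees
#'
#' Simulates `n_genes` gene trees on a 4-taxon species tree and tallies, per
#' gene, the unrooted gene-tree topology and the terminal branch extensions
#' above the speciation nodes (unrooted-tree attachment convention), without
#' materializing tree objects.  Used for Monte Carlo checks of the
#' analytical topology distribution and of the expected terminal extension
#' `1 - (1/3) exp(-d)`.
#'
#' @param species_tree ultrametric 4-taxon `phylo` in coalescent units.
#' @param n_genes number of simulated gene trees.
#' @return list with `freq` (empirical frequency of the three topologies,
#'   indexed as in [quartet_key()] over the species labels), `mean_extension`
#'   (mean over genes and the four leaves of pendant length minus the
#'   species terminal branch length), `pendant_mean` (per-taxon mean pendant
#'   lengths, named), and `n_genes`.
#' @export
msc_quartet_summary <- function(species_tree, n_genes) {
  prep <- .species_prep(species_tree)
  if (prep$ntip != 4L) stop("species tree must have exactly 4 taxa")
  key <- quartet_key(prep$tip_labels)
  pos <- match(unclass(key), prep$tip_labels)   # key order -> tip id
  tau1 <- prep$elen[seq_len(4L)]                # species terminal lengths
  counts <- numeric(3L)
  pend_sum <- numeric(4L)                       # by tip id
  for (g in seq_len(n_genes)) {
    ev <- .msc_sim(prep)
    o <- order(ev$age)
    a <- ev$age[o]; l <- ev$left[o]; r <- ev$right[o]
    # first event joins two tips: defines the unrooted topology
    x <- l[1]; y <- r[1]
    sister_of_first <- if (x == pos[1]) y else if (y == pos[1]) x else {
      # key[1]'s tip not in first pair: its sister is the remaining tip
      setdiff(pos, c(x, y, pos[1]))
    }
    j <- .topology_from_sister(key, prep$tip_labels[sister_of_first])
    counts[j] <- counts[j] + 1
    # pendant lengths in the unrooted gene tree
    pend <- numeric(4L)
    pend[c(x, y)] <- a[1]
    zw <- setdiff(1:4, c(x, y))
    if (l[2] <= 4L && r[2] <= 4L) {             # balanced: second event joins z,w
      pend[zw] <- a[2]
    } else {                                    # caterpillar: z at a2, w via root
      z <- if (l[2] <= 4L) l[2] else r[2]
      w <- setdiff(zw, z)
      pend[z] <- a[2]
      pend[w] <- 2 * a[3] - a[2]
    }
    pend_sum <- pend_sum + pend
  }
  pend_mean <- pend_sum / n_genes
  list(freq = counts / n_genes,
       mean_extension = mean(pend_mean - tau1),
       pendant_mean = setNames(pend_mean, prep$tip_labels),
       n_genes = n_genes)
}

# --- branch-length maps ------------------------------------------------------

#' Map a coalescent gene tree to substitution units with two species rates
#'
#' Each gene-tree branch is partitioned into the time segments it spends in
#' each species-tree branch; each segment is multiplied by that species
#' branch's mutation rate and the products are summed.  Under a
#' [felsenstein_condition()], the terminal species branches of the two long
#' taxa carry `mu_l`; all other species branches, and the portion of any
#' lineage above the species root, carry `mu_s`.
#'
#' @param gene_tree a rooted coalescent-unit `phylo` from
#'   [msc_gene_trees()] (leaf labels must match the species tree).
#' @param condition a [felsenstein_condition()], or a list with elements
#'   `species_tree`, `rates` (numeric, one rate per species-tree node id =
#'   rate of the branch above that node) and `above_root_rate`.
#' @return a `phylo` with substitution-unit branch lengths.
#' @export
apply_two_rate_map <- function(gene_tree, condition) {
  sp <- condition$species_tree
  prep <- .species_prep(sp)
  if (!is.null(condition$rates)) {
    rate <- condition$rates
    above_root_rate <- condition$above_root_rate
  } else {
    rate <- rep(condition$mu_s, prep$nn)
    rate[match(condition$long_taxa, prep$tip_labels)] <- condition$mu_l
    above_root_rate <- condition$mu_s
  }
  # gene node ages (coalescent gene trees are ultrametric)
  depths <- ape::node.depth.edgelength(gene_tree)
  gage <- max(depths) - depths
  gntip <- length(gene_tree$tip.label)
  # species tip set under each gene node, as species-tree tip ids
  desc <- vector("list", gntip + gene_tree$Nnode)
  tipmap <- match(gene_tree$tip.label, prep$tip_labels)
  if (anyNA(tipmap)) stop("gene tree leaves must match species tree leaves")
  for (i in seq_len(gntip)) desc[[i]] <- tipmap[i]
  po <- ape::reorder.phylo(gene_tree, "postorder")$edge
  for (r in seq_len(nrow(po)))
    desc[[po[r, 1]]] <- c(desc[[po[r, 1]]], desc[[po[r, 2]]])
  # species clades (tip-id sets) per species node
  sp_clade <- vector("list", prep$nn)
  for (i in seq_len(prep$ntip)) sp_clade[[i]] <- i
  spo <- ape::reorder.phylo(sp, "postorder")$edge
  for (r in seq_len(nrow(spo)))
    sp_clade[[spo[r, 1]]] <- c(sp_clade[[spo[r, 1]]], sp_clade[[spo[r, 2]]])
  sp_mrca <- function(S) {
    v <- S[1]
    while (!all(S %in% sp_clade[[v]])) v <- prep$parent[v]
    v
  }
  root_age <- prep$age[prep$root]
  new_len <- gene_tree$edge.length
  for (r in seq_len(nrow(gene_tree$edge))) {
    child <- gene_tree$edge[r, 2]
    t0 <- gage[child]
    t1 <- gage[gene_tree$edge[r, 1]]
    if (t1 <= t0) { new_len[r] <- 0; next }
    # host species branch at t0: climb from the mrca of the descendant species
    h <- sp_mrca(desc[[child]])
    while (h != prep$root && prep$age[prep$parent[h]] <= t0 + 1e-12)
      h <- prep$parent[h]
    total <- 0
    t <- t0
    while (t < t1 - 1e-15 && h != prep$root) {
      top <- prep$age[prep$parent[h]]
      seg <- min(t1, top) - t
      total <- total + seg * rate[h]
      t <- t + seg
      h <- prep$parent[h]
    }
    if (t < t1) {
      # remaining time inside the root branch, then above the root
      if (t < root_age) {
        # h == root but the segment below root age belongs to... the root
        # node has no branch above it; anything at or above root_age is
        # above-root.  (t can only be < root_age here if numerical noise.)
        seg <- min(t1, root_age) - t
        total <- total + seg * above_root_rate
        t <- t + seg
      }
      if (t < t1) total <- total + (t1 - t) * above_root_rate
    }
    new_len[r] <- total
  }
  out <- gene_tree
  out$edge.length <- new_len
  out
}

#' Relaxed-clock map: overall rate times per-branch Gamma multipliers
#'
#' Multiplies every branch of a coalescent-unit gene tree independently by
#' `overall_rate` and a Gamma(shape, scale) draw, giving substitution-unit
#' branch lengths with deviations from ultrametricity.
#'
#' @param gene_tree a `phylo` in coalescent units.
#' @param overall_rate substitution rate per coalescent unit (default 0.02).
#' @param shape,scale Gamma parameters (defaults 5 and 1/5; mean 1, variance
#'   1/5).  A mean far from 1 is flagged with a message.
#' @return a `phylo` with substitution-unit branch lengths.
#' @export
gamma_clock_map <- function(gene_tree, overall_rate = 0.02, shape = 5,
                            scale = 1 / 5) {
  if (abs(shape * scale - 1) > 0.1)
    message("Gamma multiplier mean ", shape * scale, " is far from 1")
  out <- gene_tree
  ne <- length(gene_tree$edge.length)
  out$edge.length <- gene_tree$edge.length * overall_rate *
    rgamma(ne, shape = shape, scale = scale)
  out
}

# --- JC69 sequences and quartet likelihood -----------------------------------

.DNA <- c("A", "C", "G", "T")

#' Simulate a JC69 alignment down a tree
#'
#' The root sequence is uniform over `{A, C, G, T}`; along each branch of
#' substitution-unit length `b`, every site independently changes to a
#' uniformly drawn base with probability `1 - exp(-4b/3)` (equivalently, the
#' probability that two ends of the branch differ is
#' `(3/4)(1 - exp(-4b/3))`).
#'
#' @param tree a `phylo` with substitution-unit branch lengths (all >= 0).
#' @param seq_len number of sites, >= 1.
#' @return character matrix, one row per leaf (rownames = leaf labels),
#'   entries in `A/C/G/T`.
#' @export
simulate_jc69 <- function(tree, seq_len) {
  stopifnot(seq_len >= 1)
  if (any(tree$edge.length < 0)) stop("negative branch length")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  seqs <- matrix(0L, nn, seq_len)
  root <- ntip + 1L
  seqs[root, ] <- sample.int(4L, seq_len, replace = TRUE)
  tr <- ape::reorder.phylo(tree, "cladewise")
  eo <- tr$edge
  elen <- tr$edge.length
  for (r in seq_len(nrow(eo))) {
    p <- eo[r, 1]; ch <- eo[r, 2]
    q <- 1 - exp(-4 * elen[r] / 3)
    x <- seqs[p, ]
    hit <- runif(seq_len) < q
    nh <- sum(hit)
    if (nh) x[hit] <- sample.int(4L, nh, replace = TRUE)
    seqs[ch, ] <- x
  }
  out <- matrix(.DNA[seqs[seq_len(ntip), , drop = FALSE]], ntip, seq_len)
  rownames(out) <- tree$tip.label
  out
}

# Compress a 4-taxon alignment (rows ordered by quartet_key) into site
# patterns: integer 4 x npat state matrix plus counts.
.aln_patterns <- function(aln) {
  key <- quartet_key(rownames(aln))
  m <- matrix(match(toupper(aln[unclass(key), , drop = FALSE]), .DNA),
              4L, ncol(aln))
  if (anyNA(m)) stop("alignment contains non-ACGT characters")
  id <- (((m[1, ] - 1L) * 4L + (m[2, ] - 1L)) * 4L + (m[3, ] - 1L)) * 4L +
    (m[4, ] - 1L)
  tab <- table(id)
  ids <- as.integer(names(tab))
  states <- rbind(ids %/% 64L %% 4L + 1L,
                  ids %/% 16L %% 4L + 1L,
                  ids %/% 4L %% 4L + 1L,
                  ids %% 4L + 1L)
  list(key = key, states = states, counts = as.numeric(tab))
}

# Pair memberships (positions in key order) for the three topologies.
.topology_pairs <- list(rbind(c(1L, 2L), c(3L, 4L)),
                        rbind(c(1L, 4L), c(2L, 3L)),
                        rbind(c(1L, 3L), c(2L, 4L)))

# JC69 log-likelihood of a 4-taxon topology with analytic gradient in the
# five branch lengths; returns a closure caching the last evaluation so
# optim's separate fn/gr calls share one likelihood pass.
.jc_obj <- function(pat, j) {
  pr <- .topology_pairs[[j]]
  obs <- pat$states
  w <- pat$counts
  np <- length(w)
  p1 <- pr[1, 1]; q1 <- pr[1, 2]; r1 <- pr[2, 1]; s1 <- pr[2, 2]
  last_b <- NULL
  last <- NULL
  function(b) {
    if (!is.null(last_b) && identical(b, last_b)) return(last)
    Tm <- vector("list", 4L)
    Dm <- vector("list", 4L)
    for (pos in 1:4) {
      Ee <- exp(-4 * b[pos] / 3)
      idx <- cbind(obs[pos, ], seq_len(np))
      M <- matrix((1 - Ee) / 4, 4L, np)
      M[idx] <- M[idx] + Ee
      D <- matrix(Ee / 3, 4L, np)     # dM/db = -(4/3)E*I(x=obs) + E/3
      D[idx] <- D[idx] - (4 / 3) * Ee
      Tm[[pos]] <- M
      Dm[[pos]] <- D
    }
    Lx <- Tm[[p1]] * Tm[[q1]]
    Ly <- Tm[[r1]] * Tm[[s1]]
    Ei <- exp(-4 * b[5] / 3)
    Sy <- colSums(Ly)
    Z <- Ei * Ly + rep((1 - Ei) * Sy / 4, each = 4L)
    site <- 0.25 * colSums(Lx * Z)
    ll <- sum(w * log(site))
    ws <- 0.25 * w / site
    g <- numeric(5L)
    g[5] <- sum(ws * colSums(Lx * ((-4 / 3 * Ei) *
                                     (Ly - rep(Sy / 4, each = 4L)))))
    g[p1] <- sum(ws * colSums((Dm[[p1]] * Tm[[q1]]) * Z))
    g[q1] <- sum(ws * colSums((Tm[[p1]] * Dm[[q1]]) * Z))
    for (ps in c(r1, s1)) {
      dLy <- if (ps == r1) Dm[[r1]] * Tm[[s1]] else Tm[[r1]] * Dm[[s1]]
      dZ <- Ei * dLy + rep((1 - Ei) * colSums(dLy) / 4, each = 4L)
      g[ps] <- sum(ws * colSums(Lx * dZ))
    }
    last_b <<- b
    last <<- list(ll = ll, grad = g)
    last
  }
}

# JC69 log-likelihood of a 4-taxon topology at fixed branch lengths.
# b = (b1..b4 terminal lengths in key position order, b5 internal).
.jc_quartet_ll <- function(pat, j, b) {
  tipcond <- function(blen, obs) {
    E <- exp(-4 * blen / 3)
    M <- matrix((1 - E) / 4, 4L, length(obs))
    M[cbind(obs, seq_along(obs))] <- M[cbind(obs, seq_along(obs))] + E
    M
  }
  pr <- .topology_pairs[[j]]
  Lx <- tipcond(b[pr[1, 1]], pat$states[pr[1, 1], ]) *
        tipcond(b[pr[1, 2]], pat$states[pr[1, 2], ])
  Ly <- tipcond(b[pr[2, 1]], pat$states[pr[2, 1], ]) *
        tipcond(b[pr[2, 2]], pat$states[pr[2, 2], ])
  Ei <- exp(-4 * b[5] / 3)
  Z <- Ei * Ly + rep((1 - Ei) * colSums(Ly) / 4, each = 4L)
  site <- 0.25 * colSums(Lx * Z)
  sum(pat$counts * log(site))
}

#' Maximum log-likelihood of a quartet topology under JC69
#'
#' Computes, for a 4-taxon alignment, the JC69 log-likelihood of quartet
#' topology `j` (indexed as in [quartet_key()] over the alignment's row
#' names) maximized over the five branch lengths, each constrained to
#' `[1e-9, 10]`.  Feeding the three values to [build_P_from_loglik()] gives
#' the normalized-likelihood posterior surrogate.  Deterministic given the
#' input (fixed multistart).
#'
#' @param aln character matrix: 4 rows (names = taxa), sites in columns.
#' @param j topology index 1, 2 or 3; `NULL` (default via
#'   [quartet_loglik_table()]) computes all three.
#' @param branch_lengths optional fixed 5-vector (4 terminals in key order,
#'   then internal); when given, no optimization is done and the
#'   log-likelihood at these lengths is returned.
#' @return maximized log-likelihood (scalar).
#' @export
quartet_topology_loglik <- function(aln, j, branch_lengths = NULL) {
  pat <- .aln_patterns(aln)
  .quartet_topology_loglik(pat, j, branch_lengths)
}

.quartet_topology_loglik <- function(pat, j, branch_lengths = NULL) {
  stopifnot(j %in% 1:3)
  if (!is.null(branch_lengths)) {
    stopifnot(length(branch_lengths) == 5L)
    return(.jc_quartet_ll(pat, j, branch_lengths))
  }
  obj <- .jc_obj(pat, j)
  nll <- function(b) -obj(b)$ll
  ngr <- function(b) -obj(b)$grad
  starts <- list(c(0.1, 0.1, 0.1, 0.1, 0.05), .jc_start(pat, j))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, nll, ngr, method = "L-BFGS-B", lower = 1e-9, upper = 10,
            control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("branch length optimization failed")
  -best$value
}

# Distance-based starting point: JC-corrected pairwise distances.
.jc_start <- function(pat, j) {
  pdiff <- function(i1, i2) {
    d <- sum(pat$counts[pat$states[i1, ] != pat$states[i2, ]]) /
      sum(pat$counts)
    min(d, 0.70)
  }
  jc <- function(p) max(-0.75 * log(1 - 4 * p / 3), 1e-6)
  pr <- .topology_pairs[[j]]
  d12 <- jc(pdiff(pr[1, 1], pr[1, 2]))
  d34 <- jc(pdiff(pr[2, 1], pr[2, 2]))
  cross <- mean(c(jc(pdiff(pr[1, 1], pr[2, 1])), jc(pdiff(pr[1, 1], pr[2, 2])),
                  jc(pdiff(pr[1, 2], pr[2, 1])), jc(pdiff(pr[1, 2], pr[2, 2]))))
  b <- numeric(5L)
  b[pr[1, ]] <- d12 / 2
  b[pr[2, ]] <- d34 / 2
  b[5] <- min(max(cross - d12 / 2 - d34 / 2, 1e-3), 5)
  pmin(pmax(b, 1e-6), 9)
}

#' Per-topology log-likelihoods of a 4-taxon alignment
#'
#' @param aln character matrix, 4 rows.
#' @return numeric length-3 vector of maximized JC69 log-likelihoods, in the
#'   topology index order of [quartet_key()].
#' @export
quartet_loglik_table <- function(aln) {
  pat <- .aln_patterns(aln)
  vapply(1:3, function(j) .quartet_topology_loglik(pat, j), numeric(1))
}

#' Quartet posterior matrix from per-gene alignments
#'
#' Runs the JC69 quartet-likelihood engine on each 4-taxon alignment and
#' normalizes the per-topology log-likelihoods into posterior surrogates.
#'
#' @param alignments list of 4-row character matrices (same taxa).
#' @param genes optional gene ids.
#' @return a [quartet_posterior()].
#' @export
quartet_posteriors_from_alignments <- function(alignments, genes = NULL) {
  key <- quartet_key(rownames(alignments[[1]]))
  ll <- vapply(alignments, quartet_loglik_table, numeric(3L))
  build_P_from_loglik(ll, key, genes = genes)
}

# --- replicate simulation -----------------------------------------------------

# Deterministic per-gene seed stream below 2^31.
.gene_seed <- function(seed, g) {
  as.integer((as.double(seed) * 100003 + as.double(g) * 7919) %% 2147483646) + 1L
}

#' Simulate one gene of a model condition
#'
#' Draws the coalescent gene tree, maps it to substitution units (two-rate
#' map for a [felsenstein_condition()], Gamma relaxed clock for an
#' [anomaly_condition()]) and simulates the JC69 alignment.  The RNG stream
#' is derived from the condition seed and the gene index, so any gene is
#' reproducible in isolation.
#'
#' @param condition a [felsenstein_condition()] or [anomaly_condition()].
#' @param g gene index in `1..n_genes`.
#' @return list with `coal_tree`, `subst_tree`, `alignment`.
#' @export
simulate_gene <- function(condition, g) {
  set.seed(.gene_seed(condition$seed, g))
  coal <- msc_gene_trees(condition$species_tree, 1)
  subst <- if (inherits(condition, "felsenstein_condition"))
    apply_two_rate_map(coal, condition)
  else
    gamma_clock_map(coal, condition$overall_rate, condition$shape,
                    condition$scale)
  list(coal_tree = coal, subst_tree = subst,
       alignment = simulate_jc69(subst, condition$seq_len))
}

#' Simulate a full replicate of a model condition
#'
#' In-memory version of [simulate_condition()]: all genes of the condition.
#'
#' @param condition a [felsenstein_condition()] or [anomaly_condition()].
#' @return list with `coal_trees`, `subst_trees` (multiPhylo) and
#'   `alignments` (list of character matrices).
#' @export
simulate_replicate <- function(condition) {
  genes <- lapply(seq_len(condition$n_genes), function(g)
    simulate_gene(condition, g))
  coal <- lapply(genes, `[[`, "coal_tree")
  subst <- lapply(genes, `[[`, "subst_tree")
  class(coal) <- class(subst) <- "multiPhylo"
  list(coal_trees = coal, subst_trees = subst,
       alignments = lapply(genes, `[[`, "alignment"))
}

#' Write a simulated replicate to disk
#'
#' Simulates every gene of the condition and writes one FASTA alignment per
#' gene (`gene_0001.fasta`, ...), the true species tree
#' (`species_tree.nwk`), the true gene trees in coalescent and substitution
#' units (`gene_trees_coalescent.nwk`, `gene_trees_subst.nwk`, one per
#' line), and a `manifest.tsv` recording every parameter and the seed.
#' Re-running with the same condition produces bit-identical files.
#'
#' @param condition a [felsenstein_condition()] or [anomaly_condition()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest as a data frame.
#' @export
simulate_condition <- function(condition, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rep <- simulate_replicate(condition)
  for (g in seq_len(condition$n_genes))
    write_fasta(rep$alignments[[g]],
                file.path(out_dir, sprintf("gene_%04d.fasta", g)))
  write_newick(condition$species_tree, file.path(out_dir, "species_tree.nwk"))
  write_newick(rep$coal_trees, file.path(out_dir, "gene_trees_coalescent.nwk"))
  write_newick(rep$subst_trees, file.path(out_dir, "gene_trees_subst.nwk"))
  pars <- condition[!vapply(condition, is.object, logical(1))]
  pars <- pars[vapply(pars, function(x)
    is.numeric(x) || is.character(x), logical(1))]
  manifest <- data.frame(
    parameter = c("class", names(pars)),
    value = c(class(condition)[1],
              vapply(pars, function(x)
                paste(format(x, digits = 15), collapse = ","), character(1))))
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Write / read a FASTA alignment
#'
#' @param aln character matrix, rownames = taxa.
#' @param path file path.
#' @return `read_fasta` returns a character matrix.
#' @export
write_fasta <- function(aln, path) {
  lines <- character(2L * nrow(aln))
  lines[seq(1L, by = 2L, length.out = nrow(aln))] <- paste0(">", rownames(aln))
  lines[seq(2L, by = 2L, length.out = nrow(aln))] <-
    apply(aln, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(dna)))
  rownames(m) <- names(dna)
  m
}
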