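#' All quartets of a taxon set
#'
#' @param taxa character vector of at least 4 distinct labels.
#' @return list of `choose(n, 4)` canonical [quartet_key()]s in deterministic
#'   (lexicographic) order.
#' @export
all_quartets <- function(taxa) {
  taxa <- sort(unique(as.character(taxa)), method = "radix")
  if (length(taxa) < 4L) stop("need at least 4 taxa")
  cmb <- combn(taxa, 4L)
  lapply(seq_len(ncol(cmb)), function(i) quartet_key(cmb[, i]))
}

#' Quartet sampling budget
#'
#' Parameters of the polytomy-directed quartet sampling scheme.
#'
#' @param rounds_budget total sampling-round budget; a polytomy of degree
#'   `deg` receives `floor(rounds_budget / deg)` rounds (minimum 1).
#'   Default 1200.
#' @param side_cap maximum number of polytomy sides used per round; when the
#'   degree exceeds it, `side_cap` sides are re-drawn uniformly each round.
#'   Default 12.
#' @param support_threshold guide-tree branches with support below this are
#'   contracted before sampling. Default 1.0.
#' @param seed optional RNG seed applied by [select_quartets()].
#' @return object of class `"quartet_budget"`.
#' @export
quartet_budget <- function(rounds_budget = 1200, side_cap = 12,
                           support_threshold = 1.0, seed = NULL) {
  stopifnot(rounds_budget >= 1, side_cap >= 4)
  structure(list(rounds_budget = rounds_budget, side_cap = side_cap,
                 support_threshold = support_threshold, seed = seed),
            class = "quartet_budget")
}

# Adjacency list of a phylo in unrooted semantics: a degree-2 (artificial
# root) node is spliced out.  Returns list(adj, ntip, spliced).
.unrooted_adjacency <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  adj <- vector("list", nn)
  for (r in seq_len(nrow(phy$edge))) {
    u <- phy$edge[r, 1]; v <- phy$edge[r, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  spliced <- integer(0)
  for (n in (ntip + 1L):nn) {
    if (length(adj[[n]]) == 2L) {       # artificial root
      a <- adj[[n]][1]; b <- adj[[n]][2]
      adj[[a]] <- c(setdiff(adj[[a]], n), b)
      adj[[b]] <- c(setdiff(adj[[b]], n), a)
      adj[[n]] <- integer(0)
      spliced <- c(spliced, n)
    }
  }
  list(adj = adj, ntip = ntip, spliced = spliced)
}

#' Probabilistic leaf draw from one side of a polytomy
#'
#' Walks from the polytomy toward the leaves, at each node choosing a child
#' uniformly at random, so a leaf is drawn with probability equal to the
#' product of `1 / (number of children)` over the internal nodes on its
#' path; leaves closer to the polytomy are favored.
#'
#' @param tree a `phylo` (treated as unrooted).
#' @param node the polytomy node id (tree rooted here conceptually).
#' @param side a neighbor node id of `node`, identifying the side subtree.
#' @return one leaf label.
#' @export
sample_leaf_from_side <- function(tree, node, side) {
  ua <- .unrooted_adjacency(tree)
  .leaf_walk(ua$adj, ua$ntip, side, node, tree$tip.label)
}

.leaf_walk <- function(adj, ntip, start, from, tip_labels) {
  cur <- start; prev <- from
  while (cur > ntip) {
    ch <- setdiff(adj[[cur]], prev)
    prev <- cur
    cur <- if (length(ch) == 1L) ch else ch[sample.int(length(ch), 1L)]
  }
  tip_labels[cur]
}

#' Sample quartets around one polytomy
#'
#' Performs `floor(rounds_budget / deg)` rounds; each round draws one leaf
#' from each of `min(deg, side_cap)` sides of the polytomy (sides re-drawn
#' uniformly without replacement each round when `deg > side_cap`) and emits
#' every quartet of the drawn leaves.  Each emitted quartet therefore has
#' its four leaves on four distinct sides.
#'
#' @param tree a `phylo` guide (treated as unrooted).
#' @param node a polytomy node id with unrooted degree at least 4.
#' @param budget a [quartet_budget()].
#' @return list of distinct [quartet_key()]s.
#' @export
sample_quartets_around_polytomy <- function(tree, node,
                                            budget = quartet_budget()) {
  ua <- .unrooted_adjacency(tree)
  sides <- ua$adj[[node]]
  deg <- length(sides)
  if (deg < 4L) {
    warning("node ", node, " has degree ", deg, " < 4; skipped")
    return(list())
  }
  rounds <- max(1L, floor(budget$rounds_budget / deg))
  m <- min(deg, budget$side_cap)
  seen <- new.env(parent = emptyenv())
  for (r in seq_len(rounds)) {
    use <- if (deg > m) sides[sample.int(deg, m)] else sides
    leaves <- vapply(use, function(s)
      .leaf_walk(ua$adj, ua$ntip, s, node, tree$tip.label), character(1))
    cmb <- combn(sort(leaves, method = "radix"), 4L)
    for (i in seq_len(ncol(cmb)))
      assign(paste(cmb[, i], collapse = "\r"), TRUE, envir = seen)
  }
  lapply(strsplit(ls(seen, sorted = TRUE), "\r", fixed = TRUE), quartet_key)
}

#' Select quartets to analyze from a guide tree
#'
#' Contracts poorly supported guide-tree branches ([contract_low_support()])
#' and samples quartets around every polytomy of the resulting
#' multifurcating tree, focusing effort on the unresolved parts.  Quartets
#' are deduplicated globally across polytomies.
#'
#' @param guide a `phylo` with support values as internal-node labels.
#' @param budget a [quartet_budget()]; its `seed`, when non-`NULL`, seeds the
#'   RNG for reproducible sampling.
#' @return list with `quartets` (list of [quartet_key()]s) and `guide` (the
#'   contracted guide tree, to pass on as an amalgamation constraint).  A
#'   fully resolved contracted guide yields an empty quartet set.
#' @export
select_quartets <- function(guide, budget = quartet_budget()) {
  if (length(guide$tip.label) < 4L) stop("guide needs at least 4 leaves")
  if (!is.null(budget$seed)) set.seed(budget$seed)
  contracted <- contract_low_support(guide, budget$support_threshold)
  ua <- .unrooted_adjacency(contracted)
  degs <- lengths(ua$adj)
  polys <- which(seq_along(degs) > ua$ntip & degs >= 4L)
  if (length(polys) == 0L) {
    message("guide fully resolved after contraction; no quartets to sample")
    return(list(quartets = list(), guide = contracted))
  }
  seen <- new.env(parent = emptyenv())
  for (u in polys) {
    for (q in sample_quartets_around_polytomy(contracted, u, budget))
      assign(paste(q, collapse = "\r"), TRUE, envir = seen)
  }
  qs <- lapply(strsplit(ls(seen, sorted = TRUE), "\r", fixed = TRUE),
               quartet_key)
  list(quartets = qs, guide = contracted)
}

# --- exact supertree by exhaustive enumeration ------------------------------

# Enumerate all unrooted binary topologies on n labeled leaves by stepwise
# insertion of leaf i+1 into every edge, in deterministic order.  Each tree
# is an edge matrix; leaves are 1..n, internal nodes n+1...
.enumerate_unrooted <- function(n) {
  trees <- list(list(edges = cbind(rep(n + 1L, 3L), 1:3), nxt = n + 2L))
  if (n == 3L) return(trees)
  for (leaf in 4:n) {
    out <- vector("list", length(trees) * (2L * (leaf - 1L) - 3L))
    k <- 0L
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edges))) {
        w <- tr$nxt
        edges <- tr$edges[-e, , drop = FALSE]
        edges <- rbind(edges, c(tr$edges[e, 1], w), c(w, tr$edges[e, 2]),
                       c(w, leaf))
        k <- k + 1L
        out[[k]] <- list(edges = edges, nxt = w + 1L)
      }
    }
    trees <- out
  }
  trees
}

# Leaf-side masks of all internal edges of an edge-matrix tree.
.edge_bipartitions <- function(edges, n) {
  nn <- max(edges)
  adj <- vector("list", nn)
  for (r in seq_len(nrow(edges))) {
    adj[[edges[r, 1]]] <- c(adj[[edges[r, 1]]], edges[r, 2])
    adj[[edges[r, 2]]] <- c(adj[[edges[r, 2]]], edges[r, 1])
  }
  int <- edges[edges[, 1] > n & edges[, 2] > n, , drop = FALSE]
  lapply(seq_len(nrow(int)), function(i) {
    u <- int[i, 1]; v <- int[i, 2]
    seen <- logical(nn)
    seen[u] <- TRUE
    stack <- u
    while (length(stack)) {
      x <- stack[1]; stack <- stack[-1]
      for (y in adj[[x]]) if (y != v && !seen[y]) {
        seen[y] <- TRUE
        stack <- c(stack, y)
      }
    }
    seen[seq_len(n)]
  })
}

# Convert an edge-matrix tree to phylo (rooted at internal node n+1).
.edges_to_phylo <- function(edges, taxa) {
  n <- length(taxa)
  nn <- max(edges)
  adj <- vector("list", nn)
  for (r in seq_len(nrow(edges))) {
    adj[[edges[r, 1]]] <- c(adj[[edges[r, 1]]], edges[r, 2])
    adj[[edges[r, 2]]] <- c(adj[[edges[r, 2]]], edges[r, 1])
  }
  new_id <- integer(nn)
  new_id[seq_len(n)] <- seq_len(n)
  counter <- n
  em <- matrix(0L, nrow(edges), 2L)
  k <- 0L
  rec <- function(node, parent) {
    counter <<- counter + 1L
    new_id[node] <<- counter
    for (ch in adj[[node]]) {
      if (identical(ch, parent)) next
      k <<- k + 1L
      if (ch <= n) {
        em[k, ] <<- c(new_id[node], ch)
      } else {
        row <- k
        rec(ch, node)
        em[row, ] <<- c(new_id[node], new_id[ch])
      }
    }
  }
  rec(n + 1L, 0L)
  phy <- list(edge = em, tip.label = taxa, Nnode = nn - n)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Exact supertree from quartet trees (n <= 8)
#'
#' Enumerates every unrooted binary topology on the taxon set
#' (`(2n-5)!!` of them) and returns one maximizing the number of input
#' quartet trees whose topology it induces.  With a multifurcating
#' `constraint` tree, only refinements of the constraint are considered.
#' Ties are broken by the deterministic enumeration order and flagged via
#' the `"tie"` attribute.
#'
#' @param quartet_trees list of resolved 4-taxon trees: `"quartet_ml"`
#'   results, 4-leaf `phylo` objects, or newick strings.
#' @param taxa the full taxon label set, `4 <= n <= 8`.
#' @param constraint optional multifurcating `phylo` on (a subset of) `taxa`;
#'   the returned tree displays all its branches.
#' @return unrooted binary `phylo`, with attributes `"score"` (quartets
#'   satisfied), `"n_candidates"` and `"tie"`.
#' @export
exact_supertree <- function(quartet_trees, taxa, constraint = NULL) {
  taxa <- sort(unique(as.character(taxa)), method = "radix")
  n <- length(taxa)
  if (n < 4L) stop("need at least 4 taxa")
  if (n > 8L)
    stop("exact search is capped at 8 taxa ((2n-5)!! topologies); ",
         "use export_for_amalgamation() and an external supertree tool")
  # normalize inputs to (leaf indices sorted, sister-of-first index)
  quartets <- lapply(quartet_trees, function(q) {
    if (inherits(q, "quartet_ml")) {
      key <- q$key
      j <- q$t_hat
    } else {
      if (is.character(q)) q <- ape::read.tree(text = q)
      key <- quartet_key(q$tip.label)
      j <- induced_quartet_topology(q, key)
      if (is.na(j) || j == QUARTET_UNRESOLVED)
        stop("every input quartet tree must be resolved on 4 taxa")
    }
    idx <- match(unclass(key), taxa)
    if (anyNA(idx)) stop("quartet taxa not in the taxon set")
    list(idx = idx, sister = c(2L, 4L, 3L)[j])  # position of key[1]'s sister
  })
  cons_masks <- NULL
  cons_pos <- NULL
  if (!is.null(constraint)) {
    ntc <- length(constraint$tip.label)
    cons_pos <- match(constraint$tip.label, taxa)
    if (anyNA(cons_pos)) stop("constraint taxa must be a subset of taxa")
    cm <- .edge_bipartitions(constraint$edge, ntc)
    cons_masks <- Filter(function(m) {
      s <- sum(m); s >= 2L && s <= ntc - 2L
    }, cm)
  }
  candidates <- .enumerate_unrooted(n)
  best_score <- -1L
  best <- NULL
  tie <- FALSE
  for (cand in candidates) {
    bip <- .edge_bipartitions(cand$edges, n)
    if (!is.null(cons_masks) && length(cons_masks)) {
      ok <- all(vapply(cons_masks, function(m)
        any(vapply(bip, function(b) {
          br <- b[cons_pos]
          all(br == m) || all(br == !m)
        }, logical(1))), logical(1)))
      if (!ok) next
    }
    score <- 0L
    for (q in quartets) {
      for (b in bip) {
        s <- b[q$idx]
        if (sum(s) == 2L) {
          sister <- which(s == s[1])[2]
          if (sister == q$sister) score <- score + 1L
          break
        }
      }
    }
    if (score > best_score) {
      best_score <- score
      best <- cand
      tie <- FALSE
    } else if (score == best_score) tie <- TRUE
  }
  if (is.null(best)) stop("no candidate topology refines the constraint")
  out <- .edges_to_phylo(best$edges, taxa)
  attr(out, "score") <- best_score
  attr(out, "n_candidates") <- length(candidates)
  attr(out, "tie") <- tie
  if (tie) message("supertree score tied; first topology in enumeration ",
                   "order returned")
  out
}

#' Export quartet trees for external amalgamation
#'
#' Writes the winning quartet topologies, one 4-taxon newick per line with
#' the internal branch length set to `d_hat`, in the format consumed by
#' standard quartet-amalgamation tools, plus (optionally) the multifurcating
#' guide tree.  Tie-flagged quartets are excluded and counted.
#'
#' @param results list of `"quartet_ml"` objects.
#' @param prefix output path prefix; files `<prefix>_quartets.nwk` and
#'   (with a guide) `<prefix>_guide.nwk` are written.
#' @param guide optional contracted guide `phylo`.
#' @return invisibly, character vector of the files written.
#' @export
export_for_amalgamation <- function(results, prefix, guide = NULL) {
  if (inherits(results, "quartet_ml")) results <- list(results)
  if (length(results) < 1L) stop("need at least one quartet result")
  ties <- vapply(results, `[[`, logical(1), "tie")
  if (any(ties))
    message(sum(ties), " tie-flagged quartet(s) excluded from export")
  lines <- vapply(results[!ties], quartet_newick, character(1))
  qfile <- paste0(prefix, "_quartets.nwk")
  writeLines(lines, qfile)
  files <- qfile
  if (!is.null(guide)) {
    gfile <- paste0(prefix, "_guide.nwk")
    write_newick(guide, gfile)
    files <- c(files, gfile)
  }
  invisible(files)
}
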