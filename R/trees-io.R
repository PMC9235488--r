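#' @importFrom stats rexp runif optim uniroot setNames rgamma
#' @importFrom utils combn read.delim write.table
NULL

#' Code returned by [induced_quartet_topology()] for a star (unresolved)
#' induced quartet.  Resolved topologies are 1, 2, 3; a missing taxon gives
#' `NA`.
#' @export
QUARTET_UNRESOLVED <- 0L

#' Canonical quartet key
#'
#' Puts four taxon labels into the canonical (lexicographic) order that fixes
#' the meaning of the three topology indices: for ordered taxa `(a, b, c, d)`,
#' index 1 is `ab|cd`, index 2 is `ad|bc` and index 3 is `ac|bd`.
#'
#' @param taxa character vector of four distinct taxon labels, any order.
#' @return character vector of length 4, sorted; class `"quartet_key"`.
#' @examples
#' quartet_key(c("D", "A", "C", "B"))
#' @export
quartet_key <- function(taxa) {
  taxa <- as.character(taxa)
  if (length(taxa) != 4L || anyDuplicated(taxa) || any(!nzchar(taxa)))
    stop("a quartet key needs exactly 4 distinct non-empty labels")
  structure(sort(taxa, method = "radix"), class = "quartet_key")
}

#' The three unrooted topologies of a quartet
#'
#' @param key a [quartet_key()].
#' @return list of three 2-column matrices; row 1 = first pair, row 2 = second
#'   pair, in index order 1 = `ab|cd`, 2 = `ad|bc`, 3 = `ac|bd`.
#' @export
quartet_topologies <- function(key) {
  k <- unclass(key)
  list(rbind(k[c(1, 2)], k[c(3, 4)]),
       rbind(k[c(1, 4)], k[c(2, 3)]),
       rbind(k[c(1, 3)], k[c(2, 4)]))
}

# sister label of key[1] under topology j
.sister_of_first <- function(key, j) unclass(key)[c(2, 4, 3)[j]]

# topology index given the label that is sister to key[1]
.topology_from_sister <- function(key, sister) {
  k <- unclass(key)
  if (sister == k[2]) 1L else if (sister == k[4]) 2L else if (sister == k[3]) 3L
  else stop("label '", sister, "' is not part of the quartet")
}

#' Induced quartet topology of a tree
#'
#' Restricts a tree to four leaves and reports which of the three unrooted
#' quartet topologies it induces.  The result is invariant to the tree's
#' rooting.
#'
#' @param tree a `phylo`.
#' @param key a [quartet_key()] (or 4 labels, canonicalized internally).
#' @return integer: `1`, `2` or `3` for a resolved induced topology (indexed
#'   as in [quartet_key()]), `0` (`QUARTET_UNRESOLVED`) when the induced
#'   4-leaf tree is a star, and `NA` when at least one of the four taxa is
#'   absent from the tree.
#' @export
induced_quartet_topology <- function(tree, key) {
  if (!inherits(key, "quartet_key")) key <- quartet_key(key)
  tl <- tree$tip.label
  if (anyDuplicated(tl)) stop("tree has duplicate leaf labels")
  if (!all(key %in% tl)) return(NA_integer_)
  sub <- ape::unroot(ape::keep.tip(tree, unclass(key)))
  if (sub$Nnode < 2L) return(QUARTET_UNRESOLVED)
  # binary unrooted: two internal nodes, tips sharing a parent are sisters
  e <- sub$edge
  parent_of <- integer(4L)
  parent_of[e[e[, 2] <= 4L, 2]] <- e[e[, 2] <= 4L, 1]
  a_idx <- match(unclass(key)[1], sub$tip.label)
  sib_idx <- setdiff(which(parent_of == parent_of[a_idx]), a_idx)
  .topology_from_sister(key, sub$tip.label[sib_idx])
}

#' Read a forest of per-gene tree samples
#'
#' Reads MCMC tree samples for one gene, either as plain newick (one tree per
#' line) or as a NEXUS trees file (e.g. MrBayes `.t` output; translate tables
#' are resolved to taxon labels).  The first `floor(burnin_frac * n)` trees
#' are discarded as burn-in.
#'
#' @param path file of newick strings (one per line) or a NEXUS trees file.
#' @param burnin_frac fraction of initial samples to discard, in `[0, 1)`.
#'   Default 0.25.
#' @param id gene identifier; defaults to the file name without extension.
#' @return object of class `"gene_forest"`: list with elements `id`, `trees`
#'   (a `multiPhylo` of retained samples, input order preserved), `n_total`,
#'   `n_retained`, `burnin_frac`, and `taxa` (union of leaf labels).
#' @export
read_newick_forest <- function(path, burnin_frac = 0.25, id = NULL) {
  if (burnin_frac < 0 || burnin_frac >= 1)
    stop("burnin_frac must be in [0, 1)")
  lines <- readLines(path, warn = FALSE)
  first <- lines[nzchar(trimws(lines))]
  if (length(first) == 0L) stop("empty input: no trees in '", path, "'")
  if (grepl("^#nexus", trimws(first[1]), ignore.case = TRUE)) {
    trees <- ape::read.nexus(path)
    if (inherits(trees, "phylo")) trees <- c(trees)
  } else {
    keep <- which(nzchar(trimws(lines)))
    trees <- vector("list", length(keep))
    for (i in seq_along(keep)) {
      tr <- tryCatch(ape::read.tree(text = .resolve_newick_comments(lines[keep[i]])),
                     error = function(e) NULL, warning = function(w) NULL)
      if (is.null(tr))
        stop("unparseable newick at line ", keep[i], " of '", path, "'")
      trees[[i]] <- tr
    }
    class(trees) <- "multiPhylo"
  }
  n_total <- length(trees)
  drop <- floor(burnin_frac * n_total)
  trees <- trees[(drop + 1L):n_total]
  structure(list(id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id,
                 trees = trees,
                 n_total = n_total,
                 n_retained = n_total - drop,
                 burnin_frac = burnin_frac,
                 taxa = sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))),
            class = "gene_forest")
}

#' @export
print.gene_forest <- function(x, ...) {
  cat("gene_forest '", x$id, "': ", x$n_retained, "/", x$n_total,
      " samples retained (burn-in ", x$burnin_frac, "), ",
      length(x$taxa), " taxa\n", sep = "")
  invisible(x)
}

# Rewrite ":length[&0.95]"-style comment support onto the node label so that
# read.tree sees "(...)0.95:length".  Comments may carry a bare number or a
# key=value list; the first numeric found is used.
.resolve_newick_comments <- function(line) {
  if (!grepl("[", line, fixed = TRUE)) return(line)
  m <- gregexpr("\\)([^():,;[]*):([0-9.eE+-]+)\\[&([^]]*)\\]", line)
  rm <- regmatches(line, m)[[1]]
  if (length(rm)) {
    for (piece in rm) {
      g <- regmatches(piece,
        regexec("\\)([^():,;[]*):([0-9.eE+-]+)\\[&([^]]*)\\]", piece))[[1]]
      num <- regmatches(g[4], regexpr("[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?", g[4]))
      lab <- if (length(num) && nzchar(num)) num else g[2]
      line <- sub(piece, paste0(")", lab, ":", g[3]), line, fixed = TRUE)
    }
  }
  # drop any remaining comments
  gsub("\\[[^]]*\\]", "", line)
}

#' Serialize trees as newick
#'
#' Writes `phylo` objects as newick with branch lengths at 12 significant
#' digits and internal-node labels (e.g. supports) preserved, one tree per
#' line.
#'
#' @param trees a `phylo` or `multiPhylo`/list of them.
#' @param path optional output file; when `NULL` the newick strings are
#'   returned.
#' @param digits significant digits for branch lengths (default 12).
#' @return character vector of newick strings, invisibly when `path` is given.
#' @export
write_newick <- function(trees, path = NULL, digits = 12) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  out <- vapply(trees, .newick_string, character(1), digits = digits)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

.newick_string <- function(phy, digits = 12) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  elen <- if (is.null(phy$edge.length)) NULL else
    setNames(phy$edge.length, phy$edge[, 2])
  nlab <- phy$node.label
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  rec <- function(node) {
    if (node <= ntip) s <- phy$tip.label[node]
    else {
      s <- paste0("(", paste(vapply(kids[[as.character(node)]], rec,
                                    character(1)), collapse = ","), ")")
      if (!is.null(nlab) && node > root - 1L) {
        lab <- nlab[node - ntip]
        if (!is.na(lab) && nzchar(lab)) s <- paste0(s, lab)
      }
    }
    if (!is.null(elen) && !is.na(elen[as.character(node)]) && node != root)
      s <- paste0(s, ":", fmt(elen[[as.character(node)]]))
    s
  }
  paste0(rec(root), ";")
}

#' Contract poorly supported branches into polytomies
#'
#' Collapses every internal branch whose support is below `threshold`,
#' producing the multifurcating guide tree used to direct quartet sampling.
#' Supports are read from internal-node labels; values above 1 are taken as
#' percentages and rescaled to `[0, 1]`.  Internal branches without a support
#' value are treated as support 0 (always contracted) with a warning.
#' Terminal branches are never contracted.
#'
#' @param tree a `phylo` with support values as internal-node labels.
#' @param threshold branches with support strictly below this are collapsed.
#'   Default 1.0 (keep only maximally supported branches).
#' @return a `phylo`, possibly multifurcating.
#' @export
contract_low_support <- function(tree, threshold = 1.0) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  internal_children <- tree$edge[tree$edge[, 2] > ntip, 2]
  if (length(internal_children) == 0L || threshold <= 0) return(tree)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  sup <- suppressWarnings(as.numeric(lab))
  if (any(is.na(sup[internal_children - ntip]))) {
    warning("internal branches without support values are treated as support 0")
    sup[is.na(sup)] <- 0
  }
  if (any(sup > 1, na.rm = TRUE)) {
    message("support values > 1 detected; rescaling from percentages to [0, 1]")
    sup <- sup / 100
  }
  drop_nodes <- internal_children[sup[internal_children - ntip] < threshold]
  if (length(drop_nodes) == 0L) return(tree)
  .collapse_internal_nodes(tree, drop_nodes)
}

# Remove the edges above the given internal nodes, attaching their children to
# the surviving ancestor.  Nodes are renumbered to ape's convention (tips
# 1..N, root N+1, internals in preorder).
.collapse_internal_nodes <- function(phy, drop_nodes) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  drop_nodes <- setdiff(drop_nodes, root)
  if (length(drop_nodes) == 0L) return(phy)
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  resolve <- function(n) { while (n %in% drop_nodes) n <- parent[n]; n }
  keep <- phy$edge[, 2][!(phy$edge[, 2] %in% drop_nodes)]
  new_parent <- vapply(parent[keep], resolve, integer(1))
  elen <- if (is.null(phy$edge.length)) NULL else
    phy$edge.length[match(keep, phy$edge[, 2])]
  # preorder renumbering over surviving nodes
  kids <- split(keep, new_parent)
  old_internal <- c(root, sort(unique(new_parent[new_parent != root])))
  old_internal <- unique(c(root, setdiff(old_internal, 1:ntip)))
  new_id <- integer(ntip + phy$Nnode)
  new_id[1:ntip] <- 1:ntip
  counter <- ntip
  order_nodes <- integer(0)
  stack <- root
  while (length(stack)) {
    n <- stack[1]; stack <- stack[-1]
    counter <- counter + 1L
    new_id[n] <- counter
    order_nodes <- c(order_nodes, n)
    ch <- kids[[as.character(n)]]
    stack <- c(ch[ch > ntip], stack)
  }
  edge <- cbind(new_id[new_parent], new_id[keep])
  out <- list(edge = edge, tip.label = phy$tip.label,
              Nnode = length(order_nodes))
  if (!is.null(elen)) out$edge.length <- elen
  if (!is.null(phy$node.label))
    out$node.label <- phy$node.label[order_nodes - ntip]
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  out
}
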