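#' Update gene-tree posteriors given the inferred species tree
#'
#' The co-estimation step: conditions each gene's posterior over the three
#' quartet topologies on the inferred species tree `theta = (t, d)`.  Per
#' gene `i`, the updated posterior is proportional to
#' `P[j,i] * P(gene topology = j | theta)` with the gene-tree prior from
#' [gene_tree_topology_prob()].  Mass can only move toward the species-tree
#' topology (for `d > 0`), so re-running [ml_quartet()] on the updated matrix
#' returns the same species tree; the update is applied once, never iterated,
#' and a guard refuses to update an already-updated matrix.
#'
#' @param P a [quartet_posterior()] (regularized or not).
#' @param t species-tree topology index (1, 2 or 3).
#' @param d species-tree internal branch length, in `[0, D_MAX]`.
#' @return a [quartet_posterior()] with the conditioning recorded in
#'   `$theta` and per-gene MAP topologies before/after in `$map_before`,
#'   `$map_after` (both with a tie attribute).
#' @export
update_gene_posteriors <- function(P, t, d) {
  stopifnot(inherits(P, "quartet_posterior"), t %in% 1:3, d >= 0, d <= D_MAX)
  if (!is.null(P$theta))
    stop("posterior matrix already conditioned on a species tree; ",
         "the co-estimation update is applied exactly once")
  prior <- gene_tree_topology_prob(1:3, t, d)
  upd <- P$P * prior
  denom <- colSums(upd)
  upd <- sweep(upd, 2L, denom, `/`)
  upd[, P$missing] <- NA_real_
  out <- quartet_posterior(P$key, upd, genes = P$genes, missing = P$missing,
                           regularized = P$regularized)
  out$theta <- list(t = as.integer(t), d = d)
  out$map_before <- map_topology(P)
  out$map_after <- map_topology(out)
  out
}

#' MAP topology of a posterior column
#'
#' Argmax topology with lowest-index tie-break.
#'
#' @param column numeric vector of 3 probabilities summing to 1, or a
#'   [quartet_posterior()] (then applied to every non-missing column).
#' @return integer topology index (vector for a matrix input; `NA` for
#'   missing columns), with attribute `"tie"` flagging exact ties.
#' @export
map_topology <- function(column) {
  if (inherits(column, "quartet_posterior")) {
    out <- rep(NA_integer_, ncol(column$P))
    ties <- logical(ncol(column$P))
    for (i in which(!column$missing)) {
      m <- map_topology(column$P[, i])
      out[i] <- m
      ties[i] <- attr(m, "tie")
    }
    attr(out, "tie") <- ties
    return(out)
  }
  stopifnot(length(column) == 3L)
  j <- which.max(column)
  structure(as.integer(j), tie = sum(column == column[j]) > 1L)
}
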