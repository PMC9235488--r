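#' Cap on the coalescent-unit internal branch length
#'
#' Beyond `D_MAX = -log(1e-8)` (about 18.42), `exp(-d)` falls below the
#' pseudo-count floor used by [regularize()] and the likelihood is flat to
#' machine precision.  Maximizers at the cap are flagged `AT_CAP` rather
#' than reported as infinite.
#' @export
D_MAX <- -log(1e-8)

#' Gene-tree topology probabilities under the multispecies coalescent
#'
#' For a quartet species tree with topology `t` and internal branch length
#' `d` (coalescent units), the probability that a gene tree has unrooted
#' topology `j` is `1 - (2/3) exp(-d)` when `j == t` and `(1/3) exp(-d)`
#' otherwise.  The three values sum to 1.
#'
#' @param j gene-tree topology index (1, 2 or 3); vectorized.
#' @param t species-tree topology index.
#' @param d internal branch length in coalescent units, `d >= 0`.
#' @return probability (vector along `j`).
#' @examples
#' gene_tree_topology_prob(1, 1, 0.1)  # ~0.397: 40% matching gene trees
#' @export
gene_tree_topology_prob <- function(j, t, d) {
  if (any(d < 0)) stop("d must be nonnegative")
  n <- max(length(j), length(d))
  j <- rep_len(j, n)
  d <- rep_len(d, n)
  ifelse(j == t, 1 - (2 / 3) * exp(-d), (1 / 3) * exp(-d))
}

#' Profile log-likelihood of a quartet species tree
#'
#' The species-tree log-likelihood marginalized over gene-tree topologies,
#' up to an additive constant that does not depend on `(t, d)`:
#' `sum_i log( P[t,i] + exp(-d) * (1/3 - P[t,i]) )` over non-missing genes.
#'
#' @param t species-tree topology index (1, 2 or 3).
#' @param d internal branch length, in `[0, D_MAX]`; vectorized.
#' @param P a regularized [quartet_posterior()].
#' @return log-likelihood value(s), finite for regularized `P`.
#' @export
quartet_loglik <- function(t, d, P) {
  p <- P$P[t, !P$missing]
  vapply(d, function(di) sum(log(p + exp(-di) * (1 / 3 - p))), numeric(1))
}

#' First and second derivatives of the profile log-likelihood in d
#'
#' Supplied to the optimizer and exposed for verification; per-gene term
#' `f = p + x(1/3 - p)` with `x = exp(-d)` has `d log f / dd = -x a / f` and
#' `d2 log f / dd2 = x a p / f^2`, where `a = 1/3 - p`.
#'
#' @inheritParams quartet_loglik
#' @return list with numeric `d1` and `d2`.
#' @export
quartet_loglik_deriv <- function(t, d, P) {
  p <- P$P[t, !P$missing]
  a <- 1 / 3 - p
  x <- exp(-d)
  f <- p + x * a
  list(d1 = sum(-x * a / f), d2 = sum(x * a * p / f^2))
}

#' Maximize the profile log-likelihood over the branch length
#'
#' Finds the global maximizer of [quartet_loglik()] over `d` in
#' `[0, D_MAX]` for a fixed topology.  The objective is concave in
#' `x = exp(-d)`, so it has at most one interior stationary point; the
#' derivative signs at the two boundaries are checked analytically and an
#' interior optimum is bracketed by root-finding on the first derivative.
#'
#' @param t species-tree topology index.
#' @param P a regularized [quartet_posterior()].
#' @param tol absolute tolerance on `d` (default `1e-9`, well inside the
#'   `1e-6` contract).
#' @return list with `d` (the maximizer), `loglik`, and `boundary` (one of
#'   `"none"`, `"zero"` for `d = 0`, `"cap"` for `d = D_MAX`).
#' @export
profile_max <- function(t, P, tol = 1e-9) {
  if (!P$regularized)
    stop("P must be regularized before optimization (see regularize())")
  p <- P$P[t, !P$missing]
  if (any(p <= 0)) stop("regularized P must be strictly positive")
  dldd <- function(d) {
    x <- exp(-d)
    sum(-x * (1 / 3 - p) / (p + x * (1 / 3 - p)))
  }
  u0 <- dldd(0)
  if (u0 <= 0) {
    d_star <- 0
    boundary <- "zero"
  } else {
    u1 <- dldd(D_MAX)
    if (u1 >= 0) {
      d_star <- D_MAX
      boundary <- "cap"
    } else {
      d_star <- uniroot(dldd, c(0, D_MAX), f.lower = u0, f.upper = u1,
                        tol = tol)$root
      boundary <- "none"
    }
  }
  list(d = d_star, loglik = quartet_loglik(t, d_star, P), boundary = boundary)
}

#' Maximum-likelihood quartet species tree
#'
#' Runs [profile_max()] for each of the three topologies and selects the
#' topology with the largest profile log-likelihood.  Ties are broken toward
#' the lowest topology index and flagged.  Reported log-likelihoods are
#' relative (an additive constant independent of `(t, d)` is dropped), so
#' they are comparable across topologies of one quartet but not across
#' quartets with different numbers of informative genes.
#'
#' @param P a [quartet_posterior()]; regularized automatically if needed.
#' @param tie_tol two profile log-likelihoods within this of each other are
#'   treated as tied (default `1e-9`).
#' @return object of class `"quartet_ml"`: list with `key`, `t_hat`, `d_hat`,
#'   `loglik` (length-3 profile log-likelihoods), `d_star` (length-3
#'   maximizers), `boundary` (length-3: `"none"`/`"zero"`/`"cap"`), `at_cap`
#'   (is `d_hat` capped?), `tie`, and `k_effective`.
#' @export
ml_quartet <- function(P, tie_tol = 1e-9) {
  stopifnot(inherits(P, "quartet_posterior"))
  if (!P$regularized) P <- regularize(P)
  prof <- lapply(1:3, profile_max, P = P)
  ll <- vapply(prof, `[[`, numeric(1), "loglik")
  t_hat <- which.max(ll)
  tie <- sum(ll >= ll[t_hat] - tie_tol) > 1L
  if (tie) t_hat <- min(which(ll >= ll[t_hat] - tie_tol))
  structure(list(key = P$key,
                 t_hat = as.integer(t_hat),
                 d_hat = prof[[t_hat]]$d,
                 loglik = ll,
                 d_star = vapply(prof, `[[`, numeric(1), "d"),
                 boundary = vapply(prof, `[[`, character(1), "boundary"),
                 at_cap = prof[[t_hat]]$boundary == "cap",
                 tie = tie,
                 k_effective = k_effective(P)),
            class = "quartet_ml")
}

#' @export
print.quartet_ml <- function(x, ...) {
  cat("quartet_ml {", paste(x$key, collapse = ", "), "}\n",
      "  t_hat = ", x$t_hat, " (", quartet_newick(x, lengths = FALSE), ")",
      if (x$tie) "  [tie]", "\n",
      "  d_hat = ", format(x$d_hat, digits = 6),
      if (x$at_cap) "  [AT_CAP]", "\n",
      "  profile loglik: ", paste(format(x$loglik, digits = 8), collapse = ", "),
      "  (k_eff = ", x$k_effective, ")\n", sep = "")
  invisible(x)
}

#' Winning quartet topology as a one-line newick string
#'
#' Serializes the inferred quartet species tree as a 4-taxon newick with the
#' internal branch length set to `d_hat` (consumable by quartet amalgamation
#' tools).
#'
#' @param result a `"quartet_ml"` object.
#' @param lengths include the internal branch length? Default `TRUE`.
#' @return newick string.
#' @export
quartet_newick <- function(result, lengths = TRUE) {
  pairs <- quartet_topologies(result$key)[[result$t_hat]]
  if (lengths)
    sprintf("((%s,%s):%.12g,(%s,%s));", pairs[1, 1], pairs[1, 2],
            result$d_hat, pairs[2, 1], pairs[2, 2])
  else
    sprintf("((%s,%s),(%s,%s));", pairs[1, 1], pairs[1, 2],
            pairs[2, 1], pairs[2, 2])
}

#' Write quartet results as TSV
#'
#' One row per quartet: the four ordered taxa, the winning topology as a
#' newick string, `d_hat`, the three profile log-likelihoods, and flags.
#'
#' @param results list of `"quartet_ml"` objects.
#' @param path output file.
#' @return invisibly, the data frame written.
#' @export
write_quartet_results <- function(results, path) {
  if (inherits(results, "quartet_ml")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(taxon1 = r$key[1], taxon2 = r$key[2], taxon3 = r$key[3],
               taxon4 = r$key[4], topology = quartet_newick(r),
               t_hat = r$t_hat, d_hat = r$d_hat,
               loglik1 = r$loglik[1], loglik2 = r$loglik[2],
               loglik3 = r$loglik[3],
               at_cap = as.integer(r$at_cap), tie = as.integer(r$tie),
               k_effective = r$k_effective)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
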