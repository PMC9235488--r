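#' Quartet posterior matrix
#'
#' Container for the 3 x k table `P` of per-gene posterior probabilities of
#' the three quartet topologies, with a per-gene missing mask.  Column `i`
#' holds `P(topology j | data of gene i)` for `j = 1, 2, 3` in the index
#' order fixed by [quartet_key()].
#'
#' @param key a [quartet_key()].
#' @param P numeric 3 x k matrix; every non-missing column must sum to 1
#'   (within 1e-9) with entries >= 0.
#' @param genes character vector of k gene ids.
#' @param missing logical vector of length k; `TRUE` columns carry no
#'   information for this quartet (taxon absent) and are ignored downstream.
#' @param regularized logical; has the pseudo-count been applied?
#' @return object of class `"quartet_posterior"`.
#' @export
quartet_posterior <- function(key, P, genes = NULL, missing = NULL,
                              regularized = FALSE) {
  if (!inherits(key, "quartet_key")) key <- quartet_key(key)
  P <- as.matrix(P)
  if (nrow(P) != 3L) stop("P must have 3 rows")
  k <- ncol(P)
  if (is.null(genes)) genes <- paste0("gene_", seq_len(k))
  if (is.null(missing)) missing <- rep(FALSE, k)
  if (length(genes) != k || length(missing) != k)
    stop("genes and missing must have one entry per column of P")
  ok <- !missing
  if (sum(ok) < 1L)
    stop("unanalyzable quartet: no gene carries all four taxa")
  if (any(P[, ok] < 0))
    stop("posterior entries must be nonnegative")
  if (any(abs(colSums(P[, ok, drop = FALSE]) - 1) > 1e-9))
    stop("every non-missing column of P must sum to 1")
  structure(list(key = key, P = P, genes = as.character(genes),
                 missing = missing, regularized = isTRUE(regularized)),
            class = "quartet_posterior")
}

#' @export
print.quartet_posterior <- function(x, ...) {
  cat("quartet_posterior {", paste(x$key, collapse = ", "), "}: k = ",
      ncol(x$P), " genes (", sum(!x$missing), " informative)",
      if (x$regularized) ", regularized" else "", "\n", sep = "")
  invisible(x)
}

#' Effective number of genes of a posterior matrix
#' @param P a [quartet_posterior()].
#' @return integer count of non-missing gene columns.
#' @export
k_effective <- function(P) sum(!P$missing)

#' Build the quartet posterior matrix from MCMC tree samples
#'
#' For each gene, the posterior probability of quartet topology `j` is the
#' fraction of retained MCMC samples whose induced quartet topology is `j`.
#' Samples whose induced quartet is a star contribute 1/3 to each topology.
#' A gene is masked missing for the quartet if any of its samples lacks one
#' of the four taxa.
#'
#' @param forests list of [read_newick_forest()] results, one per gene.
#' @param key a [quartet_key()].
#' @return a [quartet_posterior()] (not yet regularized).
#' @export
build_P_from_samples <- function(forests, key) {
  if (!inherits(key, "quartet_key")) key <- quartet_key(key)
  if (inherits(forests, "gene_forest")) forests <- list(forests)
  k <- length(forests)
  P <- matrix(NA_real_, 3L, k)
  missing <- logical(k)
  ids <- character(k)
  for (i in seq_len(k)) {
    f <- forests[[i]]
    ids[i] <- f$id
    codes <- vapply(f$trees, induced_quartet_topology, integer(1), key = key)
    if (anyNA(codes)) { missing[i] <- TRUE; next }
    n <- length(codes)
    u <- sum(codes == QUARTET_UNRESOLVED)
    P[, i] <- (tabulate(codes, nbins = 3L) + u / 3) / n
  }
  if (all(missing))
    stop("unanalyzable quartet {", paste(key, collapse = ","),
         "}: every gene misses at least one taxon")
  P[, missing] <- NA_real_
  quartet_posterior(key, P, genes = ids, missing = missing)
}

#' Build the quartet posterior matrix from per-topology log-likelihoods
#'
#' Normalizes and exponentiates per-gene log-likelihoods of the three quartet
#' topologies into approximate posterior probabilities (softmax per column,
#' stabilized by subtracting the column maximum).
#'
#' @param loglik numeric 3 x k matrix of log-likelihoods, topology index in
#'   rows (order fixed by [quartet_key()]).
#' @param key a [quartet_key()].
#' @param genes optional gene ids.
#' @return a [quartet_posterior()] (not yet regularized).
#' @export
build_P_from_loglik <- function(loglik, key, genes = NULL) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) != 3L) stop("loglik must have 3 rows")
  bad <- which(!is.finite(loglik), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite log-likelihood for gene ", bad[1, 2],
         ", topology ", bad[1, 1])
  m <- apply(loglik, 2L, max)
  E <- exp(sweep(loglik, 2L, m))
  P <- sweep(E, 2L, colSums(E), `/`)
  quartet_posterior(key, P, genes = genes)
}

#' Regularize a posterior matrix with a pseudo-count
#'
#' Adds a pseudo-count of `1e-8` to every entry and renormalizes each column:
#' `p -> (p + 1e-8) / (1 + 3e-8)`.  Guarantees strictly positive entries so
#' the profile log-likelihood stays finite at the branch-length cap.  Applied
#' exactly once before optimization; [ml_quartet()] applies it automatically
#' when needed.
#'
#' @param P a [quartet_posterior()].
#' @param pseudo pseudo-count (default `1e-8`).
#' @return the regularized [quartet_posterior()] (`regularized = TRUE`).
#' @export
regularize <- function(P, pseudo = 1e-8) {
  stopifnot(inherits(P, "quartet_posterior"))
  if (P$regularized) {
    warning("posterior matrix already regularized; returning unchanged")
    return(P)
  }
  P$P <- (P$P + pseudo) / (1 + 3 * pseudo)
  P$regularized <- TRUE
  P
}

#' Write / read a posterior matrix as TSV
#'
#' Plain-text interchange format: a `#taxa:` header comment recording the
#' four ordered taxa (and optionally the conditioning species tree), then
#' columns `gene_id`, `p1`, `p2`, `p3`, `missing`.  Values are written at 12
#' significant digits.
#'
#' @param P a [quartet_posterior()].
#' @param path output / input file.
#' @return `read_posterior_tsv` returns a [quartet_posterior()].
#' @export
write_posterior_tsv <- function(P, path) {
  stopifnot(inherits(P, "quartet_posterior"))
  hdr <- paste0("#taxa:", paste(P$key, collapse = "\t"))
  if (!is.null(P$theta))
    hdr <- c(hdr, sprintf("#theta:\t%d\t%.12g", P$theta$t, P$theta$d))
  df <- data.frame(gene_id = P$genes,
                   p1 = sprintf("%.12g", P$P[1, ]),
                   p2 = sprintf("%.12g", P$P[2, ]),
                   p3 = sprintf("%.12g", P$P[3, ]),
                   missing = as.integer(P$missing))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("gene_id", "p1", "p2", "p3", "missing"), collapse = "\t"), con)
  writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_posterior_tsv
#' @export
read_posterior_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  taxa_line <- hdr[startsWith(hdr, "#taxa:")]
  if (length(taxa_line) != 1L) stop("missing #taxa: header in '", path, "'")
  taxa <- strsplit(sub("^#taxa:", "", taxa_line), "\t")[[1]]
  df <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t",
                   stringsAsFactors = FALSE)
  P <- t(as.matrix(df[, c("p1", "p2", "p3")]))
  dimnames(P) <- NULL
  out <- quartet_posterior(quartet_key(taxa), P, genes = df$gene_id,
                           missing = as.logical(df$missing))
  theta_line <- hdr[startsWith(hdr, "#theta:")]
  if (length(theta_line) == 1L) {
    parts <- strsplit(sub("^#theta:\t?", "", theta_line), "\t")[[1]]
    out$theta <- list(t = as.integer(parts[1]), d = as.numeric(parts[2]))
  }
  out
}
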