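#' Infer maximum-likelihood quartet species trees from gene-tree samples
#'
#' For each requested quartet, builds the 3 x k posterior matrix from the
#' per-gene tree samples, regularizes it, and maximizes the marginalized
#' species-tree likelihood.
#'
#' @param forests list of [read_newick_forest()] objects, one per gene.
#' @param quartets list of [quartet_key()]s; default all quartets of the
#'   union taxon set.
#' @param update also compute the co-estimation update of the gene
#'   posteriors given each quartet species tree? Default `TRUE`.
#' @return list with `results` (list of `"quartet_ml"`) and, when `update`,
#'   `updated` (list of updated [quartet_posterior()]s).
#' @export
infer_quartet_trees <- function(forests, quartets = NULL, update = TRUE) {
  if (inherits(forests, "gene_forest")) forests <- list(forests)
  if (is.null(quartets)) {
    taxa <- sort(unique(unlist(lapply(forests, `[[`, "taxa"))))
    quartets <- all_quartets(taxa)
  }
  results <- vector("list", length(quartets))
  updated <- if (update) vector("list", length(quartets)) else NULL
  for (i in seq_along(quartets)) {
    P <- regularize(build_P_from_samples(forests, quartets[[i]]))
    r <- ml_quartet(P)
    results[[i]] <- r
    if (update)
      updated[[i]] <- update_gene_posteriors(P, r$t_hat, r$d_hat)
  }
  out <- list(results = results)
  if (update) out$updated <- updated
  out
}

#' Species tree from inferred quartet trees
#'
#' Combines quartet species trees into a full species tree: with eight or
#' fewer taxa the exact enumeration of [exact_supertree()] is used
#' (tie-flagged quartets excluded); for larger taxon sets use
#' [export_for_amalgamation()] and an external quartet-amalgamation tool.
#'
#' @param results list of `"quartet_ml"` objects.
#' @param taxa full taxon set; default the union of the quartet taxa.
#' @param constraint optional multifurcating guide `phylo`.
#' @return unrooted binary `phylo` (see [exact_supertree()]).
#' @export
species_tree_from_quartets <- function(results, taxa = NULL,
                                       constraint = NULL) {
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(results, `[[`, "key"))))
  keep <- !vapply(results, `[[`, logical(1), "tie")
  exact_supertree(results[keep], taxa, constraint = constraint)
}

#' End-to-end inference from a directory of gene-tree sample files
#'
#' Reads one newick forest per file in `trees_dir` (extensions `.nwk`,
#' `.newick`, `.trees`, `.t`, `.tre`), selects quartets (all of them, or
#' sampled around the polytomies of a guide tree), infers every quartet
#' species tree, updates the gene posteriors, and - when the taxon set has
#' at most eight taxa - assembles the species tree exactly.  Output files
#' (quartet results TSV, quartet newick, updated posterior TSVs, species
#' tree) are written under `out_prefix`.
#'
#' @param trees_dir directory of per-gene forest files.
#' @param out_prefix path prefix for outputs.
#' @param guide optional guide tree file (newick with support labels).
#' @param budget a [quartet_budget()] (used with a guide).
#' @param burnin_frac per-forest burn-in fraction (default 0.25).
#' @param seed optional RNG seed for quartet sampling.
#' @return invisibly, a list with `results`, `updated`, `species_tree`
#'   (`NULL` for more than eight taxa) and the output file paths.
#' @export
run_inference <- function(trees_dir, out_prefix, guide = NULL,
                          budget = quartet_budget(), burnin_frac = 0.25,
                          seed = NULL) {
  files <- sort(list.files(trees_dir, full.names = TRUE,
                           pattern = "\\.(nwk|newick|trees|t|tre)$"))
  if (length(files) == 0L) stop("no tree files found in '", trees_dir, "'")
  forests <- lapply(files, read_newick_forest, burnin_frac = burnin_frac)
  taxa <- sort(unique(unlist(lapply(forests, `[[`, "taxa"))))
  contracted <- NULL
  if (!is.null(guide)) {
    if (is.character(guide)) guide <- ape::read.tree(guide)
    if (!is.null(seed)) budget$seed <- seed
    sel <- select_quartets(guide, budget)
    quartets <- sel$quartets
    contracted <- sel$guide
  } else {
    quartets <- all_quartets(taxa)
  }
  inf <- infer_quartet_trees(forests, quartets)
  write_quartet_results(inf$results, paste0(out_prefix, "_quartets.tsv"))
  export_for_amalgamation(inf$results, out_prefix, guide = contracted)
  for (i in seq_along(inf$updated))
    write_posterior_tsv(inf$updated[[i]],
                        sprintf("%s_updatedP_%04d.tsv", out_prefix, i))
  species <- NULL
  if (length(taxa) <= 8L) {
    species <- species_tree_from_quartets(inf$results, taxa,
                                          constraint = contracted)
    write_newick(species, paste0(out_prefix, "_species.nwk"))
  }
  invisible(list(results = inf$results, updated = inf$updated,
                 species_tree = species, out_prefix = out_prefix))
}
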