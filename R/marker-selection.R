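# Marker informativeness ranking and constrained panel assembly.
#
# Three discrimination procedures for ranking candidate SNPs by their power
# to separate full-sib families, and a selector that walks a ranking under
# assayability and one-SNP-per-gene constraints. Ties are always broken
# lexicographically on locus id, for reproducibility.

new_marker_ranking <- function(locus_id, score, procedure, descending = TRUE) {
  ord <- order(if (descending) -score else score, locus_id)
  out <- data.frame(locus_id = locus_id[ord], score = score[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "procedure") <- procedure
  class(out) <- c("marker_ranking", "data.frame")
  out
}

#' Rank loci by Fst among full-sib families
#'
#' Orders loci by descending per-locus Weir-Cockerham theta computed on a
#' simulated (or real) progeny dataset with each cross as a subpopulation.
#' Monomorphic loci score 0 and sort last. Deterministic.
#'
#' @param progeny progeny genotype matrix.
#' @param families family (cross) label per individual.
#' @return a `marker_ranking` data frame (`locus_id`, `score`, `rank`),
#'   best locus first. Flagged (monomorphic) loci sort after every locus
#'   with a defined theta, whatever its sign.
#' @export
rank_by_fst <- function(progeny, families) {
  fst <- fst_per_locus(progeny, families)
  ord <- order(fst$monomorphic, -fst$theta, fst$locus_id)
  out <- data.frame(locus_id = fst$locus_id[ord], score = fst$theta[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "procedure") <- "fst"
  class(out) <- c("marker_ranking", "data.frame")
  out
}

#' Rank loci by closeness of MAF to 0.5
#'
#' Orders loci by ascending distance of the minor allele frequency from
#' 0.5, computed on the parent panel (parental frequencies determine the
#' expected progeny frequencies, and panel selection happens before any
#' progeny exist in a new program). The score reported is the MAF itself.
#' Deterministic.
#'
#' @param parents parent genotype matrix.
#' @return a `marker_ranking` data frame, most balanced locus first.
#' @export
rank_by_maf <- function(parents) {
  p <- allele_freqs(parents)
  maf <- pmin(p, 1 - p)
  ord <- order(abs(maf - 0.5), colnames(parents))
  out <- data.frame(locus_id = colnames(parents)[ord],
                    score = unname(maf[ord]), rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  attr(out, "procedure") <- "maf"
  class(out) <- c("marker_ranking", "data.frame")
  out
}

#' Rank loci by random-forest Gini importance
#'
#' Trains a random-forest classifier (genotype codes 0/1/2 as numeric
#' features, cross of origin as the class) and orders loci by descending
#' mean decrease in Gini impurity. Defaults to 10,000 trees — large
#' ensembles stabilize the importance ranking — with the classifier's own
#' defaults otherwise. Deterministic under `seed`. Missing genotypes are
#' not accepted; rank on unperturbed data.
#'
#' @param progeny progeny genotype matrix (no missing data).
#' @param families family (cross) label per individual; at least 2 classes.
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @return a `marker_ranking` data frame, most important locus first.
#' @export
rank_by_rf_importance <- function(progeny, families, n_trees = 10000,
                                  seed = NULL) {
  validate_genotypes(progeny)
  if (anyNA(progeny))
    stop("missing genotypes are not allowed in ranking inputs")
  y <- factor(families)
  if (nlevels(droplevels(y)) < 2L)
    stop("at least two families are required")
  x <- as.data.frame(progeny)
  fit <- with_seed(seed,
    randomForest::randomForest(x = x, y = y, ntree = n_trees,
                               importance = FALSE))
  gini <- fit$importance[, "MeanDecreaseGini"]
  new_marker_ranking(colnames(progeny), unname(gini[colnames(progeny)]), "rf")
}

#' Select the top k loci under panel constraints
#'
#' Walks the ranking best-first, skipping loci that are not assayable and
#' loci whose gene is already represented (to minimize linkage between
#' markers), and stops at `k`. If the one-SNP-per-gene constraint prevents
#' reaching `k`, it is relaxed with a warning and the best remaining
#' assayable loci fill the panel. Fewer than `k` assayable loci overall is
#' an error.
#'
#' @param ranking a `marker_ranking` data frame.
#' @param k panel size.
#' @param panel optional [snp_panel()] metadata; loci absent from it are
#'   treated as assayable with unknown gene.
#' @return character vector of `k` locus ids, in rank order.
#' @export
select_top_k <- function(ranking, k, panel = NULL) {
  stopifnot(k >= 1)
  ids <- ranking$locus_id
  if (is.null(panel)) {
    assayable <- rep(TRUE, length(ids))
    gene <- rep(NA_character_, length(ids))
  } else {
    idx <- match(ids, panel$locus_id)
    assayable <- ifelse(is.na(idx), TRUE, panel$assayable[idx])
    gene <- ifelse(is.na(idx), NA_character_, panel$gene_id[idx])
  }
  if (sum(assayable) < k)
    stop("fewer than k = ", k, " assayable loci (", sum(assayable),
         " available)")
  chosen <- character(0)
  used_genes <- character(0)
  skipped_for_gene <- character(0)
  for (i in seq_along(ids)) {
    if (length(chosen) == k) break
    if (!assayable[i]) next
    g <- gene[i]
    if (!is.na(g) && g %in% used_genes) {
      skipped_for_gene <- c(skipped_for_gene, ids[i])
      next
    }
    chosen <- c(chosen, ids[i])
    if (!is.na(g)) used_genes <- c(used_genes, g)
  }
  if (length(chosen) < k) {
    warning("one-SNP-per-gene constraint relaxed to reach k = ", k)
    fill <- utils::head(skipped_for_gene, k - length(chosen))
    chosen <- ids[ids %in% c(chosen, fill)]  # restore rank order
  }
  chosen
}
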