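# Cross-of-origin assignment within a closed mating design.
#
# Two complementary methods, mirroring standard practice in pedigree
# certification:
#  - exclusion: count, per candidate cross, the minimum number of allele
#    substitutions that would make the offspring Mendelian-compatible with
#    the parent pair, summed across loci, and reject crosses above an
#    allele-mismatch tolerance (default 1 allele across the whole
#    multilocus genotype);
#  - likelihood: per-locus mixture (1 - eps) * Mendelian transmission +
#    eps * Hardy-Weinberg, maximized over candidate crosses.
# The candidate set is always the closed design; open-population paternity
# search is out of scope. Ambiguity (exact ties) is reported, never broken
# by randomness or id order — traceability requires certainty.

# Minimum allele distance from offspring genotype g_o to any genotype
# compatible with parents (g_m, g_f); allele distance between genotypes is
# the absolute difference in B-allele dosage.
mismatch_table <- function() {
  tt <- get_transmission_table()
  mm <- array(0L, dim = c(3, 3, 3), dimnames = dimnames(tt))
  for (gm in 0:2) for (gf in 0:2) {
    compat <- which(tt[, gm + 1, gf + 1] > 0) - 1L
    for (go in 0:2)
      mm[go + 1, gm + 1, gf + 1] <- min(abs(go - compat))
  }
  mm
}

get_mismatch_table <- function() {
  if (is.null(.pedtrace_cache$mm)) .pedtrace_cache$mm <- mismatch_table()
  .pedtrace_cache$mm
}

#' Per-locus allele mismatch against a candidate parent pair
#'
#' The minimum number of allele substitutions (0, 1 or 2) turning the
#' offspring genotype into one that the parent pair can produce. A missing
#' offspring genotype is uninformative and contributes 0.
#'
#' @param g_o offspring genotype code(s); NA allowed.
#' @param g_m,g_f parental genotype codes; missing is an error.
#' @return integer mismatch count(s).
#' @export
locus_mismatch <- function(g_o, g_m, g_f) {
  n <- max(length(g_o), length(g_m), length(g_f))
  g_o <- rep_len(g_o, n); g_m <- rep_len(g_m, n); g_f <- rep_len(g_f, n)
  if (anyNA(g_m) || anyNA(g_f))
    stop("missing parental genotype: parents must be fully genotyped")
  out <- integer(n)
  ok <- !is.na(g_o)
  out[ok] <- get_mismatch_table()[cbind(g_o[ok] + 1L, g_m[ok] + 1L,
                                        g_f[ok] + 1L)]
  out
}

# Per-cross per-locus score matrix (3 x n_loci): entry [g + 1, l] is the
# score of offspring genotype g at locus l for this cross. Returns the
# n_ind vector of summed scores for a progeny matrix.
score_against_cross <- function(offspring, score3) {
  n <- nrow(offspring); L <- ncol(offspring)
  v <- matrix(0, n, L)
  ok <- !is.na(offspring)
  idx <- cbind(offspring[ok] + 1L, col(offspring)[ok])
  v[ok] <- score3[idx]
  rowSums(v)
}

#' Exclusion-based assignment to a cross of origin
#'
#' For every individual, sums the per-locus allele mismatches against each
#' cross of the design and keeps the crosses whose total does not exceed
#' `tolerance_alleles` (default 1, the customary setting that forgives a
#' single imperfect allele call). The individual is `assigned` when exactly
#' one candidate attains the minimum total, `ambiguous` when several tie
#' (e.g. crosses repeating the same parents), and `unassigned` when no
#' cross is within tolerance.
#'
#' @param offspring progeny genotype matrix.
#' @param parents parent genotype matrix (no missing data at panel loci).
#' @param design mating design.
#' @param tolerance_alleles allele-mismatch tolerance summed across loci.
#' @return data frame: `individual_id`, `status`, `assigned_cross`,
#'   `mismatch_alleles` (minimum total over the design).
#' @export
exclusion_assign <- function(offspring, parents, design,
                             tolerance_alleles = 1) {
  validate_genotypes(offspring)
  validate_genotypes(parents)
  design <- mating_design(design, parent_ids = rownames(parents))
  loci <- colnames(offspring)
  if (!all(loci %in% colnames(parents)))
    stop("offspring loci must be a subset of parent loci")
  mm <- get_mismatch_table()
  n <- nrow(offspring)
  totals <- matrix(0L, n, nrow(design),
                   dimnames = list(rownames(offspring), design$cross_id))
  for (i in seq_len(nrow(design))) {
    gm <- parents[design$mother_id[i], loci]
    gf <- parents[design$father_id[i], loci]
    if (anyNA(gm) || anyNA(gf))
      stop("missing parental genotype in cross ", design$cross_id[i])
    score3 <- vapply(seq_along(loci),
                     function(l) mm[, gm[l] + 1L, gf[l] + 1L],
                     numeric(3))
    totals[, i] <- score_against_cross(offspring, score3)
  }
  best <- apply(totals, 1L, min)
  res <- data.frame(
    individual_id = rownames(offspring),
    status = "unassigned",
    assigned_cross = NA_character_,
    mismatch_alleles = as.integer(best),
    stringsAsFactors = FALSE, row.names = NULL
  )
  within_tol <- best <= tolerance_alleles
  if (any(within_tol)) {
    n_best <- rowSums(totals == best)
    unique_best <- within_tol & n_best == 1L
    res$status[within_tol] <- ifelse(n_best[within_tol] == 1L,
                                     "assigned", "ambiguous")
    if (any(unique_best))
      res$assigned_cross[unique_best] <-
        design$cross_id[apply(totals[unique_best, , drop = FALSE], 1L,
                              which.min)]
  }
  res
}

#' Log-likelihood of a candidate cross for one offspring
#'
#' Per-locus model: with probability `1 - epsilon` the observed genotype
#' follows Mendelian transmission from the pair; with probability `epsilon`
#' it is an independent draw from Hardy-Weinberg proportions at the
#' population allele frequency (a simple contamination model for
#' genotyping error). Missing offspring loci are skipped (factor 1). With
#' `epsilon = 0` an incompatible locus yields `-Inf`.
#'
#' @param g_o offspring genotype vector (NA allowed).
#' @param g_m,g_f parental genotype vectors.
#' @param freqs per-locus A-allele frequencies (for the error term).
#' @param epsilon genotyping-error mixture weight in \[0, 1).
#' @return scalar log-likelihood.
#' @export
likelihood_of_cross <- function(g_o, g_m, g_f, freqs, epsilon = 0.01) {
  stopifnot(epsilon >= 0, epsilon < 1,
            length(g_m) == length(g_o), length(g_f) == length(g_o),
            length(freqs) == length(g_o))
  if (anyNA(g_m) || anyNA(g_f))
    stop("missing parental genotype: parents must be fully genotyped")
  ok <- !is.na(g_o)
  if (!any(ok)) return(0)
  tprob <- transmission_prob(g_o[ok], g_m[ok], g_f[ok])
  p <- freqs[ok]
  hwe <- cbind(p^2, 2 * p * (1 - p), (1 - p)^2)[cbind(seq_along(p), g_o[ok] + 1L)]
  sum(log((1 - epsilon) * tprob + epsilon * hwe))
}

#' Likelihood-based assignment to a cross of origin
#'
#' Assigns each individual to the cross maximizing
#' [likelihood_of_cross()] over the design. Exact ties (e.g. two crosses
#' listing the same parents) are reported as `ambiguous`. The margin
#' between the best and second-best log-likelihood is a per-individual
#' confidence measure.
#'
#' @inheritParams exclusion_assign
#' @param freqs per-locus A-allele frequencies; defaults to frequencies
#'   estimated from `parents`.
#' @param epsilon genotyping-error mixture weight.
#' @return data frame: `individual_id`, `status`, `assigned_cross`,
#'   `loglik_best`, `loglik_second`.
#' @export
likelihood_assign <- function(offspring, parents, design, freqs = NULL,
                              epsilon = 0.01) {
  validate_genotypes(offspring)
  validate_genotypes(parents)
  design <- mating_design(design, parent_ids = rownames(parents))
  loci <- colnames(offspring)
  if (!all(loci %in% colnames(parents)))
    stop("offspring loci must be a subset of parent loci")
  if (is.null(freqs)) freqs <- allele_freqs(parents)[loci]
  stopifnot(length(freqs) == length(loci), epsilon >= 0, epsilon < 1)
  tt <- get_transmission_table()
  hwe <- rbind(freqs^2, 2 * freqs * (1 - freqs), (1 - freqs)^2)
  n <- nrow(offspring)
  ll <- matrix(-Inf, n, nrow(design),
               dimnames = list(rownames(offspring), design$cross_id))
  for (i in seq_len(nrow(design))) {
    gm <- parents[design$mother_id[i], loci]
    gf <- parents[design$father_id[i], loci]
    if (anyNA(gm) || anyNA(gf))
      stop("missing parental genotype in cross ", design$cross_id[i])
    score3 <- vapply(seq_along(loci),
                     function(l) log((1 - epsilon) * tt[, gm[l] + 1L, gf[l] + 1L] +
                                       epsilon * hwe[, l]),
                     numeric(3))
    ll[, i] <- score_against_cross(offspring, score3)
  }
  best <- apply(ll, 1L, max)
  n_best <- rowSums(ll == best)
  second <- vapply(seq_len(n), function(i) {
    v <- sort(ll[i, ], decreasing = TRUE)
    if (length(v) >= 2L) v[2L] else -Inf
  }, numeric(1))
  res <- data.frame(
    individual_id = rownames(offspring),
    status = ifelse(n_best == 1L, "assigned", "ambiguous"),
    assigned_cross = NA_character_,
    loglik_best = best,
    loglik_second = second,
    stringsAsFactors = FALSE, row.names = NULL
  )
  uniq <- n_best == 1L
  if (any(uniq))
    res$assigned_cross[uniq] <-
      design$cross_id[apply(ll[uniq, , drop = FALSE], 1L, which.max)]
  res
}

#' Classify which parent of a putative cross is problematic
#'
#' For an individual that failed full-pair assignment to its putative
#' cross, tests single-parent compatibility against the mother and the
#' father separately: at each non-missing locus the offspring must share at
#' least one allele with the parent, and the same allele-mismatch tolerance
#' as the exclusion method applies to the summed conflicts. Outcomes:
#' `wrong_father` (mother compatible, father not), `wrong_mother`,
#' `wrong_both`, or `undetermined` (both compatible — the pair conflict
#' cannot be pinned on one parent).
#'
#' @param g_o offspring genotype vector (NA allowed).
#' @param g_m,g_f putative mother and father genotype vectors.
#' @param tolerance_alleles allele-mismatch tolerance per parent.
#' @return one of `"wrong_father"`, `"wrong_mother"`, `"wrong_both"`,
#'   `"undetermined"`.
#' @export
classify_parentage_error <- function(g_o, g_m, g_f, tolerance_alleles = 1) {
  mom_ok <- single_parent_conflicts(g_o, g_m) <= tolerance_alleles
  dad_ok <- single_parent_conflicts(g_o, g_f) <= tolerance_alleles
  if (mom_ok && !dad_ok) "wrong_father"
  else if (!mom_ok && dad_ok) "wrong_mother"
  else if (!mom_ok && !dad_ok) "wrong_both"
  else "undetermined"
}

# Summed allele conflicts between offspring and a single candidate parent:
# a locus conflicts (1 allele) only when one is AA and the other BB —
# otherwise they share an allele.
single_parent_conflicts <- function(g_o, g_p) {
  if (anyNA(g_p))
    stop("missing parental genotype: parents must be fully genotyped")
  ok <- !is.na(g_o)
  sum(abs(g_o[ok] - g_p[ok]) == 2L)
}

#' Evaluate assignments against a truth table
#'
#' Tallies, overall and per true cross, the percentage of individuals
#' wrongly assigned (assigned to a cross other than their true one),
#' correctly assigned, ambiguous and unassigned; the four percentages
#' partition 100%. The wrong percentage among assigned individuals only is
#' also reported, since both conventions are in use.
#'
#' @param results assignment data frame from [exclusion_assign()] or
#'   [likelihood_assign()].
#' @param truth data frame `individual_id`, `cross_id` covering every
#'   individual in `results`.
#' @return list with `overall` (one-row data frame: `pct_wrong`,
#'   `pct_correct`, `pct_ambiguous`, `pct_unassigned`, `pct_misassigned`
#'   (= 100 - `pct_correct`, the overall failure-to-assign-correctly
#'   rate), `pct_wrong_of_assigned`, `n`) and `per_cross` (same columns
#'   plus `cross_id`).
#' @export
evaluate_assignment <- function(results, truth) {
  idx <- match(results$individual_id, truth$individual_id)
  if (anyNA(idx))
    stop("truth table does not cover: ",
         paste(utils::head(results$individual_id[is.na(idx)]), collapse = ", "))
  true_cross <- truth$cross_id[idx]
  assigned <- results$status == "assigned"
  wrong <- assigned & results$assigned_cross != true_cross
  correct <- assigned & results$assigned_cross == true_cross
  tally <- function(sel) {
    n <- sum(sel)
    data.frame(
      pct_wrong = 100 * sum(wrong[sel]) / n,
      pct_correct = 100 * sum(correct[sel]) / n,
      pct_ambiguous = 100 * sum(results$status[sel] == "ambiguous") / n,
      pct_unassigned = 100 * sum(results$status[sel] == "unassigned") / n,
      pct_misassigned = 100 * (1 - sum(correct[sel]) / n),
      pct_wrong_of_assigned =
        if (any(assigned[sel])) 100 * sum(wrong[sel]) / sum(assigned[sel])
        else NA_real_,
      n = n
    )
  }
  per_cross <- do.call(rbind, lapply(split(seq_along(true_cross), true_cross),
                                     function(i) {
    sel <- logical(length(true_cross)); sel[i] <- TRUE
    cbind(cross_id = true_cross[i[1L]], tally(sel))
  }))
  rownames(per_cross) <- NULL
  list(overall = tally(rep(TRUE, length(true_cross))), per_cross = per_cross)
}
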