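# Per-locus population-genetic statistics for panel characterization:
# allele frequencies, observed/expected heterozygosity, polymorphic
# information content (PIC), parent-pair non-exclusion probability (NE-PP)
# and Weir-Cockerham Fst with full-sib families as subpopulations.

#' Per-locus allele frequencies
#'
#' Frequency of the reference (A) allele at each locus,
#' \eqn{p = (2 n_{AA} + n_{AB}) / (2 n)} over non-missing genotypes.
#'
#' @param m genotype matrix.
#' @return named numeric vector, one entry per locus.
#' @export
allele_freqs <- function(m) {
  validate_genotypes(m)
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0L))
    stop("locus with all genotypes missing: ",
         paste(colnames(m)[n_obs == 0L], collapse = ", "))
  # code counts B alleles, so p(A) = 1 - mean(code)/2
  1 - colSums(m, na.rm = TRUE) / (2 * n_obs)
}

#' Expected heterozygosity of a biallelic locus
#'
#' \eqn{H_e = 2p(1-p)}; no small-sample correction is applied (at the
#' sample sizes panels are characterized on, the unbiased correction is
#' below 1e-4).
#'
#' @param p allele frequency (either allele), in \[0, 1\].
#' @return expected heterozygosity in \[0, 0.5\].
#' @export
expected_heterozygosity <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  2 * p * (1 - p)
}

#' Polymorphic information content of a biallelic locus
#'
#' Botstein's PIC, specialized to two alleles:
#' \eqn{PIC = 2pq - 2p^2q^2} with \eqn{q = 1 - p}.
#'
#' @inheritParams expected_heterozygosity
#' @return PIC in \[0, 0.375\].
#' @export
pic <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  q <- 1 - p
  2 * p * q - 2 * p^2 * q^2
}

#' Parent-pair non-exclusion probability of a biallelic locus
#'
#' The probability that a random unrelated candidate parent pair is *not*
#' excluded as the parents of a random offspring, all three genotypes drawn
#' independently from Hardy-Weinberg proportions at frequency `p`. Computed
#' by exhaustive enumeration of the 27 (mother, father, offspring) genotype
#' combinations against the Mendelian compatibility predicate; see
#' [nepp_closed_form()] for the algebraic cross-check.
#'
#' A monomorphic locus (`p` of 0 or 1) can never exclude anything; it
#' returns 1 with a warning.
#'
#' @inheritParams expected_heterozygosity
#' @return non-exclusion probability in (0, 1\].
#' @export
nepp_locus <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  vapply(p, function(pp) {
    if (pp == 0 || pp == 1) {
      warning("monomorphic locus: non-exclusion probability is 1")
      return(1)
    }
    hwe <- c(pp^2, 2 * pp * (1 - pp), (1 - pp)^2)
    tt <- get_transmission_table()
    total <- 0
    for (gm in 0:2) for (gf in 0:2) for (go in 0:2)
      if (tt[go + 1, gm + 1, gf + 1] > 0)
        total <- total + hwe[gm + 1] * hwe[gf + 1] * hwe[go + 1]
    total
  }, numeric(1))
}

#' Closed-form parent-pair non-exclusion probability
#'
#' Algebraic form of [nepp_locus()] for a biallelic locus, used as an
#' independent cross-check of the enumeration. Writing \eqn{q = 1-p},
#' the probability that both random parents carry an A is
#' \eqn{(1-q^2)^2}, and similarly for B; an AB offspring is not excluded
#' when one parent carries A and the other carries B:
#' \deqn{p^2(1-q^2)^2 + q^2(1-p^2)^2 +
#'       2pq\,[\,2(1-q^2)(1-p^2) - 4p^2q^2\,].}
#'
#' @inheritParams expected_heterozygosity
#' @return non-exclusion probability.
#' @export
nepp_closed_form <- function(p) {
  stopifnot(all(p > 0), all(p < 1))
  q <- 1 - p
  p^2 * (1 - q^2)^2 + q^2 * (1 - p^2)^2 +
    2 * p * q * (2 * (1 - q^2) * (1 - p^2) - 4 * p^2 * q^2)
}

#' Combined non-exclusion probability over independent loci
#'
#' @param nepp vector of per-locus non-exclusion probabilities in (0, 1\].
#' @return their product — the probability that no locus in the panel
#'   excludes a random unrelated parent pair.
#' @export
combined_nepp <- function(nepp) {
  stopifnot(all(nepp > 0), all(nepp <= 1))
  prod(nepp)
}

#' Minor allele frequency from expected heterozygosity
#'
#' Inverts \eqn{H_e = 2p(1-p)} to its smaller root
#' \eqn{p = (1 - \sqrt{1 - 2H_e})/2}, letting published per-locus
#' \eqn{H_e} values parameterize the other statistics.
#'
#' @param he expected heterozygosity in \[0, 0.5\].
#' @return minor allele frequency in \[0, 0.5\].
#' @export
maf_from_he <- function(he) {
  stopifnot(all(he >= 0), all(he <= 0.5))
  (1 - sqrt(1 - 2 * he)) / 2
}

#' Per-locus summary statistics
#'
#' One row per locus: minor allele frequency, observed heterozygote
#' fraction among non-missing genotypes, expected heterozygosity, PIC and
#' parent-pair non-exclusion probability. Monomorphic loci get PIC 0 and
#' NE-PP 1 (they sort last in any informativeness ranking).
#'
#' @param m genotype matrix.
#' @return data frame with columns `locus_id`, `maf`, `ho`, `he`, `pic`,
#'   `nepp`.
#' @export
locus_summary <- function(m) {
  p <- allele_freqs(m)
  maf <- pmin(p, 1 - p)
  ho <- colMeans(m == 1L, na.rm = TRUE)
  poly <- p > 0 & p < 1
  nepp <- rep(1, length(p))
  if (any(poly)) nepp[poly] <- nepp_locus(p[poly])
  data.frame(
    locus_id = colnames(m),
    maf = unname(maf),
    ho = unname(ho),
    he = unname(expected_heterozygosity(p)),
    pic = unname(pic(p)),
    nepp = nepp,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Per-locus Weir-Cockerham fixation index among families
#'
#' Estimates theta (Weir & Cockerham's 1984 Fst) per locus, treating each
#' full-sib family as a subpopulation; the estimator accommodates unequal
#' family sizes and missing genotypes. Loci that are monomorphic overall
#' (or observed in fewer than two families) have no defined theta and are
#' reported as 0 with `monomorphic = TRUE`, so they sort last when ranking.
#'
#' @param m genotype matrix.
#' @param families character/factor of family labels, one per row of `m`.
#' @return data frame with columns `locus_id`, `theta`, `monomorphic`.
#' @export
fst_per_locus <- function(m, families) {
  validate_genotypes(m)
  families <- as.factor(families)
  if (length(families) != nrow(m))
    stop("family labels must cover every individual")
  if (nlevels(droplevels(families)) < 2L)
    stop("at least two families are required")
  out <- data.frame(locus_id = colnames(m), theta = 0,
                    monomorphic = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) {
    g <- m[, j]
    ok <- !is.na(g)
    fam <- droplevels(families[ok])
    g <- g[ok]
    ni <- as.numeric(table(fam))
    r <- length(ni)
    pbar_all <- mean(2 - g) / 2
    if (r < 2L || pbar_all == 0 || pbar_all == 1) {
      out$monomorphic[j] <- TRUE
      next
    }
    pi <- tapply(2 - g, fam, mean) / 2        # A-allele freq per family
    hi <- tapply(g == 1L, fam, mean)          # observed het per family
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    denom <- a + b + cc
    if (!is.finite(denom) || denom == 0) {
      out$monomorphic[j] <- TRUE
    } else {
      out$theta[j] <- a / denom
    }
  }
  out
}

#' Multilocus Weir-Cockerham fixation index
#'
#' Ratio-of-sums aggregation of the per-locus variance components over all
#' polymorphic loci, the standard way to report a panel-wide theta.
#'
#' @inheritParams fst_per_locus
#' @return a single theta estimate.
#' @export
multilocus_fst <- function(m, families) {
  validate_genotypes(m)
  families <- as.factor(families)
  num <- den <- 0
  for (j in seq_len(ncol(m))) {
    g <- m[, j]
    ok <- !is.na(g)
    fam <- droplevels(families[ok])
    g <- g[ok]
    ni <- as.numeric(table(fam))
    r <- length(ni)
    pbar_all <- mean(2 - g) / 2
    if (r < 2L || pbar_all == 0 || pbar_all == 1) next
    pi <- tapply(2 - g, fam, mean) / 2
    hi <- tapply(g == 1L, fam, mean)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) stop("no polymorphic locus: multilocus theta undefined")
  num / den
}

#' Published white spruce 36-SNP panel statistics
#'
#' Loads the packaged per-locus summary table of the operational white
#' spruce traceability array (36 successfully genotyped SNPs): observed and
#' expected heterozygosity, PIC and parent-pair non-exclusion probability
#' as printed in the original study. Useful as a reference fixture: the
#' printed He column parameterizes [pic()] and [nepp_locus()] through
#' [maf_from_he()].
#'
#' @return data frame with columns `locus`, `snp_name`, `ho`, `he`, `pic`,
#'   `nepp`.
#' @export
spruce_panel_stats <- function() {
  path <- system.file("extdata", "spruce_snp_panel_stats.tsv",
                      package = "pedtrace", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
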