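# Synthetic parent panels and mating designs.
#
# These generators emulate the structure of an advanced conifer breeding
# program: a few dozen elite parents genotyped at biallelic SNPs with
# intermediate allele frequencies, mated in controlled crosses that re-use
# parents. They make every downstream stage testable when no real parental
# genotypes are available.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Derived per-stage substream seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12289) %% 2147483647)
}

#' Draw per-locus allele frequencies
#'
#' Samples the frequency of the reference (A) allele for each locus. The
#' default rule is uniform on \[0.1, 0.5\]: intermediate frequencies typical
#' of SNPs pre-screened for informativeness, with enough spread that
#' marker-ranking procedures have signal to work with. A degenerate range
#' (`lo == hi`) gives constant frequencies.
#'
#' @param n_loci number of loci.
#' @param range length-2 numeric, frequency range (both ends in (0, 1\] for
#'   polymorphic panels; 1.0 is tolerated for degenerate test cases).
#' @param seed integer seed; identical seeds give identical draws.
#' @return numeric vector of length `n_loci`.
#' @export
generate_allele_frequencies <- function(n_loci, range = c(0.1, 0.5),
                                        seed = NULL) {
  stopifnot(n_loci >= 1, length(range) == 2, range[1] <= range[2],
            range[1] > 0, range[2] <= 1)
  if (range[1] == range[2]) return(rep(range[1], n_loci))
  with_seed(seed, stats::runif(n_loci, range[1], range[2]))
}

#' Generate a parent panel under Hardy-Weinberg proportions
#'
#' Each parent's genotype at a locus with A-allele frequency `p` is drawn
#' with probabilities \eqn{p^2, 2p(1-p), (1-p)^2} for AA/AB/BB. Generated
#' parents carry no missing data, matching the standard candidate-locus
#' prefilter (parents fully genotyped).
#'
#' @param freqs per-locus A-allele frequencies.
#' @param n_parents number of parents (at least 2 for a usable panel).
#' @param seed integer seed.
#' @param ids optional individual ids (default `P001`, `P002`, ...).
#' @param locus_ids optional locus ids (default `L001`, ...).
#' @return genotype matrix, parents in rows.
#' @export
generate_parents <- function(freqs, n_parents, seed = NULL, ids = NULL,
                             locus_ids = NULL) {
  stopifnot(n_parents >= 1, all(freqs > 0), all(freqs <= 1))
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n_parents))
  if (is.null(locus_ids)) locus_ids <- sprintf("L%03d", seq_along(freqs))
  m <- with_seed(seed, {
    # genotype code counts B alleles, so B dosage ~ Binomial(2, 1 - p)
    vapply(freqs, function(p) stats::rbinom(n_parents, 2L, 1 - p),
           integer(n_parents))
  })
  m <- matrix(as.integer(m), nrow = n_parents,
              dimnames = list(ids, locus_ids))
  validate_genotypes(m)
  m
}

#' Generate a mating design over a parent panel
#'
#' Samples `n_crosses` distinct unordered parent pairs. With
#' `shared_parent_bias = 0` pairs are drawn uniformly without replacement
#' from all possible pairs; a positive bias over-weights parents already
#' used, producing designs rich in half-sib (shared-parent) crosses, the
#' structure that most stresses cross-assignment.
#'
#' @param parent_ids character vector of parent ids.
#' @param n_crosses number of crosses; must not exceed the number of
#'   distinct unordered pairs.
#' @param seed integer seed.
#' @param shared_parent_bias non-negative; 0 = uniform pair sampling.
#' @return mating design data frame (see [mating_design()]).
#' @export
generate_mating_design <- function(parent_ids, n_crosses, seed = NULL,
                                   shared_parent_bias = 0) {
  parent_ids <- as.character(parent_ids)
  n <- length(parent_ids)
  stopifnot(n >= 2, n_crosses >= 1, shared_parent_bias >= 0)
  n_pairs <- n * (n - 1) / 2
  if (n_crosses > n_pairs)
    stop("infeasible design: ", n_crosses, " crosses requested but only ",
         n_pairs, " distinct parent pairs exist")
  pairs <- t(utils::combn(n, 2L))
  picked <- with_seed(seed, {
    if (shared_parent_bias == 0) {
      sample.int(nrow(pairs), n_crosses)
    } else {
      used <- integer(n)
      avail <- rep(TRUE, nrow(pairs))
      out <- integer(n_crosses)
      for (k in seq_len(n_crosses)) {
        idx <- which(avail)
        w <- (1 + shared_parent_bias * used[pairs[idx, 1L]]) *
             (1 + shared_parent_bias * used[pairs[idx, 2L]])
        out[k] <- idx[sample.int(length(idx), 1L, prob = w)]
        avail[out[k]] <- FALSE
        used[pairs[out[k], ]] <- used[pairs[out[k], ]] + 1L
      }
      out
    }
  })
  mating_design(data.frame(
    cross_id = sprintf("X%03d", seq_len(n_crosses)),
    mother_id = parent_ids[pairs[picked, 1L]],
    father_id = parent_ids[pairs[picked, 2L]],
    stringsAsFactors = FALSE
  ), parent_ids = parent_ids)
}

#' Generate a complete synthetic breeding population
#'
#' Convenience wrapper producing allele frequencies, a Hardy-Weinberg
#' parent panel and a mating design from one seed (per-stage substreams are
#' derived from it, so the whole population is reproducible end to end).
#' Defaults emulate a program of 73 elite parents crossed 68 times and
#' genotyped at 36 SNPs.
#'
#' @param n_parents,n_loci,n_crosses population dimensions.
#' @param freq_range allele-frequency sampling range.
#' @param shared_parent_bias see [generate_mating_design()].
#' @param seed integer seed.
#' @return list with `freqs`, `parents`, `design`.
#' @export
generate_population <- function(n_parents = 73, n_loci = 36, n_crosses = 68,
                                freq_range = c(0.1, 0.5),
                                shared_parent_bias = 0, seed = NULL) {
  freqs <- generate_allele_frequencies(n_loci, freq_range,
                                       seed = derive_seed(seed, 1L))
  parents <- generate_parents(freqs, n_parents, seed = derive_seed(seed, 2L))
  design <- generate_mating_design(rownames(parents), n_crosses,
                                   seed = derive_seed(seed, 3L),
                                   shared_parent_bias = shared_parent_bias)
  list(freqs = freqs, parents = parents, design = design)
}
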