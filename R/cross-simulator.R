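# Mendelian full-sib progeny simulation.
#
# For each cross and locus, one allele is drawn uniformly from each
# parent's two alleles, independently across loci and offspring (loci are
# treated as unlinked; panels built one-SNP-per-gene make this a good
# approximation). The same transmission table drives both the simulator and
# the likelihood assigner.

#' Mendelian transmission table
#'
#' Returns the 3x3x3 array `T[g_o + 1, g_m + 1, g_f + 1]` of probabilities
#' that parents with genotypes `g_m`, `g_f` produce an offspring with
#' genotype `g_o`, from exact gamete enumeration. Every (mother, father)
#' slice sums to 1.
#'
#' @return numeric array with dimnames `AA`/`AB`/`BB`.
#' @export
transmission_table <- function() {
  tt <- array(0, dim = c(3, 3, 3),
              dimnames = rep(list(c("AA", "AB", "BB")), 3))
  for (gm in 0:2) for (gf in 0:2) {
    pm <- gm / 2   # P(B allele transmitted by mother)
    pf <- gf / 2
    tt[1, gm + 1, gf + 1] <- (1 - pm) * (1 - pf)
    tt[2, gm + 1, gf + 1] <- pm * (1 - pf) + (1 - pm) * pf
    tt[3, gm + 1, gf + 1] <- pm * pf
  }
  tt
}

# cached at load time (build-once lookup tables)
.pedtrace_cache <- new.env(parent = emptyenv())

get_transmission_table <- function() {
  if (is.null(.pedtrace_cache$tt)) .pedtrace_cache$tt <- transmission_table()
  .pedtrace_cache$tt
}

#' Mendelian transmission probability
#'
#' @param g_o,g_m,g_f offspring, mother and father genotype codes
#'   (0 = AA, 1 = AB, 2 = BB); vectors are recycled to a common length.
#' @return probability of the offspring genotype given the parent pair.
#' @export
transmission_prob <- function(g_o, g_m, g_f) {
  n <- max(length(g_o), length(g_m), length(g_f))
  g_o <- rep_len(g_o, n); g_m <- rep_len(g_m, n); g_f <- rep_len(g_f, n)
  if (anyNA(g_o) || anyNA(g_m) || anyNA(g_f))
    stop("transmission_prob is undefined for missing genotype codes")
  stopifnot(all(g_o %in% 0:2), all(g_m %in% 0:2), all(g_f %in% 0:2))
  get_transmission_table()[cbind(g_o + 1L, g_m + 1L, g_f + 1L)]
}

#' Simulate offspring of a single cross
#'
#' @param g_mother,g_father parental genotype vectors over the same loci;
#'   missing genotypes are an error (prefilter parents first).
#' @param n number of offspring.
#' @param seed integer seed.
#' @param ids optional offspring ids.
#' @return genotype matrix with `n` rows.
#' @export
simulate_offspring <- function(g_mother, g_father, n, seed = NULL,
                               ids = NULL) {
  if (length(g_mother) != length(g_father))
    stop("parent genotype vectors must cover the same loci")
  if (anyNA(g_mother) || anyNA(g_father))
    stop("missing parental genotype: parents must be fully genotyped")
  L <- length(g_mother)
  locus_ids <- names(g_mother)
  if (is.null(locus_ids)) locus_ids <- sprintf("L%03d", seq_len(L))
  if (is.null(ids)) ids <- sprintf("O%05d", seq_len(n))
  m <- with_seed(seed, {
    bm <- matrix(stats::rbinom(n * L, 1L, rep(g_mother / 2, each = n)), n, L)
    bf <- matrix(stats::rbinom(n * L, 1L, rep(g_father / 2, each = n)), n, L)
    bm + bf
  })
  if (n == 0L) m <- matrix(integer(0), 0L, L)
  m <- matrix(as.integer(m), nrow = n, ncol = L,
              dimnames = list(ids, locus_ids))
  validate_genotypes(m)
  m
}

#' Simulate a full progeny dataset over a mating design
#'
#' Generates `n_per_cross` offspring for every cross of the design
#' (default 100, the customary scale for assignment benchmarking). The true
#' cross of each offspring is returned as a separate truth table and is
#' never encoded in the individual ids, so assignment code cannot use it.
#'
#' @param parents parent genotype matrix (no missing data at design loci).
#' @param design mating design; parent ids must resolve in `parents`.
#' @param n_per_cross offspring per cross.
#' @param seed integer seed; the dataset is reproducible bit for bit.
#' @return list with `genotypes` (progeny matrix) and `truth`
#'   (data frame `individual_id`, `cross_id`).
#' @export
simulate_progeny_dataset <- function(parents, design, n_per_cross = 100,
                                     seed = NULL) {
  validate_genotypes(parents)
  design <- mating_design(design, parent_ids = rownames(parents))
  n_cross <- nrow(design)
  total <- n_cross * n_per_cross
  ids <- sprintf("O%05d", seq_len(total))
  chunks <- vector("list", n_cross)
  for (i in seq_len(n_cross)) {
    idx <- ((i - 1L) * n_per_cross + 1L):(i * n_per_cross)
    if (n_per_cross == 0L) idx <- integer(0)
    chunks[[i]] <- simulate_offspring(
      parents[design$mother_id[i], ], parents[design$father_id[i], ],
      n_per_cross, seed = derive_seed(seed, i), ids = ids[idx])
  }
  genotypes <- do.call(rbind, chunks)
  if (is.null(genotypes))
    genotypes <- matrix(integer(0), 0L, ncol(parents),
                        dimnames = list(NULL, colnames(parents)))
  truth <- data.frame(
    individual_id = ids,
    cross_id = rep(design$cross_id, each = n_per_cross),
    stringsAsFactors = FALSE
  )
  list(genotypes = genotypes, truth = truth)
}
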