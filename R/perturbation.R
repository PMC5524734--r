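# Controlled injection of missing data and genotyping errors.
#
# Perturbations use exact counts (round(rate * n_cells) cells sampled
# without replacement over the whole individual x locus grid), not per-cell
# Bernoulli draws: a benchmark dataset advertised as "3.5% missing" carries
# exactly that proportion. Cells not selected are bit-identical to the
# input. The coordinates touched are attached as attributes
# ("missing_cells", "error_cells") for auditing.

perturb_count <- function(rate, n_cells) {
  stopifnot(rate >= 0, rate <= 1)
  as.integer(round(rate * n_cells))
}

#' Inject missing data
#'
#' Sets exactly `round(rate * n_cells)` cells, drawn uniformly without
#' replacement over the full grid, to missing.
#'
#' @param m genotype matrix.
#' @param rate fraction of cells to blank, in \[0, 1\].
#' @param seed integer seed.
#' @return perturbed matrix; attribute `missing_cells` holds the (row, col)
#'   indices blanked.
#' @export
inject_missing <- function(m, rate, seed = NULL) {
  validate_genotypes(m)
  k <- perturb_count(rate, length(m))
  cells <- with_seed(seed, sample.int(length(m), k))
  out <- m
  out[cells] <- NA_integer_
  attr(out, "missing_cells") <- arrayInd(cells, dim(m))
  out
}

#' Inject genotyping errors
#'
#' Replaces exactly `round(rate * n_cells)` cells by a wrong genotype.
#' Only non-missing cells are eligible; every altered cell differs from its
#' original. Two error models are available:
#' \describe{
#'   \item{`genotype`}{the observed genotype is replaced by one of the two
#'     *other* genotype states, chosen uniformly (default; the simplest
#'     model for errors on called genotypes).}
#'   \item{`allele`}{one of the two alleles is flipped: AA and BB become
#'     AB; AB becomes AA or BB with equal probability.}
#' }
#'
#' @param m genotype matrix.
#' @param rate fraction of the full grid to corrupt.
#' @param seed integer seed.
#' @param mode error model, `"genotype"` or `"allele"`.
#' @return perturbed matrix; attribute `error_cells` holds the altered
#'   (row, col) indices.
#' @export
inject_errors <- function(m, rate, seed = NULL,
                          mode = c("genotype", "allele")) {
  validate_genotypes(m)
  mode <- match.arg(mode)
  k <- perturb_count(rate, length(m))
  eligible <- which(!is.na(m))
  if (k > length(eligible))
    stop("cannot inject ", k, " errors: only ", length(eligible),
         " non-missing cells")
  out <- with_seed(seed, {
    cells <- eligible[sample.int(length(eligible), k)]
    old <- m[cells]
    new <- if (mode == "genotype") {
      # uniform over the two other states
      other <- cbind((old + 1L) %% 3L, (old + 2L) %% 3L)
      other[cbind(seq_len(k), sample.int(2L, k, replace = TRUE))]
    } else {
      flip_up <- sample.int(2L, k, replace = TRUE) == 1L
      ifelse(old == 0L, 1L, ifelse(old == 2L, 1L,
                                   ifelse(flip_up, 2L, 0L)))
    }
    res <- m
    res[cells] <- as.integer(new)
    attr(res, "error_cells") <- arrayInd(cells, dim(m))
    res
  })
  out
}

#' Inject genotyping errors and missing data on disjoint cells
#'
#' Applies errors first, then samples the missing cells from the cells not
#' already altered, so an injected error can never be masked by injected
#' missingness (which would silently lower the realized error rate). Both
#' counts are exact.
#'
#' @param m genotype matrix.
#' @param missing_rate,error_rate fractions of the full grid.
#' @param seed integer seed.
#' @param mode error model, see [inject_errors()].
#' @return perturbed matrix with attributes `error_cells` and
#'   `missing_cells`.
#' @export
inject_combined <- function(m, missing_rate, error_rate, seed = NULL,
                            mode = c("genotype", "allele")) {
  validate_genotypes(m)
  mode <- match.arg(mode)
  k_err <- perturb_count(error_rate, length(m))
  k_mis <- perturb_count(missing_rate, length(m))
  if (k_err + k_mis > length(m))
    stop("requested perturbation counts exceed the grid size")
  withe <- inject_errors(m, error_rate, seed = derive_seed(seed, 101L),
                         mode = mode)
  err_cells <- attr(withe, "error_cells")
  err_lin <- if (nrow(err_cells)) err_cells[, 1L] + (err_cells[, 2L] - 1L) * nrow(m)
             else integer(0)
  pool <- setdiff(seq_along(m), err_lin)
  if (k_mis > length(pool))
    stop("cannot blank ", k_mis, " cells disjoint from ", k_err, " error cells")
  mis <- with_seed(derive_seed(seed, 102L),
                   pool[sample.int(length(pool), k_mis)])
  out <- withe
  out[mis] <- NA_integer_
  attr(out, "missing_cells") <- arrayInd(mis, dim(m))
  attr(out, "error_cells") <- err_cells
  out
}
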