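# End-to-end orchestration: panel design, robustness benchmarking and
# batch certification. Each run returns plain data frames (the contract);
# plotting is left to the caller.

#' Default robustness grid
#'
#' The customary benchmark settings: five missing-data rates (3.5, 7.0,
#' 10.0, 13.5, 17.0%), five genotyping-error rates (0.5, 1.0, 2.0, 3.0,
#' 5.0%), the five paired combinations of the two, plus the clean (0, 0)
#' baseline — 16 cells.
#'
#' @return data frame with columns `missing_rate`, `error_rate`.
#' @export
default_robustness_grid <- function() {
  mis <- c(0.035, 0.07, 0.10, 0.135, 0.17)
  err <- c(0.005, 0.01, 0.02, 0.03, 0.05)
  rbind(
    data.frame(missing_rate = 0, error_rate = 0),
    data.frame(missing_rate = mis, error_rate = 0),
    data.frame(missing_rate = 0, error_rate = err),
    data.frame(missing_rate = mis, error_rate = err)
  )
}

#' Robustness of assignment to missing data and genotyping errors
#'
#' For every grid cell and replicate: simulate a fresh progeny dataset,
#' perturb it at the cell's exact missing/error rates, assign by the
#' requested methods and evaluate against the simulation truth. Results
#' come back as one long tidy table (a row per replicate x cell x method),
#' invariant to cell execution order and bit-reproducible under `seed`.
#'
#' @param parents parent genotype matrix.
#' @param design mating design.
#' @param n_per_cross offspring per cross per replicate.
#' @param grid data frame `missing_rate`, `error_rate`; defaults to
#'   [default_robustness_grid()].
#' @param n_reps replicates per cell.
#' @param seed integer seed.
#' @param methods any of `"exclusion"`, `"likelihood"`.
#' @param tolerance_alleles exclusion tolerance.
#' @param epsilon likelihood error-mixture weight.
#' @return data frame: `replicate`, `missing_rate`, `error_rate`, `method`,
#'   `pct_wrong`, `pct_correct`, `pct_ambiguous`, `pct_unassigned`,
#'   `pct_wrong_of_assigned`, `n`.
#' @export
run_robustness_grid <- function(parents, design, n_per_cross = 100,
                                grid = default_robustness_grid(),
                                n_reps = 5, seed = NULL,
                                methods = c("exclusion", "likelihood"),
                                tolerance_alleles = 1, epsilon = 0.01) {
  methods <- match.arg(methods, several.ok = TRUE)
  freqs <- allele_freqs(parents)
  rows <- list()
  for (rep_i in seq_len(n_reps)) {
    sim <- simulate_progeny_dataset(parents, design, n_per_cross,
                                    seed = derive_seed(seed, 1000L + rep_i))
    for (cell in seq_len(nrow(grid))) {
      mr <- grid$missing_rate[cell]
      er <- grid$error_rate[cell]
      pert <- inject_combined(sim$genotypes, mr, er,
                              seed = derive_seed(seed,
                                                 10000L + 100L * rep_i + cell))
      for (method in methods) {
        res <- if (method == "exclusion") {
          exclusion_assign(pert, parents, design, tolerance_alleles)
        } else {
          likelihood_assign(pert, parents, design, freqs = freqs,
                            epsilon = epsilon)
        }
        ev <- evaluate_assignment(res, sim$truth)$overall
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(replicate = rep_i, missing_rate = mr,
                           error_rate = er, method = method), ev)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Design an informative SNP panel
#'
#' Executes the panel-design workflow: simulate a progeny dataset from the
#' parents and mating design, rank the candidate loci with the requested
#' discrimination procedure, apply the assayability and one-SNP-per-gene
#' constraints, and keep the top `k`. The report also computes the other
#' two procedures' rankings and their top-`k` overlap with the selected
#' set, plus summary statistics (including the combined non-exclusion
#' probability) of the selected panel evaluated on the parents.
#'
#' @param parents parent genotype matrix (candidate loci as columns).
#' @param design mating design.
#' @param panel optional [snp_panel()] metadata for the candidates.
#' @param procedure `"rf"`, `"maf"` or `"fst"`.
#' @param k panel size.
#' @param n_per_cross offspring per cross for the ranking simulation.
#' @param n_trees random-forest ensemble size.
#' @param seed integer seed.
#' @return list: `selected` (locus ids), `ranking`, `stats`
#'   (locus summary of the selected panel), `combined_nepp`,
#'   `procedure_overlap` (top-k overlap counts between procedures).
#' @export
run_panel_design <- function(parents, design, panel = NULL,
                             procedure = c("rf", "maf", "fst"), k = 40,
                             n_per_cross = 100, n_trees = 10000,
                             seed = NULL) {
  procedure <- match.arg(procedure)
  sim <- simulate_progeny_dataset(parents, design, n_per_cross,
                                  seed = derive_seed(seed, 1L))
  fam <- sim$truth$cross_id
  rankings <- list(
    fst = rank_by_fst(sim$genotypes, fam),
    maf = rank_by_maf(parents),
    rf = rank_by_rf_importance(sim$genotypes, fam, n_trees = n_trees,
                               seed = derive_seed(seed, 2L))
  )
  selected <- select_top_k(rankings[[procedure]], k, panel = panel)
  tops <- lapply(rankings, function(r) utils::head(r$locus_id, k))
  pairs <- utils::combn(names(tops), 2L)
  overlap <- data.frame(
    procedure_a = pairs[1L, ], procedure_b = pairs[2L, ],
    shared = apply(pairs, 2L, function(pr)
      length(intersect(tops[[pr[1L]]], tops[[pr[2L]]]))),
    stringsAsFactors = FALSE
  )
  stats <- locus_summary(parents[, selected, drop = FALSE])
  list(selected = selected,
       ranking = rankings[[procedure]],
       rankings = rankings,
       stats = stats,
       combined_nepp = combined_nepp(stats$nepp),
       procedure_overlap = overlap)
}

#' Certify a batch of samples against the breeding program
#'
#' Runs the full certification chain for a batch of genotyped samples
#' (cryobank tissues and/or field trees belonging to putative cell lines):
#' individual missingness filter, exclusion assignment, likelihood
#' confirmation, parent-error classification for samples failing their
#' putative cross, fingerprint construction and per-line stage diagnosis.
#' Samples whose two assignment methods disagree are flagged
#' `methods_discordant` for manual review rather than silently resolved.
#'
#' @param samples genotype matrix of the batch.
#' @param metadata data frame with one row per sample: `sample_id`,
#'   `line_id`, `role` (`cryobank_tissue` or `field_tree`),
#'   `putative_cross`.
#' @param parents parent genotype matrix.
#' @param design mating design.
#' @param max_missing individual missingness filter threshold.
#' @param tolerance_alleles exclusion tolerance.
#' @param epsilon likelihood error-mixture weight.
#' @return list: `samples` (per-sample table: status of both methods,
#'   legitimacy vs putative cross, parent-error class, discordance flag,
#'   fingerprint), `lines` (per-line diagnosis), `summary` (counts per
#'   line classification), `n_filtered` (samples dropped for missingness).
#' @export
run_certification <- function(samples, metadata, parents, design,
                              max_missing = 0.15, tolerance_alleles = 1,
                              epsilon = 0.01) {
  stopifnot(all(c("sample_id", "line_id", "role", "putative_cross") %in%
                  names(metadata)))
  design <- mating_design(design, parent_ids = rownames(parents))
  kept <- filter_individuals_by_missingness(samples, max_missing)
  n_filtered <- nrow(samples) - nrow(kept)
  meta <- metadata[match(rownames(kept), metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata does not cover every sample")
  excl <- exclusion_assign(kept, parents, design, tolerance_alleles)
  lik <- likelihood_assign(kept, parents, design, epsilon = epsilon)
  legitimate <- excl$status == "assigned" &
    excl$assigned_cross == meta$putative_cross
  discordant <- excl$status == "assigned" & lik$status == "assigned" &
    excl$assigned_cross != lik$assigned_cross
  pec <- rep(NA_character_, nrow(kept))
  loci <- colnames(kept)
  for (i in which(!legitimate)) {
    ci <- match(meta$putative_cross[i], design$cross_id)
    if (is.na(ci)) next
    pec[i] <- classify_parentage_error(
      kept[i, ], parents[design$mother_id[ci], loci],
      parents[design$father_id[ci], loci],
      tolerance_alleles = tolerance_alleles)
  }
  per_sample <- data.frame(
    sample_id = rownames(kept),
    line_id = meta$line_id,
    role = meta$role,
    putative_cross = meta$putative_cross,
    exclusion_status = excl$status,
    exclusion_cross = excl$assigned_cross,
    likelihood_cross = lik$assigned_cross,
    legitimate = legitimate,
    methods_discordant = discordant,
    parent_error_class = pec,
    fingerprint = unname(build_fingerprints(kept)),
    stringsAsFactors = FALSE
  )
  lines <- do.call(rbind, lapply(split(per_sample, per_sample$line_id),
                                 function(df) {
    members <- data.frame(member_id = df$sample_id, role = df$role,
                          legitimate = df$legitimate,
                          fingerprint = df$fingerprint,
                          parent_error_class = df$parent_error_class,
                          stringsAsFactors = FALSE)
    d <- withCallingHandlers(diagnose_cell_line(members),
                             warning = function(w) invokeRestart("muffleWarning"))
    data.frame(line_id = df$line_id[1L],
               classification = d$classification,
               detail = d$detail,
               identical_members = d$identical,
               n_members = nrow(df),
               any_discordant = any(df$methods_discordant),
               stringsAsFactors = FALSE)
  }))
  rownames(lines) <- NULL
  summary <- as.data.frame(table(classification = lines$classification),
                           stringsAsFactors = FALSE)
  names(summary)[2L] <- "n_lines"
  list(samples = per_sample, lines = lines, summary = summary,
       n_filtered = n_filtered)
}
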