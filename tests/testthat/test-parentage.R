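test_that("per-locus allele mismatch counts minimal substitutions", {
  expect_identical(locus_mismatch(1, 0, 0), 1L)  # AB from AA x AA
  expect_identical(locus_mismatch(2, 0, 0), 2L)  # BB from AA x AA
  expect_identical(locus_mismatch(0, 0, 1), 0L)  # AA from AA x AB
  expect_identical(locus_mismatch(0, 2, 2), 2L)
  expect_identical(locus_mismatch(0, 0, 2), 1L)  # AA where AB is obligate
  # missing offspring genotype is uninformative
  expect_identical(locus_mismatch(NA, 0, 0), 0L)
  expect_error(locus_mismatch(0, NA, 1), "missing parental")
})

test_that("exclusion assignment applies the allele-mismatch tolerance", {
  parents <- make_geno(rbind(c(0L, 0L), c(0L, 0L), c(2L, 0L)),
                       ids = c("m1", "f1", "f2"))
  design <- mating_design(data.frame(cross_id = c("c1", "c2"),
                                     mother_id = "m1",
                                     father_id = c("f1", "f2")))
  # offspring AB at locus 1: c2 (AA x BB) fits perfectly, c1 needs 1 allele
  off <- make_geno(rbind(c(1L, 0L)), ids = "o1")
  res0 <- exclusion_assign(off, parents, design, tolerance_alleles = 0)
  expect_identical(res0$status, "assigned")
  expect_identical(res0$assigned_cross, "c2")

  # with only the imperfect cross available, tolerance 1 still assigns
  res1 <- exclusion_assign(off, parents, design[1, ], tolerance_alleles = 1)
  expect_identical(res1$status, "assigned")
  expect_identical(res1$mismatch_alleles, 1L)
  res1b <- exclusion_assign(off, parents, design[1, ], tolerance_alleles = 0)
  expect_identical(res1b$status, "unassigned")

  # duplicated parent pairs can never be told apart
  dup <- mating_design(data.frame(cross_id = c("c1", "c1bis"),
                                  mother_id = "m1", father_id = "f1"))
  off2 <- make_geno(rbind(c(0L, 0L)), ids = "o2")
  expect_identical(exclusion_assign(off2, parents, dup, 1)$status,
                   "ambiguous")
})

test_that("error-free progeny are always compatible with their true cross", {
  pop <- tiny_population(21)
  sim <- simulate_progeny_dataset(pop$parents, pop$design, 15, seed = 22)
  res <- exclusion_assign(sim$genotypes, pop$parents, pop$design,
                          tolerance_alleles = 0)
  ev <- evaluate_assignment(res, sim$truth)$overall
  expect_equal(ev$pct_wrong, 0)
  expect_equal(ev$pct_unassigned, 0)
  # the minimum mismatch total is 0 for everyone (the truth attains it)
  expect_true(all(res$mismatch_alleles == 0L))
})

test_that("perturbation can raise the true-cross mismatch by at most its allele distance", {
  pop <- tiny_population(31, n_parents = 8, n_loci = 12, n_crosses = 4)
  sim <- simulate_progeny_dataset(pop$parents, pop$design, 10, seed = 32)
  pert <- inject_errors(sim$genotypes, 0.05, seed = 33)
  cells <- attr(pert, "error_cells")
  d_added <- abs(pert[cells] - sim$genotypes[cells])
  d_per_ind <- tapply(d_added, cells[, 1], sum)
  loci <- colnames(sim$genotypes)
  for (i in seq_len(nrow(pert))) {
    ci <- match(sim$truth$cross_id[i], pop$design$cross_id)
    mm <- sum(locus_mismatch(pert[i, ],
                             pop$parents[pop$design$mother_id[ci], loci],
                             pop$parents[pop$design$father_id[ci], loci]))
    d <- d_per_ind[as.character(i)]
    expect_lte(mm, if (is.na(d)) 0 else d)
  }
})

test_that("likelihood of a cross follows the Mendelian-HWE mixture", {
  freqs <- rep(0.5, 3)
  # obligate heterozygote everywhere: probability 1 per locus
  expect_equal(likelihood_of_cross(rep(1L, 3), rep(0L, 3), rep(2L, 3),
                                   freqs, epsilon = 0), 0)
  # 1:2:1 segregation contributes log(0.25)
  expect_equal(likelihood_of_cross(c(0L, NA, NA), rep(1L, 3), rep(1L, 3),
                                   freqs, epsilon = 0), log(0.25))
  # incompatible locus at epsilon 0: impossible
  expect_identical(likelihood_of_cross(c(2L, 1L, 1L), rep(0L, 3), rep(0L, 3),
                                       freqs, epsilon = 0), -Inf)
  # with contamination the same locus gets the HWE mass
  ll <- likelihood_of_cross(c(2L, NA, NA), rep(0L, 3), rep(0L, 3),
                            freqs, epsilon = 0.01)
  expect_equal(ll, log(0.01 * 0.25))
})

test_that("likelihood assignment picks the Mendelian-dominant cross and flags ties", {
  parents <- make_geno(rbind(rep(0L, 6), rep(2L, 6), rep(1L, 6), rep(1L, 6)),
                       ids = c("pAA", "pBB", "h1", "h2"))
  design <- mating_design(data.frame(cross_id = c("cross_hom", "cross_het"),
                                     mother_id = c("pAA", "h1"),
                                     father_id = c("pBB", "h2")))
  off <- make_geno(rbind(rep(1L, 6)), ids = "o1")
  res <- likelihood_assign(off, parents, design, freqs = rep(0.5, 6),
                           epsilon = 0)
  expect_identical(res$assigned_cross, "cross_hom")
  expect_equal(res$loglik_best, 0)              # per-locus probability 1
  expect_equal(res$loglik_second, 6 * log(0.5)) # AB x AB gives 1/2 per locus

  dup <- mating_design(data.frame(cross_id = c("a", "b"),
                                  mother_id = "h1", father_id = "h2"))
  expect_identical(likelihood_assign(off, parents, dup,
                                     freqs = rep(0.5, 6))$status,
                   "ambiguous")
})

test_that("likelihood assignment recovers every true cross on clean data", {
  pop <- tiny_population(41, n_parents = 8, n_loci = 36, n_crosses = 2)
  sim <- simulate_progeny_dataset(pop$parents, pop$design, 50, seed = 42)
  res <- likelihood_assign(sim$genotypes, pop$parents, pop$design,
                           epsilon = 0.01)
  ev <- evaluate_assignment(res, sim$truth)$overall
  expect_equal(ev$pct_correct, 100)
})

test_that("exclusion and likelihood agree on error-free data where both assign", {
  pop <- tiny_population(51)
  sim <- simulate_progeny_dataset(pop$parents, pop$design, 10, seed = 52)
  re <- exclusion_assign(sim$genotypes, pop$parents, pop$design, 1)
  rl <- likelihood_assign(sim$genotypes, pop$parents, pop$design)
  both <- re$status == "assigned" & rl$status == "assigned"
  expect_gt(sum(both), 0)
  expect_identical(re$assigned_cross[both], rl$assigned_cross[both])
})

test_that("problematic-parent classification separates mother and father conflicts", {
  g_m <- rep(0L, 10)                   # putative mother AA everywhere
  g_f <- rep(0L, 10)                   # putative father AA everywhere
  # hard conflict = offspring BB where a parent is AA (no shared allele)
  off <- c(2L, 2L, rep(0L, 8))
  mother_ok <- c(1L, 1L, rep(0L, 8))   # shares an allele everywhere
  expect_identical(classify_parentage_error(off, mother_ok, g_f),
                   "wrong_father")
  expect_identical(classify_parentage_error(off, g_m, mother_ok),
                   "wrong_mother")
  expect_identical(classify_parentage_error(off, g_m, g_f), "wrong_both")
  expect_identical(classify_parentage_error(rep(0L, 10), g_m, g_f),
                   "undetermined")
  # a single conflicting allele sits within the default tolerance
  off_one <- c(2L, rep(0L, 9))
  expect_identical(classify_parentage_error(off_one, g_m, g_f),
                   "undetermined")
})

test_that("assignment evaluation partitions every individual exactly once", {
  truth <- data.frame(individual_id = c("a", "b", "c", "d"),
                      cross_id = c("c1", "c1", "c2", "c2"))
  results <- data.frame(
    individual_id = c("a", "b", "c", "d"),
    status = c("assigned", "assigned", "ambiguous", "unassigned"),
    assigned_cross = c("c1", "c2", NA, NA),
    stringsAsFactors = FALSE
  )
  ev <- evaluate_assignment(results, truth)$overall
  expect_equal(ev$pct_wrong, 25)
  expect_equal(ev$pct_correct, 25)
  expect_equal(ev$pct_ambiguous, 25)
  expect_equal(ev$pct_unassigned, 25)
  expect_equal(ev$pct_wrong + ev$pct_correct + ev$pct_ambiguous +
                 ev$pct_unassigned, 100)
  expect_equal(ev$pct_misassigned, 75)
  expect_equal(ev$pct_wrong_of_assigned, 50)
  per <- evaluate_assignment(results, truth)$per_cross
  expect_identical(nrow(per), 2L)
})
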