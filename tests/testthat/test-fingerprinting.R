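test_that("fingerprints concatenate panel-ordered genotypes canonically", {
  g <- c(0L, 1L, 2L, NA, 0L)
  expect_identical(build_fingerprint(g), "AHB?A")
  expect_identical(fingerprint_missing("AHB?A"), 1L)
  expect_identical(build_fingerprint(rep(NA_integer_, 36)),
                   strrep("?", 36))
  m <- make_geno(rbind(c(0L, 1L), c(2L, NA)))
  expect_identical(unname(build_fingerprints(m)), c("AH", "B?"))
})

test_that("fingerprint matching tolerates mismatches and missing loci as declared", {
  full <- strrep("A", 36)
  db <- fingerprint_db(c("line1", "line2", "line3"),
                       role = "cryobank_tissue",
                       fingerprint = c(full,
                                       paste0(strrep("A", 35), "B"),
                                       strrep("B", 36)))
  hit <- match_fingerprint(full, db, max_mismatch = 0)
  expect_identical(hit$line_id, "line1")
  expect_identical(hit$mismatches, 0)
  expect_identical(hit$overlap, 36)

  hits1 <- match_fingerprint(full, db, max_mismatch = 1)
  expect_identical(hits1$line_id, c("line1", "line2"))
  expect_identical(hits1$mismatches, c(0, 1))

  # missing loci drop out of the comparison on either side
  holey <- paste0(strrep("?", 6), strrep("A", 30))
  hit2 <- match_fingerprint(holey, db, max_mismatch = 0, min_overlap = 30)
  expect_identical(hit2$line_id, "line1")
  expect_identical(hit2$overlap, 30)

  # overlap below the floor everywhere: flagged, not guessed
  sparse <- paste0(strrep("?", 30), strrep("A", 6))
  res <- match_fingerprint(sparse, db)
  expect_identical(nrow(res), 0L)
  expect_true(isTRUE(attr(res, "insufficient_data")))

  # symmetry of the pairwise comparison
  a <- "AH?BA"; b <- "AHB?B"
  expect_identical(match_fingerprint(a, fingerprint_db("x", "r", b),
                                     max_mismatch = 5, min_overlap = 1)$mismatches,
                   match_fingerprint(b, fingerprint_db("x", "r", a),
                                     max_mismatch = 5, min_overlap = 1)$mismatches)
})

test_that("duplicate detection reports identical pairs and only pairs", {
  pop <- generate_population(n_parents = 40, n_loci = 36, n_crosses = 20,
                             seed = 14)
  sim <- simulate_progeny_dataset(pop$parents, pop$design, 5, seed = 15)
  fps <- build_fingerprints(sim$genotypes)
  planted <- fps
  planted[["O00100"]] <- planted[["O00001"]]
  base <- find_duplicate_fingerprints(fps)
  withp <- find_duplicate_fingerprints(planted)
  extra <- setdiff(paste(withp$id1, withp$id2),
                   paste(base$id1, base$id2))
  expect_identical(extra, "O00001 O00100")

  distinct <- c(a = "AAAA", b = "ABAA", c = "BBBB")
  expect_identical(nrow(find_duplicate_fingerprints(distinct,
                                                    min_overlap = 4)), 0L)
})

test_that("full-sib fingerprint collisions occur at the enumerated per-locus rate", {
  # same-cross sibs at an AB x AB locus share a genotype with probability
  # (1/4)^2 + (1/2)^2 + (1/4)^2 = 3/8; across L independent such loci the
  # collision probability is (3/8)^L
  L <- 6
  parents <- make_geno(matrix(1L, 2, L), ids = c("m", "f"))
  design <- mating_design(data.frame(cross_id = "c1", mother_id = "m",
                                     father_id = "f"))
  n <- 600
  sim <- simulate_progeny_dataset(parents, design, n, seed = 16)
  fps <- build_fingerprints(sim$genotypes)
  dup <- find_duplicate_fingerprints(fps, min_overlap = L)
  n_pairs <- n * (n - 1) / 2
  p_coll <- (3 / 8)^L
  expected <- n_pairs * p_coll
  # observed collisions within 4 sd of the enumeration-based expectation
  expect_lt(abs(nrow(dup) - expected), 4 * sqrt(expected) + 1)
})

test_that("replicate concordance averages agreement over shared calls", {
  expect_equal(replicate_concordance(strrep("A", 36), strrep("A", 36)), 1)
  one_off <- paste0("H", strrep("A", 35))
  expect_equal(replicate_concordance(strrep("A", 36), one_off), 35 / 36)
  with_hole <- paste0("?", strrep("A", 35))
  expect_equal(replicate_concordance(one_off, with_hole), 1)
})

test_that("fingerprint databases round-trip as plain TSV", {
  db <- fingerprint_db(c("l1", "l2"), c("cryobank_tissue", "field_tree"),
                       c("AHB?", "BBAA"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprint_db(db, path)
  expect_identical(read_fingerprint_db(path), db)
})

test_that("cell-line diagnosis attributes errors to the production stage", {
  fp <- strrep("A", 20)
  fp_alt <- strrep("B", 20)
  # identical members, all illegitimate, wrong father: breeding stage
  rec <- data.frame(member_id = c("t1", "t2", "cr"),
                    role = c("field_tree", "field_tree", "cryobank_tissue"),
                    legitimate = FALSE,
                    fingerprint = fp,
                    parent_error_class = "wrong_father")
  d <- diagnose_cell_line(rec)
  expect_identical(d$classification, "breeding_stage_error")
  expect_identical(d$detail, "pollen_contamination")
  expect_true(d$identical)

  # legitimate cryobank tissue, one stray tree: production stage
  rec2 <- data.frame(member_id = c("cr", "t1", "t2"),
                     role = c("cryobank_tissue", "field_tree", "field_tree"),
                     legitimate = c(TRUE, TRUE, FALSE),
                     fingerprint = c(fp, fp, fp_alt))
  expect_identical(diagnose_cell_line(rec2)$classification,
                   "production_stage_error")

  # legitimate trees, wrong tissue in the cryobank
  rec3 <- data.frame(member_id = c("cr", "t1"),
                     role = c("cryobank_tissue", "field_tree"),
                     legitimate = c(FALSE, TRUE),
                     fingerprint = c(fp_alt, fp))
  expect_identical(diagnose_cell_line(rec3)$classification,
                   "cryobank_error")

  # clean line
  rec4 <- data.frame(member_id = c("cr", "t1"),
                     role = c("cryobank_tissue", "field_tree"),
                     legitimate = TRUE, fingerprint = fp)
  expect_identical(diagnose_cell_line(rec4)$classification, "clean")

  # no cryobank member: limited classification, with a warning
  rec5 <- data.frame(member_id = c("t1", "t2"),
                     role = "field_tree", legitimate = FALSE,
                     fingerprint = fp)
  expect_warning(d5 <- diagnose_cell_line(rec5), "cryobank")
  expect_identical(d5$classification, "breeding_stage_error")
})
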