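# Multilocus genotype fingerprints for clonal identity monitoring.
#
# A fingerprint is the concatenation of all single-locus genotypes in
# fixed panel order, one symbol per locus: A (homozygous reference),
# H (heterozygous), B (homozygous alternate), ? (missing). Constant-width
# strings make fingerprint databases trivially diffable plain text.

FP_SYMBOLS <- c("A", "H", "B")

#' Build a fingerprint from a genotype vector
#'
#' @param g panel-ordered genotype vector (codes 0/1/2/NA).
#' @return character scalar; missing genotypes become `?`.
#' @export
build_fingerprint <- function(g) {
  sym <- rep("?", length(g))
  ok <- !is.na(g)
  sym[ok] <- FP_SYMBOLS[g[ok] + 1L]
  paste(sym, collapse = "")
}

#' Build fingerprints for every row of a genotype matrix
#'
#' @param m genotype matrix.
#' @return named character vector of fingerprints.
#' @export
build_fingerprints <- function(m) {
  validate_genotypes(m)
  out <- vapply(seq_len(nrow(m)), function(i) build_fingerprint(m[i, ]),
                character(1))
  names(out) <- rownames(m)
  out
}

fp_to_codes <- function(fp) {
  s <- strsplit(fp, "", fixed = TRUE)[[1L]]
  match(s, FP_SYMBOLS) - 1L  # '?' -> NA
}

#' Count missing symbols in a fingerprint
#'
#' @param fp fingerprint string(s).
#' @return integer count(s) of `?` symbols.
#' @export
fingerprint_missing <- function(fp) {
  vapply(fp, function(x) sum(strsplit(x, "", fixed = TRUE)[[1L]] == "?"),
         integer(1), USE.NAMES = FALSE)
}

compare_fingerprints <- function(a, b) {
  ga <- fp_to_codes(a); gb <- fp_to_codes(b)
  if (length(ga) != length(gb))
    stop("fingerprints compare only over a shared panel")
  both <- !is.na(ga) & !is.na(gb)
  c(mismatches = sum(ga[both] != gb[both]), overlap = sum(both))
}

#' Match a query fingerprint against a database
#'
#' Compares the query with every database entry over the loci non-missing
#' in both, and returns the entries with at most `max_mismatch`
#' disagreements and at least `min_overlap` jointly observed loci, ranked
#' by (mismatches ascending, overlap descending). Defaults mirror the
#' usual 15% missingness tolerance: `min_overlap = ceiling(0.85 * panel
#' size)` and a single tolerated mismatch. When no entry reaches
#' `min_overlap` the result is empty with attribute
#' `insufficient_data = TRUE`.
#'
#' @param query fingerprint string.
#' @param db data frame with columns `line_id` and `fingerprint` (see
#'   [fingerprint_db()]).
#' @param max_mismatch maximum tolerated disagreements.
#' @param min_overlap minimum jointly non-missing loci.
#' @return data frame `line_id`, `mismatches`, `overlap`, best match first.
#' @export
match_fingerprint <- function(query, db, max_mismatch = 1,
                              min_overlap = ceiling(0.85 * nchar(query))) {
  cmp <- t(vapply(db$fingerprint, compare_fingerprints, numeric(2),
                  a = query))
  res <- data.frame(line_id = db$line_id,
                    mismatches = cmp[, "mismatches"],
                    overlap = cmp[, "overlap"],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(res) && all(res$overlap < min_overlap)) {
    out <- res[0, ]
    attr(out, "insufficient_data") <- TRUE
    return(out)
  }
  res <- res[res$mismatches <= max_mismatch & res$overlap >= min_overlap, ,
             drop = FALSE]
  res <- res[order(res$mismatches, -res$overlap, res$line_id), ]
  rownames(res) <- NULL
  res
}

#' Find pairs of indistinguishable fingerprints
#'
#' Reports every pair of fingerprints with zero mismatches over their
#' mutually non-missing loci and overlap at least `min_overlap`. With
#' missing data, identity is not transitive, so pairwise links are
#' reported as such and never closed into larger groups.
#'
#' @param fps named character vector of fingerprints.
#' @param min_overlap minimum jointly non-missing loci for a link.
#' @return data frame `id1`, `id2`, `overlap`, one row per identical pair.
#' @export
find_duplicate_fingerprints <- function(fps,
                                        min_overlap =
                                          ceiling(0.85 * nchar(fps[[1L]]))) {
  ids <- names(fps)
  if (is.null(ids)) ids <- as.character(seq_along(fps))
  codes <- lapply(fps, fp_to_codes)
  n <- length(fps)
  out <- list()
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq((i + 1L), n)) {
      both <- !is.na(codes[[i]]) & !is.na(codes[[j]])
      ov <- sum(both)
      if (ov >= min_overlap && all(codes[[i]][both] == codes[[j]][both]))
        out[[length(out) + 1L]] <- data.frame(
          id1 = ids[i], id2 = ids[j], overlap = ov,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(id1 = character(0), id2 = character(0),
                      overlap = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Concordance between replicate fingerprints
#'
#' Fraction of genotype calls agreeing between two replicate assays of the
#' same sample, computed over the mutually non-missing loci (the usual
#' reproducibility-rate statistic for a genotyping assay).
#'
#' @param fp_a,fp_b replicate fingerprint strings.
#' @return agreement fraction in \[0, 1\] (NaN when no locus overlaps).
#' @export
replicate_concordance <- function(fp_a, fp_b) {
  cmp <- compare_fingerprints(fp_a, fp_b)
  1 - cmp[["mismatches"]] / cmp[["overlap"]]
}

#' Create, read and write a fingerprint database
#'
#' The database is a plain append-only TSV with columns `line_id`, `role`
#' (`parent`, `progeny`, `cryobank_tissue` or `field_tree`) and
#' `fingerprint`, easy to inspect and modify by hand.
#'
#' @param line_id,role,fingerprint column vectors.
#' @return data frame database.
#' @export
fingerprint_db <- function(line_id, role, fingerprint) {
  stopifnot(length(unique(nchar(fingerprint))) <= 1L)
  data.frame(line_id = as.character(line_id), role = as.character(role),
             fingerprint = as.character(fingerprint),
             stringsAsFactors = FALSE)
}

#' @rdname fingerprint_db
#' @param path TSV path.
#' @export
read_fingerprint_db <- function(path) {
  db <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  fingerprint_db(db$line_id, db$role, db$fingerprint)
}

#' @rdname fingerprint_db
#' @param db database data frame.
#' @export
write_fingerprint_db <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Diagnose the production stage at which a cell line's error occurred
#'
#' Combines, for all sampled members of one embryogenic cell line
#' (cryobank tissue and field trees), their fingerprints and their
#' legitimacy against the line's putative cross, and classifies the line:
#' \describe{
#'   \item{`clean`}{all members legitimate and mutually identical.}
#'   \item{`breeding_stage_error`}{all members identical but illegitimate —
#'     the error predates multiplication (wrong pollen or mislabelled
#'     parent); `detail` carries the parent-error class when supplied.}
#'   \item{`production_stage_error`}{cryobank tissue legitimate but at
#'     least one field tree illegitimate or fingerprint-mismatched — the
#'     mix-up happened in the laboratory, cutting production or planting.}
#'   \item{`cryobank_error`}{field trees legitimate but the cryobank
#'     tissue is not — misidentified tissue in the cryobank.}
#' }
#' A record without a cryobank member can only distinguish breeding-stage
#' from downstream errors and triggers a warning.
#'
#' @param members data frame with one row per sampled tissue: `member_id`,
#'   `role` (`cryobank_tissue` or `field_tree`), `legitimate` (logical:
#'   assigned to the putative cross), `fingerprint`, and optionally
#'   `parent_error_class`.
#' @param min_overlap minimum jointly non-missing loci for the identity
#'   checks.
#' @return list with `classification`, `detail`, `identical` (logical: all
#'   members mutually indistinguishable).
#' @export
diagnose_cell_line <- function(members,
                               min_overlap =
                                 ceiling(0.85 * nchar(members$fingerprint[1L]))) {
  stopifnot(nrow(members) >= 1L,
            all(c("member_id", "role", "legitimate", "fingerprint") %in%
                  names(members)))
  pairs_identical <- TRUE
  n <- nrow(members)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      cmp <- compare_fingerprints(members$fingerprint[i],
                                  members$fingerprint[j])
      if (cmp[["overlap"]] < min_overlap || cmp[["mismatches"]] > 0) {
        pairs_identical <- FALSE
      }
    }
  }
  cryo <- members$role == "cryobank_tissue"
  field <- members$role == "field_tree"
  detail <- NA_character_
  if (!any(cryo)) {
    warning("no cryobank member: classification limited to breeding vs field stage")
    if (all(!members$legitimate) && pairs_identical) {
      cls <- "breeding_stage_error"
    } else if (all(members$legitimate) && pairs_identical) {
      cls <- "clean"
    } else {
      cls <- "production_stage_error"
    }
  } else if (all(members$legitimate) && pairs_identical) {
    cls <- "clean"
  } else if (all(!members$legitimate) && pairs_identical) {
    cls <- "breeding_stage_error"
  } else if (all(members$legitimate[cryo]) &&
             (any(!members$legitimate[field]) || !pairs_identical)) {
    cls <- "production_stage_error"
  } else if (any(!members$legitimate[cryo]) &&
             (!any(field) || all(members$legitimate[field]))) {
    cls <- "cryobank_error"
  } else {
    # mixed illegitimacy with discordant fingerprints: the earliest
    # demonstrable error is at the breeding stage
    cls <- "breeding_stage_error"
  }
  if (cls == "breeding_stage_error" &&
      "parent_error_class" %in% names(members)) {
    pec <- members$parent_error_class[!members$legitimate]
    pec <- pec[!is.na(pec)]
    if (length(pec)) {
      top <- names(sort(table(pec), decreasing = TRUE))[1L]
      detail <- switch(top,
                       wrong_father = "pollen_contamination",
                       wrong_mother = "parental_misidentification",
                       wrong_both = "parental_misidentification",
                       top)
    }
  }
  list(classification = cls, detail = detail, identical = pairs_identical)
}
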