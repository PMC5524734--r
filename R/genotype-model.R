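# Core genotype data model and file I/O.
#
# Genotype matrices are plain integer matrices, individuals in rows and loci
# in columns, coded as the count of the alternate (B) allele: 0 = AA,
# 1 = AB, 2 = BB, NA = missing. Row and column names carry the individual
# and locus identifiers and must be unique.

GENO_TOKENS <- c(AA = 0L, AB = 1L, BA = 1L, BB = 2L)

#' Validate a genotype matrix
#'
#' Checks that `m` is an integer (or integer-valued) matrix with codes in
#' \{0, 1, 2, NA\} and unique, non-empty row and column names.
#'
#' @param m matrix to validate.
#' @return `m`, invisibly, coerced to integer storage.
#' @export
validate_genotypes <- function(m) {
  if (!is.matrix(m)) stop("genotypes must be a matrix (individuals x loci)")
  if ((nrow(m) > 0L && is.null(rownames(m))) ||
      (ncol(m) > 0L && is.null(colnames(m))))
    stop("genotype matrix must have individual ids (rownames) and locus ids (colnames)")
  if (anyDuplicated(rownames(m)))
    stop("duplicated individual id: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicated locus id: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  v <- m[!is.na(m)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    stop("genotype codes must be 0 (AA), 1 (AB), 2 (BB) or NA")
  storage.mode(m) <- "integer"
  invisible(m)
}

#' Read a genotype table
#'
#' Parses the tab-separated genotype dialect: a header row of locus ids, one
#' row per individual, first column the individual id, genotype tokens
#' `AA`, `AB` (or `BA`; allele order within a heterozygote carries no
#' meaning), `BB`, and a missing token (default `NA`). Any other token is an
#' error, never silently treated as missing.
#'
#' @param path path to a TSV file.
#' @param missing_token token representing a missing genotype.
#' @return integer genotype matrix (see [validate_genotypes()]).
#' @export
read_genotype_table <- function(path, missing_token = "NA") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("no individuals in '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  locus_ids <- header[-1L]
  if (length(locus_ids) == 0L) stop("no loci in '", path, "'")
  if (anyDuplicated(locus_ids))
    stop("duplicated locus id: ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "))
  body <- fields[-1L]
  bad <- which(lengths(body) != length(header))
  if (length(bad))
    stop("ragged row ", bad[1L] + 1L, ": expected ", length(header),
         " fields, found ", length(body[[bad[1L]]]))
  ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicated individual id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tok <- matrix(unlist(lapply(body, `[`, -1L)),
                nrow = length(ids), ncol = length(locus_ids), byrow = TRUE)
  m <- decode_genotype_tokens(tok, missing_token)
  dimnames(m) <- list(ids, locus_ids)
  validate_genotypes(m)
  m
}

decode_genotype_tokens <- function(tok, missing_token = "NA") {
  g <- array(NA_integer_, dim = dim(tok))
  is_missing <- tok == missing_token
  known <- tok %in% names(GENO_TOKENS)
  unknown <- !is_missing & !known
  if (any(unknown))
    stop("unknown genotype token: ",
         paste(unique(tok[unknown]), collapse = ", "))
  g[known] <- GENO_TOKENS[tok[known]]
  g
}

encode_genotype_tokens <- function(m, missing_token = "NA") {
  tok <- matrix(missing_token, nrow = nrow(m), ncol = ncol(m))
  ok <- !is.na(m)
  tok[ok] <- c("AA", "AB", "BB")[m[ok] + 1L]
  tok
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]: writing then reading returns an
#' identical matrix.
#'
#' @param m genotype matrix.
#' @param path output path.
#' @param missing_token token written for missing genotypes.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(m, path, missing_token = "NA") {
  validate_genotypes(m)
  tok <- encode_genotype_tokens(m, missing_token)
  lines <- c(
    paste(c("individual_id", colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)),
           function(i) paste(c(rownames(m)[i], tok[i, ]), collapse = "\t"),
           character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Construct and validate a mating design
#'
#' A mating design lists the controlled crosses of a closed breeding
#' program: one row per cross with a unique `cross_id` and the ids of the
#' two parents. A parent may appear in several crosses (shared parents are
#' the norm when, say, 68 crosses are made among 73 elite trees), but a
#' cross may not be selfed.
#'
#' @param crosses data frame with columns `cross_id`, `mother_id`,
#'   `father_id`.
#' @param parent_ids optional character vector; when given, every parent in
#'   the design must be present in it.
#' @return the validated design (a `data.frame`).
#' @export
mating_design <- function(crosses, parent_ids = NULL) {
  need <- c("cross_id", "mother_id", "father_id")
  if (!all(need %in% names(crosses)))
    stop("mating design needs columns: ", paste(need, collapse = ", "))
  crosses <- as.data.frame(crosses)[need]
  for (col in need) crosses[[col]] <- as.character(crosses[[col]])
  if (anyDuplicated(crosses$cross_id))
    stop("duplicated cross_id: ",
         paste(unique(crosses$cross_id[duplicated(crosses$cross_id)]),
               collapse = ", "))
  selfed <- crosses$mother_id == crosses$father_id
  if (any(selfed))
    stop("mother and father identical in cross: ",
         paste(crosses$cross_id[selfed], collapse = ", "))
  if (!is.null(parent_ids)) {
    dangling <- setdiff(c(crosses$mother_id, crosses$father_id), parent_ids)
    if (length(dangling))
      stop("parent id not found in parent panel: ",
           paste(dangling, collapse = ", "))
  }
  crosses
}

#' Read a mating design
#'
#' Reads a 3-column TSV with header `cross_id`, `mother_id`, `father_id`
#' and validates it with [mating_design()].
#'
#' @inheritParams read_genotype_table
#' @param parent_ids optional parent panel ids to validate against.
#' @return validated design data frame.
#' @export
read_mating_design <- function(path, parent_ids = NULL) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  mating_design(df, parent_ids = parent_ids)
}

#' Write a mating design
#'
#' @param design validated mating design.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mating_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a SNP panel description
#'
#' Per-locus metadata used when assembling a genotyping array: the gene the
#' SNP resides in (so panels can be constrained to one SNP per gene, which
#' minimizes linkage between markers), whether an assay can be designed for
#' it on the target platform, and the platform quality score (e.g. an
#' Illumina GC score) in \[0, 1\].
#'
#' @param locus_id unique locus identifiers.
#' @param gene_id optional gene identifiers (NA when unknown).
#' @param assayable logical; can a probe/assay be designed for this SNP.
#' @param quality_score optional per-locus genotyping quality in \[0, 1\].
#' @return a `data.frame` with one row per locus.
#' @export
snp_panel <- function(locus_id, gene_id = NA_character_, assayable = TRUE,
                      quality_score = NA_real_) {
  locus_id <- as.character(locus_id)
  if (anyDuplicated(locus_id))
    stop("duplicated locus id: ",
         paste(unique(locus_id[duplicated(locus_id)]), collapse = ", "))
  qs <- rep_len(as.numeric(quality_score), length(locus_id))
  if (any(!is.na(qs) & (qs < 0 | qs > 1)))
    stop("quality_score must lie in [0, 1]")
  data.frame(
    locus_id = locus_id,
    gene_id = rep_len(as.character(gene_id), length(locus_id)),
    assayable = rep_len(as.logical(assayable), length(locus_id)),
    quality_score = qs,
    stringsAsFactors = FALSE
  )
}

#' Drop individuals with excessive missing data
#'
#' Removes individuals whose fraction of missing genotypes is strictly
#' greater than `max_missing_fraction` (the conventional "more than 15%"
#' rule keeps an individual sitting exactly on the boundary). Row order of
#' the survivors is preserved.
#'
#' @param m genotype matrix.
#' @param max_missing_fraction tolerated missing fraction in \[0, 1\].
#' @return the filtered genotype matrix (possibly with zero rows).
#' @export
filter_individuals_by_missingness <- function(m, max_missing_fraction = 0.15) {
  validate_genotypes(m)
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  frac <- rowMeans(is.na(m))
  m[frac <= max_missing_fraction, , drop = FALSE]
}

#' Prefilter candidate loci on parental completeness and assay quality
#'
#' Retains the loci that pass the two standard candidate-screening rules for
#' parentage panels: (1) no missing genotype for any parent, and (2) a
#' platform quality score greater than or equal to `min_quality` (default
#' 0.60). Loci with no recorded quality score are not screened on quality.
#'
#' @param parents parent genotype matrix.
#' @param panel SNP panel ([snp_panel()]); its loci must all be columns of
#'   `parents`.
#' @param min_quality minimum acceptable quality score.
#' @return the filtered panel.
#' @export
prefilter_panel <- function(parents, panel, min_quality = 0.60) {
  validate_genotypes(parents)
  absent <- setdiff(panel$locus_id, colnames(parents))
  if (length(absent))
    stop("panel locus not in parent matrix: ", paste(absent, collapse = ", "))
  complete <- colSums(is.na(parents[, panel$locus_id, drop = FALSE])) == 0L
  quality_ok <- is.na(panel$quality_score) | panel$quality_score >= min_quality
  panel[complete & quality_ok, , drop = FALSE]
}

#' Import biallelic genotypes from a VCF file
#'
#' Maps diploid GT fields to the internal codes (0/0 to 0, 0/1 or 1/0 to 1,
#' 1/1 to 2, missing to NA). Multi-allelic records are rejected: the
#' parentage machinery is defined only for biallelic SNPs. Requires the
#' `vcfR` package.
#'
#' @param path path to a VCF file.
#' @return genotype matrix, individuals in rows.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package 'vcfR' is required for VCF import")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record(s) in VCF: only biallelic SNPs are supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- vcfR::getID(v)
  if (any(is.na(ids)))
    ids[is.na(ids)] <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))[is.na(ids)]
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x %in% "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% "1/1"] <- 2L
    bad <- !is.na(x) & !(x %in% c("0/0", "0/1", "1/0", "1/1", "./."))
    if (any(bad)) stop("unsupported GT value: ", paste(unique(x[bad]), collapse = ", "))
    out
  }
  m <- apply(gt, 2L, code)
  m <- t(matrix(m, nrow = nrow(gt), dimnames = list(ids, colnames(gt))))
  validate_genotypes(m)
  m
}
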