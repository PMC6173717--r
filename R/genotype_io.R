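# Reading, writing and filtering of genotype matrices, tag matrices and
# sample sheets.
#
# Genotype matrices are integer matrices (loci x samples) with values
# 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
# NA = missing.  Two on-disk dialects are supported: VCF v4.2 (GT field,
# biallelic SNPs only) and a TSV dialect (rows = loci, columns = samples,
# '#'-prefixed header, NA for missing).  All readers tolerate gzip.

#' Locus-filtering thresholds
#'
#' Defaults follow the standard RADseq population-filtering recipe: a locus
#' is retained only if genotyped in at least 75% of males *and* 75% of
#' females, has pooled minor-allele frequency of at least 0.05, and has
#' observed heterozygosity of at most 0.75 (the heterozygosity ceiling
#' removes over-merged paralogous stacks, which look like excessively
#' heterozygous loci).
#'
#' @param min_presence_per_sex Minimum genotyping call rate within each sex.
#' @param min_maf Minimum minor-allele frequency over non-missing calls,
#'   sexes pooled.
#' @param max_obs_het Maximum fraction of non-missing calls that are
#'   heterozygous.
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_presence_per_sex = 0.75,
                          min_maf = 0.05,
                          max_obs_het = 0.75) {
  .check_frac(min_presence_per_sex, "min_presence_per_sex")
  .check_frac(min_maf, "min_maf")
  .check_frac(max_obs_het, "max_obs_het")
  structure(list(min_presence_per_sex = min_presence_per_sex,
                 min_maf = min_maf, max_obs_het = max_obs_het),
            class = "filter_params")
}

#' Validate a genotype matrix
#' @noRd
.check_gm <- function(gm) {
  .assert(is.matrix(gm), "genotypes must be a matrix (loci x samples)")
  .assert(!is.null(rownames(gm)) && !anyDuplicated(rownames(gm)),
          "locus identifiers (rownames) must be present and unique")
  .assert(!is.null(colnames(gm)) && !anyDuplicated(colnames(gm)),
          "sample identifiers (colnames) must be present and unique")
  vals <- gm[!is.na(gm)]
  .assert(all(vals %in% 0:2), "genotype calls must be 0, 1, 2 or NA")
  invisible(gm)
}

#' Match a sample sheet against a genotype or tag matrix
#' @noRd
.check_sheet <- function(sheet, sample_ids = NULL) {
  .assert(is.data.frame(sheet) && all(c("sample_id", "sex") %in% names(sheet)),
          "sample sheet must have columns sample_id and sex")
  .assert(!anyDuplicated(sheet$sample_id), "duplicate sample_id in sheet")
  bad <- setdiff(unique(sheet$sex), c("M", "F"))
  .assert(length(bad) == 0, "unknown sex token(s): %s",
          paste(bad, collapse = ", "))
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, sheet$sample_id)
    .assert(length(missing) == 0,
            "sample(s) absent from sample sheet: %s",
            paste(missing, collapse = ", "))
  }
  invisible(sheet)
}

# -- TSV dialect -------------------------------------------------------------

#' Write a genotype (or tag) matrix in the TSV dialect
#'
#' @param gm Integer matrix with locus rownames and sample colnames.
#' @param path Output path (`.gz` for compressed output).
#' @export
write_genotypes_tsv <- function(gm, path) {
  con <- .open_maybe_gz(path, "wt")
  on.exit(close(con))
  writeLines(paste(c("#locus_id", colnames(gm)), collapse = "\t"), con)
  body <- cbind(rownames(gm),
                matrix(ifelse(is.na(gm), "NA", as.character(gm)), nrow = nrow(gm)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @noRd
.read_matrix_tsv <- function(path) {
  con <- .open_maybe_gz(path)
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  .assert(startsWith(header, "#"), "expected a '#'-prefixed header in %s", path)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  dat <- read.table(con, sep = "\t", header = FALSE, col.names = cols,
                    na.strings = "NA", check.names = FALSE,
                    colClasses = c("character", rep("integer", length(cols) - 1L)))
  m <- as.matrix(dat[, -1L, drop = FALSE])
  rownames(m) <- dat[[1L]]
  .assert(!anyDuplicated(rownames(m)), "duplicate locus identifiers in %s", path)
  m
}

#' Read a genotype matrix
#'
#' @param path Input path (plain or gzipped).
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return Integer matrix, loci x samples, values 0/1/2/NA.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  gm <- if (format == "vcf") .read_genotypes_vcf(path) else .read_matrix_tsv(path)
  .check_gm(gm)
  gm
}

#' Read a tag presence/absence matrix (TSV dialect, 0/1 cells)
#' @param path Input path.
#' @export
read_tag_presence <- function(path) {
  m <- .read_matrix_tsv(path)
  .assert(all(m %in% 0:1, na.rm = TRUE), "tag matrix cells must be 0 or 1")
  m[is.na(m)] <- 0L
  m
}

#' Write a tag presence/absence matrix
#' @param tags 0/1 matrix.
#' @param path Output path.
#' @export
write_tag_presence <- function(tags, path) write_genotypes_tsv(tags, path)

#' Read or write a sample sheet (TSV: sample_id, sex, optional extras)
#'
#' @param path File path.
#' @return Data frame with at least `sample_id` and `sex` columns.
#' @export
read_sample_sheet <- function(path) {
  con <- .open_maybe_gz(path)
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  cols <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  .assert(all(c("sample_id", "sex") %in% cols),
          "sample sheet header must contain sample_id and sex")
  sheet <- read.table(con, sep = "\t", header = FALSE, col.names = cols,
                      na.strings = "NA", stringsAsFactors = FALSE)
  .check_sheet(sheet)
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet Sample-sheet data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  .check_sheet(sheet)
  con <- .open_maybe_gz(path, "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(sheet), collapse = "\t")), con)
  write.table(sheet, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# -- VCF ---------------------------------------------------------------------

#' Write a genotype matrix as a minimal VCF v4.2
#'
#' Each locus becomes one biallelic SNP record (REF "A", ALT "T") with a
#' GT-only FORMAT.
#'
#' @param gm Genotype matrix.
#' @param path Output path.
#' @export
write_genotypes_vcf <- function(gm, path) {
  .check_gm(gm)
  con <- .open_maybe_gz(path, "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=sexturn",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(gm)), collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix(gt_code[as.character(gm)], nrow = nrow(gm))
  gt[is.na(gt)] <- "./."
  lines <- paste(
    "un", seq_len(nrow(gm)), rownames(gm), "A", "T", ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' @noRd
.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  multi <- grepl(",", v@fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    message(sprintf("rejected %d multiallelic VCF record(s)", sum(multi)))
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- v@fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste(v@fix[no_id, "CHROM"], v@fix[no_id, "POS"], sep = "_")
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  m <- apply(gt, 2, code)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(NULL, colnames(gt)))
  rownames(m) <- ids
  m
}

# -- Locus filters -----------------------------------------------------------

#' Apply the standard locus filters
#'
#' Retains a locus only if (i) its genotyping call rate is at least
#' `min_presence_per_sex` within males *and* within females, (ii) its
#' minor-allele frequency over non-missing calls (sexes pooled) is at least
#' `min_maf`, and (iii) its observed heterozygosity (fraction of non-missing
#' calls that are heterozygous) is at most `max_obs_het`.  Per-rule removal
#' counts are attached as the `"filter_log"` attribute and reported via
#' `message()`.
#'
#' Note the documented caveat of the heterozygosity ceiling: if the
#' heterogametic sex makes up more than `max_obs_het` of the samples, fully
#' sex-linked loci (heterozygous in every heterogametic individual) can
#' themselves exceed the ceiling and be removed.
#'
#' @param gm Genotype matrix (0/1/2/NA).
#' @param sheet Sample sheet covering every sample in `gm`.
#' @param params A [filter_params()] object.
#' @return The filtered genotype matrix (possibly zero rows, with a
#'   warning), with attribute `filter_log`.
#' @export
filter_loci <- function(gm, sheet, params = filter_params()) {
  .check_gm(gm)
  .check_sheet(sheet, colnames(gm))
  sex <- sheet$sex[match(colnames(gm), sheet$sample_id)]
  .assert(all(c("M", "F") %in% sex), "both sexes must be present before filtering")

  obs <- !is.na(gm)
  pres_m <- rowMeans(obs[, sex == "M", drop = FALSE])
  pres_f <- rowMeans(obs[, sex == "F", drop = FALSE])
  n_obs <- rowSums(obs)
  alt <- rowSums(gm, na.rm = TRUE)           # alternate-allele count
  freq_alt <- alt / (2 * n_obs)
  maf <- pmin(freq_alt, 1 - freq_alt)
  het <- rowSums(gm == 1L, na.rm = TRUE) / n_obs

  ok_pres <- pres_m >= params$min_presence_per_sex &
    pres_f >= params$min_presence_per_sex
  ok_maf <- !is.na(maf) & maf >= params$min_maf
  ok_het <- !is.na(het) & het <= params$max_obs_het
  keep <- ok_pres & ok_maf & ok_het

  log <- c(input = nrow(gm),
           fail_presence = sum(!ok_pres),
           fail_maf = sum(!ok_maf),
           fail_het = sum(!ok_het),
           retained = sum(keep))
  message(sprintf(
    "filter_loci: %d/%d loci retained (presence fails %d, MAF fails %d, het fails %d)",
    log[["retained"]], log[["input"]], log[["fail_presence"]],
    log[["fail_maf"]], log[["fail_het"]]))
  if (log[["retained"]] == 0L) warning("no loci passed the filters")
  out <- gm[keep, , drop = FALSE]
  attr(out, "filter_log") <- log
  out
}
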