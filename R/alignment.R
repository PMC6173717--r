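# BLAST outfmt-6 style alignment hits: reading, best-hit filtering, and the
# scaffold-to-chromosome map used for chromosome assignment.

.OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Alignment-hit filtering thresholds
#'
#' A query's best hit is retained only if its e-value is strictly below
#' `max_evalue` and, when a second hit exists, the second-best e-value is at
#' least `min_next_hit_ratio_orders` orders of magnitude larger (i.e. worse)
#' than the best.  The ratio rule guards against the highly repetitive
#' content of anuran genomes producing near-tied multi-mappings.
#'
#' @param max_evalue Maximum (exclusive) e-value of the best hit.
#' @param min_next_hit_ratio_orders Required separation, in orders of
#'   magnitude, between best and second-best e-values.
#' @export
alignment_filter_params <- function(max_evalue = 1e-20,
                                    min_next_hit_ratio_orders = 5) {
  .assert(max_evalue > 0, "`max_evalue` must be positive")
  .assert(min_next_hit_ratio_orders >= 0, "`min_next_hit_ratio_orders` must be >= 0")
  structure(list(max_evalue = max_evalue,
                 min_next_hit_ratio_orders = min_next_hit_ratio_orders),
            class = "alignment_filter_params")
}

#' Read tabular alignment hits (BLAST outfmt 6, twelve columns)
#'
#' @param path Path to a tab-separated hits file (gzip tolerated).
#' @return Data frame with the standard twelve outfmt-6 columns; subject
#'   coordinates are 1-based inclusive as emitted by BLAST.
#' @export
read_alignment_hits <- function(path) {
  con <- .open_maybe_gz(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 12L)
  .assert(length(bad) == 0,
          "malformed alignment line %d in %s: expected 12 fields, found %d",
          bad[1], path, nf[bad[1]])
  m <- do.call(rbind, parts)
  hits <- data.frame(m, stringsAsFactors = FALSE)
  names(hits) <- .OUTFMT6_COLS
  num_cols <- c("pident", "evalue", "bitscore")
  int_cols <- c("length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send")
  for (cc in num_cols) hits[[cc]] <- as.numeric(hits[[cc]])
  for (cc in int_cols) hits[[cc]] <- as.integer(hits[[cc]])
  bad <- which(!is.finite(hits$evalue) | hits$evalue < 0)
  .assert(length(bad) == 0, "malformed e-value on alignment line %d in %s",
          bad[1], path)
  hits
}

#' Keep each query's best hit if it is unambiguous
#'
#' Applies the retention rule of [alignment_filter_params()] per query and
#' returns at most one row (the best hit) per query.
#'
#' @param hits Data frame of hits with at least `qseqid`, `sseqid` and
#'   `evalue` columns.
#' @param params An [alignment_filter_params()] object.
#' @return Data frame of retained best hits (possibly zero rows), with
#'   attribute `n_discarded_queries`.
#' @export
filter_alignment_hits <- function(hits, params = alignment_filter_params()) {
  .assert(all(c("qseqid", "sseqid", "evalue") %in% names(hits)),
          "`hits` must have qseqid, sseqid and evalue columns")
  if (nrow(hits) == 0L) {
    out <- hits
    attr(out, "n_discarded_queries") <- 0L
    return(out)
  }
  ord <- order(hits$qseqid, hits$evalue)
  h <- hits[ord, , drop = FALSE]
  first <- !duplicated(h$qseqid)
  best <- h[first, , drop = FALSE]
  # second-best e-value per query, NA when single-hit
  idx_first <- which(first)
  nxt <- ifelse(idx_first + 1L <= nrow(h) &
                  h$qseqid[pmin(idx_first + 1L, nrow(h))] == best$qseqid,
                h$evalue[pmin(idx_first + 1L, nrow(h))], NA_real_)
  sep_ok <- is.na(nxt) |
    (best$evalue == 0 & nxt > 0) |
    (best$evalue > 0 & nxt >= best$evalue * 10^params$min_next_hit_ratio_orders)
  keep <- best$evalue < params$max_evalue & sep_ok
  out <- best[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_discarded_queries") <- sum(!keep)
  out
}

#' Read a scaffold-to-chromosome map (two-column TSV)
#'
#' @param path TSV with columns scaffold and chromosome ('#'-prefixed header
#'   optional).
#' @return Data frame `scaffold`, `chromosome`.
#' @export
read_scaffold_map <- function(path) {
  con <- .open_maybe_gz(path)
  on.exit(close(con))
  dat <- read.table(con, sep = "\t", header = FALSE, comment.char = "#",
                    col.names = c("scaffold", "chromosome"),
                    stringsAsFactors = FALSE)
  .assert(!anyDuplicated(dat$scaffold), "duplicate scaffolds in %s", path)
  dat
}

#' Write alignment hits in outfmt-6 layout
#' @param hits Hits data frame.
#' @param path Output path.
#' @export
write_alignment_hits <- function(hits, path) {
  con <- .open_maybe_gz(path, "wt")
  on.exit(close(con))
  write.table(hits[, .OUTFMT6_COLS], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
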