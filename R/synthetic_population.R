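# Synthetic population genotypes with known sex-linkage structure.
#
# The generator emulates the data structure produced by RADseq genotyping of
# a wild population with phenotypically sexed individuals:
#   * y_snp loci        -- a fully penetrant Y- (or W-) specific SNP: the
#                          heterogametic sex is heterozygous (X allele + Y
#                          allele), the homogametic sex homozygous X/X.
#   * sex_limited loci  -- RADtags present only in the heterogametic sex
#                          (Y-specific restriction sites, X null alleles);
#                          these live in the tag presence/absence matrix.
#   * x_hemizygous loci -- loci hemizygous in the heterogametic sex (present
#                          on the X only, or carrying a paternal-X-specific
#                          allele): the homogametic sex is heterozygous, the
#                          heterogametic sex called homozygous.  On an XY
#                          simulation these produce the classic pseudo-ZW
#                          signal picked up by ZW-orientation screens.
#   * autosomal loci    -- Hardy-Weinberg draws at a sampled minor-allele
#                          frequency, independent of sex.
#
# Genotypes are coded 0/1/2 copies of the alternate allele, NA = missing;
# the Y-specific allele is always the alternate allele (allele 1).

#' Parameters for a synthetic population simulation
#'
#' Bundles and validates the data-generating assumptions for
#' [simulate_population()].
#'
#' Fractional locus counts are rounded down (floor), and any remainder of the
#' sex-linked fraction not claimed by the three sex-linked classes is
#' assigned back to the autosomal class, so class counts are deterministic.
#'
#' @param n_males,n_females Number of samples of each phenotypic sex (both
#'   must be at least 1; the screens are undefined with a single-sex sample
#'   set).
#' @param n_loci Total number of simulated loci (RADtags).
#' @param system Sex-determination system: `"XY"` (male heterogametic),
#'   `"ZW"` (female heterogametic) or `"NONE"` (no sex linkage; forces
#'   `prop_sexlinked = 0`).
#' @param prop_sexlinked Fraction of loci on the sex chromosome.
#' @param prop_y_snp,prop_sex_limited,prop_x_hemizygous Fractions of the
#'   sex-linked loci emitted as each class (see file header); they must sum
#'   to at most 1.
#' @param n_y_haplotypes Number of distinct Y (or W) lineages segregating
#'   among heterogametic samples.  With more than one, each `y_snp` locus
#'   carries an allele private to one haplotype, so no single Y-specific SNP
#'   is shared by all heterogametic individuals.
#' @param autosomal_maf_dist Function of `n` returning `n` autosomal
#'   minor-allele frequencies.  Default draws uniformly on \[0.05, 0.5\];
#'   the study data's real frequency spectrum is unknown, so this is a free
#'   simulation parameter, not an estimate.
#' @param error_rate Per-genotype miscall probability; a miscalled genotype
#'   is replaced by one of the two other genotype values with equal
#'   probability.  For tags, the probability of a spurious presence.
#' @param missing_rate Per-genotype missing probability (per-tag dropout
#'   probability for the tag matrix).
#' @param seed RNG seed recorded in the simulation metadata.
#'
#' @return An object of class `pop_sim_params` (a validated list).
#' @seealso [simulate_population()]
#' @export
pop_sim_params <- function(n_males, n_females, n_loci,
                           system = c("XY", "ZW", "NONE"),
                           prop_sexlinked = 0.05,
                           prop_y_snp = 0.6,
                           prop_sex_limited = 0.2,
                           prop_x_hemizygous = 0.2,
                           n_y_haplotypes = 1L,
                           autosomal_maf_dist = function(n) runif(n, 0.05, 0.5),
                           error_rate = 0,
                           missing_rate = 0,
                           seed = NULL) {
  system <- match.arg(system)
  .assert(n_males >= 1 && n_females >= 1,
          "both sexes must be represented: sex-linkage screens are undefined with zero %s",
          if (n_males < 1) "males" else "females")
  .assert(n_loci >= 1, "`n_loci` must be at least 1")
  for (nm in c("prop_sexlinked", "prop_y_snp", "prop_sex_limited",
               "prop_x_hemizygous", "error_rate", "missing_rate"))
    .check_frac(get(nm), nm)
  .assert(prop_y_snp + prop_sex_limited + prop_x_hemizygous <= 1 + 1e-12,
          "prop_y_snp + prop_sex_limited + prop_x_hemizygous must be <= 1")
  .assert(n_y_haplotypes >= 1, "`n_y_haplotypes` must be >= 1")
  .assert(is.function(autosomal_maf_dist),
          "`autosomal_maf_dist` must be a function of n")
  if (system == "NONE") prop_sexlinked <- 0
  structure(list(
    n_males = as.integer(n_males), n_females = as.integer(n_females),
    n_loci = as.integer(n_loci), system = system,
    prop_sexlinked = prop_sexlinked, prop_y_snp = prop_y_snp,
    prop_sex_limited = prop_sex_limited,
    prop_x_hemizygous = prop_x_hemizygous,
    n_y_haplotypes = as.integer(n_y_haplotypes),
    autosomal_maf_dist = autosomal_maf_dist,
    error_rate = error_rate, missing_rate = missing_rate, seed = seed
  ), class = "pop_sim_params")
}

#' Deterministic per-class locus counts for a parameter set
#' @noRd
.locus_class_counts <- function(p) {
  n_sl   <- floor(p$prop_sexlinked * p$n_loci)
  n_y    <- floor(p$prop_y_snp * n_sl)
  n_lim  <- floor(p$prop_sex_limited * n_sl)
  n_hemi <- floor(p$prop_x_hemizygous * n_sl)
  c(y_snp = n_y, sex_limited = n_lim, x_hemizygous = n_hemi,
    autosomal = p$n_loci - n_y - n_lim - n_hemi)
}

#' Simulate a sexed population of RADseq genotypes and tags
#'
#' Generates a diploid genotype matrix, a RADtag presence/absence matrix, a
#' sample sheet with phenotypic sex (and Y-haplotype index for heterogametic
#' samples), and truth labels for every locus.  See the class definitions at
#' the top of this file for what each locus class looks like before noise.
#'
#' Genotype and tag noise is applied after the clean construction: first
#' miscalls at `error_rate`, then missingness at `missing_rate`.
#'
#' @param params A [pop_sim_params()] object.
#' @return An object of class `pop_sim`: a list with elements
#'   * `genotypes`: integer matrix, loci x samples, values 0/1/2/NA.  Rows
#'     are SNP loci (the `sex_limited` class has no genotypes and appears
#'     only in `tags`).
#'   * `tags`: 0/1 matrix of RADtag presence, one row per locus (all
#'     classes).
#'   * `truth`: data frame `locus_id`, `class` partitioning all loci.
#'   * `sheet`: data frame `sample_id`, `sex` ("M"/"F"), `y_haplotype`
#'     (integer, NA for the homogametic sex).
#'   * `params`: the input parameters (seed included).
#' @examples
#' sim <- simulate_population(pop_sim_params(10, 10, 500, "XY", seed = 1))
#' table(sim$truth$class)
#' @export
simulate_population <- function(params) {
  .assert(inherits(params, "pop_sim_params"),
          "`params` must come from pop_sim_params()")
  p <- params
  .seed_if(p$seed)

  counts <- .locus_class_counts(p)
  classes <- rep(names(counts), counts)
  locus_ids <- sprintf("L%06d", seq_len(p$n_loci))
  truth <- data.frame(locus_id = locus_ids, class = classes,
                      stringsAsFactors = FALSE)

  samples <- c(sprintf("M%03d", seq_len(p$n_males)),
               sprintf("F%03d", seq_len(p$n_females)))
  sex <- rep(c("M", "F"), c(p$n_males, p$n_females))
  het_sex <- if (p$system == "ZW") "F" else "M"
  is_het <- sex == het_sex
  n_samp <- length(samples)

  # Y (or W) haplotype assignment: round-robin so a 12-male, 2-haplotype
  # design yields the 6 + 6 split used in the subsampling experiment.
  y_hap <- rep(NA_integer_, n_samp)
  if (p$system != "NONE")
    y_hap[is_het] <- rep_len(seq_len(p$n_y_haplotypes), sum(is_het))

  snp_classes <- classes[classes != "sex_limited"]
  snp_ids <- locus_ids[classes != "sex_limited"]
  geno <- matrix(NA_integer_, length(snp_ids), n_samp,
                 dimnames = list(snp_ids, samples))

  auto <- snp_classes == "autosomal"
  if (any(auto)) {
    maf <- p$autosomal_maf_dist(sum(auto))
    geno[auto, ] <- matrix(
      rbinom(sum(auto) * n_samp, 2L, rep(maf, n_samp)),
      nrow = sum(auto))
  }
  ysnp <- snp_classes == "y_snp"
  if (any(ysnp)) {
    # Each Y-specific SNP belongs to one Y haplotype; carriers are het.
    hap_of_locus <- rep_len(seq_len(p$n_y_haplotypes), sum(ysnp))
    carrier <- outer(hap_of_locus, y_hap, function(h, s) !is.na(s) & h == s)
    geno[ysnp, ] <- ifelse(carrier, 1L, 0L)
  }
  hemi <- snp_classes == "x_hemizygous"
  if (any(hemi)) {
    # Paternal-X-specific allele: homogametic sex het, heterogametic sex
    # hemizygous and called homozygous reference.
    geno[hemi, ] <- matrix(rep(ifelse(is_het, 0L, 1L), each = sum(hemi)),
                           nrow = sum(hemi))
  }

  tags <- matrix(1L, p$n_loci, n_samp, dimnames = list(locus_ids, samples))
  lim <- classes == "sex_limited"
  if (any(lim))
    tags[lim, ] <- matrix(rep(as.integer(is_het), each = sum(lim)),
                          nrow = sum(lim))

  if (p$error_rate > 0) {
    flip <- matrix(runif(length(geno)) < p$error_rate, nrow = nrow(geno)) &
      !is.na(geno)
    if (any(flip)) {
      shift <- sample(1:2, sum(flip), replace = TRUE)
      geno[flip] <- (geno[flip] + shift) %% 3L
    }
    spur <- matrix(runif(length(tags)) < p$error_rate, nrow = nrow(tags))
    tags[spur & tags == 0L] <- 1L
  }
  if (p$missing_rate > 0) {
    geno[matrix(runif(length(geno)) < p$missing_rate, nrow = nrow(geno))] <-
      NA_integer_
    drop <- matrix(runif(length(tags)) < p$missing_rate, nrow = nrow(tags))
    tags[drop & tags == 1L] <- 0L
  }

  sheet <- data.frame(sample_id = samples, sex = sex, y_haplotype = y_hap,
                      stringsAsFactors = FALSE)
  structure(list(genotypes = geno, tags = tags, truth = truth,
                 sheet = sheet, params = p),
            class = "pop_sim")
}

#' @export
print.pop_sim <- function(x, ...) {
  cat(sprintf("pop_sim: %d loci x %d samples (%s system)\n",
              x$params$n_loci, nrow(x$sheet), x$params$system))
  print(table(x$truth$class))
  invisible(x)
}

#' Catalogue of subsampling designs for the screening diagnostics
#'
#' The designs probe how sample size, sex skew and Y-haplotype structure
#' affect screen yield and validation: a balanced series from 19M/19F down
#' to 5M/5F, a male skew (18M/9F), a female skew (9M/18F), and a
#' two-haplotype design (6 males of each of two Y haplotypes plus 12
#' females).
#'
#' @return A named list of designs; each has `name`, `n_males`, `n_females`
#'   and optionally `male_haplotypes` (a vector of per-haplotype male
#'   counts).
#' @seealso [subsample_experiment()]
#' @export
scenario_catalog <- function() {
  designs <- list()
  for (n in 19:5) {
    d <- list(name = sprintf("balanced_%dM_%dF", n, n),
              n_males = n, n_females = n)
    designs[[d$name]] <- d
  }
  designs[["male_skew_18M_9F"]] <-
    list(name = "male_skew_18M_9F", n_males = 18L, n_females = 9L)
  designs[["female_skew_9M_18F"]] <-
    list(name = "female_skew_9M_18F", n_males = 9L, n_females = 18L)
  designs[["two_haplotypes_6M_6M_12F"]] <-
    list(name = "two_haplotypes_6M_6M_12F", n_males = 12L, n_females = 12L,
         male_haplotypes = c(6L, 6L))
  designs
}

#' Simulate tabular alignment hits with a known chromosome truth
#'
#' Builds a toy chromosome-assigned reference (13 chromosomes by default,
#' each split into several scaffolds), assigns every locus a true
#' chromosome (sex-linked classes all on `sexlinked_chrom`, autosomal loci
#' uniformly), and emits BLAST outfmt-6 style hits for an `align_rate`
#' fraction of loci.  A fraction `ambiguous_rate` of aligned loci receive a
#' strong second hit within the e-value-ratio window so that the best-hit
#' filter discards them, mimicking repetitive regions.
#'
#' @param locus_ids Character vector of locus identifiers (the catalogue).
#' @param truth Optional truth data frame from [simulate_population()]; loci
#'   whose class is not `autosomal` are placed on `sexlinked_chrom`.
#' @param sexlinked_chrom Chromosome carrying the sex-linked loci.
#' @param n_chromosomes,scaffolds_per_chrom Reference layout.
#' @param align_rate Fraction of loci that produce a retained-quality hit.
#' @param ambiguous_rate Fraction of aligned loci given a near-tied second
#'   hit.
#' @param seed RNG seed.
#' @return A list with `hits` (12-column outfmt-6 data frame),
#'   `scaffold_map` (data frame `scaffold`, `chromosome`) and `chrom_truth`
#'   (named character vector, NA for unaligned loci).
#' @export
simulate_alignment_hits <- function(locus_ids, truth = NULL,
                                    sexlinked_chrom = "Chr05",
                                    n_chromosomes = 13L,
                                    scaffolds_per_chrom = 5L,
                                    align_rate = 0.8,
                                    ambiguous_rate = 0.02,
                                    seed = NULL) {
  .seed_if(seed)
  chroms <- sprintf("Chr%02d", seq_len(n_chromosomes))
  .assert(sexlinked_chrom %in% chroms,
          "`sexlinked_chrom` must be one of %s", paste(chroms, collapse = ", "))
  scaffold_map <- data.frame(
    scaffold = sprintf("scaffold_%03d", seq_len(n_chromosomes * scaffolds_per_chrom)),
    chromosome = rep(chroms, each = scaffolds_per_chrom),
    stringsAsFactors = FALSE)

  n <- length(locus_ids)
  true_chrom <- sample(chroms, n, replace = TRUE)
  if (!is.null(truth)) {
    sl <- truth$locus_id[truth$class != "autosomal"]
    true_chrom[locus_ids %in% sl] <- sexlinked_chrom
  }
  names(true_chrom) <- locus_ids

  aligned <- runif(n) < align_rate
  idx <- which(aligned)
  pick_scaffold <- function(chrom) {
    cand <- scaffold_map$scaffold[scaffold_map$chromosome == chrom]
    cand[sample.int(length(cand), 1L)]
  }
  scafs <- vapply(true_chrom[idx], pick_scaffold, character(1))
  best_e <- 10^runif(length(idx), -40, -25)
  mk_hit <- function(q, s, e) {
    start <- sample.int(1e6, length(q), replace = TRUE)
    data.frame(qseqid = q, sseqid = s, pident = round(runif(length(q), 90, 100), 2),
               length = 92L, mismatch = sample(0:5, length(q), replace = TRUE),
               gapopen = 0L, qstart = 1L, qend = 92L,
               sstart = start, send = start + 91L,
               evalue = e, bitscore = round(180 - 3 * log10(e + 1e-300)),
               stringsAsFactors = FALSE)
  }
  hits <- mk_hit(locus_ids[idx], scafs, best_e)
  # weak secondary hits (pass the ratio filter) for a third of aligned loci
  sec <- which(runif(length(idx)) < 1 / 3)
  if (length(sec)) {
    other <- scaffold_map$scaffold[sample.int(nrow(scaffold_map), length(sec),
                                              replace = TRUE)]
    hits <- rbind(hits, mk_hit(locus_ids[idx][sec], other, best_e[sec] * 1e10))
  }
  # near-tied second hits -> filtered out as ambiguous
  amb <- which(runif(length(idx)) < ambiguous_rate)
  if (length(amb)) {
    other <- scaffold_map$scaffold[sample.int(nrow(scaffold_map), length(amb),
                                              replace = TRUE)]
    hits <- rbind(hits, mk_hit(locus_ids[idx][amb], other, best_e[amb] * 10))
    true_chrom[idx][amb] <- NA_character_
  }
  true_chrom[!aligned] <- NA_character_
  list(hits = hits, scaffold_map = scaffold_map, chrom_truth = true_chrom)
}
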