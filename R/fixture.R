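# Packaged data: the Ranidae sex-chromosome turnover history and tip-state
# matrix, and a synthetic per-chromosome gene-count table.

#' Load the packaged Ranidae turnover fixture
#'
#' The fixture encodes the sex-chromosome turnover history across 28 true
#' frog (Ranidae) species: 13 transition events — 8 interspecific
#' chromosome changes (two of them in the ambiguous root region, with
#' unknown chromosome identities), 3 intraspecific events (*R. japonica*,
#' *R. pipiens*, *P. porosus*) and 2 homologous XY-to-ZW transitions on
#' Chr08 in *G. rugosa* — together with per-tip state probabilities over
#' the five chromosomes observed as sex-linked (equal probabilities where
#' a species is polymorphic, uniform rows where the system is unknown) and
#' the per-chromosome count of species using each chromosome.
#'
#' File checksums are verified against the fixture metadata on every load.
#'
#' @return List with
#'   * `events`: a `turnover_history` data frame (13 rows),
#'   * `tip_states`: 28 x 5 probability matrix (species x chromosome),
#'   * `chromosome_usage`: named integer vector of species counts,
#'   * `species`: the 28 species names,
#'   * `tree`: `NULL` (the dated phylogeny is not part of the fixture),
#'   * `meta`: the fixture metadata (version, caveats).
#' @examples
#' fx <- load_fig1_fixture()
#' count_turnovers(fx$events)
#' @export
load_fig1_fixture <- function() {
  dir <- system.file("extdata", package = "sexturn", mustWork = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "ranidae_fixture_meta.json"),
                              simplifyVector = TRUE)
  for (f in names(meta$checksums)) {
    got <- unname(tools::md5sum(file.path(dir, f)))
    .assert(identical(got, meta$checksums[[f]]),
            "checksum mismatch for fixture file %s", f)
  }
  read_fixture_tsv <- function(f, ...) {
    con <- file(file.path(dir, f))
    on.exit(close(con))
    header <- readLines(con, n = 1L)
    cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
    read.table(file.path(dir, f), sep = "\t", skip = 1L, col.names = cols,
               stringsAsFactors = FALSE, ...)
  }
  events <- turnover_history(read_fixture_tsv("ranidae_turnover_events.tsv"))
  usage_df <- read_fixture_tsv("ranidae_chromosome_usage.tsv")
  usage <- setNames(as.integer(usage_df$n_species), usage_df$chromosome)
  ts_df <- read_fixture_tsv("ranidae_tip_states.tsv")
  tip_states <- as.matrix(ts_df[, -1L])
  rownames(tip_states) <- ts_df$species
  tip_states <- tip_state_matrix(tip_states, colnames(tip_states))
  list(events = events, tip_states = tip_states,
       chromosome_usage = usage, species = rownames(tip_states),
       tree = NULL, meta = meta)
}

#' Load the synthetic per-chromosome gene-count table
#'
#' A synthetic stand-in for a per-chromosome gene-count annotation of a
#' 13-chromosome frog genome (counts decrease with chromosome rank,
#' roughly size-proportional).  Used by examples and by the recruitment
#' null; it is not an annotation of any real genome.
#'
#' @return Named integer vector of gene counts, Chr01..Chr13.
#' @export
load_gene_counts_synthetic <- function() {
  path <- system.file("extdata", "gene_counts_synthetic.tsv",
                      package = "sexturn", mustWork = TRUE)
  dat <- read.table(path, sep = "\t", skip = 1L,
                    col.names = c("chromosome", "n_genes"),
                    stringsAsFactors = FALSE)
  setNames(as.integer(dat$n_genes), dat$chromosome)
}
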