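# End-to-end orchestration: simulate (or read) inputs, filter, screen,
# permutation-validate, and assign the sex chromosome, with every stage's
# outputs and seeds persisted to a run directory.

#' Run the marker-to-chromosome pipeline
#'
#' Executes, in order: simulate/ingest -> filter -> screen ->
#' permute-validate -> assign.  Inputs come either from a simulation block
#' or from file paths; all stage outputs are written as TSV under
#' `out_dir` and a JSON run log records the seeds and decisions.
#'
#' @param config A list (or path to a YAML file) with elements
#'   * `seed`: master seed; stage seeds are derived from it by fixed
#'     offsets,
#'   * `out_dir`: run directory (created),
#'   * either `simulate` (arguments to [pop_sim_params()], plus optional
#'     `alignment` arguments to [simulate_alignment_hits()]) or `inputs`
#'     (paths: `genotypes`, `tags`, `sample_sheet`, and optionally `hits`,
#'     `scaffold_map`),
#'   * optional parameter blocks `filter`, `screens`, `permutation`,
#'     `assignment` overriding the respective defaults.
#' @return Invisibly, a list with the per-stage results: `sim` (when
#'   simulated), `filtered`, `report`, `null`, `decisions`, `assignment`
#'   (when alignment inputs exist), and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    .assert(file.exists(config), "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  .assert(is.list(config), "`config` must be a list or a YAML path")
  out_dir <- config$out_dir
  .assert(!is.null(out_dir), "config needs an `out_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stage_seed <- function(k) if (is.null(seed)) NULL else as.integer(seed) + k
  log <- list(seed = seed, stages = list())

  # -- stage: simulate or ingest --------------------------------------------
  hits <- NULL; scaffold_map <- NULL; sim <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    aln_args <- sim_args$alignment
    sim_args$alignment <- NULL
    sim_args$seed <- stage_seed(1L)
    params <- do.call(pop_sim_params, sim_args)
    sim <- simulate_population(params)
    gm <- sim$genotypes; tags <- sim$tags; sheet <- sim$sheet
    write_genotypes_tsv(gm, file.path(out_dir, "genotypes.tsv"))
    write_tag_presence(tags, file.path(out_dir, "tags.tsv"))
    write_sample_sheet(sheet, file.path(out_dir, "sample_sheet.tsv"))
    write.table(sim$truth, file.path(out_dir, "truth_labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(aln_args)) {
      aln_args$locus_ids <- rownames(tags)
      aln_args$truth <- sim$truth
      aln_args$seed <- stage_seed(2L)
      aln <- do.call(simulate_alignment_hits, aln_args)
      hits <- aln$hits; scaffold_map <- aln$scaffold_map
      write_alignment_hits(hits, file.path(out_dir, "hits.tsv"))
      write.table(scaffold_map, file.path(out_dir, "scaffold_map.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
    log$stages$simulate <- list(seed = stage_seed(1L),
                                n_loci = params$n_loci, system = params$system)
  } else {
    inp <- config$inputs
    .assert(is.list(inp), "config needs either `simulate` or `inputs`")
    for (f in c("genotypes", "tags", "sample_sheet"))
      .assert(!is.null(inp[[f]]) && file.exists(inp[[f]]),
              "input file for `%s` not found: %s", f,
              if (is.null(inp[[f]])) "(unset)" else inp[[f]])
    gm <- read_genotypes(inp$genotypes)
    tags <- read_tag_presence(inp$tags)
    sheet <- read_sample_sheet(inp$sample_sheet)
    if (!is.null(inp$hits)) {
      hits <- read_alignment_hits(inp$hits)
      scaffold_map <- read_scaffold_map(inp$scaffold_map)
    }
  }

  # -- stage: filter ---------------------------------------------------------
  fp <- do.call(filter_params, config$filter %||% list())
  filtered <- filter_loci(gm, sheet, fp)
  write_genotypes_tsv(filtered, file.path(out_dir, "genotypes_filtered.tsv"))
  log$stages$filter <- as.list(attr(filtered, "filter_log"))

  # -- stage: screens + permutation validation -------------------------------
  sp <- do.call(screen_params, config$screens %||% list())
  report <- run_all_screens(filtered, tags, sheet, sp)
  write_marker_sets(report$sets, file.path(out_dir, "marker_sets.tsv"))
  pc_args <- config$permutation %||% list()
  pc_args$seed <- pc_args$seed %||% stage_seed(3L)
  pc <- do.call(permutation_config, pc_args)
  null <- build_null(filtered, tags, sheet, sp, pc)
  decisions <- validate_screens(null)
  write.table(decisions, file.path(out_dir, "validation_decisions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(permutation = seq_len(nrow(null$null)), null$null),
              file.path(out_dir, "null_series.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log$stages$permutation <- list(seed = pc$seed,
                                 n_permutations = pc$n_permutations,
                                 percentile = pc$percentile)

  # -- stage: chromosome assignment ------------------------------------------
  assignment <- NULL
  if (!is.null(hits)) {
    ac_args <- config$assignment %||% list()
    ac_args$seed <- ac_args$seed %||% stage_seed(4L)
    ac <- do.call(assignment_config, ac_args)
    fh <- filter_alignment_hits(hits)
    passing <- decisions[decisions$pass & decisions$approach != "sex_limited", ]
    marker_ids <- unique(unlist(lapply(
      paste0(passing$approach, "_", passing$orientation),
      function(nm) report$sets[[nm]]$markers)))
    if (length(marker_ids) > 0) {
      counts <- assign_markers(marker_ids, fh, scaffold_map)
      nul <- random_subset_null(rownames(tags), fh, scaffold_map,
                                length(marker_ids), ac)
      assignment <- identify_sex_chromosome(counts$counts, nul, ac)
      write.table(assignment$table,
                  file.path(out_dir, "chromosome_assignment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      log$stages$assignment <- list(
        seed = ac$seed, set_size = length(marker_ids),
        identified = assignment$identified)
    } else {
      log$stages$assignment <- list(identified = character(0),
                                    note = "no validated marker set")
    }
  }

  log$decisions <- decisions
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(sim = sim, filtered = filtered, report = report,
                 null = null, decisions = decisions,
                 assignment = assignment, out_dir = out_dir))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
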