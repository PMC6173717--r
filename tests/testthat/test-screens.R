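# The three sex-linkage screens, in both orientations.

# hand-built matrices over 20 males + 20 females
hand_sheet <- data.frame(sample_id = c(sprintf("M%02d", 1:20),
                                       sprintf("F%02d", 1:20)),
                         sex = rep(c("M", "F"), each = 20))

test_that("the allele-frequency screen enforces the male band and female floor", {
  gm <- rbind(
    half_het = c(rep(1L, 10), rep(0L, 10), rep(0L, 20)),  # male X freq 0.75
    all_het  = c(rep(1L, 20), rep(0L, 20)),               # male X freq 0.50
    mono     = rep(0L, 40))
  colnames(gm) <- hand_sheet$sample_id
  ms <- screen_allele_freq(gm, hand_sheet, "XY")
  expect_identical(ms$markers, "all_het")
  expect_equal(ms$stats$x_freq_heterogametic, 0.5)
})

test_that("the heterozygosity screen requires zero female hets and half het males", {
  gm <- rbind(
    one_f_het = c(rep(1L, 20), 1L, rep(0L, 19)),      # every male het, 1 female het
    boundary  = c(rep(1L, 10), rep(0L, 10), rep(0L, 20)),  # 10/20 males het
    below     = c(rep(1L, 9), rep(0L, 11), rep(0L, 20)))   # 9/20 males het
  colnames(gm) <- hand_sheet$sample_id
  ms <- screen_heterozygosity(gm, hand_sheet, "XY")
  expect_identical(ms$markers, "boundary")
})

test_that("the sex-limited screen needs total female absence and half male presence", {
  tags <- rbind(
    nine   = c(rep(1L, 9), rep(0L, 11), rep(0L, 20)),
    ten    = c(rep(1L, 10), rep(0L, 10), rep(0L, 20)),
    allall = rep(1L, 40))
  colnames(tags) <- hand_sheet$sample_id
  ms <- screen_sex_limited(tags, hand_sheet, "XY")
  expect_identical(ms$markers, "ten")
})

test_that("all-missing loci in one sex are unevaluable, never flagged", {
  gm <- matrix(c(rep(1L, 20), rep(NA_integer_, 20)), nrow = 1,
               dimnames = list("L1", hand_sheet$sample_id))
  expect_length(screen_allele_freq(gm, hand_sheet, "XY")$markers, 0)
  expect_equal(screen_allele_freq(gm, hand_sheet, "XY")$n_unevaluable, 1L)
  expect_length(screen_heterozygosity(gm, hand_sheet, "XY")$markers, 0)
})

test_that("noise-free screens recover the truth sets exactly, both orientations", {
  sim <- simulate_population(pop_sim_params(20, 20, 2000, "XY",
    prop_sexlinked = 0.1, prop_y_snp = 0.5, prop_sex_limited = 0.25,
    prop_x_hemizygous = 0.25, seed = 11))
  truth <- split(sim$truth$locus_id, sim$truth$class)
  rep <- run_all_screens(sim$genotypes, sim$tags, sim$sheet)
  expect_setequal(rep$sets$freq_XY$markers, truth$y_snp)
  expect_setequal(rep$sets$het_XY$markers, truth$y_snp)
  expect_setequal(rep$sets$sex_limited_XY$markers, truth$sex_limited)
  # the pseudo-ZW confound: ZW-orientation screens flag the hemizygous loci
  expect_setequal(rep$sets$freq_ZW$markers, truth$x_hemizygous)
  expect_setequal(rep$sets$het_ZW$markers, truth$x_hemizygous)
  expect_length(rep$sets$sex_limited_ZW$markers, 0)
  expect_equal(unname(rep$overlap_freq_het[["XY"]]), length(truth$y_snp))
})

test_that("screens equal a per-locus recomputation on noisy data", {
  sim <- simulate_population(pop_sim_params(14, 17, 1500, "XY",
    prop_sexlinked = 0.1, error_rate = 0.02, missing_rate = 0.15, seed = 12))
  for (orient in c("XY", "ZW")) {
    orc <- oracle_screens(sim$genotypes, sim$tags, sim$sheet$sex, orient)
    expect_setequal(screen_allele_freq(sim$genotypes, sim$sheet, orient)$markers,
                    orc$freq)
    expect_setequal(screen_heterozygosity(sim$genotypes, sim$sheet, orient)$markers,
                    orc$het)
    expect_setequal(screen_sex_limited(sim$tags, sim$sheet, orient)$markers,
                    orc$sex_limited)
  }
})

test_that("relabelling the sexes turns XY screens into ZW screens exactly", {
  sim <- simulate_population(pop_sim_params(12, 15, 1000, "XY",
    prop_sexlinked = 0.1, error_rate = 0.02, missing_rate = 0.1, seed = 13))
  swapped <- sim$sheet
  swapped$sex <- ifelse(swapped$sex == "M", "F", "M")
  expect_setequal(
    screen_allele_freq(sim$genotypes, swapped, "XY")$markers,
    screen_allele_freq(sim$genotypes, sim$sheet, "ZW")$markers)
  expect_setequal(
    screen_heterozygosity(sim$genotypes, swapped, "XY")$markers,
    screen_heterozygosity(sim$genotypes, sim$sheet, "ZW")$markers)
  expect_setequal(
    screen_sex_limited(sim$tags, swapped, "XY")$markers,
    screen_sex_limited(sim$tags, sim$sheet, "ZW")$markers)
})

test_that("tightening the homogametic frequency floor never grows the set", {
  sim <- simulate_population(pop_sim_params(10, 10, 1000, "XY",
    prop_sexlinked = 0.1, error_rate = 0.03, seed = 14))
  loose <- screen_allele_freq(sim$genotypes, sim$sheet, "XY",
                              screen_params(x_freq_min_homogametic = 0.90))
  tight <- screen_allele_freq(sim$genotypes, sim$sheet, "XY",
                              screen_params(x_freq_min_homogametic = 0.98))
  expect_true(all(tight$markers %in% loose$markers))
})

test_that("with genotyping error the het screen stays within zero-female-het loci", {
  sim <- simulate_population(pop_sim_params(15, 15, 1500, "XY",
    prop_sexlinked = 0.1, error_rate = 0.02, seed = 15))
  ms <- screen_heterozygosity(sim$genotypes, sim$sheet, "XY")
  females <- sim$sheet$sample_id[sim$sheet$sex == "F"]
  n_f_het <- rowSums(sim$genotypes[ms$markers, females, drop = FALSE] == 1L,
                     na.rm = TRUE)
  expect_true(all(n_f_het == 0))
})

test_that("two Y haplotypes depress the heterozygosity-screen yield", {
  # with dropout, carrier fractions sit at the 0.5 boundary under two
  # haplotypes and lose loci to sampling noise; one haplotype has full slack
  yield <- function(n_hap, seed) {
    sim <- simulate_population(pop_sim_params(12, 12, 1200, "XY",
      prop_sexlinked = 0.25, prop_y_snp = 1, prop_sex_limited = 0,
      prop_x_hemizygous = 0, n_y_haplotypes = n_hap,
      missing_rate = 0.1, seed = seed))
    length(screen_heterozygosity(sim$genotypes, sim$sheet, "XY")$markers)
  }
  expect_lt(yield(2, 16), yield(1, 16))
})
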