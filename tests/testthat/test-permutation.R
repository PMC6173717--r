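# The sex-permutation empirical null and its validation rule.

test_that("a strong noise-free signal exceeds the entire null", {
  sim <- simulate_population(pop_sim_params(20, 20, 1000, "XY",
    prop_sexlinked = 0.1, seed = 21))
  nul <- build_null(sim$genotypes, sim$tags, sim$sheet,
                    config = permutation_config(200, seed = 22))
  for (s in c("freq_XY", "het_XY", "sex_limited_XY"))
    expect_gt(nul$observed[[s]], max(nul$null[, s]))
  dec <- validate_screens(nul)
  expect_true(all(dec$pass[dec$orientation == "XY"]))
})

test_that("the null series is reproducible under a fixed seed", {
  sim <- simulate_population(pop_sim_params(8, 8, 400, "NONE", seed = 23))
  n1 <- build_null(sim$genotypes, sim$tags, sim$sheet,
                   config = permutation_config(50, seed = 24))
  n2 <- build_null(sim$genotypes, sim$tags, sim$sheet,
                   config = permutation_config(50, seed = 24))
  expect_identical(n1$null, n2$null)
  expect_identical(n1$perm_seeds, 24L + 1:50)
})

test_that("ties at the percentile threshold FAIL, and zero observed always FAILs", {
  fake <- structure(list(
    observed = c(freq_XY = 5, het_XY = 0, sex_limited_XY = 34,
                 freq_ZW = 3, het_ZW = 2, sex_limited_ZW = 1),
    null = cbind(freq_XY = rep(5, 1000), het_XY = rpois(1000, 2),
                 sex_limited_XY = rep(0, 1000), freq_ZW = rep(4, 1000),
                 het_ZW = rep(2, 1000), sex_limited_ZW = rep(2, 1000)),
    percentile = 99, n_permutations = 1000L, perm_seeds = 1:1000),
    class = "empirical_null")
  dec <- validate_screens(fake)
  dec <- setNames(dec$pass, dec$screen)
  expect_false(dec[["freq_XY"]])        # observed equals the threshold
  expect_false(dec[["het_XY"]])         # observed zero
  expect_true(dec[["sex_limited_XY"]])  # null all zero, observed 34
  expect_false(dec[["het_ZW"]])         # tie again
})

test_that("too few permutations for the percentile warns and uses exact ranks", {
  sim <- simulate_population(pop_sim_params(5, 5, 200, "NONE", seed = 25))
  nul <- build_null(sim$genotypes, sim$tags, sim$sheet,
                    config = permutation_config(20, seed = 26))
  w <- capture_warnings(validate_screens(nul))
  expect_true(all(grepl("exact rank", w)))
  expect_length(w, 6)                   # one warning per screen
})

test_that("permuting already-permuted labels leaves the null unchanged in law", {
  sim <- simulate_population(pop_sim_params(10, 10, 800, "NONE", seed = 27))
  n1 <- build_null(sim$genotypes, sim$tags, sim$sheet,
                   config = permutation_config(1000, seed = 28))
  shuffled <- sim$sheet
  set.seed(29)
  shuffled$sex <- sample(shuffled$sex)
  n2 <- build_null(sim$genotypes, sim$tags, sim$sheet |>
                     transform(sex = shuffled$sex),
                   config = permutation_config(1000, seed = 30))
  for (s in c("freq_XY", "het_XY")) {
    ks <- suppressWarnings(stats::ks.test(n1$null[, s], n2$null[, s]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("the subsampling experiment reports one validated row per design and screen", {
  sim <- simulate_population(pop_sim_params(20, 20, 600, "XY",
    prop_sexlinked = 0.1, seed = 31))
  designs <- list(list(name = "d19", n_males = 19L, n_females = 19L),
                  list(name = "d5", n_males = 5L, n_females = 5L))
  tab <- subsample_experiment(sim$genotypes, sim$tags, sim$sheet, designs,
                              config = permutation_config(100, seed = 32))
  expect_equal(nrow(tab), 2L * 6L)
  expect_setequal(unique(tab$design), c("d19", "d5"))
  expect_error(
    subsample_experiment(sim$genotypes, sim$tags, sim$sheet,
                         list(list(name = "big", n_males = 30L, n_females = 5L)),
                         config = permutation_config(10, seed = 1)),
    "needs 30 M")
})

test_that("a two-Y-haplotype design yields fewer het-screen markers than one haplotype", {
  counts <- sapply(c(2L, 1L), function(n_hap) {
    sim <- simulate_population(pop_sim_params(12, 12, 1000, "XY",
      prop_sexlinked = 0.2, prop_y_snp = 1, prop_sex_limited = 0,
      prop_x_hemizygous = 0, n_y_haplotypes = n_hap, missing_rate = 0.1,
      seed = 33))
    designs <- list(list(name = "hap", n_males = 12L, n_females = 12L,
                         male_haplotypes = if (n_hap == 2L) c(6L, 6L) else NULL))
    if (n_hap == 1L) designs[[1]]$male_haplotypes <- NULL
    tab <- suppressWarnings(          # 50 permutations: exact-rank warnings
      subsample_experiment(sim$genotypes, sim$tags, sim$sheet, designs,
                           config = permutation_config(50, seed = 34)))
    tab$observed[tab$screen == "het_XY"]
  })
  expect_lt(counts[1], counts[2])
})

test_that("the 99th-percentile rule controls false validation on null data", {
  # scaled-down calibration: 40 independent no-signal datasets
  pass <- matrix(NA, 40, 6)
  for (i in seq_len(40)) {
    sim <- simulate_population(pop_sim_params(10, 10, 800, "NONE",
                                              seed = 400 + i))
    nul <- build_null(sim$genotypes, sim$tags, sim$sheet,
                      config = permutation_config(200, seed = 500 + i))
    pass[i, ] <- validate_screens(nul)$pass
  }
  expect_lte(max(colMeans(pass)), 0.075)
})
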