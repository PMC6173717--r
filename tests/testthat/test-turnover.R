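# Turnover counting, rates, heterogamety tests and the recruitment null.

test_that("the packaged Ranidae fixture carries the published structure", {
  fx <- load_fig1_fixture()
  expect_length(fx$species, 28)
  expect_equal(nrow(fx$events), 13L)
  expect_true(all(!is.na(fx$events$ancestral_system) &
                    !is.na(fx$events$derived_system)))
  homol <- fx$events[fx$events$scope == "homologous", ]
  expect_equal(nrow(homol), 2L)
  expect_true(all(grepl("rugosa", homol$label)))
  expect_true(all(homol$ancestral_system == "XY" & homol$derived_system == "ZW"))
  expect_equal(fx$chromosome_usage[["Chr01"]], 8L)
  expect_equal(unname(rowSums(fx$tip_states)), rep(1, 28))
  # species-usage totals agree with the tip-state support pattern
  support <- colSums(fx$tip_states > 0.4)
  expect_equal(support[names(fx$chromosome_usage)],
               as.numeric(fx$chromosome_usage), ignore_attr = TRUE)
})

test_that("turnover counting partitions events as documented", {
  fx <- load_fig1_fixture()
  tc <- count_turnovers(fx$events)
  expect_equal(tc$total, 13L)
  expect_equal(tc$n_preserving_heterogamety, 11L)
  expect_equal(tc$per_derived_chromosome[["Chr05"]], 5L)
  expect_equal(tc$per_derived_chromosome[["Chr08"]], 3L)
  # unknown derived states count in the total but not per chromosome
  expect_equal(sum(tc$per_derived_chromosome), 11L)
  expect_equal(as.integer(tc$by_scope), c(8L, 3L, 2L))

  empty <- turnover_history(data.frame(ancestral_chr = character(),
                                       derived_chr = character()))
  tc0 <- count_turnovers(empty)
  expect_equal(tc0$total, 0L)
  expect_length(tc0$per_derived_chromosome, 0)
})

test_that("malformed histories are rejected", {
  expect_error(turnover_history(data.frame(
    ancestral_chr = "Chr01", derived_chr = "Chr02",
    ancestral_system = "XY", derived_system = "ZW",
    scope = "homologous")), "homologous")
  expect_error(turnover_history(data.frame(
    ancestral_chr = "Chr01", derived_chr = "Chr02",
    ancestral_system = "XX", derived_system = "XY")), "XY or ZW")
})

test_that("the turnover rate is events per Myr of summed branch length", {
  expect_equal(turnover_rate(50, 1)$rate, 0.02)
  r <- turnover_rate(650, 13)
  expect_equal(r$rate, 0.02)
  expect_equal(r$myr_per_turnover, 50)
  expect_equal(turnover_rate(100, 0)$rate, 0)
  expect_equal(turnover_rate(100, 0)$myr_per_turnover, Inf)
  expect_error(turnover_rate(0, 1), "positive")
  # tree input: any representation preserving total length gives the same rate
  tr <- simulate_tree(20, 30, seed = 91)
  expect_equal(turnover_rate(tr, 4)$rate,
               turnover_rate(ape::ladderize(tr), 4)$rate)
  expect_equal(turnover_rate(tr, 4)$rate, 4 / sum(tr$edge.length))
})

test_that("the exact heterogamety binomial matches closed forms", {
  expect_equal(heterogamety_binomial(13, 13, 0.5), 1 / 8192)
  expect_equal(heterogamety_binomial(11, 13, 0.5), 92 / 8192)
  expect_equal(heterogamety_binomial(0, 7, 0.31), 1)
  # agrees with the standard exact test in both tails
  expect_equal(heterogamety_binomial(11, 13, 0.75),
               stats::binom.test(11, 13, 0.75, "greater")$p.value)
  expect_equal(heterogamety_binomial(11, 13, 0.5, "two.sided"),
               stats::binom.test(11, 13, 0.5, "two.sided")$p.value)
})

test_that("the recruitment null reduces to closed forms in degenerate designs", {
  # all genes on one chromosome: every replicate puts all 13 events there
  res <- recruitment_null_test(c(Chr01 = 500), c(Chr01 = 13), 200, seed = 92)
  expect_true(all(res$null[, "Chr01"] == 13L))
  expect_equal(res$p_upper[["Chr01"]], 1)
  # two equal chromosomes: the upper tail is hypergeometric
  gc <- c(Chr01 = 400, Chr02 = 400)
  res <- recruitment_null_test(gc, c(Chr01 = 10, Chr02 = 3), 4000, seed = 93)
  p_exact <- 1 - stats::phyper(9, 400, 400, 13)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p_upper_raw[["Chr01"]] - p_exact), 3 * se)
  # reproducible under a fixed seed
  expect_identical(recruitment_null_test(gc, c(Chr01 = 13), 100, seed = 94),
                   recruitment_null_test(gc, c(Chr01 = 13), 100, seed = 94))
  expect_error(recruitment_null_test(c(Chr01 = 5), c(Chr01 = 13), 10),
               "more recruitments")
})

test_that("the recruitment regression behaves at both extremes", {
  x <- c(120, 250, 300, 410, 520)
  fit <- suppressWarnings(recruitment_regression(2 * x, x))  # perfect fit
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  expect_error(recruitment_regression(1:5, rep(3, 5)), "zero variance")
  # independent response: R^2 stays near zero on average
  set.seed(95)
  r2 <- replicate(50, recruitment_regression(rpois(13, 2),
                                             seq(700, 3500, length.out = 13))$r_squared)
  expect_lt(mean(r2), 0.25)
})

test_that("extra (intraspecific/homologous) events combine with mapped ones", {
  tr <- simulate_tree(6, 40, seed = 96)
  m <- mk_model(c("Chr01", "Chr05"), "ER", 1e-10)
  tips <- setNames(rep("Chr01", 6), tr$tip.label)
  maps <- stochastic_map(tr, tips, m, n_maps = 50, seed = 97)
  extra <- data.frame(ancestral_chr = "Chr08", derived_chr = "Chr08",
                      ancestral_system = "XY", derived_system = "ZW",
                      scope = "homologous")
  tc <- count_turnovers(maps, extra_events = extra)
  expect_equal(tc$total, 1L)
  expect_equal(tc$per_derived_chromosome[["Chr08"]], 1L)
  expect_equal(tc$n_preserving_heterogamety, 0L)
})
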