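# The synthetic-data generators: population genotypes, subsampling designs,
# dated trees and Markov character histories.

test_that("locus classes follow the requested fractions with floor rounding", {
  p <- pop_sim_params(5, 5, 1000, "XY", prop_sexlinked = 0.1,
                      prop_y_snp = 0.55, prop_sex_limited = 0.25,
                      prop_x_hemizygous = 0.15, seed = 1)
  sim <- simulate_population(p)
  counts <- table(sim$truth$class)
  expect_equal(unname(counts[["y_snp"]]), 55)          # floor(0.55 * 100)
  expect_equal(unname(counts[["sex_limited"]]), 25)
  expect_equal(unname(counts[["x_hemizygous"]]), 15)
  expect_equal(unname(counts[["autosomal"]]), 905)     # remainder is autosomal
  expect_setequal(sim$truth$locus_id,
                  c(rownames(sim$genotypes),
                    sim$truth$locus_id[sim$truth$class == "sex_limited"]))
})

test_that("a NONE-system simulation has no sex-linked loci", {
  sim <- simulate_population(pop_sim_params(8, 8, 300, "NONE",
                                            prop_sexlinked = 0.5, seed = 2))
  expect_true(all(sim$truth$class == "autosomal"))
})

test_that("noise-free Y-specific SNPs are het in every male, hom in every female", {
  p <- pop_sim_params(12, 15, 1000, "XY", prop_sexlinked = 0.1,
                      prop_y_snp = 1, prop_sex_limited = 0,
                      prop_x_hemizygous = 0, seed = 3)
  sim <- simulate_population(p)
  ids <- sim$truth$locus_id[sim$truth$class == "y_snp"]
  expect_length(ids, 100)
  males <- sim$sheet$sample_id[sim$sheet$sex == "M"]
  females <- sim$sheet$sample_id[sim$sheet$sex == "F"]
  expect_true(all(sim$genotypes[ids, males] == 1L))
  expect_true(all(sim$genotypes[ids, females] == 0L))
})

test_that("noise-free sex-limited tags and hemizygous loci have the built-in patterns", {
  sim <- simulate_population(pop_sim_params(10, 10, 500, "XY",
    prop_sexlinked = 0.2, prop_y_snp = 0.3, prop_sex_limited = 0.4,
    prop_x_hemizygous = 0.3, seed = 4))
  males <- sim$sheet$sex == "M"
  lim <- sim$truth$locus_id[sim$truth$class == "sex_limited"]
  expect_true(all(sim$tags[lim, males] == 1L))
  expect_true(all(sim$tags[lim, !males] == 0L))
  hemi <- sim$truth$locus_id[sim$truth$class == "x_hemizygous"]
  expect_true(all(sim$genotypes[hemi, males] == 0L))   # hemizygous, called hom
  expect_true(all(sim$genotypes[hemi, !males] == 1L))  # het in homogametic sex
})

test_that("ZW simulations mirror the XY patterns with sexes swapped", {
  sim <- simulate_population(pop_sim_params(10, 10, 400, "ZW",
    prop_sexlinked = 0.25, prop_y_snp = 1, prop_sex_limited = 0,
    prop_x_hemizygous = 0, seed = 5))
  ids <- sim$truth$locus_id[sim$truth$class == "y_snp"]
  females <- sim$sheet$sample_id[sim$sheet$sex == "F"]
  expect_true(all(sim$genotypes[ids, females] == 1L))
})

test_that("invalid parameters are rejected", {
  expect_error(pop_sim_params(0, 10, 100, "XY"), "zero males")
  expect_error(pop_sim_params(10, 0, 100, "XY"), "zero females")
  expect_error(pop_sim_params(5, 5, 100, "XY", prop_sexlinked = 1.2), "0, 1")
  expect_error(pop_sim_params(5, 5, 100, "XY", prop_y_snp = 0.6,
                              prop_sex_limited = 0.3, prop_x_hemizygous = 0.3),
               "<= 1")
  expect_error(pop_sim_params(5, 5, 100, "XY", n_y_haplotypes = 0), ">= 1")
})

test_that("with several Y haplotypes each Y-specific SNP is private to one lineage", {
  sim <- simulate_population(pop_sim_params(12, 12, 600, "XY",
    prop_sexlinked = 0.5, prop_y_snp = 1, prop_sex_limited = 0,
    prop_x_hemizygous = 0, n_y_haplotypes = 2, seed = 6))
  expect_equal(as.integer(table(sim$sheet$y_haplotype)[c("1", "2")]), c(6L, 6L))
  ids <- sim$truth$locus_id[sim$truth$class == "y_snp"]
  males <- sim$sheet$sample_id[sim$sheet$sex == "M"]
  n_het_males <- rowSums(sim$genotypes[ids, males] == 1L)
  expect_true(all(n_het_males == 6L))   # exactly the carriers of one haplotype
})

test_that("y_snp survival under genotyping error matches a per-locus recomputation", {
  sim <- simulate_population(pop_sim_params(15, 15, 2000, "XY",
    prop_sexlinked = 0.2, prop_y_snp = 1, prop_sex_limited = 0,
    prop_x_hemizygous = 0, error_rate = 0.01, seed = 7))
  ms <- screen_heterozygosity(sim$genotypes, sim$sheet, "XY")
  y_ids <- sim$truth$locus_id[sim$truth$class == "y_snp"]
  orc <- oracle_screens(sim$genotypes, sim$tags, sim$sheet$sex, "XY")
  expect_equal(sum(ms$markers %in% y_ids), sum(orc$het %in% y_ids))
  expect_setequal(ms$markers, orc$het)
})

test_that("the scenario catalogue holds the published designs", {
  cat <- scenario_catalog()
  balanced <- Filter(function(d) is.null(d$male_haplotypes) &&
                       d$n_males == d$n_females, cat)
  expect_setequal(vapply(balanced, `[[`, integer(1), "n_males"), 5:19)
  expect_true(any(vapply(cat, function(d)
    d$n_males == 18 && d$n_females == 9, logical(1))))
  expect_true(any(vapply(cat, function(d)
    d$n_males == 9 && d$n_females == 18, logical(1))))
  hap <- Filter(function(d) !is.null(d$male_haplotypes), cat)
  expect_length(hap, 1)
  expect_equal(hap[[1]]$male_haplotypes, c(6L, 6L))
  expect_equal(hap[[1]]$n_females, 12L)
})

test_that("simulated trees are ultrametric with the requested root age", {
  tr <- simulate_tree(2, root_age = 10, seed = 1)
  expect_equal(sum(tr$edge.length), 20)
  tr <- simulate_tree(50, root_age = 55, seed = 2)
  depths <- ape::node.depth.edgelength(tr)[1:50]
  expect_true(max(abs(depths - 55)) < 1e-9)
  expect_identical(ape::write.tree(simulate_tree(50, 55, seed = 9)),
                   ape::write.tree(simulate_tree(50, 55, seed = 9)))
  expect_error(simulate_tree(1, 10), "at least 2")
})

test_that("a zero generator leaves every lineage in the root state", {
  tr <- simulate_tree(10, 30, seed = 3)
  Q <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  sim <- simulate_states_on_tree(tr, Q, "B", seed = 4)
  expect_true(all(sim$tip_states == "B"))
  expect_equal(nrow(sim$history), 0L)
})

test_that("character simulation is reproducible and rejects malformed generators", {
  tr <- simulate_tree(15, 40, seed = 5)
  Q <- random_q(3)
  s1 <- simulate_states_on_tree(tr, Q, 1, seed = 6)
  s2 <- simulate_states_on_tree(tr, Q, 1, seed = 6)
  expect_identical(s1$history, s2$history)
  bad <- Q; bad[1, 2] <- -1
  expect_error(simulate_states_on_tree(tr, bad, 1), "off-diagonal")
  bad2 <- Q; bad2[1, 1] <- 0
  expect_error(simulate_states_on_tree(tr, bad2, 1), "sum to 0")
})

test_that("continuous-time event counts agree with a fine-step discrete-time simulator", {
  tr <- simulate_tree(10, 20, seed = 7)
  r <- 0.04
  Q <- matrix(c(-r, r, r, -r), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  set.seed(8)
  n_rep <- 300
  ct <- vapply(seq_len(n_rep), function(i)
    nrow(simulate_states_on_tree(tr, Q, 1)$history), numeric(1))
  dt <- vapply(seq_len(n_rep), function(i)
    disc_time_events(tr, Q, 1, dt = 0.005), numeric(1))
  se <- sqrt(var(ct) / n_rep + var(dt) / n_rep)
  expect_lt(abs(mean(ct) - mean(dt)), 3 * se)
})

test_that("simulated alignment hits carry a consistent chromosome truth", {
  sim <- simulate_population(pop_sim_params(10, 10, 400, "XY",
    prop_sexlinked = 0.2, seed = 9))
  aln <- simulate_alignment_hits(rownames(sim$tags), sim$truth,
                                 sexlinked_chrom = "Chr05", seed = 10)
  fh <- filter_alignment_hits(aln$hits)
  chrom <- aln$scaffold_map$chromosome[match(fh$sseqid, aln$scaffold_map$scaffold)]
  names(chrom) <- fh$qseqid
  truth <- aln$chrom_truth[names(chrom)]
  expect_true(all(chrom == truth))
  sl <- sim$truth$locus_id[sim$truth$class != "autosomal"]
  expect_true(all(aln$chrom_truth[sl] %in% c("Chr05", NA)))
})
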