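# Synthetic pedigrees, dispersal with crossing aversion, and noisy
# sample genotypes.

test_that("pedigree bookkeeping records each first-order pair once", {
  tr <- generate_population(1, 2, n_loci = 10, seed = 1)
  rel <- tr$relationships
  expect_equal(sum(rel$type == "FS"), 1)
  expect_equal(sum(rel$type == "PO"), 4)  # 2 offspring x 2 parents
  key <- paste(pmin(rel$id_a, rel$id_b), pmax(rel$id_a, rel$id_b))
  expect_false(anyDuplicated(key) > 0)
})

test_that("founder heterozygosity matches Hardy-Weinberg at p = 0.5", {
  n_fam <- 400
  tr <- generate_population(n_fam, 0, n_loci = 20,
                            allele_freqs = rep(0.5, 20), seed = 2)
  G <- tr$genotypes
  het <- mean(G == 1)
  # binomial oracle: het ~ Bernoulli(0.5) over n_ind * n_loci draws
  se <- sqrt(0.5 * 0.5 / length(G))
  expect_lt(abs(het - 0.5), 3 * se)
})

test_that("offspring genotypes are Mendelian-consistent with parents", {
  tr <- generate_population(30, 3, n_loci = 30, seed = 3)
  ped <- tr$pedigree
  off <- ped[!ped$is_founder, ]
  G <- tr$genotypes
  for (i in seq_len(nrow(off))) {
    go <- G[off$individual_id[i], ]
    gm <- G[off$mother_id[i], ]
    gf <- G[off$father_id[i], ]
    # each offspring allele must be transmittable: dosage bounded by
    # parental gamete possibilities
    lo <- (gm == 2) + (gf == 2)          # forced alt gametes
    hi <- (gm >= 1) + (gf >= 1)          # available alt gametes
    expect_true(all(go >= lo & go <= hi))
  }
})

test_that("degenerate allele frequencies are rejected", {
  expect_error(generate_population(2, 1, n_loci = 3,
                                   allele_freqs = c(0.5, 1, 0.5), seed = 1),
               "strictly inside")
  expect_error(generate_population(2, 1, n_loci = 3,
                                   allele_freqs = c(0, 0.5, 0.5), seed = 1),
               "strictly inside")
})

test_that("full female aversion logs zero female crossings", {
  rs <- make_straight_rivers()
  tr <- generate_population(60, 2, n_loci = 10, seed = 4)
  kern <- dispersal_kernel_spec(female_crossing_aversion = 1)
  tr <- disperse_and_settle(tr, rs, kern, seed = 5)
  cr <- tr$crossings
  expect_true(all(cr$n_crossed[cr$sex == "female"] == 0))
  expect_gt(sum(cr$n_crossed[cr$sex == "male"]), 0)
})

test_that("without rivers no crossings are logged", {
  rs <- generate_landscape(landscape_spec(n_rivers = 0), seed = 1)
  tr <- generate_population(30, 2, n_loci = 10, seed = 6)
  tr <- disperse_and_settle(tr, rs, seed = 7)
  expect_true(all(tr$crossings$n_crossed == 0))
})

test_that("with zero aversion and equal kernels the sexes cross equally", {
  rs <- make_straight_rivers()
  kern <- dispersal_kernel_spec(male = list(meanlog = log(25), sdlog = 0.6),
                                female = list(meanlog = log(25), sdlog = 0.6),
                                female_crossing_aversion = 0,
                                male_crossing_aversion = 0)
  tr <- generate_population(1500, 1, n_loci = 2, seed = 8)
  tr <- disperse_and_settle(tr, rs, kern, seed = 9)
  cr <- tr$crossings
  pm <- mean(cr$n_crossed[cr$sex == "male"] >= 1)
  pf <- mean(cr$n_crossed[cr$sex == "female"] >= 1)
  # two-proportion comparison within Monte-Carlo error
  ht <- prop.test(c(sum(cr$n_crossed[cr$sex == "male"] >= 1),
                    sum(cr$n_crossed[cr$sex == "female"] >= 1)),
                  c(sum(cr$sex == "male"), sum(cr$sex == "female")))
  expect_gt(ht$p.value, 0.001)
  expect_lt(abs(pm - pf), 0.1)
})

test_that("noise-free single samples reproduce truth exactly", {
  d <- small_noisy_dataset(seed = 10, n_families = 10)
  ss <- sample_genotypes(d$truth, samples_per_individual = 1,
                         error_rate = 0, missing_rate = 0, jitter_sd = 0,
                         marker_dropout = 0, seed = 11)
  expect_equal(nrow(ss$meta), nrow(d$truth$pedigree))
  expect_equal(unname(ss$geno),
               unname(d$truth$genotypes[ss$meta$true_individual_id, ]))
  expect_equal(cbind(ss$meta$x, ss$meta$y),
               unname(d$truth$coords[ss$meta$true_individual_id, ]))
  ymat <- ss$sex_markers[, paste0("Y", 1:4)]
  ped <- d$truth$pedigree
  true_sex <- ped$sex[match(ss$meta$true_individual_id, ped$individual_id)]
  expect_equal(unname(rowSums(ymat) >= 1), true_sex == "male")
})

test_that("full missingness yields empty calls that clustering rejects", {
  d <- small_noisy_dataset(seed = 12, n_families = 5)
  ss <- sample_genotypes(d$truth, samples_per_individual = 1,
                         missing_rate = 1, seed = 13)
  expect_true(all(is.na(ss$geno)))
  expect_error(cluster_samples(ss), "min_comparable_loci")
})

test_that("pairwise mismatches between replicate samples match a binomial oracle", {
  e <- 0.01; L <- 85
  tr <- generate_population(300, 0, n_loci = L, seed = 14)
  rs <- generate_landscape(landscape_spec(n_rivers = 0), seed = 1)
  tr <- disperse_and_settle(tr, rs, seed = 15)
  ss <- sample_genotypes(tr, samples_per_individual = 2, error_rate = e,
                         missing_rate = 0, jitter_sd = 0, seed = 16)
  id <- ss$meta$true_individual_id
  first <- match(unique(id), id)
  second <- first + 1L
  mm <- vapply(seq_along(first), function(i)
    allele_mismatch_count(ss$geno[first[i], ], ss$geno[second[i], ])$mismatches,
    0)
  # direct binomial oracle at tiny per-allele error: each of 2L alleles
  # differs when exactly one copy flipped; P ~ 2e(1-e) per allele, minus
  # the chance paired flips cancel on the dosage scale (simulated)
  set.seed(17)
  sim <- replicate(4000, {
    g <- rbinom(L, 2, tr$allele_freqs)
    flip <- function(g) g - rbinom(L, g, e) + rbinom(L, 2 - g, e)
    sum(abs(flip(g) - flip(g)))
  })
  se <- sqrt(var(sim) / length(sim) + var(mm) / length(mm))
  expect_lt(abs(mean(mm) - mean(sim)), 4 * se)
})

test_that("generation is reproducible: identical seeds, identical objects", {
  a <- small_noisy_dataset(seed = 18)
  b <- small_noisy_dataset(seed = 18)
  expect_identical(a$truth, b$truth)
  expect_identical(a$samples, b$samples)
})
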