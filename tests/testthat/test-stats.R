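# Classical tests behind the barrier hypotheses, each checked against an
# independent formula-level implementation.

test_that("Yates chi-square matches the textbook formula", {
  # all expected counts 2: sum((|O-E|-0.5)^2/E) = 0.5
  tr <- suppressWarnings(crossing_proportion_test(3, 4, 1, 4))
  expect_equal(unname(tr$statistic), 0.5)
  expect_equal(tr$statistic,
               chisq_yates_oracle(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)))
  # identical proportions: 0 after the clamped correction
  expect_equal(crossing_proportion_test(10, 20, 10, 20)$statistic, 0)
  # group-swap symmetry
  a <- crossing_proportion_test(17, 60, 5, 45)
  b <- crossing_proportion_test(5, 45, 17, 60)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_error(crossing_proportion_test(1, 0, 1, 2), "positive")
  expect_error(crossing_proportion_test(5, 4, 1, 2), "exceed")
})

test_that("Yates chi-square agrees with the oracle on random tables", {
  set.seed(60)
  for (i in 1:100) {
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
    if (any(colSums(tab) == 0)) next
    tr <- suppressWarnings(crossing_proportion_test(k1, n1, k2, n2))
    expect_equal(unname(tr$statistic), chisq_yates_oracle(tab),
                 tolerance = 1e-8)
  }
})

test_that("Fisher's exact p equals exhaustive fixed-margin enumeration", {
  set.seed(61)
  for (i in 1:60) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    tr <- fisher_exact_or(tab)
    expect_equal(tr$p_value, fisher_p_enum_oracle(tab), tolerance = 1e-10)
  }
  bal <- fisher_exact_or(matrix(5, 2, 2))
  expect_equal(bal$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(bal$p_value, 1)
  deg <- fisher_exact_or(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_true(is.na(deg$odds_ratio))
})

test_that("distance ANOVA and Tukey agree with formula-level oracles", {
  set.seed(62)
  for (i in 1:20) {
    d <- data.frame(
      distance_km = c(rnorm(12, 50, 20), rnorm(15, 25, 10), rnorm(9, 45, 15)),
      class = rep(c("MM", "FF", "MF"), c(12, 15, 9)))
    tr <- distance_anova_tukey(d)
    orc <- anova_oracle(d$distance_km, d$class)
    expect_equal(unname(tr$statistic), orc$F, tolerance = 1e-8)
    expect_equal(tr$p_value, orc$p, tolerance = 1e-8)
    tko <- tukey_oracle(d$distance_km, d$class)
    for (cmp in tr$tukey$comparison) {
      expect_equal(tr$tukey$p_adj[tr$tukey$comparison == cmp],
                   unname(tko[[cmp]]["p_adj"]), tolerance = 1e-8)
    }
  }
})

test_that("equal group means give F = 0 and Tukey p near 1", {
  v <- rep(c(1, 2, 3, 4), 3)
  d <- data.frame(distance_km = v, class = rep(c("MM", "FF", "MF"), each = 4))
  tr <- distance_anova_tukey(d)
  expect_equal(unname(tr$statistic), 0)
  expect_true(all(tr$tukey$p_adj > 0.999))
})

test_that("the one-proportion z-test follows the score formula", {
  tr <- direction_proportion_test(50, 100, "two.sided")
  expect_equal(unname(tr$statistic), 0)
  expect_equal(tr$p_value, 1)
  set.seed(63)
  for (i in 1:50) {
    n <- sample(10:300, 1); k <- sample(0:n, 1)
    z <- z_prop_oracle(k, n)
    two <- direction_proportion_test(k, n, "two.sided")
    less <- direction_proportion_test(k, n, "less")
    expect_equal(unname(two$statistic), z, tolerance = 1e-10)
    expect_equal(two$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-10)
    expect_equal(less$p_value, pnorm(z), tolerance = 1e-10)
    expect_equal(two$chi_squared, z^2, tolerance = 1e-10)
  }
  # extreme deficit: exact binomial tail is 0.5^20; the normal
  # approximation is of the same small order
  expect_equal(binom_tail_oracle(0, 20), 2^-20)
  expect_lt(direction_proportion_test(0, 20, "less")$p_value, 1e-5)
})

test_that("KS D equals the pooled-CDF sup-difference oracle", {
  same <- c(10, 20, 30, 44)
  expect_equal(unname(angle_distribution_test(same, same)$statistic), 0)
  expect_equal(unname(angle_distribution_test(c(0, 1, 2), c(88, 89, 90))$statistic), 1)
  set.seed(64)
  for (i in 1:40) {
    a <- runif(sample(5:60, 1), 0, 90)
    b <- runif(sample(5:60, 1), 0, 90)
    expect_equal(unname(angle_distribution_test(a, b)$statistic),
                 ks_D_oracle(a, b), tolerance = 1e-10)
  }
})

test_that("angle filtering by distance behaves and errors helpfully", {
  a <- c(10, 80); da <- c(30, 10)
  b <- c(20, 70); db <- c(40, 50)
  tr <- angle_distribution_test(a, b, da, db, min_distance_km = 25)
  expect_equal(tr$n, c(1, 2))
  expect_error(angle_distribution_test(a, b, da, db, min_distance_km = 60),
               "no angles left")
  expect_error(angle_distribution_test(a, b, min_distance_km = 25),
               "distances not supplied")
})

test_that("multi-location crossing uses the any-pair rule", {
  rs <- river_set(list(list(name = "R", polyline = cbind(c(-1e5, 1e5), c(0, 0)))),
                  reference_azimuth_deg = 0)
  mk_inds <- function(locs, sexes) {
    ids <- sprintf("I%04d", seq_along(locs))
    meta <- data.frame(individual_id = ids, sex = sexes,
                       sex_ambiguous = FALSE,
                       n_samples = vapply(locs, nrow, 0L),
                       x = vapply(locs, function(l) mean(l[, 1]), 0),
                       y = vapply(locs, function(l) mean(l[, 2]), 0))
    names(locs) <- ids
    structure(list(meta = meta, locations = locs), class = "individual_set")
  }
  inds <- mk_inds(list(rbind(c(0, -50), c(10, 60)),            # opposite banks
                       rbind(c(0, 10), c(5, 40), c(2, -30)),   # 1st-3rd pair crosses
                       rbind(c(0, 5), c(8, 45))),              # same bank
                  c("male", "female", "female"))
  tab <- multilocation_crossing_table(inds, rs)
  expect_equal(tab["male", "crossed"], 1L)
  expect_equal(tab["female", "crossed"], 1L)
  expect_equal(tab["female", "not_crossed"], 1L)
  # single-location individuals excluded with a warning
  solo <- mk_inds(list(rbind(c(0, 5))), "male")
  expect_warning(tab2 <- multilocation_crossing_table(solo, rs), "empty")
  expect_equal(sum(tab2), 0L)
})
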