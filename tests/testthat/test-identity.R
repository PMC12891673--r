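# Individual identification: mismatch counting, single-linkage
# clustering, consensus, sexing, spatial centres.

make_samples <- function(geno, ypos = NULL, xy = NULL) {
  n <- nrow(geno)
  if (is.null(ypos)) ypos <- rep(FALSE, n)
  Y <- matrix(0L, n, 4, dimnames = list(NULL, paste0("Y", 1:4)))
  Y[ypos, 1] <- 1L
  X <- matrix(1L, n, 3, dimnames = list(NULL, paste0("X", 1:3)))
  if (is.null(xy)) xy <- cbind(seq_len(n) * 1000, 0)
  panel <- make_snp_panel(ncol(geno))
  colnames(geno) <- panel$locus
  rownames(geno) <- sprintf("S%03d", seq_len(n))
  structure(list(meta = data.frame(sample_id = rownames(geno),
                                   true_individual_id = NA, x = xy[, 1],
                                   y = xy[, 2], year = NA),
                 sex_markers = cbind(Y, X), geno = geno, panel = panel),
            class = "sample_set")
}

test_that("allele mismatches follow the multiset-intersection definition", {
  g1 <- rep(0L, 85); g2 <- g1
  g2[1] <- 1L  # A/A vs A/T
  expect_equal(allele_mismatch_count(g1, g2),
               list(mismatches = 1L, comparable_loci = 85L))
  g3 <- g1; g3[1] <- 2L  # A/A vs T/T
  expect_equal(allele_mismatch_count(g1, g3)$mismatches, 2L)
  expect_equal(allele_mismatch_count(g1, g1),
               list(mismatches = 0L, comparable_loci = 85L))
  g4 <- g1; g4[1:5] <- NA
  expect_equal(allele_mismatch_count(g1, g4)$comparable_loci, 80L)
  expect_error(allele_mismatch_count(g1, g1[1:10]), "panel")
})

test_that("the 12-mismatch tolerance separates at 13 and merges at 12", {
  base <- matrix(0L, 2, 85)
  g13 <- base; g13[2, 1:13] <- 1L
  expect_equal(nrow(cluster_samples(make_samples(g13))$meta), 2)
  g12 <- base; g12[2, 1:12] <- 1L
  expect_equal(nrow(cluster_samples(make_samples(g12))$meta), 1)
  g0 <- base
  expect_equal(nrow(cluster_samples(make_samples(g0))$meta), 1)
})

test_that("single linkage chains A-B-C into one individual", {
  g <- matrix(0L, 3, 85)
  g[2, 1:10] <- 1L          # A-B: 10
  g[3, 1:10] <- 2L          # B-C: 10, A-C: 20
  expect_equal(allele_mismatch_count(g[1, ], g[3, ])$mismatches, 20L)
  cl <- cluster_samples(make_samples(g))
  expect_equal(nrow(cl$meta), 1)
  expect_equal(cl$meta$n_samples, 3)
  # oracle: connected components of the thresholded distance matrix
  d <- outer(1:3, 1:3, Vectorize(function(i, j)
    allele_mismatch_count(g[i, ], g[j, ])$mismatches))
  adj <- d <= 12; diag(adj) <- FALSE
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, "undirected"))$no
  expect_equal(nrow(cl$meta), comp)
})

test_that("clustering is invariant to input record order", {
  d <- small_noisy_dataset(seed = 30, n_families = 15)
  ss <- d$samples
  cl1 <- cluster_samples(ss)
  perm <- sample(nrow(ss$meta))
  ss2 <- ss
  ss2$meta <- ss$meta[perm, ]
  ss2$geno <- ss$geno[perm, , drop = FALSE]
  ss2$sex_markers <- ss$sex_markers[perm, , drop = FALSE]
  cl2 <- cluster_samples(ss2)
  expect_equal(nrow(cl1$meta), nrow(cl2$meta))
  # same partition of sample ids
  part <- function(cl) sort(unname(vapply(cl$members,
                                          function(m) paste(sort(m), collapse = "+"), "")))
  expect_equal(part(cl1), part(cl2))
})

test_that("individual count is monotone non-increasing in max_mismatch", {
  d <- small_noisy_dataset(seed = 31, n_families = 15)
  counts <- vapply(c(0, 4, 8, 12, 20, 40),
                   function(mm) nrow(cluster_samples(d$samples,
                                                     max_mismatch = mm)$meta), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("samples cluster back to their true individuals at default noise", {
  d <- small_noisy_dataset(seed = 32, n_families = 50)
  cl <- cluster_samples(d$samples)
  truth <- d$samples$meta$true_individual_id[match(names(cl$sample_map),
                                                   d$samples$meta$sample_id)]
  # fraction of samples assigned to the modal cluster of their individual
  correct <- unlist(lapply(split(cl$sample_map, truth), function(v)
    v == names(which.max(table(v)))))
  expect_gte(mean(correct), 0.99)
})

test_that("consensus genotype takes the majority and NAs out ties", {
  expect_equal(consensus_genotype(rbind(c(1L, 1L), c(1L, 0L), c(0L, NA))),
               c(1L, NA))
  expect_equal(consensus_genotype(rbind(c(1L), c(0L))), NA_integer_)
  expect_equal(consensus_genotype(c(2L, 0L, NA)), c(2L, 0L, NA))
  expect_equal(consensus_genotype(rbind(c(NA_integer_), c(NA_integer_))),
               NA_integer_)
})

test_that("sex assignment follows the majority rule with ambiguity on ties", {
  expect_equal(assign_sex(c(TRUE, TRUE, TRUE)), "male")
  expect_equal(assign_sex(c(FALSE, FALSE)), "female")
  expect_equal(assign_sex(c(TRUE, TRUE, FALSE, FALSE)), "ambiguous")
})

test_that("spatial centres are arithmetic means with translation equivariance", {
  loc <- rbind(c(0, 0), c(2, 0), c(1, 3))
  expect_equal(spatial_center(loc), c(1, 1))
  expect_equal(spatial_center(rbind(c(5, 7))), c(5, 7))
  expect_equal(spatial_center(loc + rep(c(10, -4), each = 3)),
               spatial_center(loc) + c(10, -4))
  expect_error(spatial_center(loc[0, , drop = FALSE]), "no locations")
})

test_that("under-typed samples are excluded and logged", {
  g <- matrix(0L, 3, 85)
  g[3, 1:30] <- NA  # 55 typed < 60
  cl <- cluster_samples(make_samples(g), min_comparable_loci = 60)
  expect_equal(cl$excluded_samples, "S003")
  expect_equal(sum(cl$meta$n_samples), 2)
})
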