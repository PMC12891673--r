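#' Individual identification from replicated noisy genotypes
#'
#' Non-invasive sampling yields several error-prone genotypes per
#' animal. Samples are collapsed into individuals by single-linkage
#' clustering of the allele-mismatch graph: two samples are linked when
#' they disagree at no more than `max_mismatch` alleles across the loci
#' typed in both. Each cluster receives a majority-rule consensus
#' genotype, a sex from the Y/X marker calls, and a spatial centre (the
#' arithmetic mean of its sample coordinates).
#'
#' @name genotype_identity
NULL

#' Allele mismatches between two genotypes
#'
#' Per locus typed in both genotypes the mismatch is `2 - |intersection|`
#' of the two unordered allele pairs (0, 1 or 2); loci missing in either
#' are excluded from both totals. For biallelic dosage coding this is
#' `|dosage_a - dosage_b|`.
#'
#' @param a,b named integer dosage vectors over the same panel (`NA` =
#'   missing), e.g. rows of a `sample_set$geno` matrix.
#' @return list with `mismatches` and `comparable_loci`.
#' @export
allele_mismatch_count <- function(a, b) {
  if (length(a) != length(b) ||
      (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b))))
    stop("genotypes come from different panels")
  ok <- !is.na(a) & !is.na(b)
  list(mismatches = sum(abs(a[ok] - b[ok])),
       comparable_loci = sum(ok))
}

# Pairwise mismatch and comparable-locus matrices for all samples.
# Unary half-allele encoding turns the dosage L1 distance into a Hamming
# distance computable with three matrix products.
.mismatch_matrices <- function(G) {
  P <- !is.na(G)
  B <- cbind(G >= 1, G >= 2)
  B[is.na(B)] <- FALSE
  storage.mode(B) <- "double"
  Pm <- cbind(P, P); storage.mode(Pm) <- "double"
  BB <- tcrossprod(B)
  BP <- tcrossprod(B, Pm)
  mism <- BP + t(BP) - 2 * BB
  Pd <- P; storage.mode(Pd) <- "double"
  list(mismatches = mism, comparable = tcrossprod(Pd))
}

#' Majority-rule consensus genotype
#'
#' Per locus, the most frequent call among non-missing member calls;
#' ties and all-missing loci give `NA`.
#'
#' @param members dosage matrix (members x loci) or a single vector.
#' @return integer dosage vector.
#' @export
consensus_genotype <- function(members) {
  members <- rbind(members)
  apply(members, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_integer_)
    tb <- tabulate(v + 1L, 3L)
    mx <- max(tb)
    if (sum(tb == mx) > 1) NA_integer_ else which.max(tb) - 1L
  })
}

#' Assign sex from member Y-marker positivity
#'
#' A sample is Y-positive when at least one of its Y markers amplified.
#' The individual is male when a strict majority of its members are
#' Y-positive, female when a strict majority are Y-negative, and
#' `"ambiguous"` on a tie.
#'
#' @param y_positive logical vector, one entry per member sample.
#' @return `"male"`, `"female"` or `"ambiguous"`.
#' @export
assign_sex <- function(y_positive) {
  n_pos <- sum(y_positive); n <- length(y_positive)
  if (n_pos * 2 > n) "male" else if (n_pos * 2 < n) "female" else "ambiguous"
}

#' Arithmetic-mean spatial centre
#'
#' @param locations two-column matrix of coordinates (metres).
#' @return `c(x, y)`.
#' @export
spatial_center <- function(locations) {
  locations <- rbind(locations)
  if (nrow(locations) == 0) stop("no locations")
  colMeans(locations)
}

#' Collapse samples into individuals
#'
#' Single-linkage clustering on the graph whose edges join sample pairs
#' with at most `max_mismatch` allele mismatches. Components are taken
#' over the full edge set, so the result does not depend on input order.
#' Samples typed at fewer than `min_comparable_loci` loci are excluded
#' (and listed in the result) before clustering.
#'
#' @param samples a `sample_set`.
#' @param max_mismatch maximum tolerated allele mismatches (default 12).
#' @param min_comparable_loci minimum non-missing loci per sample
#'   (default 60 of 85); guards against spurious matches on near-empty
#'   genotypes.
#' @return object of class `individual_set`: `meta` (individual_id, sex,
#'   sex_ambiguous, n_samples, x, y), `geno` consensus dosage matrix,
#'   `members` and `locations` lists, `excluded_samples`, `panel`.
#' @export
cluster_samples <- function(samples, max_mismatch = 12, min_comparable_loci = 60) {
  stopifnot(inherits(samples, "sample_set"))
  typed <- rowSums(!is.na(samples$geno))
  keep <- typed >= min_comparable_loci
  excluded <- samples$meta$sample_id[!keep]
  if (!any(keep)) stop("no sample passes the min_comparable_loci filter")
  G <- samples$geno[keep, , drop = FALSE]
  meta <- samples$meta[keep, , drop = FALSE]
  sexm <- samples$sex_markers[keep, , drop = FALSE]

  mm <- .mismatch_matrices(G)
  adj <- mm$mismatches <= max_mismatch
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership

  # stable ids: clusters ordered by first member appearance
  first <- tapply(seq_along(comp), comp, min)
  ord <- rank(first)
  cl <- as.integer(ord[as.character(comp)])
  k <- max(cl)

  ids <- sprintf("I%04d", seq_len(k))
  cons <- matrix(NA_integer_, k, ncol(G), dimnames = list(ids, colnames(G)))
  sex <- character(k)
  centers <- matrix(NA_real_, k, 2)
  members <- vector("list", k); locations <- vector("list", k)
  ypos <- rowSums(sexm[, grepl("^Y", colnames(sexm)), drop = FALSE]) >= 1
  for (i in seq_len(k)) {
    m <- which(cl == i)
    members[[i]] <- meta$sample_id[m]
    loc <- cbind(meta$x[m], meta$y[m])
    locations[[i]] <- loc
    centers[i, ] <- spatial_center(loc)
    cons[i, ] <- consensus_genotype(G[m, , drop = FALSE])
    sex[i] <- assign_sex(ypos[m])
  }
  out_meta <- data.frame(individual_id = ids, sex = sex,
                         sex_ambiguous = sex == "ambiguous",
                         n_samples = tabulate(cl, k),
                         x = centers[, 1], y = centers[, 2],
                         stringsAsFactors = FALSE)
  names(members) <- names(locations) <- ids
  structure(list(meta = out_meta, geno = cons, members = members,
                 locations = locations, excluded_samples = excluded,
                 sample_map = stats::setNames(ids[cl], meta$sample_id),
                 panel = samples$panel),
            class = "individual_set")
}

#' @export
print.individual_set <- function(x, ...) {
  tb <- table(factor(x$meta$sex, c("female", "male", "ambiguous")))
  cat("<individual_set> ", nrow(x$meta), " individuals (",
      tb[["female"]], " F, ", tb[["male"]], " M, ", tb[["ambiguous"]],
      " ambiguous) from ", sum(x$meta$n_samples), " samples\n", sep = "")
  invisible(x)
}
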