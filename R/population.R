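#' Synthetic pedigrees, dispersal and noisy fecal-sample genotypes
#'
#' The generator emulates the statistical structure the downstream
#' analysis assumes: nuclear families genotyped at a biallelic SNP panel,
#' sex-specific dispersal distance kernels with an optional aversion to
#' settling across a river, and replicated noisy samples per individual
#' (per-allele genotyping error, per-locus missingness, spatial scatter
#' of sample locations around the individual's range centre). Ground
#' truth (pedigree, coordinates, crossing events) is retained for
#' parameter-recovery tests.
#'
#' @name synthetic_data
NULL

#' Define a biallelic SNP panel
#'
#' @param n_loci number of autosomal loci.
#' @return data.frame with columns `locus`, `a1`, `a2` (allele letters,
#'   `a1` alphabetically first so the dosage coding round-trips CSV).
#' @export
make_snp_panel <- function(n_loci = 85) {
  pairs <- t(utils::combn(c("A", "C", "G", "T"), 2))  # 6 ordered pairs
  idx <- (seq_len(n_loci) - 1) %% nrow(pairs) + 1
  data.frame(locus = sprintf("L%03d", seq_len(n_loci)),
             a1 = pairs[idx, 1], a2 = pairs[idx, 2],
             stringsAsFactors = FALSE)
}

#' Specify sex-specific dispersal kernels
#'
#' Distances are drawn from log-normal kernels (heavy right tail, as
#' dispersal distance distributions whose SD rivals the mean require).
#' Defaults put the male median at 45 km and the female median at 18 km
#' (kernel means about 56 and 23 km). `female_crossing_aversion` is the
#' probability that a proposed female settlement whose straight path from
#' the mother crosses at least one river is rejected and redrawn;
#' crossing-averse settlement is modelled by rejection-resampling so the
#' realised distance distribution of each sex keeps its kernel.
#'
#' @param male,female lists `list(meanlog =, sdlog =)` on the km scale.
#' @param female_crossing_aversion,male_crossing_aversion in `[0, 1]`.
#' @return object of class `dispersal_kernel_spec`.
#' @export
dispersal_kernel_spec <- function(male = list(meanlog = log(45), sdlog = 0.672),
                                  female = list(meanlog = log(18), sdlog = 0.687),
                                  female_crossing_aversion = 0.8,
                                  male_crossing_aversion = 0) {
  for (a in c(female_crossing_aversion, male_crossing_aversion))
    if (a < 0 || a > 1) stop("crossing aversion must lie in [0, 1]")
  structure(list(male = male, female = female,
                 female_crossing_aversion = female_crossing_aversion,
                 male_crossing_aversion = male_crossing_aversion),
            class = "dispersal_kernel_spec")
}

#' Generate a pedigreed population with Hardy-Weinberg founders
#'
#' Each family has two unrelated founder parents (one mother, one
#' father) drawn from Hardy-Weinberg proportions at the supplied allele
#' frequencies, and offspring produced by Mendelian transmission.
#' Offspring sexes are Bernoulli(0.5). All first-order relationships
#' (parent-offspring and full-sibling pairs) are recorded exactly once.
#'
#' @param n_families number of families.
#' @param offspring_per_family a fixed count, or a `function(n)` drawing
#'   one count per family; default `1 + rpois(n, 1)`.
#' @param n_loci panel size (default 85).
#' @param allele_freqs per-locus alternate-allele frequencies in (0, 1);
#'   default drawn uniformly from `[0.3, 0.7]`.
#' @param seed integer seed.
#' @return object of class `synthetic_truth`: pedigree, relationship
#'   table, genotype dosage matrix, allele frequencies, panel, seed.
#' @export
generate_population <- function(n_families, offspring_per_family = NULL,
                                n_loci = 85, allele_freqs = NULL, seed = 1L) {
  if (n_loci < 1) stop("n_loci must be >= 1")
  set.seed(seed)
  if (is.null(allele_freqs)) allele_freqs <- stats::runif(n_loci, 0.3, 0.7)
  if (length(allele_freqs) != n_loci) stop("allele_freqs length != n_loci")
  if (any(allele_freqs <= 0 | allele_freqs >= 1))
    stop("allele frequencies must lie strictly inside (0, 1)")
  if (is.null(offspring_per_family))
    offspring_per_family <- function(n) 1 + stats::rpois(n, 1)
  n_off <- if (is.function(offspring_per_family))
    offspring_per_family(n_families) else rep(offspring_per_family, n_families)
  n_off <- as.integer(n_off)
  if (length(n_off) != n_families || any(n_off < 0))
    stop("offspring_per_family must yield one non-negative count per family")

  panel <- make_snp_panel(n_loci)
  n_par <- 2L * n_families
  n_tot <- n_par + sum(n_off)
  ids <- sprintf("B%04d", seq_len(n_tot))
  fam <- integer(n_tot); sex <- character(n_tot)
  mother <- father <- rep(NA_character_, n_tot)

  mo_idx <- seq_len(n_families) * 2L - 1L
  fa_idx <- mo_idx + 1L
  fam[mo_idx] <- fam[fa_idx] <- seq_len(n_families)
  sex[mo_idx] <- "female"; sex[fa_idx] <- "male"

  off_idx <- if (sum(n_off) > 0) (n_par + 1L):n_tot else integer(0)
  off_fam <- rep(seq_len(n_families), n_off)
  fam[off_idx] <- off_fam
  sex[off_idx] <- sample(c("female", "male"), length(off_idx), replace = TRUE)
  mother[off_idx] <- ids[mo_idx][off_fam]
  father[off_idx] <- ids[fa_idx][off_fam]

  # founders: HW dosages; offspring: one gamete per parent per locus
  G <- matrix(NA_integer_, n_tot, n_loci, dimnames = list(ids, panel$locus))
  G[c(mo_idx, fa_idx), ] <- stats::rbinom(n_par * n_loci, 2,
                                          rep(allele_freqs, each = n_par))
  if (length(off_idx) > 0) {
    gm <- G[mother[off_idx], , drop = FALSE]
    gf <- G[father[off_idx], , drop = FALSE]
    gam_m <- stats::rbinom(length(gm), 1, gm / 2)
    gam_f <- stats::rbinom(length(gf), 1, gf / 2)
    G[off_idx, ] <- gam_m + gam_f
  }

  pedigree <- data.frame(individual_id = ids, sex = sex, family = fam,
                         mother_id = mother, father_id = father,
                         is_founder = is.na(mother),
                         stringsAsFactors = FALSE)

  # first-order relationships, each unordered pair exactly once
  rel <- list()
  for (f in seq_len(n_families)) {
    kids <- ids[off_idx][off_fam == f]
    if (length(kids) == 0) next
    rel[[length(rel) + 1]] <- data.frame(
      id_a = c(rep(ids[mo_idx[f]], length(kids)), rep(ids[fa_idx[f]], length(kids))),
      id_b = rep(kids, 2), type = "PO", stringsAsFactors = FALSE)
    if (length(kids) >= 2) {
      cb <- t(utils::combn(kids, 2))
      rel[[length(rel) + 1]] <- data.frame(id_a = cb[, 1], id_b = cb[, 2],
                                           type = "FS", stringsAsFactors = FALSE)
    }
  }
  relationships <- if (length(rel)) do.call(rbind, rel) else
    data.frame(id_a = character(), id_b = character(), type = character())

  structure(list(pedigree = pedigree, relationships = relationships,
                 genotypes = G, allele_freqs = allele_freqs, panel = panel,
                 coords = NULL, crossings = NULL, kernel = NULL, seed = seed),
            class = "synthetic_truth")
}

# one vectorised rejection-sampling pass: settle `pending` individuals
# from their origin points; returns accepted coordinates and crossings
.settle_batch <- function(origin, meanlog, sdlog, aversion, rivers, extent,
                          max_retries) {
  n <- nrow(origin)
  res <- matrix(NA_real_, n, 2)
  crossings <- integer(n)
  pending <- seq_len(n)
  tries <- 0L
  while (length(pending) > 0) {
    tries <- tries + 1L
    if (tries > max_retries)
      stop("settlement failed after ", max_retries,
           " retries (aversion/geometry make settlement impossible)")
    m <- length(pending)
    d <- stats::rlnorm(m, meanlog[pending], sdlog[pending]) * 1000  # metres
    th <- stats::runif(m, 0, 2 * pi)
    prop <- origin[pending, , drop = FALSE] + cbind(d * cos(th), d * sin(th))
    inside <- if (is.null(extent)) rep(TRUE, m) else
      prop[, 1] >= extent[1] & prop[, 1] <= extent[2] &
      prop[, 2] >= extent[3] & prop[, 2] <= extent[4]
    ncross <- integer(m)
    if (length(rivers$rivers) > 0 && any(inside)) {
      ncross[inside] <- .rivers_crossed_batch(
        origin[pending[inside], , drop = FALSE],
        prop[inside, , drop = FALSE], rivers)
    }
    averse_reject <- ncross >= 1 &
      stats::runif(m) < aversion[pending]
    accept <- inside & !averse_reject
    idx <- pending[accept]
    res[idx, ] <- prop[accept, , drop = FALSE]
    crossings[idx] <- ncross[accept]
    pending <- pending[!accept]
  }
  list(coords = res, crossings = crossings)
}

#' Place mothers and settle dispersing individuals on the landscape
#'
#' Mothers are placed uniformly over the extent inset by
#' `mother_margin_m` (so that settlement of their kin is rarely clipped
#' by the study boundary). Fathers and offspring settle at a distance
#' drawn from their sex's kernel in a uniform direction from the mother;
#' a proposal is redrawn with probability equal to the sex's crossing
#' aversion whenever the straight mother-to-proposal segment crosses at
#' least one river, and always when it falls outside the extent. True
#' per-dispersal crossing counts are logged.
#'
#' @param truth a [generate_population()] result.
#' @param rivers a [river_set()] (its extent bounds settlement).
#' @param kernel a [dispersal_kernel_spec()].
#' @param seed integer seed.
#' @param mother_margin_m inset of the mother-placement region, metres.
#' @param max_retries bounded-retry limit per settlement pass.
#' @return `truth` with `$coords` (matrix, rownames = individual ids),
#'   `$crossings` (per-dispersal log) and `$kernel` filled.
#' @export
disperse_and_settle <- function(truth, rivers, kernel = dispersal_kernel_spec(),
                                seed = 1L, mother_margin_m = 50e3,
                                max_retries = 1000L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(rivers, "river_set"),
            inherits(kernel, "dispersal_kernel_spec"))
  set.seed(seed)
  ped <- truth$pedigree
  extent <- rivers$extent
  if (is.null(extent)) stop("river set carries no extent; settlement unbounded")
  n <- nrow(ped)
  coords <- matrix(NA_real_, n, 2, dimnames = list(ped$individual_id, NULL))

  mo <- which(ped$is_founder & ped$sex == "female")
  mm <- min(mother_margin_m, 0.45 * (extent[2] - extent[1]),
            0.45 * (extent[4] - extent[3]))
  coords[mo, 1] <- stats::runif(length(mo), extent[1] + mm, extent[2] - mm)
  coords[mo, 2] <- stats::runif(length(mo), extent[3] + mm, extent[4] - mm)

  disp <- which(!(ped$is_founder & ped$sex == "female"))
  mother_of_family <- ped$individual_id[mo][match(ped$family[disp], ped$family[mo])]
  origin_id <- ifelse(ped$is_founder[disp], mother_of_family, ped$mother_id[disp])
  origin <- coords[origin_id, , drop = FALSE]
  male <- ped$sex[disp] == "male"
  meanlog <- ifelse(male, kernel$male$meanlog, kernel$female$meanlog)
  sdlog <- ifelse(male, kernel$male$sdlog, kernel$female$sdlog)
  aversion <- ifelse(male, kernel$male_crossing_aversion,
                     kernel$female_crossing_aversion)
  st <- .settle_batch(origin, meanlog, sdlog, aversion, rivers, extent,
                      max_retries)
  coords[disp, ] <- st$coords

  d_km <- sqrt(rowSums((st$coords - origin)^2)) / 1000
  truth$coords <- coords
  truth$crossings <- data.frame(individual_id = ped$individual_id[disp],
                                sex = ped$sex[disp],
                                origin_id = origin_id,
                                distance_km = d_km,
                                n_crossed = st$crossings,
                                stringsAsFactors = FALSE)
  truth$kernel <- kernel
  truth$rivers <- rivers
  truth
}

#' Draw noisy replicated fecal-sample genotypes from the truth
#'
#' Every individual yields at least one sample. Sample coordinates are
#' the true coordinate plus isotropic Gaussian noise; each allele call
#' flips to the locus's other allele independently with `error_rate`;
#' each locus call is dropped with `missing_rate`. Y markers amplify
#' only in males (subject to dropout), X markers in both sexes.
#'
#' @param truth a settled [synthetic_truth] (coordinates present).
#' @param samples_per_individual fixed count or `function(n)`; default
#'   `1 + rpois(n, 0.9)` (about 1.9 samples per individual, as seen in
#'   multi-year non-invasive collections).
#' @param error_rate per-allele substitution probability (default 0.01).
#' @param missing_rate per-locus dropout probability (default 0.03).
#' @param jitter_sd isotropic SD of sample scatter, metres (default
#'   2000; within-range movement between depositions).
#' @param marker_dropout per-marker amplification failure rate for the
#'   Y/X sexing loci (default 0.05).
#' @param seed integer seed.
#' @return object of class `sample_set`: `meta` (sample_id,
#'   true_individual_id, x, y), `sex_markers` (0/1 matrix, Y1..Y4 and
#'   X1..X3), `geno` (dosage matrix with `NA` missing), `panel`.
#' @export
sample_genotypes <- function(truth, samples_per_individual = NULL,
                             error_rate = 0.01, missing_rate = 0.03,
                             jitter_sd = 2000, marker_dropout = 0.05,
                             seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.null(truth$coords)) stop("truth has no coordinates; run disperse_and_settle first")
  set.seed(seed)
  if (is.null(samples_per_individual))
    samples_per_individual <- function(n) 1 + stats::rpois(n, 0.9)
  ped <- truth$pedigree
  n_ind <- nrow(ped)
  k <- if (is.function(samples_per_individual))
    samples_per_individual(n_ind) else rep(samples_per_individual, n_ind)
  k <- pmax(as.integer(k), 1L)
  idx <- rep(seq_len(n_ind), k)
  n_s <- length(idx)
  n_loci <- ncol(truth$genotypes)

  g <- truth$genotypes[idx, , drop = FALSE]
  # per-allele substitution on the dosage scale
  if (error_rate > 0) {
    alt_to_ref <- stats::rbinom(length(g), g, error_rate)
    ref_to_alt <- stats::rbinom(length(g), 2L - g, error_rate)
    g <- g - alt_to_ref + ref_to_alt
  }
  if (missing_rate > 0)
    g[stats::runif(length(g)) < missing_rate] <- NA_integer_

  male <- ped$sex[idx] == "male"
  Y <- matrix(0L, n_s, 4, dimnames = list(NULL, paste0("Y", 1:4)))
  Y[male, ] <- stats::rbinom(sum(male) * 4, 1, 1 - marker_dropout)
  X <- matrix(stats::rbinom(n_s * 3, 1, 1 - marker_dropout), n_s, 3,
              dimnames = list(NULL, paste0("X", 1:3)))

  xy <- truth$coords[idx, , drop = FALSE]
  if (jitter_sd > 0)
    xy <- xy + matrix(stats::rnorm(2 * n_s, 0, jitter_sd), n_s, 2)

  meta <- data.frame(sample_id = sprintf("S%05d", seq_len(n_s)),
                     true_individual_id = ped$individual_id[idx],
                     x = xy[, 1], y = xy[, 2], year = NA_integer_,
                     stringsAsFactors = FALSE)
  rownames(g) <- meta$sample_id
  structure(list(meta = meta, sex_markers = cbind(Y, X), geno = g,
                 panel = truth$panel, seed = seed),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> ", nrow(x$meta), " samples, ", ncol(x$geno),
      " autosomal loci, ", sum(is.na(x$geno)), " missing calls\n", sep = "")
  invisible(x)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", nrow(x$pedigree), " individuals (",
      sum(x$pedigree$is_founder), " founders), ", ncol(x$genotypes),
      " loci; coordinates ", if (is.null(x$coords)) "absent" else "present",
      "\n", sep = "")
  invisible(x)
}
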