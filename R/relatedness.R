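#' Pairwise relatedness and first-order dyads
#'
#' Relatedness is estimated with the Lynch & Ritland (1999) regression
#' estimator: per locus, with one individual as reference,
#'
#' \deqn{r_x = \frac{p_a(\delta_{bc}+\delta_{bd}) +
#'   p_b(\delta_{ac}+\delta_{ad}) - 4 p_a p_b}
#'   {(1+\delta_{ab})(p_a+p_b) - 4 p_a p_b}}
#'
#' where the reference genotype carries alleles \eqn{a, b} with
#' population frequencies \eqn{p_a, p_b} and the partner carries
#' \eqn{c, d}. Loci are combined with the published weights
#' \eqn{w_x = ((1+\delta_{ab})(p_a+p_b) - 4 p_a p_b)/(2 p_a p_b)} and the
#' estimate is averaged over the two reference orderings, the convention
#' of the estimator's standard implementations. Pairs with estimated
#' \eqn{r} above a threshold (default 0.4) are taken as first-order
#' dyads (parent-offspring or full siblings, expected \eqn{r = 0.5}).
#'
#' @name relatedness_dyads
NULL

#' Empirical allele frequencies from consensus genotypes
#'
#' @param individuals an `individual_set`, or a dosage matrix.
#' @return list with `p_alt` (named per-locus alternate-allele
#'   frequency over non-missing calls) and `retained` (polymorphic loci
#'   with at least one call; only these enter relatedness estimation).
#' @export
estimate_allele_frequencies <- function(individuals) {
  G <- if (inherits(individuals, "individual_set")) individuals$geno else individuals
  if (nrow(G) < 2) stop("need at least 2 individuals")
  p <- colMeans(G, na.rm = TRUE) / 2
  n_called <- colSums(!is.na(G))
  retained <- colnames(G)[n_called > 0 & p > 0 & p < 1 & !is.nan(p)]
  dropped <- setdiff(colnames(G), retained)
  if (length(dropped))
    message(length(dropped), " monomorphic/empty locus(es) excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  list(p_alt = p[retained], retained = retained)
}

# Vectorised per-locus LR terms with x as reference.
# gx, gy: dosage matrices (pairs x loci) over retained loci; p: alt freq.
# Returns num = N_x / (2 pa pb), den = D_x / (2 pa pb) summed over loci.
.lr_half <- function(gx, gy, p) {
  q <- 1 - p
  pm <- matrix(p, nrow(gx), ncol(gx), byrow = TRUE)
  qm <- 1 - pm
  s_alt <- gy          # partner's count of alternate alleles
  s_ref <- 2 - gy
  het <- gx == 1
  pa <- ifelse(gx == 0, qm, ifelse(het, qm, pm))  # allele a = ref unless hom alt
  pb <- ifelse(gx == 0, qm, ifelse(het, pm, pm))
  sa <- ifelse(gx == 0, s_ref, ifelse(het, s_ref, s_alt))
  sb <- ifelse(gx == 0, s_ref, ifelse(het, s_alt, s_alt))
  dab <- ifelse(het, 0, 1)
  num <- pa * sb + pb * sa - 4 * pa * pb
  den <- (1 + dab) * (pa + pb) - 4 * pa * pb
  w <- 2 * pa * pb
  ok <- !is.na(gx) & !is.na(gy)
  num[!ok] <- 0; den[!ok] <- 0; w[!ok] <- 1
  list(num = rowSums(num / w), den = rowSums(den / w), shared = rowSums(ok))
}

# Batch LR estimates for index pairs (i, j) into dosage matrix G.
.lr_pairs <- function(G, p_alt, i_idx, j_idx, min_shared_loci = 40,
                      chunk = 20000L) {
  loci <- names(p_alt)
  G <- G[, loci, drop = FALSE]
  n <- length(i_idx)
  r <- rep(NA_real_, n)
  shared <- integer(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    gx <- G[i_idx[s:e], , drop = FALSE]
    gy <- G[j_idx[s:e], , drop = FALSE]
    hx <- .lr_half(gx, gy, p_alt)
    hy <- .lr_half(gy, gx, p_alt)
    r[s:e] <- (hx$num / hx$den + hy$num / hy$den) / 2
    shared[s:e] <- hx$shared
  }
  r[shared < min_shared_loci] <- NA_real_
  list(r = r, shared = shared)
}

#' Lynch-Ritland relatedness between two genotypes
#'
#' Weighted multilocus estimate averaged over both reference orderings;
#' loci missing in either genotype are skipped.
#'
#' @param gx,gy named dosage vectors.
#' @param freqs result of [estimate_allele_frequencies()].
#' @param min_shared_loci minimum shared non-missing loci for a valid
#'   estimate (default 40); below it `NA` is returned.
#' @return relatedness estimate (unbounded; 0 for unrelated, 0.5 for
#'   first-order kin in expectation).
#' @export
lynch_ritland_r <- function(gx, gy, freqs, min_shared_loci = 40) {
  G <- rbind(gx, gy)
  .lr_pairs(G, freqs$p_alt, 1L, 2L, min_shared_loci)$r
}

#' Build annotated first-order dyads
#'
#' All unordered pairs of sexed individuals with estimated relatedness
#' strictly above `r_threshold` become dyads, annotated with sex class
#' (MM/FF/MF), centre-to-centre distance, dispersal angle against the
#' reference line, direction class, and rivers crossed (odd parity).
#' Pairs of coincident centres get `NA` angle and direction but keep
#' distance and crossing count.
#'
#' @param individuals an `individual_set`.
#' @param rivers a [river_set()] (supplies the reference azimuth).
#' @param freqs allele frequencies; estimated from `individuals` when
#'   `NULL`.
#' @param r_threshold first-order threshold (default 0.4).
#' @param min_shared_loci minimum shared loci per pair (default 40).
#' @return data.frame of class `dyad_table`: `id_a`, `id_b`, `class`,
#'   `r`, `distance_km`, `angle_deg`, `direction`, `rivers_crossed`.
#' @export
build_dyads <- function(individuals, rivers, freqs = NULL, r_threshold = 0.4,
                        min_shared_loci = 40) {
  stopifnot(inherits(individuals, "individual_set"), inherits(rivers, "river_set"))
  meta <- individuals$meta[!individuals$meta$sex_ambiguous, , drop = FALSE]
  if (nrow(meta) < 2) stop("need at least 2 sexed individuals")
  if (is.null(freqs)) freqs <- estimate_allele_frequencies(individuals)
  idx <- match(meta$individual_id, rownames(individuals$geno))
  pr <- t(utils::combn(seq_len(nrow(meta)), 2))
  lr <- .lr_pairs(individuals$geno, freqs$p_alt, idx[pr[, 1]], idx[pr[, 2]],
                  min_shared_loci)
  sel <- which(!is.na(lr$r) & lr$r > r_threshold)
  ia <- pr[sel, 1]; ib <- pr[sel, 2]
  p1 <- cbind(meta$x[ia], meta$y[ia])
  p2 <- cbind(meta$x[ib], meta$y[ib])
  d_km <- sqrt(rowSums((p2 - p1)^2)) / 1000
  nonzero <- d_km > 0
  ang <- rep(NA_real_, length(sel))
  if (any(nonzero)) {
    az <- rivers$reference_azimuth_deg
    if (is.null(az)) stop("river set has no reference azimuth")
    u <- c(sin(az * pi / 180), cos(az * pi / 180))
    dv <- p2 - p1
    cosang <- abs(dv[, 1] * u[1] + dv[, 2] * u[2]) / sqrt(rowSums(dv^2))
    ang[nonzero] <- acos(pmin(pmax(cosang[nonzero], -1), 1)) * 180 / pi
  }
  ncross <- rep(0L, length(sel))
  if (length(sel) && length(rivers$rivers) > 0 && any(nonzero)) {
    ncross[nonzero] <- .rivers_crossed_batch(p1[nonzero, , drop = FALSE],
                                             p2[nonzero, , drop = FALSE], rivers)
  }
  sexpair <- cbind(meta$sex[ia], meta$sex[ib])
  cls <- ifelse(sexpair[, 1] == "male" & sexpair[, 2] == "male", "MM",
         ifelse(sexpair[, 1] == "female" & sexpair[, 2] == "female", "FF", "MF"))
  out <- data.frame(id_a = meta$individual_id[ia], id_b = meta$individual_id[ib],
                    class = cls, r = lr$r[sel], distance_km = d_km,
                    angle_deg = ang, direction = classify_direction(ang),
                    rivers_crossed = ncross, stringsAsFactors = FALSE)
  class(out) <- c("dyad_table", "data.frame")
  out
}
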