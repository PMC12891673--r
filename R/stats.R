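#' Hypothesis tests for sex-specific barrier effects
#'
#' Wrappers around the standard tests of the barrier analysis, each
#' returning a uniform `test_report`, plus the Monte-Carlo
#' random-direction null for female crossing rates and the
#' multiply-sampled-individual crossing table.
#'
#' @name barrier_stats
NULL

test_report <- function(statistic_name, statistic, p_value, df = NA_real_,
                        alternative = "two.sided", ...) {
  structure(list(statistic_name = statistic_name, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 alternative = alternative, ...),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat("<test_report> ", x$statistic_name, " = ", format(x$statistic),
      if (!is.na(x$df)) paste0(", df = ", format(x$df)) else "",
      ", p = ", format(x$p_value), " (", x$alternative, ")\n", sep = "")
  invisible(x)
}

#' Yates-corrected chi-square comparison of two crossing proportions
#'
#' @param n_crossed_a,n_a crossings and total dyads in group a.
#' @param n_crossed_b,n_b same for group b.
#' @return `test_report` with the chi-square statistic (1 df).
#' @export
crossing_proportion_test <- function(n_crossed_a, n_a, n_crossed_b, n_b) {
  if (n_a <= 0 || n_b <= 0) stop("group totals must be positive")
  if (n_crossed_a > n_a || n_crossed_b > n_b) stop("crossings exceed totals")
  ht <- stats::prop.test(c(n_crossed_a, n_crossed_b), c(n_a, n_b),
                         correct = TRUE)
  test_report("chi_squared_yates", ht$statistic, ht$p.value, df = ht$parameter,
              proportions = unname(ht$estimate),
              counts = c(n_crossed_a, n_a, n_crossed_b, n_b))
}

#' Fisher's exact test with conditional-MLE odds ratio
#'
#' Exact two-sided p (summing fixed-margin table probabilities not
#' larger than the observed one), conditional maximum-likelihood odds
#' ratio and exact 95% CI from the noncentral hypergeometric likelihood.
#'
#' @param table 2x2 integer matrix (e.g. sex by crossed status).
#' @return `test_report` with `odds_ratio`, `ci95`.
#' @export
fisher_exact_or <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(test_report("fisher_exact", NA_real_, 1,
                       odds_ratio = NA_real_, ci95 = c(NA_real_, NA_real_),
                       note = "degenerate margin: odds ratio undefined"))
  }
  ht <- stats::fisher.test(table)
  test_report("fisher_exact", ht$estimate, ht$p.value,
              odds_ratio = unname(ht$estimate), ci95 = as.numeric(ht$conf.int))
}

#' One-way ANOVA of dyad distance on sex class, with Tukey HSD
#'
#' @param dyads a `dyad_table` (needs `distance_km`, `class`).
#' @return `test_report` with F statistic, df pair, and `tukey`
#'   data.frame of pairwise adjusted comparisons.
#' @export
distance_anova_tukey <- function(dyads) {
  keep <- !is.na(dyads$distance_km) & !is.na(dyads$class)
  d <- dyads[keep, , drop = FALSE]
  tb <- table(d$class)
  use <- names(tb)[tb >= 2]
  if (length(use) < length(tb))
    warning("class(es) with < 2 dyads excluded from ANOVA: ",
            paste(setdiff(names(tb), use), collapse = ", "))
  if (length(use) < 2) stop("need at least 2 classes with >= 2 dyads")
  d <- d[d$class %in% use, , drop = FALSE]
  d$class <- factor(d$class)
  fit <- stats::aov(distance_km ~ class, data = d)
  an <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit)$class
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  test_report("anova_F", an$`F value`[1], an$`Pr(>F)`[1],
              df = c(an$Df[1], an$Df[2]),
              group_means = tapply(d$distance_km, d$class, mean),
              group_sd = tapply(d$distance_km, d$class, stats::sd),
              tukey = tukey)
}

#' One-proportion score z-test of direction D1 against p = 0.5
#'
#' Uncorrected score test; `z^2` equals the corresponding 1-df
#' chi-square, which is how such tests are often printed.
#'
#' @param n_D1 dyads classified D1.
#' @param n_total dyads with a defined direction.
#' @param alternative `"two.sided"` or `"less"` (deficit of D1).
#' @return `test_report` with z (and `chi_squared = z^2`).
#' @export
direction_proportion_test <- function(n_D1, n_total,
                                      alternative = c("two.sided", "less")) {
  alternative <- match.arg(alternative)
  if (n_total < 1) stop("n_total must be >= 1")
  phat <- n_D1 / n_total
  z <- (phat - 0.5) / sqrt(0.25 / n_total)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              less = stats::pnorm(z))
  test_report("z_one_proportion", z, p, alternative = alternative,
              chi_squared = z^2, proportion = phat, n = n_total)
}

#' Two-sample Kolmogorov-Smirnov comparison of dispersal-angle sets
#'
#' Optionally restricted to long dispersals (distance strictly above
#' `min_distance_km`), which are the ones likely to force a crossing
#' choice.
#'
#' @param angles_a,angles_b angle vectors (degrees).
#' @param distances_a,distances_b matching distance vectors (km); only
#'   needed when filtering.
#' @param min_distance_km keep dispersals with distance above this
#'   (default 0 = all).
#' @return `test_report` with the KS D statistic.
#' @export
angle_distribution_test <- function(angles_a, angles_b,
                                    distances_a = NULL, distances_b = NULL,
                                    min_distance_km = 0) {
  if (min_distance_km > 0) {
    if (is.null(distances_a) || is.null(distances_b))
      stop("distance filtering requested but distances not supplied")
    angles_a <- angles_a[distances_a > min_distance_km]
    angles_b <- angles_b[distances_b > min_distance_km]
  }
  angles_a <- angles_a[!is.na(angles_a)]
  angles_b <- angles_b[!is.na(angles_b)]
  if (length(angles_a) == 0 || length(angles_b) == 0)
    stop("no angles left after filtering at ", min_distance_km,
         " km; lower min_distance_km or check the dyad set")
  ht <- suppressWarnings(stats::ks.test(angles_a, angles_b))
  test_report("ks_D", ht$statistic, ht$p.value,
              n = c(length(angles_a), length(angles_b)),
              min_distance_km = min_distance_km)
}

#' Random-direction Monte-Carlo null for crossing proportions
#'
#' Each replicate draws `n_dyads` start points with replacement from the
#' pool of known disperser coordinates, assigns each exactly one of the
#' observed dispersal distances (a permutation: drawn without
#' replacement) and a direction uniform on `[0, 360)` degrees, and
#' records the proportion of simulated dispersals crossing at least one
#' river. The observed proportion is compared against the replicate
#' distribution by a one-sided one-sample t-test (mean of the null
#' greater than observed) and against its empirical 2.5th percentile
#' (type-7 interpolation).
#'
#' @param start_pool two-column matrix of disperser coordinates (metres).
#' @param observed_distances_km observed dyad distances (km); the
#'   without-replacement draw uses each exactly once per replicate.
#' @param rivers a [river_set()].
#' @param n_dyads dispersals per replicate; must equal
#'   `length(observed_distances_km)`.
#' @param reps number of replicates (default 1000).
#' @param seed integer seed.
#' @param observed_proportion observed crossing proportion to test
#'   against (may be `NULL`: summaries only).
#' @param keep_first_replicate retain the first replicate's draws (for
#'   diagnostics).
#' @return object of class `null_sim`.
#' @export
simulate_null_crossings <- function(start_pool, observed_distances_km, rivers,
                                    n_dyads = length(observed_distances_km),
                                    reps = 1000, seed = 1L,
                                    observed_proportion = NULL,
                                    keep_first_replicate = FALSE) {
  start_pool <- rbind(start_pool)
  if (nrow(start_pool) == 0) stop("start pool is empty")
  if (n_dyads != length(observed_distances_km))
    stop("n_dyads (", n_dyads, ") must equal the number of observed distances (",
         length(observed_distances_km), ")")
  set.seed(seed)
  props <- numeric(reps)
  first <- NULL
  chunk <- max(1L, floor(2e6 / max(n_dyads, 1)))
  r0 <- 1L
  while (r0 <= reps) {
    r1 <- min(r0 + chunk - 1L, reps)
    nb <- r1 - r0 + 1L
    m <- nb * n_dyads
    starts <- start_pool[sample.int(nrow(start_pool), m, replace = TRUE), ,
                         drop = FALSE]
    # one permutation of the observed distances per replicate
    dists <- as.vector(vapply(seq_len(nb),
                              function(i) sample(observed_distances_km),
                              numeric(n_dyads))) * 1000
    th <- stats::runif(m, 0, 2 * pi)
    ends <- starts + cbind(dists * cos(th), dists * sin(th))
    crossed <- if (length(rivers$rivers) == 0) integer(m) else
      .rivers_crossed_batch(starts, ends, rivers)
    props[r0:r1] <- colMeans(matrix(crossed >= 1, n_dyads, nb))
    if (keep_first_replicate && r0 == 1L)
      first <- list(starts = starts[seq_len(n_dyads), , drop = FALSE],
                    distances_km = dists[seq_len(n_dyads)] / 1000,
                    crossed = crossed[seq_len(n_dyads)])
    r0 <- r1 + 1L
  }
  tt <- if (!is.null(observed_proportion) && stats::sd(props) > 0) {
    stats::t.test(props, mu = observed_proportion, alternative = "greater")
  } else NULL
  structure(list(replicate_proportions = props,
                 mean_proportion = mean(props),
                 lower_2p5_percentile = stats::quantile(props, 0.025,
                                                        names = FALSE, type = 7),
                 observed_proportion = observed_proportion,
                 t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 one_sided_p = if (is.null(tt)) NA_real_ else tt$p.value,
                 n_dyads_per_replicate = n_dyads, reps = reps, seed = seed,
                 first_replicate = first),
            class = "null_sim")
}

#' @export
print.null_sim <- function(x, ...) {
  cat("<null_sim> ", x$reps, " replicates of ", x$n_dyads_per_replicate,
      " dispersals: mean crossing proportion ",
      sprintf("%.3f", x$mean_proportion), ", 2.5th percentile ",
      sprintf("%.3f", x$lower_2p5_percentile), sep = "")
  if (!is.null(x$observed_proportion))
    cat("; observed ", sprintf("%.3f", x$observed_proportion),
        " (t = ", sprintf("%.2f", x$t_statistic), ", one-sided p = ",
        format.pval(x$one_sided_p), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Crossing status of multiply-sampled individuals, by sex
#'
#' An individual with at least two sampling locations counts as having
#' crossed when any unordered pair of its locations has at least one
#' river crossed (odd parity). Single-location individuals are excluded.
#'
#' @param individuals an `individual_set`.
#' @param rivers a [river_set()].
#' @return 2x2 integer matrix, rows `male`/`female`, columns
#'   `crossed`/`not_crossed`.
#' @export
multilocation_crossing_table <- function(individuals, rivers) {
  meta <- individuals$meta
  multi <- which(meta$n_samples >= 2 & !meta$sex_ambiguous)
  out <- matrix(0L, 2, 2, dimnames = list(c("male", "female"),
                                          c("crossed", "not_crossed")))
  if (length(multi) == 0) {
    warning("no multiply-sampled sexed individuals; table is empty")
    return(out)
  }
  for (i in multi) {
    loc <- unique(individuals$locations[[meta$individual_id[i]]])
    crossed <- FALSE
    if (nrow(loc) >= 2) {
      pr <- t(utils::combn(nrow(loc), 2))
      nc <- .rivers_crossed_batch(loc[pr[, 1], , drop = FALSE],
                                  loc[pr[, 2], , drop = FALSE], rivers)
      crossed <- any(nc >= 1)
    } else next  # duplicate coordinates only: no movement observed
    out[meta$sex[i], if (crossed) "crossed" else "not_crossed"] <-
      out[meta$sex[i], if (crossed) "crossed" else "not_crossed"] + 1L
  }
  out
}
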