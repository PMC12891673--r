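#' Full barrier analysis: configuration and orchestration
#'
#' [run_analysis()] chains individual identification, dyad construction,
#' the barrier hypothesis tests (crossing proportions, random-direction
#' null, multi-location Fisher table, distance ANOVA, direction and
#' angle tests) and per-sex spatial PCA into one machine-readable
#' report. Every stochastic stage derives its seed from the single
#' `seed` in the configuration, so identical inputs and seed give
#' byte-identical reports.
#'
#' @name pipeline_cli
NULL

#' Pipeline configuration
#'
#' Houses the thresholds of the analysis: a 12-allele mismatch tolerance
#' for individual identification, the first-order relatedness threshold
#' r > 0.4, the 25 km cut separating long dispersals, 1000 null
#' replicates, and a 0.05 significance level (stored for the summary
#' layer; the report always carries raw p-values).
#'
#' @param max_mismatch allele-mismatch tolerance (default 12).
#' @param min_comparable_loci minimum typed loci per sample (default 60).
#' @param r_threshold first-order relatedness threshold (default 0.4).
#' @param min_shared_loci minimum shared loci per pair (default 40).
#' @param long_dispersal_km long-dispersal cut for the angle KS test
#'   (default 25).
#' @param null_reps random-direction null replicates (default 1000).
#' @param spca_permutations Monte-Carlo permutations (default 999).
#' @param jitter_sd duplicate-coordinate jitter for the network, metres
#'   (default 1).
#' @param alpha significance threshold recorded in the report.
#' @param reference_azimuth_deg optional reference-line override.
#' @param seed integer master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(max_mismatch = 12, min_comparable_loci = 60,
                            r_threshold = 0.4, min_shared_loci = 40,
                            long_dispersal_km = 25, null_reps = 1000,
                            spca_permutations = 999, jitter_sd = 1,
                            alpha = 0.05, reference_azimuth_deg = NULL,
                            seed = 1L) {
  cfg <- list(max_mismatch = max_mismatch,
              min_comparable_loci = min_comparable_loci,
              r_threshold = r_threshold, min_shared_loci = min_shared_loci,
              long_dispersal_km = long_dispersal_km, null_reps = null_reps,
              spca_permutations = spca_permutations, jitter_sd = jitter_sd,
              alpha = alpha, reference_azimuth_deg = reference_azimuth_deg,
              seed = as.integer(seed))
  num <- unlist(cfg[c("max_mismatch", "min_comparable_loci", "r_threshold",
                      "min_shared_loci", "long_dispersal_km", "null_reps",
                      "spca_permutations", "alpha")])
  if (any(num <= 0)) stop("all thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         " (check the inputs and thresholds for this stage)", call. = FALSE))
}

#' Run the full barrier analysis
#'
#' @param samples a `sample_set` (from [read_genotypes()] or
#'   [sample_genotypes()]).
#' @param rivers a [river_set()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, writes `report.json`,
#'   `individuals.csv`, `dyads.csv`, per-sex sPCA score tables, and a
#'   genotype matrix with river-band region labels for external
#'   multivariate tooling (e.g. DAPC).
#' @return an `analysis_report` list.
#' @export
run_analysis <- function(samples, rivers, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(samples, "sample_set"), inherits(rivers, "river_set"))
  if (!is.null(config$reference_azimuth_deg))
    rivers$reference_azimuth_deg <- config$reference_azimuth_deg
  seed <- config$seed
  check_crs_overlap(samples, rivers)

  inds <- .stage("identify", cluster_samples(
    samples, max_mismatch = config$max_mismatch,
    min_comparable_loci = config$min_comparable_loci))
  dyads <- .stage("dyads", build_dyads(
    inds, rivers, r_threshold = config$r_threshold,
    min_shared_loci = config$min_shared_loci))

  sex_counts <- table(factor(inds$meta$sex, c("male", "female", "ambiguous")))
  dyad_counts <- table(factor(dyads$class, c("MM", "FF", "MF")))

  mm <- dyads[dyads$class == "MM", , drop = FALSE]
  ff <- dyads[dyads$class == "FF", , drop = FALSE]

  barrier <- .stage("barriers", {
    h1 <- if (nrow(mm) > 0 && nrow(ff) > 0)
      crossing_proportion_test(sum(mm$rivers_crossed >= 1), nrow(mm),
                               sum(ff$rivers_crossed >= 1), nrow(ff)) else NULL
    null_sim <- if (nrow(ff) > 0) {
      pool <- unique(rbind(
        as.matrix(inds$meta[match(ff$id_a, inds$meta$individual_id), c("x", "y")]),
        as.matrix(inds$meta[match(ff$id_b, inds$meta$individual_id), c("x", "y")])))
      simulate_null_crossings(pool, ff$distance_km, rivers,
                              reps = config$null_reps, seed = seed + 1L,
                              observed_proportion = mean(ff$rivers_crossed >= 1))
    } else NULL
    multiloc <- multilocation_crossing_table(inds, rivers)
    h2 <- if (length(unique(dyads$class)) >= 2) distance_anova_tukey(dyads) else NULL
    h3 <- if (nrow(mm) > 0 && any(!is.na(mm$direction)))
      direction_proportion_test(sum(mm$direction == "D1", na.rm = TRUE),
                                sum(!is.na(mm$direction)), "two.sided") else NULL
    h4 <- if (nrow(ff) > 0 && any(!is.na(ff$direction)))
      direction_proportion_test(sum(ff$direction == "D1", na.rm = TRUE),
                                sum(!is.na(ff$direction)), "less") else NULL
    ks_all <- if (nrow(mm) > 0 && nrow(ff) > 0)
      angle_distribution_test(mm$angle_deg, ff$angle_deg) else NULL
    ks_long <- if (any(mm$distance_km > config$long_dispersal_km) &&
                   any(ff$distance_km > config$long_dispersal_km))
      angle_distribution_test(mm$angle_deg, ff$angle_deg,
                              mm$distance_km, ff$distance_km,
                              min_distance_km = config$long_dispersal_km) else NULL
    list(h1_crossing_chisq = h1, null_simulation = null_sim,
         multilocation_table = multiloc,
         multilocation_fisher = if (sum(multiloc) > 0)
           fisher_exact_or(multiloc) else NULL,
         h2_distance_anova = h2, h3_male_direction = h3,
         h4_female_direction = h4, h4_ks_all = ks_all, h4_ks_long = ks_long)
  })

  spca_by_sex <- .stage("spca", {
    res <- list()
    for (sx in c("male", "female")) {
      sel <- inds$meta$sex == sx
      if (sum(sel) < 3) { res[[sx]] <- NULL; next }
      coords <- as.matrix(inds$meta[sel, c("x", "y")])
      net <- build_network(coords, jitter_sd = config$jitter_sd,
                           seed = seed + 2L)
      sp <- spca(inds$geno[sel, , drop = FALSE], net)
      mc <- global_local_tests(inds$geno[sel, , drop = FALSE], net,
                               n_permutations = config$spca_permutations,
                               seed = seed + 3L)
      res[[sx]] <- list(n = sum(sel), eigenvalues = sp$eigenvalues,
                        leading_moran_i = sp$moran_i[1],
                        pct_variance_axis1 =
                          100 * sp$axis_variance[1] / sum(sp$axis_variance),
                        global_p = mc$global_p, local_p = mc$local_p,
                        scores = sp$scores[, 1, drop = TRUE], coords = coords)
    }
    res
  })

  report <- structure(list(
    schema_version = "1.0",
    individuals = list(total = nrow(inds$meta),
                       males = unname(sex_counts[["male"]]),
                       females = unname(sex_counts[["female"]]),
                       sex_ambiguous = unname(sex_counts[["ambiguous"]]),
                       excluded_samples = length(inds$excluded_samples)),
    dyads = list(MM = unname(dyad_counts[["MM"]]),
                 FF = unname(dyad_counts[["FF"]]),
                 MF = unname(dyad_counts[["MF"]]),
                 total = nrow(dyads)),
    crossing_proportions = list(
      MM = if (nrow(mm)) mean(mm$rivers_crossed >= 1) else NA_real_,
      FF = if (nrow(ff)) mean(ff$rivers_crossed >= 1) else NA_real_),
    barrier = barrier,
    spca = lapply(spca_by_sex, function(s)
      s[c("n", "leading_moran_i", "pct_variance_axis1", "global_p", "local_p")]),
    provenance = list(config = unclass(config), seed = seed,
                      n_samples = nrow(samples$meta))),
    class = "analysis_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(report, file.path(out_dir, "report.json"))
    utils::write.csv(inds$meta, file.path(out_dir, "individuals.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(dyads), file.path(out_dir, "dyads.csv"),
                     row.names = FALSE)
    bands <- assign_bands(as.matrix(inds$meta[, c("x", "y")]), rivers)
    gm <- data.frame(individual_id = inds$meta$individual_id,
                     sex = inds$meta$sex, region = bands,
                     inds$geno, check.names = FALSE)
    utils::write.csv(gm, file.path(out_dir, "genotypes_regions.csv"),
                     row.names = FALSE)
    for (sx in names(spca_by_sex)) {
      s <- spca_by_sex[[sx]]
      utils::write.csv(
        data.frame(individual_id = inds$meta$individual_id[inds$meta$sex == sx],
                   x = s$coords[, 1], y = s$coords[, 2], pc1 = s$scores),
        file.path(out_dir, paste0("spca_scores_", sx, ".csv")),
        row.names = FALSE)
    }
  }
  report
}

#' Serialise an analysis report to JSON
#'
#' Writes with fixed numeric formatting so identical analyses give
#' byte-identical files.
#'
#' @param report an `analysis_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "test_report")) x <- unclass(x)
    if (inherits(x, "null_sim")) {
      x <- unclass(x)
      x$replicate_proportions <- NULL  # bulky; summaries retained
      x$first_replicate <- NULL
    }
    if (is.matrix(x)) return(list(dimnames = dimnames(x),
                                  values = as.data.frame(x)))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = 12, na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat("  individuals: ", x$individuals$total, " (", x$individuals$males, " M / ",
      x$individuals$females, " F)\n", sep = "")
  cat("  dyads: MM ", x$dyads$MM, ", FF ", x$dyads$FF, ", MF ", x$dyads$MF,
      "\n", sep = "")
  cp <- x$crossing_proportions
  cat("  crossing proportions: MM ", sprintf("%.3f", cp$MM), ", FF ",
      sprintf("%.3f", cp$FF), "\n", sep = "")
  if (!is.null(x$barrier$h1_crossing_chisq))
    cat("  H1 chi-square = ", sprintf("%.2f", x$barrier$h1_crossing_chisq$statistic),
        ", p = ", format.pval(x$barrier$h1_crossing_chisq$p_value), "\n", sep = "")
  if (!is.null(x$barrier$null_simulation))
    cat("  null simulation mean = ",
        sprintf("%.3f", x$barrier$null_simulation$mean_proportion),
        " (observed ", sprintf("%.3f", x$barrier$null_simulation$observed_proportion),
        ")\n", sep = "")
  for (sx in names(x$spca))
    cat("  sPCA ", sx, ": global p = ", x$spca[[sx]]$global_p,
        ", local p = ", x$spca[[sx]]$local_p, "\n", sep = "")
  invisible(x)
}
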