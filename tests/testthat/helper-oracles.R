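# Independent oracle implementations used to cross-check the package.
# Each transcribes the underlying definition in a separate code path
# (scalar loops, enumeration, dense sampling) and stays independent of
# the implementation it checks.

# --- geometry ---------------------------------------------------------

# parametric segment-segment intersection: proper crossing only
seg_seg_intersect_oracle <- function(a1, a2, b1, b2) {
  r <- a2 - a1; s <- b2 - b1
  denom <- r[1] * s[2] - r[2] * s[1]
  if (denom == 0) return(FALSE)
  t <- ((b1[1] - a1[1]) * s[2] - (b1[2] - a1[2]) * s[1]) / denom
  u <- ((b1[1] - a1[1]) * r[2] - (b1[2] - a1[2]) * r[1]) / denom
  t > 0 && t < 1 && u > 0 && u < 1
}

seg_poly_oracle <- function(p1, p2, poly) {
  n <- 0L
  for (j in seq_len(nrow(poly) - 1))
    if (seg_seg_intersect_oracle(p1, p2, poly[j, ], poly[j + 1, ])) n <- n + 1L
  n
}

# side-of-river oracle for x-monotone rivers spanning the x-range:
# linear interpolation of the river's y at a given x
river_y_at <- function(poly, x) stats::approx(poly[, 1], poly[, 2], xout = x)$y

# crossed iff endpoints lie on opposite sides (strictly) of the river
crossed_oracle <- function(p1, p2, poly) {
  s1 <- p1[2] > river_y_at(poly, p1[1])
  s2 <- p2[2] > river_y_at(poly, p2[1])
  s1 != s2
}

rivers_crossed_oracle <- function(p1, p2, rivers) {
  sum(vapply(rivers$rivers, function(rv) crossed_oracle(p1, p2, rv$polyline),
             logical(1)))
}

# --- Lynch-Ritland, symbol-by-symbol on allele characters -------------

# gx, gy: length-2 character vectors of alleles; p: named freq per allele
lr_locus_oracle <- function(gx, gy, p) {
  a <- gx[1]; b <- gx[2]; cc <- gy[1]; d <- gy[2]
  pa <- p[[a]]; pb <- p[[b]]
  dlt <- function(u, v) as.numeric(u == v)
  num <- pa * (dlt(b, cc) + dlt(b, d)) + pb * (dlt(a, cc) + dlt(a, d)) -
    4 * pa * pb
  den <- (1 + dlt(a, b)) * (pa + pb) - 4 * pa * pb
  w <- den / (2 * pa * pb)
  list(r = num / den, w = w)
}

# multilocus weighted estimate averaged over both reference orderings;
# geno_x/geno_y: list of length-2 character vectors (or NULL = missing)
lr_oracle <- function(geno_x, geno_y, freq_list) {
  half <- function(gx, gy) {
    sw <- 0; swr <- 0
    for (l in seq_along(gx)) {
      if (is.null(gx[[l]]) || is.null(gy[[l]])) next
      o <- lr_locus_oracle(gx[[l]], gy[[l]], freq_list[[l]])
      sw <- sw + o$w
      swr <- swr + o$w * o$r
    }
    swr / sw
  }
  (half(geno_x, geno_y) + half(geno_y, geno_x)) / 2
}

# dosage matrix row -> list of allele-character pairs
dosage_to_alleles <- function(g, panel) {
  lapply(seq_along(g), function(j) {
    if (is.na(g[j])) return(NULL)
    switch(g[j] + 1L,
           c(panel$a1[j], panel$a1[j]),
           c(panel$a1[j], panel$a2[j]),
           c(panel$a2[j], panel$a2[j]))
  })
}

freqs_to_list <- function(p_alt, panel) {
  lapply(seq_along(p_alt), function(j) {
    l <- list()
    l[[panel$a1[j]]] <- 1 - p_alt[[j]]
    l[[panel$a2[j]]] <- p_alt[[j]]
    l
  })
}

# --- classical tests, formula level -----------------------------------

chisq_yates_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((abs(tab - E) - pmin(0.5, abs(tab - E)))^2 / E)
}

ks_D_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), 0)
  Fb <- vapply(pts, function(t) mean(b <= t), 0)
  max(abs(Fa - Fb))
}

z_prop_oracle <- function(k, n, p0 = 0.5) (k / n - p0) / sqrt(p0 * (1 - p0) / n)

anova_oracle <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  ss_b <- 0; ss_w <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_b <- ss_b + length(v) * (mean(v) - gm)^2
    ss_w <- ss_w + sum((v - mean(v))^2)
  }
  df1 <- length(unique(groups)) - 1
  df2 <- length(values) - length(unique(groups))
  F <- (ss_b / df1) / (ss_w / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE),
       msw = ss_w / df2, df2 = df2)
}

tukey_oracle <- function(values, groups) {
  an <- anova_oracle(values, groups)
  gs <- sort(unique(as.character(groups)))
  k <- length(gs)
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    vi <- values[groups == gs[i]]; vj <- values[groups == gs[j]]
    diff <- mean(vj) - mean(vi)
    se <- sqrt(an$msw / 2 * (1 / length(vi) + 1 / length(vj)))
    p <- stats::ptukey(abs(diff) / se, k, an$df2, lower.tail = FALSE)
    out[[paste0(gs[j], "-", gs[i])]] <- c(diff = diff, p_adj = p)
  }
  out
}

# exact fixed-margin enumeration of the Fisher two-sided p
# (tables at least as extreme = probability not above the observed
# table's, with the customary relative slack on the comparison)
fisher_p_enum_oracle <- function(tab) {
  m <- rowSums(tab); nn <- colSums(tab); N <- sum(tab)
  kr <- max(0, nn[1] - m[2]):min(m[1], nn[1])
  prob <- vapply(kr, function(k)
    choose(m[1], k) * choose(m[2], nn[1] - k) / choose(N, nn[1]), 0)
  obs <- prob[kr == tab[1, 1]]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

binom_tail_oracle <- function(k, n, p = 0.5) sum(stats::dbinom(0:k, n, p))

# --- Delaunay, brute force --------------------------------------------

# edge (i, j) is Delaunay iff some circumcircle through i and j and a
# third point contains no other point (general-position point sets)
brute_delaunay_edges <- function(pts) {
  n <- nrow(pts)
  circum <- function(a, b, c) {
    ax <- pts[a, 1]; ay <- pts[a, 2]; bx <- pts[b, 1]; by <- pts[b, 2]
    cx <- pts[c, 1]; cy <- pts[c, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  edges <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- FALSE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      cc <- circum(i, j, k)
      if (is.null(cc)) next
      d2 <- sqrt((pts[, 1] - cc[1])^2 + (pts[, 2] - cc[2])^2)
      if (all(d2[-c(i, j, k)] > cc[3] * (1 + 1e-9))) { ok <- TRUE; break }
    }
    if (ok) edges <- rbind(edges, c(i, j))
  }
  edges
}

edge_key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))

# --- shared fixtures ---------------------------------------------------

make_straight_rivers <- function(n = 3, spacing = 75e3, extent = c(0, 400e3, 0, 300e3)) {
  generate_landscape(landscape_spec(extent = extent, n_rivers = n,
                                    river_spacing = spacing,
                                    meander_amplitude = 0), seed = 1)
}

small_noisy_dataset <- function(seed = 1, n_families = 40) {
  ls1 <- generate_landscape(landscape_spec(), seed = seed)
  tr <- generate_population(n_families, 2, seed = seed)
  tr <- disperse_and_settle(tr, ls1, seed = seed + 1)
  ss <- sample_genotypes(tr, seed = seed + 2)
  list(rivers = ls1, truth = tr, samples = ss)
}
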