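# Remaining pieces of the association battery: Mantel test, one-way ANOVA
# with Fisher's LSD letters, Mann-Whitney differential gene counts,
# genome-distance vs geography correlation, and BH correction.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `p_adj(i) = min_{j >= rank(i)} (m/j) p_(j)`,
#' capped at 1, original order preserved.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance
#' from simultaneous row/column permutations of the second matrix:
#' `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)`.
#'
#' @param d1,d2 `dist` objects or square matrices in the same sample order.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list with `r` and `p`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = NULL) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop("distance matrices differ in size")
  if (!is.null(seed)) set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(m1), stats::as.dist(m2),
                      method = "pearson", permutations = n_perm)
  list(r = unname(mt$statistic), p = unname(mt$signif))
}

#' One-way ANOVA with Fisher's LSD compact letter display
#'
#' One-way ANOVA followed by all pairwise t-tests using the pooled error
#' mean square (`df = N - k`), BH correction across the pairs, and a
#' compact letter display at `p_adj < alpha_adj`: groups sharing a letter
#' are not significantly different.
#'
#' @param y numeric response.
#' @param group factor or character grouping, aligned with `y`.
#' @param alpha_adj significance threshold on adjusted pairwise p-values
#'   (default 0.1).
#' @return list: `anova_p`, `pairs` (data.frame `group1`, `group2`, `p`,
#'   `p_adj`), `letters` (data.frame `group`, `n`, `mean`, `letters`,
#'   ordered by decreasing mean).
#' @export
anova_lsd_letters <- function(y, group, alpha_adj = 0.1) {
  ok <- !is.na(y) & !is.na(group)
  y <- y[ok]; group <- droplevels(factor(group[ok]))
  sizes <- table(group)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("group(s) with < 2 samples dropped: ", paste(small, collapse = ", "))
    keep <- !(group %in% small)
    y <- y[keep]; group <- droplevels(group[keep])
    sizes <- table(group)
  }
  k <- nlevels(group)
  if (k < 2L) stop("need at least 2 groups with >= 2 samples")
  fit <- stats::aov(y ~ group)
  an <- summary(fit)[[1L]]  # row 1 = group, row 2 = residuals
  mse <- an[["Mean Sq"]][2L]
  dfe <- an[["Df"]][2L]
  means <- tapply(y, group, mean)
  if (k == 1L || mse == 0) stop("degenerate ANOVA")
  pr <- utils::combn(levels(group), 2L)
  pvals <- apply(pr, 2L, function(g) {
    se <- sqrt(mse * (1 / sizes[[g[1L]]] + 1 / sizes[[g[2L]]]))
    tval <- (means[[g[1L]]] - means[[g[2L]]]) / se
    2 * stats::pt(abs(tval), dfe, lower.tail = FALSE)
  })
  padj <- bh_adjust(pvals)
  pairs <- data.frame(group1 = pr[1L, ], group2 = pr[2L, ], p = pvals,
                      p_adj = padj, row.names = NULL, stringsAsFactors = FALSE)
  ord <- names(sort(means, decreasing = TRUE))
  sig <- matrix(FALSE, k, k, dimnames = list(ord, ord))
  for (i in seq_len(ncol(pr))) {
    if (padj[i] < alpha_adj) {
      sig[pr[1L, i], pr[2L, i]] <- sig[pr[2L, i], pr[1L, i]] <- TRUE
    }
  }
  lett <- .compact_letters(!sig)
  letters_df <- data.frame(group = ord, n = as.integer(sizes[ord]),
                           mean = unname(means[ord]), letters = lett[ord],
                           row.names = NULL, stringsAsFactors = FALSE)
  list(anova_p = an[["Pr(>F)"]][1L], pairs = pairs, letters = letters_df)
}

# Compact letter display from a symmetric non-significance matrix (TRUE =
# not significantly different). Enumerates maximal cliques of the
# non-significance graph (group counts here are small) and assigns one
# letter per clique in the given group order.
.compact_letters <- function(nonsig) {
  k <- nrow(nonsig)
  groups <- rownames(nonsig)
  if (k > 20L) stop("compact letter display supports at most 20 groups")
  cliques <- list()
  for (mask in seq_len(2^k - 1L)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    sub <- nonsig[members, members, drop = FALSE]
    if (!all(sub)) next
    maximal <- TRUE
    for (v in setdiff(seq_len(k), members)) {
      if (all(nonsig[v, members])) { maximal <- FALSE; break }
    }
    if (maximal) cliques[[length(cliques) + 1L]] <- members
  }
  cliques <- cliques[order(vapply(cliques, min, 1L))]
  out <- stats::setNames(rep("", k), groups)
  for (ci in seq_along(cliques)) {
    lab <- letters[(ci - 1L) %% 26L + 1L]
    if (ci > 26L) lab <- paste0(lab, (ci - 1L) %/% 26L)
    for (g in cliques[[ci]]) out[g] <- paste0(out[g], lab)
  }
  out
}

#' Mann-Whitney differential gene counts between two genome groups
#'
#' Per gene family, a two-sided Mann-Whitney test of the per-genome counts
#' in group A vs group B, with BH correction across families. For small
#' samples the p-value is computed by exact enumeration of all group
#' assignments (valid under ties); larger samples use the tie-corrected
#' normal approximation. A family constant across both groups has `p = 1`
#' by convention.
#'
#' @param counts_a,counts_b genomes-by-families count matrices with the
#'   same column names (a single family may be given as plain vectors).
#' @param exact_limit enumerate exactly when `choose(nA+nB, nA)` is at most
#'   this (default 20000).
#' @return data.frame: `family`, `u`, `p`, `p_adj`, `direction` (sign of
#'   the median difference A - B), `n_a`, `n_b`.
#' @export
mw_differential_counts <- function(counts_a, counts_b, exact_limit = 20000L) {
  if (is.vector(counts_a)) counts_a <- matrix(counts_a, ncol = 1L,
                                              dimnames = list(NULL, "family"))
  if (is.vector(counts_b)) counts_b <- matrix(counts_b, ncol = 1L,
                                              dimnames = list(NULL, "family"))
  stopifnot(nrow(counts_a) > 0L, nrow(counts_b) > 0L,
            identical(colnames(counts_a), colnames(counts_b)))
  fams <- colnames(counts_a)
  rows <- lapply(fams, function(f) {
    a <- counts_a[, f]; b <- counts_b[, f]
    r <- .mw_one(a, b, exact_limit)
    data.frame(family = f, u = r$u, p = r$p,
               direction = sign(stats::median(a) - stats::median(b)),
               n_a = length(a), n_b = length(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[, c("family", "u", "p", "p_adj", "direction", "n_a", "n_b")]
}

# One two-sided Mann-Whitney test; exact enumeration for small samples.
.mw_one <- function(a, b, exact_limit) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    rk <- rank(pooled)
    sum(rk[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  if (stats::sd(pooled) == 0) return(list(u = u_obs, p = 1))
  if (choose(n1 + n2, n1) <= exact_limit) {
    rk <- rank(pooled)
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(rk[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p_lo <- mean(u_all <= u_obs + 1e-9)
    p_hi <- mean(u_all >= u_obs - 1e-9)
    return(list(u = u_obs, p = min(1, 2 * min(p_lo, p_hi))))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Correlation of genome distances with geographic separation
#'
#' Over all genome pairs, Pearson correlations of the genomic distance with
#' (i) great-circle (haversine) distance in km between isolation sites,
#' (ii) the latitudinal difference converted to km along a meridian, and
#' (iii) the longitudinal difference scaled by the cosine of the mean
#' latitude.
#'
#' @param genome_dist `dist` or square matrix of genome distances (e.g.
#'   Mash), labelled by genome id.
#' @param sites data.frame with columns `lat`, `lon`, rownames = genome id.
#' @return data.frame with rows `geographic`, `latitudinal`,
#'   `longitudinal`: `predictor`, `r`, `p`, `n_pairs`. `r` is `NA` when a
#'   predictor has zero variance (e.g. all genomes from one site).
#' @export
genome_geo_correlation <- function(genome_dist, sites) {
  m <- as.matrix(genome_dist)
  ids <- rownames(m)
  stopifnot(!is.null(ids), all(c("lat", "lon") %in% names(sites)))
  have <- ids %in% rownames(sites) &
    !is.na(sites[ids, "lat"]) & !is.na(sites[ids, "lon"])
  if (!all(have)) {
    message(sum(!have), " genome(s) without coordinates excluded")
    m <- m[have, have, drop = FALSE]
    ids <- ids[have]
  }
  n <- length(ids)
  if (n < 3L) stop("need at least 3 genomes with coordinates")
  lat <- sites[ids, "lat"]; lon <- sites[ids, "lon"]
  pr <- utils::combn(n, 2L)
  i <- pr[1L, ]; j <- pr[2L, ]
  km_per_deg <- pi * 6371 / 180
  geo <- geosphere::distHaversine(cbind(lon[i], lat[i]),
                                  cbind(lon[j], lat[j])) / 1000
  dlat <- abs(lat[i] - lat[j]) * km_per_deg
  dlon <- abs(lon[i] - lon[j]) * km_per_deg *
    cos((lat[i] + lat[j]) / 2 * pi / 180)
  gd <- m[cbind(i, j)]
  one <- function(pred, label) {
    if (stats::sd(pred) == 0 || stats::sd(gd) == 0) {
      return(data.frame(predictor = label, r = NA_real_, p = NA_real_,
                        n_pairs = length(pred), stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(gd, pred, method = "pearson")
    data.frame(predictor = label, r = unname(ct$estimate), p = ct$p.value,
               n_pairs = length(pred), stringsAsFactors = FALSE)
  }
  rbind(one(geo, "geographic"), one(dlat, "latitudinal"),
        one(dlon, "longitudinal"))
}
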