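# Alpha diversity (Observed ZOTUs, Shannon, Faith's PD), beta diversity
# (Bray-Curtis, Jensen-Shannon divergence), and the adjacent-age community
# dissimilarity trajectory.

#' Alpha diversity indices
#'
#' Computed on a rarefied count table so samples share a common depth.
#' `observed` counts features with positive counts; `shannon` is
#' \eqn{-\sum p_i \ln p_i} (natural log); `faiths_pd` is the total branch
#' length of the minimal subtree connecting each sample's observed tips to
#' the root (root path included).
#'
#' @param table samples-by-ZOTUs count matrix.
#' @param tree rooted `phylo` with branch lengths, tips labelled by ZOTU
#'   ids; `NULL` omits Faith's PD with a warning.
#' @return data.frame with columns `observed`, `shannon` and (if a tree is
#'   given) `faiths_pd`; rownames = sample ids.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  stopifnot(is.matrix(table), all(table >= 0))
  out <- data.frame(observed = rowSums(table > 0),
                    shannon = vegan::diversity(table, index = "shannon"),
                    row.names = rownames(table))
  if (is.null(tree)) {
    warning("no tree supplied; faiths_pd omitted")
    return(out)
  }
  miss <- setdiff(colnames(table)[colSums(table) > 0], tree$tip.label)
  if (length(miss)) stop("observed ZOTUs missing from the tree: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  pd <- picante::pd(table[, colnames(table) %in% tree$tip.label, drop = FALSE],
                    tree, include.root = TRUE)
  out$faiths_pd <- pd$PD[match(rownames(out), rownames(pd))]
  out
}

#' Beta diversity distance matrix
#'
#' `bray_curtis(x, y) = sum|x_i - y_i| / sum(x_i + y_i)`; `jsd(x, y)` is the
#' Jensen-Shannon divergence (natural log) of the vectors renormalised to
#' sum 1: `0.5 KL(x||m) + 0.5 KL(y||m)` with `m = (x + y)/2`.
#'
#' @param x samples-by-features non-negative matrix (counts or fractions).
#' @param metric `"bray_curtis"` or `"jsd"`.
#' @return `dist` object over the samples.
#' @export
beta_diversity <- function(x, metric = c("bray_curtis", "jsd")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(x), all(x >= 0))
  zero <- rowSums(x) == 0
  if (any(zero)) stop("zero-sum sample(s): ",
                      paste(rownames(x)[zero], collapse = ", "))
  if (metric == "bray_curtis") return(vegan::vegdist(x, method = "bray"))
  p <- x / rowSums(x)
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d[j, i] <- d[i, j] <- .jsd_pair(p[i, ], p[j, ])
    }
  }
  stats::as.dist(d)
}

# JSD of two probability vectors, natural log, 0*log0 = 0.
.jsd_pair <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Adjacent-age community dissimilarity trajectory
#'
#' Ages are floored to integer years (infants under 1 fall in bin 0). For
#' every age bin `a` whose neighbour `a - 1` is occupied, all cross pairs of
#' samples between the two bins contribute a Bray-Curtis distance at bin
#' `a`. A loess trend over the points is returned alongside.
#'
#' @param profiles samples-by-features abundance matrix.
#' @param ages numeric ages (years, >= 0), aligned with rows of `profiles`.
#' @param span loess span for the trend (default 0.75).
#' @return list: `points` (data.frame `age_bin`, `distance`), `trend`
#'   (data.frame `age_bin`, `fit` on the occupied bins), or empty `points`
#'   if no two adjacent bins are occupied.
#' @export
adjacent_age_dissimilarity <- function(profiles, ages, span = 0.75) {
  stopifnot(nrow(profiles) == length(ages), all(ages >= 0))
  bin <- floor(ages)
  d <- as.matrix(beta_diversity(profiles, "bray_curtis"))
  pts <- list()
  for (a in sort(unique(bin))) {
    i <- which(bin == a); j <- which(bin == a - 1)
    if (length(j) == 0L) next
    pts[[length(pts) + 1L]] <- data.frame(
      age_bin = a, distance = as.vector(d[i, j, drop = FALSE]))
  }
  if (length(pts) == 0L) {
    return(list(points = data.frame(age_bin = numeric(0), distance = numeric(0)),
                trend = NULL))
  }
  points <- do.call(rbind, pts)
  trend <- NULL
  if (length(unique(points$age_bin)) >= 4L) {
    fit <- stats::loess(distance ~ age_bin, data = points, span = span,
                        degree = 2L)
    grid <- sort(unique(points$age_bin))
    trend <- data.frame(age_bin = grid,
                        fit = stats::predict(fit, newdata = data.frame(age_bin = grid)))
  }
  list(points = points, trend = trend)
}

#' Age trend of a single feature
#'
#' Loess smooth on a fixed age grid plus an ordinary least-squares slope
#' (with SE), and the smoothed values at the annotation ages (defaults 16
#' and 30 — descriptive markers of community change, not detected change
#' points).
#'
#' @param feature per-sample values (abundance or index).
#' @param ages numeric ages aligned with `feature`.
#' @param span loess span.
#' @param grid ages at which the smooth is evaluated (default 101 points
#'   spanning the data).
#' @param annotate_at ages to annotate (default `c(16, 30)`).
#' @return list: `loess` (data.frame `age`, `fit`), `slope`, `slope_se`,
#'   `slope_p`, `annotations` (named vector of smoothed values).
#' @export
age_trend <- function(feature, ages, span = 0.75, grid = NULL,
                      annotate_at = c(16, 30)) {
  stopifnot(length(feature) == length(ages))
  ok <- stats::complete.cases(feature, ages)
  feature <- feature[ok]; ages <- ages[ok]
  if (length(feature) < 10L) stop("age_trend needs at least 10 complete cases")
  if (stats::sd(feature) == 0) {
    warning("constant feature; degenerate smoothing")
    grid <- grid %||% seq(min(ages), max(ages), length.out = 101L)
    return(list(loess = data.frame(age = grid, fit = rep(feature[1L], length(grid))),
                slope = 0, slope_se = 0, slope_p = NA_real_,
                annotations = stats::setNames(rep(feature[1L], length(annotate_at)),
                                              annotate_at)))
  }
  if (is.null(grid)) grid <- seq(min(ages), max(ages), length.out = 101L)
  lo <- stats::loess(feature ~ ages, span = span, degree = 2L)
  fit_grid <- stats::predict(lo, newdata = data.frame(ages = grid))
  lmfit <- stats::lm(feature ~ ages)
  co <- summary(lmfit)$coefficients
  ann_ok <- annotate_at >= min(ages) & annotate_at <= max(ages)
  ann <- rep(NA_real_, length(annotate_at))
  ann[ann_ok] <- stats::predict(lo, newdata = data.frame(ages = annotate_at[ann_ok]))
  list(loess = data.frame(age = grid, fit = fit_grid),
       slope = co["ages", "Estimate"], slope_se = co["ages", "Std. Error"],
       slope_p = co["ages", "Pr(>|t|)"],
       annotations = stats::setNames(ann, annotate_at))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
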