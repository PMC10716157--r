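# Distance-based redundancy analysis: principal-coordinates embedding of a
# (Gower-centred) dissimilarity matrix followed by redundancy analysis on
# covariate model matrices, with Ezekiel-adjusted R-squared and row-
# permutation tests. The permutation scorer works on precomputed PCoA axes,
# which keeps forward selection over many candidates and permutations fast.

# Gower-centred PCoA. Returns axes Y (n x k, Y Y' reconstructs the positive
# part), the positive eigenvalues, and the total inertia. Negative-
# eigenvalue axes are dropped with a message.
pcoa_axes <- function(d, tol = 1e-8) {
  m <- as.matrix(d)
  n <- nrow(m)
  g <- -0.5 * m^2
  g <- sweep(g, 1L, rowMeans(g))
  g <- sweep(g, 2L, colMeans(g))  # second sweep restores the grand mean
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  scale_ <- max(abs(e$values))
  pos <- e$values > tol * scale_
  if (any(e$values < -tol * scale_)) {
    message(sum(e$values < -tol * scale_),
            " negative PCoA eigenvalue(s) dropped (",
            signif(sum(e$values[e$values < 0]) / sum(e$values[pos]) * 100, 3),
            "% of positive inertia)")
  }
  y <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                               nrow = sum(pos))
  rownames(y) <- rownames(m)
  list(axes = y, eigenvalues = e$values[pos], total_inertia = sum(e$values[pos]))
}

# Centred model matrix (no intercept column) for one covariate; factors are
# dummy-coded against their first level.
.model_cols <- function(x) {
  if (is.character(x)) x <- factor(x)
  if (is.factor(x)) {
    x <- droplevels(x)
    if (nlevels(x) < 2L) stop("degenerate model: covariate is constant")
    mm <- stats::model.matrix(~x)[, -1L, drop = FALSE]
  } else {
    if (stats::sd(x) == 0) stop("degenerate model: covariate is constant")
    mm <- matrix(as.numeric(x), ncol = 1L)
  }
  sweep(mm, 2L, colMeans(mm))
}

# Orthonormal basis of the column space (rank-revealing QR).
.qbasis <- function(x, tol = 1e-9) {
  qr_ <- qr(x, tol = tol)
  if (qr_$rank == 0L) return(matrix(0, nrow(x), 0L))
  qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
}

#' Univariate distance-based redundancy analysis
#'
#' Embeds the dissimilarity matrix by Gower-centred principal coordinates
#' (negative-eigenvalue axes dropped), regresses the coordinates on the
#' covariate's centred model matrix, and reports the constrained-inertia
#' fraction R-squared, the Ezekiel-adjusted R-squared
#' `1 - (1 - R2)(n - 1)/(n - m - 1)` with `m` the model degrees of freedom,
#' and a permutation p-value from row permutations of the covariate.
#'
#' @param d `dist` or square matrix of dissimilarities.
#' @param covariate numeric vector or factor, aligned with the samples of
#'   `d`; rows with `NA` are removed (complete-case analysis).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param term label recorded in the result.
#' @return data.frame row: `term`, `r2`, `adj_r2`, `df`, `p`, `n`.
#' @export
dbrda_univariate <- function(d, covariate, n_perm = 999L, seed = NULL,
                             term = deparse(substitute(covariate))) {
  term <- paste(term, collapse = "")  # force before `covariate` is modified
  m <- as.matrix(d)
  ok <- !is.na(covariate)
  if (sum(ok) < 10L) stop("fewer than 10 complete cases")
  m <- m[ok, ok, drop = FALSE]
  covariate <- if (is.factor(covariate)) droplevels(covariate[ok]) else covariate[ok]
  pc <- pcoa_axes(m)
  x <- .model_cols(covariate)
  q <- .qbasis(x)
  mdf <- ncol(q)
  n <- nrow(m)
  r2 <- sum(crossprod(q, pc$axes)^2) / pc$total_inertia
  adj <- 1 - (1 - r2) * (n - 1) / (n - mdf - 1)
  if (!is.null(seed)) set.seed(seed)
  perm_r2 <- .perm_r2(q, pc$axes, n_perm) / pc$total_inertia
  p <- (1 + sum(perm_r2 >= r2 - 1e-12)) / (1 + n_perm)
  data.frame(term = term, r2 = r2, adj_r2 = adj, df = mdf, p = p, n = n,
             stringsAsFactors = FALSE)
}

# Conditional permutation test of one candidate block given the already
# selected orthonormal basis `qs`: pseudo-F of the added inertia under row
# permutations of the candidate only.
.perm_partial_p <- function(xt, qs, y, tot, r2s, n, n_perm, r2_new, madd) {
  qdf <- ncol(qs)
  fobs <- ((r2_new - r2s) / madd) / ((1 - r2_new) / (n - 1 - qdf - madd))
  if (ncol(xt) == 1L) {
    pm <- matrix(xt[replicate(n_perm, sample.int(n))], n, n_perm)
    pm <- pm - qs %*% crossprod(qs, pm)
    nrm <- sqrt(colSums(pm^2))
    ok <- nrm > 1e-12
    pm[, ok] <- sweep(pm[, ok, drop = FALSE], 2L, nrm[ok], "/")
    r2p <- rep(0, n_perm)
    r2p[ok] <- rowSums(crossprod(pm[, ok, drop = FALSE], y)^2) / tot
    fperm <- r2p / ((1 - r2s - r2p) / (n - 1 - qdf - 1))
  } else {
    fperm <- vapply(seq_len(n_perm), function(i) {
      xp <- xt[sample.int(n), , drop = FALSE]
      qp <- .qbasis(xp - qs %*% crossprod(qs, xp))
      if (ncol(qp) == 0L) return(0)
      r2p <- sum(crossprod(qp, y)^2) / tot
      (r2p / ncol(qp)) / ((1 - r2s - r2p) / (n - 1 - qdf - ncol(qp)))
    }, 0)
  }
  (1 + sum(fperm >= fobs - 1e-12)) / (1 + n_perm)
}

# Constrained inertia ||Q[perm,]' Y||^2 for n_perm row permutations.
# Permuting covariate rows is equivalent to permuting the rows of its
# orthonormal basis (QR commutes with row permutation).
.perm_r2 <- function(q, y, n_perm) {
  n <- nrow(q)
  if (ncol(q) == 1L) {
    pm <- replicate(n_perm, sample.int(n))
    qp <- matrix(q[pm], n, n_perm)
    rowSums(crossprod(qp, y)^2)  # one row per permutation
  } else {
    vapply(seq_len(n_perm), function(i) {
      sum(crossprod(q[sample.int(n), , drop = FALSE], y)^2)
    }, 0)
  }
}

#' Forward-selection (stepwise) dbRDA
#'
#' Forward selection over candidate covariates: at each step the candidate
#' with the largest resulting adjusted R-squared is added, provided its
#' conditional permutation p-value (pseudo-F of the added term, permuting
#' only that candidate's rows) is at most `alpha` and the resulting
#' adjusted R-squared does not exceed the global model's (the scope rule);
#' selection stops when no candidate qualifies.
#'
#' @param d `dist` or square dissimilarity matrix.
#' @param candidates data.frame of candidate covariates (numeric or
#'   factor/character columns); complete cases across all candidates are
#'   used.
#' @param n_perm permutations per candidate test (default 999).
#' @param alpha entry threshold on the permutation p (default 0.05).
#' @param seed RNG seed.
#' @param max_steps cap on the number of selection steps (default
#'   unlimited); useful when only the leading drivers are of interest.
#' @param r2_scope enforce the scope rule (default `TRUE`). Note that when
#'   the non-driving candidates are pure noise, the global model's adjusted
#'   R-squared estimates the best submodel's value without bias, so the
#'   scope comparison at the first step is close to a coin flip; disable
#'   the scope when the question is which candidate ranks first rather
#'   than how far selection should run.
#' @return list: `path` (data.frame `step`, `term`, `r2`, `adj_r2`,
#'   `adj_r2_increase`, `p`), `global_adj_r2`, `n`. `path` has zero rows if
#'   nothing qualifies.
#' @export
dbrda_stepwise <- function(d, candidates, n_perm = 999L, alpha = 0.05,
                           seed = NULL, max_steps = Inf, r2_scope = TRUE) {
  stopifnot(is.data.frame(candidates), ncol(candidates) >= 2L)
  m <- as.matrix(d)
  ok <- stats::complete.cases(candidates)
  if (sum(ok) < 10L) stop("fewer than 10 complete cases across candidates")
  m <- m[ok, ok, drop = FALSE]
  candidates <- candidates[ok, , drop = FALSE]
  n <- nrow(m)
  pc <- pcoa_axes(m)
  y <- pc$axes; tot <- pc$total_inertia
  cols <- lapply(candidates, .model_cols)
  if (!is.null(seed)) set.seed(seed)

  qg <- .qbasis(do.call(cbind, cols))
  r2g <- sum(crossprod(qg, y)^2) / tot
  global_adj <- 1 - (1 - r2g) * (n - 1) / (n - ncol(qg) - 1)

  qs <- matrix(0, n, 0L)
  r2s <- 0
  adj_prev <- 0
  path <- list()
  remaining <- names(cols)
  repeat {
    # score every remaining candidate by the adjusted R2 of the grown model
    cand <- lapply(remaining, function(term) {
      xt <- cols[[term]]
      qa <- .qbasis(xt - qs %*% crossprod(qs, xt))
      if (ncol(qa) == 0L) return(NULL)  # collinear with the selected set
      r2_new <- r2s + sum(crossprod(qa, y)^2) / tot
      adj_new <- 1 - (1 - r2_new) * (n - 1) / (n - ncol(qs) - ncol(qa) - 1)
      list(term = term, r2_new = r2_new, adj_new = adj_new, madd = ncol(qa))
    })
    cand <- cand[!vapply(cand, is.null, TRUE)]
    if (!length(cand)) break
    best <- cand[[which.max(vapply(cand, `[[`, 0, "adj_new"))]]
    # the model must improve and stay inside the global (all-covariates)
    # adjusted-R2 scope
    if (best$adj_new <= adj_prev) break
    if (r2_scope && best$adj_new > global_adj + 1e-12) break
    pval <- .perm_partial_p(cols[[best$term]], qs, y, tot, r2s, n, n_perm,
                            best$r2_new, best$madd)
    if (pval > alpha) break
    xt <- cols[[best$term]]
    qs <- cbind(qs, .qbasis(xt - qs %*% crossprod(qs, xt)))
    path[[length(path) + 1L]] <- data.frame(
      step = length(path) + 1L, term = best$term, r2 = best$r2_new,
      adj_r2 = best$adj_new, adj_r2_increase = best$adj_new - adj_prev,
      p = pval, stringsAsFactors = FALSE)
    r2s <- best$r2_new
    adj_prev <- best$adj_new
    remaining <- setdiff(remaining, best$term)
    if (!length(remaining) || length(path) >= max_steps) break
  }
  selected <- vapply(path, function(p) p$term, "")
  path <- if (length(path)) do.call(rbind, path) else
    data.frame(step = integer(0), term = character(0), r2 = numeric(0),
               adj_r2 = numeric(0), adj_r2_increase = numeric(0),
               p = numeric(0), stringsAsFactors = FALSE)
  list(path = path, global_adj_r2 = global_adj, n = n)
}
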