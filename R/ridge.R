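# Ridge-regression covariate association. Ridge is used because population
# covariates (geography, ethnicity, diet, urbanization) are strongly
# correlated; the L2 penalty stabilises the joint model. Continuous inputs
# and the response are z-scored; categorical covariates are dummy-coded
# against declared reference levels; the intercept is unpenalised.

#' Default reference levels for categorical covariates
#'
#' Comparisons are reported against: female (sex), Han (ethnicity), rice
#' (staple food type), rural (urban/rural/pastoral residence), April
#' (sampling month).
#'
#' @return named character vector, covariate name -> reference level.
#' @export
reference_levels <- function() {
  c(sex = "female", ethnicity = "Han", staple = "rice",
    residence = "rural", month = "April")
}

# Build the z-scored / dummy-coded design. Returns list(design, y, n).
.ridge_design <- function(y, X, ref_levels) {
  stopifnot(is.data.frame(X), length(y) == nrow(X))
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  blocks <- lapply(names(X), function(nm) {
    v <- X[[nm]]
    if (is.character(v)) v <- factor(v)
    if (is.factor(v)) {
      v <- droplevels(v)
      if (nm %in% names(ref_levels) && ref_levels[[nm]] %in% levels(v)) {
        v <- stats::relevel(v, ref_levels[[nm]])
      }
      if (nlevels(v) < 2L) return(NULL)
      mm <- stats::model.matrix(~v)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(nm, ":", levels(v)[-1L])
      mm
    } else {
      s <- stats::sd(v)
      if (s == 0) return(NULL)
      matrix((v - mean(v)) / s, ncol = 1L, dimnames = list(NULL, nm))
    }
  })
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]
  if (!length(blocks)) stop("no usable covariates (all constant)")
  design <- do.call(cbind, blocks)
  if (stats::sd(y) > 0) y <- (y - mean(y)) / stats::sd(y)
  list(design = design, y = y, n = n)
}

#' Ridge-regression association of one feature with covariates
#'
#' Minimises `||y - b0 - X b||^2 + lambda ||b||^2` (intercept unpenalised)
#' on the z-scored scale. With `lambda = "auto"` the penalty is chosen by
#' generalized cross-validation on a log-spaced grid. Coefficient standard
#' errors use the ridge sandwich `Var(b) = s^2 W X'X W` with
#' `W = (X'X + lambda I)^{-1}` and `s^2 = RSS/(n - df - 1)`,
#' `df = tr(H(lambda))`; p-values are two-sided t-tests on `n - df - 1`
#' degrees of freedom.
#'
#' @param y numeric response (a species abundance or a diversity index).
#' @param X data.frame of covariates (numeric or factor/character); rows
#'   with missing values are dropped (complete-case).
#' @param lambda non-negative penalty, or `"auto"` for GCV.
#' @param ref_levels named vector of reference levels for categorical
#'   covariates (default [reference_levels()]).
#' @return data.frame: `term`, `estimate`, `se`, `p`, `n`; the chosen
#'   penalty and GCV degrees of freedom are attached as attributes
#'   `lambda` and `df`.
#' @export
ridge_associate <- function(y, X, lambda = "auto",
                            ref_levels = reference_levels()) {
  d <- .ridge_design(y, X, ref_levels)
  Z <- d$design; yy <- d$y; n <- d$n
  if (n < ncol(Z)) stop("fewer complete cases than coefficients")
  Zc <- sweep(Z, 2L, colMeans(Z))
  yc <- yy - mean(yy)
  sv <- svd(Zc)
  if (identical(lambda, "auto")) {
    grid <- 10^seq(-4, 4, length.out = 101L)
    uty <- crossprod(sv$u, yc)
    gcv <- vapply(grid, function(l) {
      shrink <- sv$d^2 / (sv$d^2 + l)
      df <- sum(shrink) + 1
      resid2 <- sum((uty * (1 - shrink))^2) + sum(yc^2) - sum(uty^2)
      n * resid2 / (n - df)^2
    }, 0)
    lambda <- grid[which.min(gcv)]
  }
  if (!is.numeric(lambda) || lambda < 0) stop("lambda must be >= 0 or \"auto\"")
  w <- if (lambda == 0) {
    solve(crossprod(Zc))
  } else {
    solve(crossprod(Zc) + diag(lambda, ncol(Zc)))
  }
  beta <- drop(w %*% crossprod(Zc, yc))
  fitted <- drop(Zc %*% beta)
  rss <- sum((yc - fitted)^2)
  df <- sum(sv$d^2 / (sv$d^2 + lambda)) + 1  # +1: unpenalised intercept
  sigma2 <- rss / max(n - df, 1)
  vb <- sigma2 * (w %*% crossprod(Zc) %*% w)
  se <- sqrt(diag(vb))
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = max(n - df, 1), lower.tail = FALSE)
  out <- data.frame(term = colnames(Zc), estimate = beta, se = se, p = p,
                    n = n, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "lambda") <- lambda
  attr(out, "df") <- df
  out
}

#' Ridge screen across many features with BH correction
#'
#' Runs [ridge_associate()] per feature and applies Benjamini-Hochberg
#' correction to each term's p-values across features.
#'
#' @param features samples-by-features numeric matrix.
#' @param X covariate data.frame (rows aligned with `features`).
#' @param ... passed to [ridge_associate()].
#' @return data.frame: `feature`, `term`, `estimate`, `se`, `p`, `p_adj`,
#'   `n`.
#' @export
ridge_screen <- function(features, X, ...) {
  stopifnot(is.matrix(features), nrow(features) == nrow(X))
  res <- lapply(colnames(features), function(f) {
    r <- ridge_associate(features[, f], X, ...)
    cbind(feature = f, r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::ave(out$p, out$term, FUN = bh_adjust)
  out[, c("feature", "term", "estimate", "se", "p", "p_adj", "n")]
}

#' Linear regression of a feature on a covariate, adjusted for age and sex
#'
#' Ordinary least squares with the target covariate plus adjustment
#' covariates; continuous inputs and the response are z-scored. Used as the
#' unpenalised comparison to the ridge models.
#'
#' @param y numeric feature.
#' @param x covariate of interest (numeric or factor).
#' @param adjust data.frame of adjustment covariates (typically age and
#'   sex), aligned with `y`.
#' @param term label for the target covariate.
#' @return data.frame rows for the target term(s): `term`, `estimate`,
#'   `se`, `p`, `n`.
#' @export
linreg_adjusted <- function(y, x, adjust, term = "x") {
  stopifnot(is.data.frame(adjust), length(y) == nrow(adjust),
            length(x) == length(y))
  dat <- data.frame(.y = y, .x = x, adjust, stringsAsFactors = TRUE)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 10L) stop("fewer than 10 complete cases")
  for (nm in names(dat)) {
    if (is.numeric(dat[[nm]]) && stats::sd(dat[[nm]]) > 0) {
      dat[[nm]] <- (dat[[nm]] - mean(dat[[nm]])) / stats::sd(dat[[nm]])
    }
  }
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design; aliased: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  co <- summary(fit)$coefficients
  rows <- grep("^\\.x", rownames(co))
  data.frame(term = sub("^\\.x", term, rownames(co)[rows]),
             estimate = co[rows, "Estimate"], se = co[rows, "Std. Error"],
             p = co[rows, "Pr(>|t|)"], n = nrow(dat),
             row.names = NULL, stringsAsFactors = FALSE)
}
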