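test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.05, 6)), rep(0.05, 6))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(41)
  for (i in 1:25) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # invariant to input permutation (up to reordering)
  p <- runif(10)
  o <- sample(10)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
})

test_that("Mantel test statistics behave on canonical inputs", {
  set.seed(42)
  m <- matrix(runif(100), 10, 10); m <- (m + t(m)) / 2; diag(m) <- 0
  d <- as.dist(m)
  same <- mantel_test(d, d, n_perm = 199, seed = 1)
  expect_equal(same$r, 1)
  expect_equal(same$p, 1 / 200)
  mono <- mantel_test(d, sqrt(d), n_perm = 99, seed = 1)
  expect_gt(mono$r, 0.9)
  expect_error(mantel_test(d, dist(rnorm(5))), "size")
})

test_that("ANOVA + LSD letters separate clear groups and merge null groups", {
  set.seed(43)
  y <- c(rnorm(20, 0), rnorm(20, 10))
  g <- rep(c("lo", "hi"), each = 20)
  res <- anova_lsd_letters(y, g)
  expect_lt(res$anova_p, 1e-10)
  expect_identical(sort(unique(res$letters$letters)), c("a", "b"))
  # same-distribution groups share one letter most of the time
  share <- 0
  for (i in 1:100) {
    y0 <- rnorm(45)
    g0 <- rep(c("a", "b", "c"), each = 15)
    r0 <- anova_lsd_letters(y0, g0)
    if (all(grepl("a", r0$letters$letters))) share <- share + 1
  }
  # BH at 0.1 keeps the null all-shared rate near 90%; allow binomial noise
  expect_gte(share, 84)
  expect_warning(anova_lsd_letters(c(1, 2, 3, 4, 5), c("a", "a", "b", "b", "c")),
                 "dropped")
  suppressWarnings(
    expect_error(anova_lsd_letters(c(1, 2), c("a", "b")), "2 groups"))
})

test_that("pairwise LSD p-values use the pooled error mean square", {
  set.seed(44)
  y <- rnorm(30, rep(c(0, 1, 4), each = 10))
  g <- rep(c("a", "b", "c"), each = 10)
  res <- anova_lsd_letters(y, g)
  fit <- aov(y ~ factor(g))
  mse <- summary(fit)[[1]][["Mean Sq"]][2]
  tval <- (mean(y[g == "a"]) - mean(y[g == "b"])) / sqrt(mse * (1 / 10 + 1 / 10))
  p_ab <- 2 * pt(abs(tval), 27, lower.tail = FALSE)
  expect_equal(res$pairs$p[res$pairs$group1 == "a" & res$pairs$group2 == "b"],
               p_ab)
})

test_that("Mann-Whitney exact p matches full enumeration, ties included", {
  mwa <- matrix(c(5, 6, 7, 8), ncol = 1, dimnames = list(NULL, "f"))
  mwb <- matrix(c(0, 0, 1, 1), ncol = 1, dimnames = list(NULL, "f"))
  res <- mw_differential_counts(mwa, mwb)
  expect_equal(res$u, 16)
  expect_equal(res$p, 2 / choose(8, 4))
  expect_identical(res$direction, 1)
  # constant family
  cst <- matrix(1, 3, 1, dimnames = list(NULL, "f"))
  expect_equal(mw_differential_counts(cst, cst)$p, 1)
  # tie-free exact p agrees with wilcox.test's exact distribution
  set.seed(45)
  for (i in 1:10) {
    a <- sample(100, 5); b <- sample(200:300, 4)
    got <- mw_differential_counts(matrix(a, ncol = 1, dimnames = list(NULL, "f")),
                                  matrix(b, ncol = 1, dimnames = list(NULL, "f")))
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    expect_equal(got$u, unname(ref$statistic))
  }
})

test_that("planted differential families are recovered under BH", {
  set.seed(46)
  n_fam <- 40
  a <- matrix(rpois(15 * n_fam, 3), 15, n_fam)
  b <- matrix(rpois(15 * n_fam, 3), 15, n_fam)
  b[, 1:3] <- b[, 1:3] + 6  # planted shifts
  colnames(a) <- colnames(b) <- paste0("fam", seq_len(n_fam))
  res <- mw_differential_counts(a, b)
  hit <- res$family[res$p_adj < 0.05]
  expect_true(all(paste0("fam", 1:3) %in% hit))
  expect_lte(length(setdiff(hit, paste0("fam", 1:3))), 2)
})

test_that("genome-geography correlation decomposes into lat/lon components", {
  set.seed(47)
  n <- 12
  sites <- data.frame(lat = runif(n, 23, 50), lon = runif(n, 75, 130),
                      row.names = paste0("g", seq_len(n)))
  km <- pi * 6371 / 180
  pr <- combn(n, 2)
  dlat <- abs(sites$lat[pr[1, ]] - sites$lat[pr[2, ]]) * km
  m <- matrix(0, n, n, dimnames = list(rownames(sites), rownames(sites)))
  m[t(pr)] <- dlat; m <- m + t(m)
  res <- genome_geo_correlation(m, sites)
  expect_equal(res$r[res$predictor == "latitudinal"], 1, tolerance = 1e-12)
  expect_lt(res$p[res$predictor == "latitudinal"], 1e-10)
  expect_lt(abs(res$r[res$predictor == "longitudinal"]), 0.7)
  # all genomes from one site: undefined correlation reported as NA
  one <- data.frame(lat = rep(30, 5), lon = rep(100, 5),
                    row.names = paste0("g", 1:5))
  m5 <- matrix(runif(25), 5, 5); m5 <- (m5 + t(m5)) / 2; diag(m5) <- 0
  dimnames(m5) <- list(rownames(one), rownames(one))
  res1 <- genome_geo_correlation(m5, one)
  expect_true(all(is.na(res1$r)))
})

test_that("planted latitude-only structure leaves longitude null", {
  set.seed(48)
  sig <- 0
  for (i in 1:20) {
    n <- 15
    sites <- data.frame(lat = runif(n, 20, 50), lon = runif(n, 75, 130),
                        row.names = paste0("g", seq_len(n)))
    pr <- combn(n, 2)
    d <- abs(sites$lat[pr[1, ]] - sites$lat[pr[2, ]]) + rnorm(ncol(pr), 0, 2)
    m <- matrix(0, n, n, dimnames = list(rownames(sites), rownames(sites)))
    m[t(pr)] <- d; m <- m + t(m); diag(m) <- 0
    res <- genome_geo_correlation(m, sites)
    if (res$p[res$predictor == "longitudinal"] < 0.05) sig <- sig + 1
  }
  expect_lte(sig, 4)
})
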