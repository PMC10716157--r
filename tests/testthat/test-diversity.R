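test_that("alpha diversity closed forms", {
  m <- rbind(s1 = c(500, 500, 500, 500), s2 = c(2000, 0, 0, 0))
  colnames(m) <- paste0("Z", 1:4)
  a <- suppressWarnings(alpha_diversity(m))
  expect_equal(unname(a["s1", "shannon"]), log(4))
  expect_identical(unname(a["s1", "observed"]), 4)
  expect_identical(unname(a["s2", "observed"]), 1)
  expect_equal(unname(a["s2", "shannon"]), 0)
})

test_that("Shannon is maximal at the uniform composition", {
  set.seed(4)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    x <- matrix(rmultinom(1, 2000, rgamma(k, 1)), 1)
    colnames(x) <- paste0("Z", 1:k)
    u <- matrix(rep(100, k), 1, dimnames = list(NULL, paste0("Z", 1:k)))
    expect_lte(suppressWarnings(alpha_diversity(x))$shannon, log(k) + 1e-12)
    expect_equal(suppressWarnings(alpha_diversity(u))$shannon, log(k))
  }
})

test_that("Faith's PD on a star tree counts observed unit branches", {
  star <- ape::read.tree(text = "(Z1:1,Z2:1,Z3:1,Z4:1,Z5:1):0;")
  m <- rbind(s1 = c(5, 3, 1, 0, 0))
  colnames(m) <- paste0("Z", 1:5)
  a <- alpha_diversity(m, star)
  expect_equal(unname(a$faiths_pd), 3)
})

test_that("Faith's PD is monotone and totals the tree length", {
  set.seed(9)
  tr <- ape::rcoal(12)
  full <- matrix(1, 1, 12, dimnames = list("s", tr$tip.label))
  a_full <- alpha_diversity(full, tr)
  expect_equal(unname(a_full$faiths_pd), sum(tr$edge.length))
  sub <- full; sub[1, 1:5] <- 0
  a_sub <- alpha_diversity(sub, tr)
  expect_lte(a_sub$faiths_pd, a_full$faiths_pd)
  expect_equal(unname(a_sub$faiths_pd), oracle_pd(tr, tr$tip.label[6:12]))
})

test_that("beta diversity closed forms and metric properties", {
  m <- rbind(a = c(1, 2, 3, 0), b = c(1, 2, 3, 0), c = c(0, 0, 0, 5))
  colnames(m) <- paste0("Z", 1:4)
  bc <- as.matrix(beta_diversity(m, "bray_curtis"))
  js <- as.matrix(beta_diversity(m, "jsd"))
  expect_equal(bc["a", "b"], 0)
  expect_equal(js["a", "b"], 0)
  expect_equal(bc["a", "c"], 1)           # disjoint supports
  expect_equal(js["a", "c"], log(2))
  expect_true(all(abs(bc - t(bc)) < 1e-12))
  expect_true(all(bc >= 0 & bc <= 1))
  expect_true(all(js >= 0 & js <= log(2) + 1e-12))
  expect_error(beta_diversity(rbind(a = c(0, 0)), "jsd"), "zero-sum")
})

test_that("beta metrics match the elementwise oracles on random pairs", {
  set.seed(21)
  for (i in 1:20) {
    m <- matrix(rexp(8), 2, 4, dimnames = list(c("x", "y"), paste0("Z", 1:4)))
    expect_equal(as.numeric(beta_diversity(m, "bray_curtis")),
                 oracle_bray(m[1, ], m[2, ]), tolerance = 1e-12)
    expect_equal(as.numeric(beta_diversity(m, "jsd")),
                 oracle_jsd(m[1, ], m[2, ]), tolerance = 1e-12)
  }
})

test_that("JSD agrees with the phyloseq implementation", {
  skip_if_not_installed("phyloseq")
  set.seed(5)
  m <- matrix(rpois(40, 20) + 1, 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("Z", 1:10)))
  ours <- as.matrix(beta_diversity(m, "jsd"))
  ps <- phyloseq::phyloseq(phyloseq::otu_table(m, taxa_are_rows = FALSE))
  theirs <- as.matrix(phyloseq::distance(ps, method = "jsd"))
  expect_equal(ours, theirs[rownames(ours), colnames(ours)],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("adjacent-age pairs are counted per neighbouring bin pair", {
  prof <- matrix(c(rep(c(1, 0), 3), rep(c(0, 1), 2)), 5, 2, byrow = TRUE,
                 dimnames = list(paste0("s", 1:5), c("f1", "f2")))
  ages <- c(4.2, 4.9, 4.5, 5.3, 5.8)  # 3 samples in bin 4, 2 in bin 5
  res <- adjacent_age_dissimilarity(prof, ages)
  expect_identical(nrow(res$points), 6L)  # m * n cross pairs at bin 5
  expect_true(all(res$points$age_bin == 5))
  # identical communities one year apart yield distance zero
  same <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("f1", "f2")))
  r0 <- adjacent_age_dissimilarity(same, c(5.3, 4.9))
  expect_identical(nrow(r0$points), 1L)
  expect_equal(r0$points$distance, 0)
  # a single occupied bin yields no pairs
  r1 <- adjacent_age_dissimilarity(same, c(5.1, 5.7))
  expect_identical(nrow(r1$points), 0L)
})

test_that("age trends recover slopes and flag degenerate features", {
  ages <- seq(1, 80, length.out = 60)
  res <- suppressWarnings(age_trend(ages, ages))  # exact fit by design
  expect_equal(res$slope, 1, tolerance = 1e-10)
  expect_equal(res$loess$fit, res$loess$age, tolerance = 0.02)
  expect_equal(unname(res$annotations["16"]), 16, tolerance = 0.1)
  expect_warning(r2 <- age_trend(rep(1, 60), ages), "constant")
  expect_equal(r2$slope, 0)
})

test_that("a piecewise break shows up as peak curvature near the break", {
  ages <- seq(0.5, 60, length.out = 300)
  y <- pmin(ages, 16) * 0.5 - pmax(ages - 16, 0) * 0.5
  res <- age_trend(y, ages, span = 0.25)
  fit <- res$loess$fit
  curv <- abs(diff(diff(fit)))
  peak_age <- res$loess$age[which.max(curv) + 1]
  expect_lt(abs(peak_age - 16), 3)
})

test_that("white-noise features rarely show significant slopes", {
  set.seed(77)
  cover <- 0
  for (i in 1:50) {
    ages <- runif(40, 0, 80)
    res <- age_trend(rnorm(40), ages)
    ci <- res$slope + c(-1.96, 1.96) * res$slope_se
    if (ci[1] <= 0 && ci[2] >= 0) cover <- cover + 1
  }
  expect_gte(cover, 45)  # >= 90% nominal coverage
})
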