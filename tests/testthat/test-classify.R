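test_that("hit filtering applies inclusive thresholds and the target cap", {
  h <- make_hits("Z1", rep("d__B;g__Bifidobacterium", 4), c(200, 150, 120, 100))
  h$pident <- c(74.9, 75, 98, 98)
  h$qcovhsp <- c(100, 60, 59.9, 100)
  h$evalue <- c(1e-50, 1e-50, 1e-50, 1e-9)
  out <- filter_hits(h)
  expect_identical(out$bitscore, 150)  # only the inclusive-bound row survives
  # cap: 1500 passing hits -> top 1000 by bit score (sort-and-slice oracle)
  big <- make_hits("Z1", rep("d__B", 1500), sample(seq_len(1500)))
  capped <- filter_hits(big)
  expect_identical(nrow(capped), 1000L)
  expect_setequal(capped$bitscore, sort(big$bitscore, decreasing = TRUE)[1:1000])
})

test_that("top-percent LCA follows the retention rule", {
  g <- "d__B;p__A;f__F;g__Bifidobacterium"
  s1 <- paste0(g, ";s__Bifidobacterium x")
  s2 <- paste0(g, ";s__Bifidobacterium y")
  one <- lca_top_percent(make_hits("Z", s1, 150))
  expect_identical(one$taxonomy, s1)
  expect_identical(one$max_bit, 150)
  # 185 >= 0.9 * 200: both retained, collapse to genus
  both <- lca_top_percent(make_hits("Z", c(s1, s2), c(200, 185)))
  expect_identical(both$taxonomy, g)
  # 179 < 180: second hit dropped, species stands
  top <- lca_top_percent(make_hits("Z", c(s1, s2), c(200, 179)))
  expect_identical(top$taxonomy, s1)
  # min_score drops everything
  none <- lca_top_percent(make_hits("Z", s1, 99))
  expect_true(is.na(none$taxonomy))
})

test_that("random hit sets match the brute-force LCA of the retained set", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(2:50, 1)
    bits <- runif(n, 50, 400)
    lins <- replicate(n, random_lineage())
    got <- lca_top_percent(make_hits("Z", lins, bits))
    keep <- bits >= 100 & bits >= 0.9 * max(bits[bits >= 100], -Inf)
    if (!any(keep)) {
      expect_true(is.na(got$taxonomy))
    } else {
      expect_identical(got$taxonomy, oracle_lca(lins[keep]))
    }
  }
})

test_that("stricter retention never yields a coarser LCA", {
  set.seed(33)
  for (i in 1:30) {
    n <- sample(2:20, 1)
    hits <- make_hits("Z", replicate(n, random_lineage()), runif(n, 90, 300))
    loose <- lca_top_percent(hits, min_score = 100, top_percent = 20)
    strict <- lca_top_percent(hits, min_score = 100, top_percent = 5)
    if (!is.na(strict$taxonomy) && !is.na(loose$taxonomy)) {
      # the strict LCA must extend the loose one (field-wise prefix)
      expect_identical(tax_lca(c(strict$taxonomy, loose$taxonomy)),
                       loose$taxonomy)
    }
  }
})

test_that("arbitration fires the documented branch on canonical cases", {
  bg <- "d__B;g__Bifidobacterium"
  bl <- "d__B;g__Bifidobacterium;s__Bifidobacterium longum"
  bb <- "d__B;g__Bifidobacterium;s__Bifidobacterium breve"
  nb <- "d__B;g__Lactobacillus;s__Lactobacillus x"
  r <- arbitrate(NA, NA, NA, NA, "z")
  expect_identical(r$status, "discarded_no_hits")
  r <- arbitrate(nb, 300, bl, 250, "z")
  expect_identical(r$status, "discarded_nonbif_nt_dominant")
  r <- arbitrate(bl, 200, bl, 180, "z")
  expect_identical(r$source, "agree")
  r <- arbitrate(bg, 190, bl, 200, "z")  # 0.9*200 = 180 <= 190 -> finer wins
  expect_identical(r$taxonomy, bl)
  expect_identical(r$rule_fired, "rule4_merge_finer")
  r <- arbitrate(bg, 150, bb, 200, "z")  # 180 > 150 -> BIF
  expect_identical(r$taxonomy, bb)
  expect_identical(r$rule_fired, "rule5_bif_dominant")
  expect_warning(r <- arbitrate(bl, 250, bb, 200, "z"), "NT")
  expect_identical(r$taxonomy, bl)
  expect_identical(r$rule_fired, "rule6_nt_dominant")
})

test_that("classification composes filtering, LCA and arbitration per ZOTU", {
  plan <- data.frame(
    zotu_id = sprintf("Z%02d", 1:12),
    rule = rep(c("rule1_no_hits", "rule2_nonbif_nt_dominant", "rule3_agree",
                 "rule4_merge_finer", "rule5_bif_dominant",
                 "rule6_nt_dominant"), each = 2),
    stringsAsFactors = FALSE)
  ht <- simulate_hit_tables(plan)
  res <- suppressWarnings(
    suppressMessages(classify_table(plan$zotu_id, ht$nt, ht$bif)))
  expect_identical(res$rule_fired, plan$rule)
  expect_identical(sum(res$status == "assigned"), 8L)
  # empty hit tables: everything discarded as no-hits
  empty <- simulate_hit_tables(plan[0, , drop = FALSE])
  res0 <- suppressMessages(classify_table(c("A", "B"), empty$nt, empty$bif))
  expect_identical(unique(res0$status), "discarded_no_hits")
  # hits for unknown ZOTUs are skipped with a warning
  suppressWarnings(expect_warning(
    suppressMessages(classify_table("Z03", ht$nt, ht$bif)), "not in the ZOTU"))
})

test_that("species-level agreement reduces to the single-database LCA", {
  sp <- "d__B;g__Bifidobacterium;s__Bifidobacterium bifidum"
  nt <- make_hits("Z1", sp, 300)
  bif <- make_hits("Z1", sp, 280)
  res <- suppressMessages(classify_table("Z1", nt, bif))
  expect_identical(res$taxonomy, lca_top_percent(nt)$taxonomy)
  expect_identical(res$source, "agree")
})
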