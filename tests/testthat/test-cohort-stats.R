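test_that("the 2x2 exact test agrees with the reference implementation", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(2, 1, 1, 2), 2))$p.value, 1)

  set.seed(12)
  for (i in 1:200) {
    tab <- matrix(sample(0:25, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    ours <- fisher_exact_2x2(tab)
    ref <- fisher.test(tab)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$odds_ratio, unname(ref$estimate), tolerance = 1e-8)
  }
  expect_warning(deg <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2,
                                                byrow = TRUE)),
                 "degenerate")
  expect_equal(deg$p.value, 1)
  expect_error(fisher_exact_2x2(matrix(c(1, 2, 3, 4.5), 2)), "integer")
})

test_that("the r x c exact test generalizes the 2x2 case", {
  set.seed(13)
  for (i in 1:25) {
    tab <- matrix(sample(1:15, 4, replace = TRUE), 2)
    expect_equal(fisher_exact_rxc(tab)$p.value,
                 fisher_exact_2x2(tab)$p.value, tolerance = 1e-12)
  }
  expect_equal(fisher_exact_rxc(matrix(1, 2, 3))$p.value, 1)

  tab23 <- matrix(c(6, 2, 2, 2, 6, 2), 2, 3, byrow = TRUE)
  res <- fisher_exact_rxc(tab23)
  expect_identical(res$method, "exhaustive enumeration")
  # independent brute-force enumeration over both free cells of row 1
  rs <- rowSums(tab23); cs <- colSums(tab23)
  lp_obs <- kpsfusion:::log_table_prob(tab23)
  p_brute <- 0
  for (a in 0:min(rs[1], cs[1])) for (b in 0:min(rs[1] - a, cs[2])) {
    t2 <- rbind(c(a, b, rs[1] - a - b), cs - c(a, b, rs[1] - a - b))
    if (any(t2 < 0)) next
    lp <- kpsfusion:::log_table_prob(t2)
    if (lp <= lp_obs + 1e-7) p_brute <- p_brute + exp(lp)
  }
  expect_equal(res$p.value, p_brute, tolerance = 1e-12)
  expect_equal(res$p.value, fisher.test(tab23)$p.value, tolerance = 1e-8)

  mc <- fisher_exact_rxc(tab23, max_tables = 1, mc_samples = 2e4, seed = 4)
  expect_identical(mc$method, "Monte Carlo")
  expect_lt(abs(mc$p.value - res$p.value), 4 * mc$std_error + 1e-3)
})

test_that("Mann-Whitney U handles ties, exact and approximate paths", {
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 4.5)
  expect_equal(same$p.value, 1)

  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p.value, 0.1)     # 2 of the 20 assignments as extreme

  expect_equal(mann_whitney_u(5, 5)$p.value, 1)

  # exact path against wilcox.test where both are exact (no ties)
  set.seed(14)
  for (i in 1:20) {
    a <- sample(1:100, 5); b <- sample(1:200, 6) + 0.5  # no cross-group ties
    ours <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
  # normal approximation with tie correction, no continuity correction
  set.seed(15)
  a <- sample(1:8, 30, replace = TRUE); b <- sample(3:10, 25, replace = TRUE)
  ours <- mann_whitney_u(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_identical(ours$method, "normal approximation with tie correction")
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)

  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("p-value formatting follows the table convention", {
  expect_identical(format_pvalue(c(0.234, 0.005, 0.0004, NA)),
                   c("0.23", "0.005", "<0.001", NA))
  expect_identical(format_pvalue(0.0101), "0.01")
})

test_that("the baseline table summarizes and tests every parameter", {
  co <- small_cohort()
  t1 <- suppressWarnings(build_table1(co$records))
  # 21 binaries + 3 laterality + 4 extent + 5 continuous rows
  expect_equal(nrow(t1), 33)
  ns <- attr(t1, "group_sizes")
  expect_equal(sum(ns), nrow(co$records))

  grp <- co$records$postop_kps_6mo < 70
  x <- co$records$aphasia
  tab <- matrix(c(sum(x == 1 & grp), sum(x == 0 & grp),
                  sum(x == 1 & !grp), sum(x == 0 & !grp)), 2, 2, byrow = TRUE)
  expect_equal(t1$p_numeric[t1$parameter == "aphasia"],
               fisher_exact_2x2(tab)$p.value)
  expect_equal(t1$p_numeric[t1$parameter == "age"],
               mann_whitney_u(co$records$age[grp],
                              co$records$age[!grp])$p.value)
  lat_p <- t1$p_numeric[t1$parameter == "laterality" & t1$level == "right"]
  lat_tab <- rbind(table(factor(co$records$laterality[grp],
                                levels = c("right", "left", "bilateral"))),
                   table(factor(co$records$laterality[!grp],
                                levels = c("right", "left", "bilateral"))))
  expect_equal(lat_p, fisher_exact_rxc(lat_tab)$p.value)

  csv <- tempfile(fileext = ".csv")
  md <- tempfile(fileext = ".md")
  write_table1(t1, csv)
  write_table1(t1, md)
  expect_equal(nrow(utils::read.csv(csv)), 33)
  expect_true(any(grepl("^\\|", readLines(md))))
})
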