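test_that("group summaries follow the X/S/Md conventions", {
  s <- summarize_group(c(1, 2, 3))
  expect_equal(c(s$n, s$X, s$S, s$Md), c(3, 2, 1, 2))
  one <- summarize_group(5)
  expect_equal(c(one$X, one$S, one$Md), c(5, 0, 5))
  expect_equal(summarize_group(c(1, 2, 3, 4))$Md, 2.5)
  expect_error(summarize_group(numeric(0)), "non-empty")
  expect_error(summarize_group(c(1, NA)), "missing")
})

test_that("forced Mann-Whitney reproduces the enumerated worked example", {
  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6),
                        force_test = "mann-whitney")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_two_sided, 0.1)
  expect_false(cmp$significant)

  same <- compare_groups(c(2, 2, 2, 2), c(2, 2, 2, 2),
                         force_test = "mann-whitney")
  expect_equal(same$p_two_sided, 1)
  expect_false(same$significant)
})

test_that("clearly separated distributions are significant under either test", {
  set.seed(7)
  a <- rnorm(100, 0, 1)
  b <- rnorm(100, 5, 1)
  for (tst in c("mann-whitney", "t-two-sided")) {
    cmp <- compare_groups(a, b, force_test = tst)
    expect_true(cmp$significant)
    expect_lt(cmp$p_two_sided, 1e-6)
  }
})

test_that("test selection screens each sample for normality", {
  set.seed(8)
  norm_a <- rnorm(80)
  norm_b <- rnorm(80, 0.2)
  skew <- exp(rnorm(80, 0, 1.5))   # heavily lognormal
  expect_identical(compare_groups(norm_a, skew)$test, "mann-whitney")
  auto <- compare_groups(norm_a, norm_b)
  forced_t <- compare_groups(norm_a, norm_b, force_test = "t-two-sided")
  expect_identical(auto$test, "t-two-sided")
  expect_equal(auto$p_two_sided, forced_t$p_two_sided)
  expect_equal(forced_t$p_two_sided,
               t.test(norm_a, norm_b, var.equal = TRUE)$p.value)
  expect_error(compare_groups(1, 1:5), "at least 2")
})

test_that("C-class bins anchor on the reference median and partition the axis", {
  ref <- rep(100, 10)
  h <- c_class_histogram(c(100, 200, 70, 70.8, 400, 30), ref)
  expect_equal(h$anchor_2C, 100)
  expect_identical(as.character(h$assignments),
                   c("~2C", "~4C", "<2C", "~2C", "~8C", "<2C"))
  expect_equal(sum(h$counts), 6)
  expect_equal(sum(h$fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(h$edges) > 0))

  # label invariance under joint rescaling of values and reference
  set.seed(10)
  vals <- exp(rnorm(50, log(120), 0.6))
  refs <- exp(rnorm(20, log(100), 0.1))
  h1 <- c_class_histogram(vals, refs)
  h2 <- c_class_histogram(vals * 3.7, refs * 3.7)
  expect_identical(as.character(h1$assignments),
                   as.character(h2$assignments))

  expect_error(c_class_histogram(100, rep(100, 5)), ">= 10")
  expect_error(c_class_histogram(-1, ref), "positive")
})

test_that("scatter diagrams keep only AAR-defined nuclei and warn on empty groups", {
  df <- data.frame(Sc_pct = c(100, 100, 20, 0), AAR = c(1, 1, 1.8, NA))
  expect_warning(
    sc <- scatter_diagram(df, c("hom", "hom", "dec", "empty")),
    "empty")
  expect_equal(nrow(sc$data), 3)
  expect_true(all(sc$data$Sc_pct[sc$data$group == "hom"] == 100))
  expect_true(all(sc$data$AAR[sc$data$group == "hom"] == 1))
  expect_s3_class(sc$plot, "ggplot")

  regions <- data.frame(label = "decondensed", sc_min = 0, sc_max = 40,
                        aar_min = 1.3, aar_max = 2)
  sc2 <- scatter_diagram(df[1:3, ], "g", regions = regions)
  expect_s3_class(sc2$plot, "ggplot")
})

test_that("index ratios express scored classes per cells examined", {
  r <- index_ratios(cell_class_counts(2000, mitoses = 40,
                                      abnormal_mitoses = 10))
  expect_equal(r$percent[r$measure == "mitotic_index"], 2.0)
  expect_equal(r$percent[r$measure == "abnormal_of_mitoses_pct"], 25)

  none <- index_ratios(cell_class_counts(500))
  expect_true(all(none$percent[none$measure != "abnormal_of_mitoses_pct"] == 0))
  expect_true(is.na(none$percent[none$measure == "abnormal_of_mitoses_pct"]))

  expect_error(cell_class_counts(0), ">= 1")
  expect_error(cell_class_counts(10, mitoses = 11), "exceed")
  expect_error(cell_class_counts(10, mitoses = 2, abnormal_mitoses = 3),
               "abnormal_mitoses")
})
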