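test_that("identical samples are declared non-significant with p = 1", {
  # heavily skewed sample so the normality check routes to Mann-Whitney
  x <- c(1, 1, 1, 1, 2, 2, 3, 8, 50, 400)
  res <- choose_and_run_test(x, x)
  expect_equal(res$test_name, "mann_whitney")
  expect_equal(res$p_value, 1)
  expect_equal(res$stars, "ns")
})

test_that("small-sample Mann-Whitney matches full enumeration", {
  # canonical case: complete separation of {1,2,3} vs {4,5,6}
  res <- flimredox:::mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)  # 2 of the C(6,3)=20 labelings are as extreme

  # tie-free random samples: enumeration agrees with wilcox.test's exact p
  set.seed(7)
  for (i in 1:20) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    a <- round(rnorm(n1), 6); b <- round(rnorm(n2, 0.5), 6)
    enum <- flimredox:::mann_whitney_exact(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(enum$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(enum$statistic, unname(ref$statistic))
  }

  # with ties the enumeration still returns a valid midrank-based p
  tied <- flimredox:::mann_whitney_exact(c(1, 1, 2, 3), c(2, 3, 3, 4))
  expect_gte(tied$p_value, 0)
  expect_lte(tied$p_value, 1)
})

test_that("the decision tree picks the documented branches", {
  set.seed(40)
  # normal, equal variance -> unpaired t
  a <- rnorm(40); b <- rnorm(40, 0.2)
  r1 <- choose_and_run_test(a, b)
  expect_equal(r1$test_name, "t_unpaired")

  # normal, very unequal variance -> Welch
  r2 <- choose_and_run_test(rnorm(50, 0, 0.5), rnorm(50, 0.2, 3))
  expect_equal(r2$test_name, "t_welch")

  # heavy-tailed -> Mann-Whitney
  r3 <- choose_and_run_test(rcauchy(40), rcauchy(40, 1))
  expect_equal(r3$test_name, "mann_whitney")

  # purity: same inputs, same outcome
  expect_identical(choose_and_run_test(a, b), choose_and_run_test(a, b))

  # constant group falls through to Mann-Whitney with a warning
  expect_warning(r4 <- choose_and_run_test(rep(1, 10), rnorm(10, 2, 0.1)),
                 "Constant")
  expect_equal(r4$test_name, "mann_whitney")

  expect_error(choose_and_run_test(c(1, 2), c(3, 4, 5)),
               class = "flimredox_insufficient_sample_error")
})

test_that("stars follow the GraphPad mapping", {
  expect_equal(stars_label(c(0.2, 0.051, 0.05, 0.01, 0.001, 1e-4, 1e-5)),
               c("ns", "ns", "*", "**", "***", "****", "****"))
  expect_error(stars_label(1.2), class = "flimredox_parameter_error")
})

test_that("group summaries use the n-1 convention and per-cell ratios", {
  rec <- tibble::tibble(
    a1 = c(0.690, 0.7), a2 = c(0.310, 0.3),
    tau_mean = c(0.9, 1.1), tau_bound = c(3.0, 3.1),
    converged = c(TRUE, TRUE)
  )
  s <- summarize_group(rec, "tau_mean")
  expect_equal(s$mean, 1.0)
  expect_equal(s$sd, sqrt(0.02), tolerance = 1e-12)

  # single record: sd undefined, reported 0 with flag
  s1 <- summarize_group(rec[1, ], "tau_mean")
  expect_equal(s1$sd, 0)
  expect_false(s1$sd_defined)

  # a1/a2 is the mean of per-cell ratios
  s2 <- summarize_group(rec, "a1_over_a2")
  expect_equal(s2$mean, mean(c(0.690 / 0.310, 0.7 / 0.3)))
  expect_equal(round(0.690 / 0.310, 3), 2.226)

  none <- dplyr::mutate(rec, converged = FALSE)
  expect_error(summarize_group(none, "tau_mean"),
               class = "flimredox_empty_group_error")
})

test_that("redox ratios follow the pooled-sum convention and scale invariance", {
  tb <- tibble::tibble(nadh = 2, nad = 4, nadph = 1, nadp = 1)
  r <- compute_redox_ratios(tb)
  expect_equal(r$nadh_nad, 0.5)
  expect_equal(r$nadph_nadp, 1.0)
  expect_equal(r$nadph_nadp_combined, 0.6)

  # mean-of-ratios alternative
  r2 <- compute_redox_ratios(tb, combined = "mean_of_ratios")
  expect_equal(r2$nadph_nadp_combined, 0.75)

  # equal concentrations: all ratios 1
  eq <- compute_redox_ratios(tibble::tibble(nadh = 3, nad = 3, nadph = 3,
                                            nadp = 3))
  expect_equal(unlist(eq[c("nadh_nad", "nadph_nadp", "nadph_nadp_combined")]),
               c(nadh_nad = 1, nadph_nadp = 1, nadph_nadp_combined = 1))

  # doubling every concentration changes nothing
  r3 <- compute_redox_ratios(dplyr::mutate(tb, dplyr::across(
    dplyr::everything(), ~ .x * 2)))
  expect_equal(r3[c("nadh_nad", "nadph_nadp", "nadph_nadp_combined")],
               r[c("nadh_nad", "nadph_nadp", "nadph_nadp_combined")])

  expect_error(compute_redox_ratios(tibble::tibble(nadh = 1, nad = 0,
                                                   nadph = 1, nadp = 1)),
               class = "flimredox_undefined_ratio_error")

  # replicate summaries
  reps <- tibble::tibble(sample = rep(c("ctl", "h2o2"), each = 3),
                         nadh = c(2, 2.2, 1.8, 1, 1.1, 0.9),
                         nad = rep(4, 6), nadph = rep(1, 6), nadp = rep(1, 6))
  sm <- summarize_redox_ratios(compute_redox_ratios(reps))
  expect_equal(nrow(sm), 6)  # 2 samples x 3 ratios
  expect_equal(sm$n, rep(3L, 6))
})
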