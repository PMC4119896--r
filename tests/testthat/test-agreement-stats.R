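test_that("cohens_kappa matches hand-computed values and edge cases", {
  expect_equal(cohens_kappa(c("a", "b", "a", "c"), c("a", "b", "a", "c")), 1)
  # observed agreement equal to chance agreement
  expect_equal(cohens_kappa(c("a", "a", "b", "b"), c("a", "b", "a", "b")), 0)
  # 2x2 cross-table with counts 8 (agree-pos), 6 (agree-neg), 3 and 3:
  # p_o = 14/20, p_e = (11/20)^2 + (9/20)^2 = 0.505, kappa = 0.195/0.495 = 13/33
  r1 <- rep(c("pos", "neg", "pos", "neg"), times = c(8, 6, 3, 3))
  r2 <- rep(c("pos", "neg", "neg", "pos"), times = c(8, 6, 3, 3))
  expect_equal(cohens_kappa(r1, r2), 13 / 33, tolerance = 1e-12)
  # identical constant vectors: degenerate perfect agreement
  expect_equal(cohens_kappa(rep("x", 5), rep("x", 5)), 1)
  expect_error(cohens_kappa(c("a", "b"), c("a", "b", "c")), "equal length")
  expect_error(cohens_kappa("a", "a"), "at least 2")
})

test_that("kendalls_w handles perfect, reversed and tied rankings", {
  expect_equal(kendalls_w(cbind(1:10, 1:10 * 2, 1:10 + 3)), 1)
  expect_equal(kendalls_w(cbind(1:10, 10:1)), 0)
  # tie-corrected W cross-checked against the Friedman statistic
  # (raters as blocks): chi2_F = m (n - 1) W
  withr::with_seed(77, {
    for (i in 1:10) {
      n <- sample(4:9, 1); m <- sample(2:5, 1)
      sc <- matrix(sample(1:4, n * m, replace = TRUE), n, m)
      f <- unname(stats::friedman.test(t(sc))$statistic)
      expect_equal(kendalls_w(sc), f / (m * (n - 1)), tolerance = 1e-12)
    }
  })
  # ranks only: monotone transform of a rater's scores leaves W unchanged
  sc <- matrix(c(3, 1, 4, 2, 2, 2, 5, 1, 9, 4, 6, 6), 4, 3)
  sc2 <- sc; sc2[, 2] <- sc[, 2]^2
  expect_equal(kendalls_w(sc2), kendalls_w(sc))
  expect_error(kendalls_w(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(kendalls_w(matrix(1:3, 3, 1)), "at least 2")
})

test_that("phi_coefficient reproduces the published correlations", {
  t1 <- contingency_2x2(rbind(c(66, 12), c(12, 15)))
  t2 <- contingency_2x2(rbind(c(48, 30), c(3, 24)))
  expect_equal(round(phi_coefficient(t1), 3), 0.402)
  expect_equal(round(phi_coefficient(t2), 3), 0.441)
  expect_equal(phi_coefficient(contingency_2x2(rbind(c(9, 0), c(0, 4)))), 1)
  expect_error(phi_coefficient(contingency_2x2(rbind(c(3, 4), c(0, 0)))),
               "zero margin")
})

test_that("phi equals the correlation of the expanded indicator vectors", {
  set.seed(12)
  for (i in 1:100) {
    tb <- random_table()
    iv <- expand_indicators(tb)
    expect_equal(phi_coefficient(tb), cor(iv$row, iv$col), tolerance = 1e-12)
  }
})

test_that("chi_square_2x2 matches stats::chisq.test and the N phi^2 identity", {
  # identical row proportions: no association
  flat <- contingency_2x2(rbind(c(10, 20), c(20, 40)))
  expect_equal(chi_square_2x2(flat, yates = FALSE)$statistic, 0)
  expect_equal(chi_square_2x2(flat, yates = FALSE)$p_value, 1)
  set.seed(31)
  for (i in 1:50) {
    tb <- random_table()
    n <- sum(tb$counts)
    un <- chi_square_2x2(tb, yates = FALSE)
    ya <- chi_square_2x2(tb, yates = TRUE)
    expect_equal(un$statistic, n * phi_coefficient(tb)^2, tolerance = 1e-12)
    expect_lte(ya$statistic, un$statistic + 1e-12)
    # the oracle warns about its own approximation on small tables
    ref_u <- suppressWarnings(stats::chisq.test(tb$counts, correct = FALSE))
    ref_y <- suppressWarnings(stats::chisq.test(tb$counts, correct = TRUE))
    expect_equal(un$statistic, unname(ref_u$statistic), tolerance = 1e-10)
    expect_equal(un$p_value, unname(ref_u$p.value), tolerance = 1e-10)
    expect_equal(ya$statistic, unname(ref_y$statistic), tolerance = 1e-10)
    expect_equal(ya$p_value, unname(ref_y$p.value), tolerance = 1e-10)
  }
})

test_that("diagnostics reproduces the published accuracy metrics", {
  t1 <- contingency_2x2(rbind(c(66, 12), c(12, 15)),
                        c("shorter", "longer"), c("shorter", "longer"),
                        "KPG", "Stewart")
  d1 <- diagnostics(t1, positive_label = "shorter", reference = "cols")
  expect_equal(d1$sensitivity, 66 / 78)
  expect_equal(d1$specificity, 15 / 27)
  expect_equal(d1$ppv, 66 / 78)
  expect_equal(d1$npv, 15 / 27)
  expect_equal(round(d1$lr_positive, 3), 1.904)
  expect_equal(round(d1$lr_negative, 3), 0.277)
  t2 <- contingency_2x2(rbind(c(48, 30), c(3, 24)),
                        c("easy", "difficult"), c("easy", "difficult"),
                        "KPG", "Ericson-Kurol")
  d2 <- diagnostics(t2, positive_label = "easy", reference = "cols")
  expect_equal(round(d2$sensitivity, 3), 0.941)
  expect_equal(round(d2$specificity, 3), 0.444)
  expect_equal(round(d2$npv, 3), 0.889)
})

test_that("diagnostics flags undefined ratios instead of returning numbers", {
  perfect <- contingency_2x2(rbind(c(12, 0), c(0, 9)))
  d <- diagnostics(perfect)
  expect_equal(unlist(d[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
  expect_equal(d$lr_negative, 0)
  expect_true(is.na(d$lr_positive))
  expect_false(d$defined[["lr_positive"]])
  expect_true(d$defined[["lr_negative"]])
  # zero reference-positive margin: sensitivity undefined
  t0 <- contingency_2x2(rbind(c(0, 5), c(0, 7)))
  d0 <- diagnostics(t0, reference = "cols")
  expect_true(is.na(d0$sensitivity))
  expect_false(d0$defined[["sensitivity"]])
})

test_that("sensitivity/PPV duality holds under table transposition", {
  set.seed(90)
  for (i in 1:30) {
    tb <- random_table()
    tt <- contingency_2x2(t(tb$counts), colnames(tb$counts), rownames(tb$counts),
                          tb$col_index, tb$row_index)
    expect_equal(diagnostics(tb, "pos", "cols")$sensitivity,
                 diagnostics(tt, "pos", "cols")$ppv)
    expect_equal(diagnostics(tb, "pos", "cols")$ppv,
                 diagnostics(tt, "pos", "cols")$sensitivity)
  }
})

test_that("relabeling symmetry: reversing both label orders is consistent", {
  set.seed(91)
  for (i in 1:20) {
    tb <- random_table()
    sw <- contingency_2x2(tb$counts[2:1, 2:1], rev(rownames(tb$counts)),
                          rev(colnames(tb$counts)))
    expect_equal(phi_coefficient(sw), phi_coefficient(tb), tolerance = 1e-12)
    expect_equal(chi_square_2x2(sw)$statistic, chi_square_2x2(tb)$statistic,
                 tolerance = 1e-12)
    d1 <- diagnostics(tb, "pos", "cols")
    d2 <- diagnostics(sw, "pos", "cols")
    expect_equal(d2$sensitivity, d1$sensitivity)
    expect_equal(d2$npv, d1$npv)
  }
})

test_that("kappa_sample_size follows the Bloch-Kraemer closed form", {
  # study design values: null 0.40, alternative 0.70, prevalence 0.70,
  # two-sided alpha 0.05, power 0.80
  expect_identical(kappa_sample_size(0.40, 0.70, 0.70), 76L)
  # inverse-square law at fixed variance multipliers
  q0 <- canimpact:::bk_variance_q(0.40, 0.70)
  q1 <- canimpact:::bk_variance_q(0.70, 0.70)
  za <- qnorm(0.975); zb <- qnorm(0.80)
  n_raw <- function(d) ((za * sqrt(q0) + zb * sqrt(q1)) / d)^2
  expect_equal(n_raw(0.30) / n_raw(0.60), 4, tolerance = 1e-12)
  expect_error(kappa_sample_size(0.40, 0.40, 0.70), "diverges")
  expect_error(kappa_sample_size(0.40, 0.4005, 0.70), "diverges")
  expect_error(kappa_sample_size(0.40, 0.70, 0), "prevalence")
  expect_error(kappa_sample_size(0.40, 0.70, 1), "prevalence")
  expect_error(kappa_sample_size(1.2, 0.7, 0.5), "\\(-1, 1\\)")
})

test_that("rating_panel enforces unique keys and panel slicing works", {
  df <- data.frame(case_id = c("c1", "c1", "c2", "c2"),
                   rater_id = "R1", timepoint = c("t0", "t1", "t0", "t1"),
                   index = "kpg_total", value = c("3", "4", "8", "8"))
  p <- rating_panel(df)
  expect_s3_class(p, "rating_panel")
  expect_error(rating_panel(rbind(df, df[1, ])), "duplicate")
  m <- panel_matrix(p, "kpg_total", "t0")
  expect_equal(m, matrix(c(3, 8), 2, 1, dimnames = list(c("c1", "c2"), "R1")))
  expect_error(panel_matrix(p, "missing_index", "t0"), "empty")
})
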