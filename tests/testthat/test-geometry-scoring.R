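test_that("score_axis counts strictly exceeded boundaries and caps at 5", {
  th <- c(2, 4, 6, 8, 10)
  expect_identical(score_axis(0, th), 0L)
  expect_identical(score_axis(0, c(1, 2, 3, 4, 5)), 0L)
  expect_identical(score_axis(5, th), 2L)
  expect_identical(score_axis(100, th), 5L)
  # a displacement exactly on a boundary takes the lower subscore
  expect_identical(score_axis(4, th), 1L)
  expect_identical(score_axis(10, th), 4L)
})

test_that("score_axis rejects invalid inputs", {
  expect_error(score_axis(1, c(5, 4, 3, 2, 1)), "strictly increasing")
  expect_error(score_axis(1, c(1, 1, 2, 3, 4)), "strictly increasing")
  expect_error(score_axis(-0.1, c(1, 2, 3, 4, 5)), "nonnegative")
  expect_error(score_axis(Inf, c(1, 2, 3, 4, 5)), "finite")
})

test_that("score_axis is nondecreasing in displacement", {
  set.seed(101)
  for (i in 1:200) {
    th <- sort(runif(5, 0, 20))
    if (any(diff(th) <= 0)) next
    d <- sort(runif(2, 0, 25))
    expect_lte(score_axis(d[1], th), score_axis(d[2], th))
  }
})

test_that("categorize_kpg reproduces the published band examples", {
  expect_identical(categorize_kpg(11, "original"), "moderate")
  expect_identical(categorize_kpg(7, "original"), "easy")
  expect_identical(categorize_kpg(7, "modified"), "moderate")
  expect_identical(categorize_kpg(15, "dichotomous"), "difficult-very difficult")
  expect_identical(categorize_kpg(14, "dichotomous"), "easy-moderate")
})

test_that("categorize_kpg partitions 0..30 with no gaps or overlaps", {
  bands <- list(
    original = list(easy = 0:9, moderate = 10:14, difficult = 15:19,
                    "extremely difficult" = 20:30),
    modified = list(easy = 0:6, moderate = 7:14, difficult = 15:19,
                    "extremely difficult" = 20:30),
    dichotomous = list("easy-moderate" = 0:14,
                       "difficult-very difficult" = 15:30))
  for (scheme in names(bands)) {
    labels <- vapply(0:30, categorize_kpg, character(1), scheme = scheme)
    # every total receives exactly one label, and the label's band contains it
    expect_length(labels, 31L)
    for (t in 0:30) {
      expect_true(t %in% bands[[scheme]][[labels[t + 1]]],
                  label = sprintf("%s scheme, total %d", scheme, t))
    }
  }
  expect_error(categorize_kpg(31, "original"), "0..30")
  expect_error(categorize_kpg(-1, "dichotomous"), "0..30")
})

test_that("compute_kpg reproduces the worked subscore example (total 11)", {
  k <- compute_kpg(offset_case(5, 10, 5, 3, 1, 7), straight_frame())
  expect_identical(c(k$Cx, k$Rx, k$Cy, k$Ry, k$Cz, k$Rz), c(2L, 1L, 3L, 0L, 2L, 3L))
  expect_identical(k$total, 11L)
  expect_identical(k$category_original, "moderate")
  expect_identical(k$category_dichotomous, "easy-moderate")
})

test_that("compute_kpg spans the extremes of the scale", {
  fr <- straight_frame()
  ideal <- canine_case("ideal", "right", fr$ideal_cusp, fr$ideal_apex)
  k0 <- compute_kpg(ideal, fr)
  expect_identical(k0$total, 0L)
  expect_identical(k0$category_original, "easy")
  expect_identical(k0$category_modified, "easy")
  expect_identical(k0$category_dichotomous, "easy-moderate")
  kmax <- compute_kpg(offset_case(15, 20, 12, 11, 16, 12), fr)
  expect_identical(kmax$total, 30L)
  expect_identical(kmax$category_original, "extremely difficult")
})

test_that("total equals the sum of the six subscores on random cases", {
  set.seed(33)
  fr <- straight_frame()
  for (i in 1:50) {
    k <- compute_kpg(offset_case(runif(1, 0, 14), runif(1, 0, 18), runif(1, 0, 12),
                                 runif(1, 0, 14), runif(1, 0, 18), runif(1, 0, 12)),
                     fr)
    expect_identical(k$total, as.integer(k$Cx + k$Rx + k$Cy + k$Ry + k$Cz + k$Rz))
  }
})

test_that("mirroring a case to the other side leaves its KPG score unchanged", {
  set.seed(7)
  fr <- straight_frame()
  for (i in 1:20) {
    right <- offset_case(runif(1, 0, 14), runif(1, 0, 18), runif(1, 0, 12),
                         runif(1, 0, 14), runif(1, 0, 18), runif(1, 0, 12))
    left <- mirror_case(right, fr$midsagittal_x)
    kr <- compute_kpg(right, fr)
    kl <- compute_kpg(left, fr)
    expect_identical(kr[c("Cx", "Rx", "Cy", "Ry", "Cz", "Rz", "total",
                          "category_original", "category_modified",
                          "category_dichotomous")],
                     kl[c("Cx", "Rx", "Cy", "Ry", "Cz", "Rz", "total",
                          "category_original", "category_modified",
                          "category_dichotomous")])
  }
})

test_that("frame and case constructors reject degenerate geometry", {
  expect_error(anatomy_frame(0, rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                             cbind(seq(-40, 0, 10), 0, 25),
                             c(-20, 0, 25), c(-20, 25, 25),
                             -15, -11.75, -8.5, -4.25),
               "collinear")
  expect_error(anatomy_frame(0, rbind(c(-40, 0, 25), c(40, 0, 25), c(0, 0, 30)),
                             cbind(c(0, -10, -20, -30), 0, 25),
                             c(-20, 0, 25), c(-20, 25, 25),
                             -15, -11.75, -8.5, -4.25),
               "ordered")
  expect_error(canine_case("a", "right", c(1, 2, 3), c(1, 2, 3)), "distinct")
  expect_error(canine_case("a", "up", c(1, 2, 3), c(1, 2, 4)))
})

test_that("score_cases returns one labelled row per case", {
  fr <- straight_frame()
  cases <- list(offset_case(5, 10, 5, 3, 1, 7, id = "a"),
                offset_case(0, 0, 0, 0, 0, 0, id = "b", side = "left"))
  df <- score_cases(cases, fr)
  expect_identical(df$case_id, c("a", "b"))
  expect_identical(df$total, c(11L, 0L))
  expect_identical(df$cat_dichotomous, rep("easy-moderate", 2))
})
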