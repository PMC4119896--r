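#' Labelled 2x2 contingency table
#'
#' The unit of all cross-index comparisons: counts `a, b, c, d` laid out as
#' `rbind(c(a, b), c(c, d))` with row and column category labels and the names
#' of the two classifications being crossed.
#'
#' @param counts 2 x 2 matrix of nonnegative integer counts, total > 0.
#' @param row_labels,col_labels length-2 character vectors of category labels.
#' @param row_index,col_index names of the classifications on rows / columns.
#' @return An object of class `contingency_2x2`.
#' @examples
#' tb <- contingency_2x2(rbind(c(66, 12), c(12, 15)),
#'                       row_labels = c("shorter", "longer"),
#'                       col_labels = c("shorter", "longer"),
#'                       row_index = "KPG", col_index = "Stewart")
#' phi_coefficient(tb)
#' @export
contingency_2x2 <- function(counts, row_labels = c("positive", "negative"),
                            col_labels = c("positive", "negative"),
                            row_index = "A", col_index = "B") {
  counts <- as.matrix(counts)
  if (any(dim(counts) != c(2L, 2L)) || !is.numeric(counts) || anyNA(counts) ||
      any(counts < 0) || any(counts != round(counts))) {
    stop("'counts' must be a 2 x 2 matrix of nonnegative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("table total must be positive", call. = FALSE)
  if (length(row_labels) != 2L || length(col_labels) != 2L) {
    stop("row and column labels must each have length 2", call. = FALSE)
  }
  dimnames(counts) <- list(as.character(row_labels), as.character(col_labels))
  structure(list(counts = counts,
                 row_index = as.character(row_index),
                 col_index = as.character(col_index)),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("2x2 table: %s (rows) x %s (cols), N = %d\n",
              x$row_index, x$col_index, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

table_cells <- function(table) {
  m <- table$counts
  list(a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2],
       r1 = sum(m[1, ]), r2 = sum(m[2, ]),
       c1 = sum(m[, 1]), c2 = sum(m[, 2]), n = sum(m))
}

#' Cohen's kappa for two paired categorical ratings
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e), with observed
#' agreement p_o and chance agreement p_e from the product of the two raters'
#' marginal category proportions. When both vectors are the identical constant
#' rating (p_e = 1, p_o = 1) agreement is perfect and 1 is returned.
#'
#' @param ratings_1,ratings_2 equal-length vectors (length >= 2) of category
#'   labels over a shared category set.
#' @return Kappa in [-1, 1].
#' @export
cohens_kappa <- function(ratings_1, ratings_2) {
  if (length(ratings_1) != length(ratings_2)) {
    stop("rating vectors must have equal length", call. = FALSE)
  }
  if (length(ratings_1) < 2L) stop("need at least 2 paired ratings", call. = FALSE)
  if (anyNA(ratings_1) || anyNA(ratings_2)) stop("missing ratings not allowed", call. = FALSE)
  levs <- sort(unique(c(as.character(ratings_1), as.character(ratings_2))))
  f1 <- factor(as.character(ratings_1), levels = levs)
  f2 <- factor(as.character(ratings_2), levels = levs)
  n <- length(f1)
  po <- mean(f1 == f2)
  pe <- sum((table(f1) / n) * (table(f2) / n))
  if (1 - pe < 1e-12) {
    return(if (po >= 1 - 1e-12) 1 else NaN)
  }
  (po - pe) / (1 - pe)
}

#' Kendall's coefficient of concordance W (tie-corrected)
#'
#' Agreement among m raters ranking n cases, from the variance of rank sums
#' with the standard tie correction: W = 12 S / (m^2 (n^3 - n) - m sum(T_j)),
#' where S is the sum of squared deviations of the case rank sums from their
#' mean, ranks are midranks within each rater, and T_j = sum(t^3 - t) over
#' each rater's tie groups.
#'
#' @param scores numeric matrix, cases in rows, raters in columns; no missing
#'   cells (no imputation is performed).
#' @return W in [0, 1].
#' @export
kendalls_w <- function(scores) {
  scores <- as.matrix(scores)
  if (!is.numeric(scores)) stop("'scores' must be numeric", call. = FALSE)
  if (anyNA(scores)) stop("missing cells not allowed in a concordance slice", call. = FALSE)
  n <- nrow(scores)
  m <- ncol(scores)
  if (n < 2L || m < 2L) stop("need at least 2 cases and 2 raters", call. = FALSE)
  ranks <- apply(scores, 2L, rank)
  rs <- rowSums(ranks)
  s <- sum((rs - mean(rs))^2)
  tie_j <- apply(scores, 2L, function(col) {
    t <- table(col)
    sum(t^3 - t)
  })
  denom <- m^2 * (n^3 - n) - m * sum(tie_j)
  if (denom <= 0) {
    # every rater gave all cases the same score: rank sums cannot vary
    return(if (s == 0) 1 else NaN)
  }
  12 * s / denom
}

#' Extract a cases x raters score matrix from a rating panel
#'
#' @param panel a [rating_panel()].
#' @param index index name to slice.
#' @param timepoint timepoint to slice.
#' @return Numeric matrix with cases in rows and raters in columns.
#' @export
panel_matrix <- function(panel, index, timepoint) {
  stopifnot(inherits(panel, "rating_panel"))
  sl <- panel[panel$index == index & panel$timepoint == timepoint, , drop = FALSE]
  if (nrow(sl) == 0L) stop("empty panel slice", call. = FALSE)
  cases <- sort(unique(sl$case_id))
  raters <- sort(unique(sl$rater_id))
  m <- matrix(NA_real_, length(cases), length(raters),
              dimnames = list(cases, raters))
  m[cbind(match(sl$case_id, cases), match(sl$rater_id, raters))] <-
    suppressWarnings(as.numeric(sl$value))
  if (anyNA(m)) stop("panel slice has missing or non-numeric cells", call. = FALSE)
  m
}

#' Phi coefficient of a 2x2 table
#'
#' phi = (ad - bc) / sqrt(r1 r2 c1 c2); identical to the Pearson correlation
#' of the two 0/1 indicator variables the table summarises.
#'
#' @param table a [contingency_2x2()]; all four margins must be positive.
#' @return phi in [-1, 1].
#' @export
phi_coefficient <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  z <- table_cells(table)
  if (min(z$r1, z$r2, z$c1, z$c2) == 0) {
    stop("phi undefined: table has a zero margin", call. = FALSE)
  }
  (z$a * z$d - z$b * z$c) / sqrt(z$r1 * z$r2 * z$c1 * z$c2)
}

#' Chi-square test of independence for a 2x2 table
#'
#' Uncorrected statistic N (ad - bc)^2 / (r1 r2 c1 c2) (equal to N phi^2), or
#' with the Yates continuity correction N (max(|ad - bc| - N/2, 0))^2 /
#' (r1 r2 c1 c2). The p-value comes from the chi-square distribution with one
#' degree of freedom.
#'
#' @param table a [contingency_2x2()]; all four margins must be positive.
#' @param yates apply the continuity correction? Default `TRUE`.
#' @return List with `statistic`, `p_value`, `df` (always 1) and `yates`.
#' @export
chi_square_2x2 <- function(table, yates = TRUE) {
  stopifnot(inherits(table, "contingency_2x2"))
  z <- table_cells(table)
  if (min(z$r1, z$r2, z$c1, z$c2) == 0) {
    stop("chi-square undefined: table has a zero margin", call. = FALSE)
  }
  dev <- z$a * z$d - z$b * z$c
  num <- if (yates) max(abs(dev) - z$n / 2, 0)^2 else dev^2
  stat <- z$n * num / (z$r1 * z$r2 * z$c1 * z$c2)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, yates = isTRUE(yates))
}

#' Diagnostic accuracy of one classification against a reference standard
#'
#' Treats one side of the table as the reference standard and the other as
#' the index test: sensitivity = TP / reference positives, specificity =
#' TN / reference negatives, PPV and NPV from the test margins, LR+ =
#' sensitivity / (1 - specificity), LR- = (1 - sensitivity) / specificity.
#' Metrics whose denominator is zero are returned as `NA` with the matching
#' entry of `defined` set to `FALSE`, never as numbers.
#'
#' @param table a [contingency_2x2()].
#' @param positive_label which category label counts as positive; defaults to
#'   the first row label (the orientation consistent with the reported tables).
#' @param reference `"cols"` (default) if the column classification is the
#'   reference standard, `"rows"` otherwise.
#' @return An object of class `diagnostic_report`: sensitivity, specificity,
#'   ppv, npv, lr_positive, lr_negative, plus `positive_label`,
#'   `reference_index` and the named logical vector `defined`.
#' @export
diagnostics <- function(table, positive_label = rownames(table$counts)[1],
                        reference = c("cols", "rows")) {
  stopifnot(inherits(table, "contingency_2x2"))
  reference <- match.arg(reference)
  m <- table$counts
  if (reference == "rows") {
    m <- t(m)
    ref_index <- table$row_index
  } else {
    ref_index <- table$col_index
  }
  # after orientation: columns = reference standard, rows = index test
  rl <- rownames(m); cl <- colnames(m)
  ri <- match(positive_label, rl); ci <- match(positive_label, cl)
  if (is.na(ri) && is.na(ci)) {
    stop(sprintf("positive label '%s' not found among the table's labels",
                 positive_label), call. = FALSE)
  }
  # the two dichotomies may carry different wordings (e.g. shorter/longer vs
  # easy/difficult); categories are then aligned by position
  if (is.na(ri)) ri <- ci
  if (is.na(ci)) ci <- ri
  tp <- m[ri, ci]; fn <- sum(m[-ri, ci])
  fp <- m[ri, -ci]; tn <- sum(m[-ri, -ci])
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  lrp <- if (!is.na(sens) && !is.na(spec) && (1 - spec) > 0) sens / (1 - spec) else NA_real_
  lrn <- if (!is.na(sens) && !is.na(spec) && spec > 0) (1 - sens) / spec else NA_real_
  out <- list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
              lr_positive = lrp, lr_negative = lrn,
              positive_label = positive_label, reference_index = ref_index)
  out$defined <- !vapply(out[1:6], is.na, logical(1))
  structure(out, class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("Diagnostic accuracy (reference: %s, positive: '%s')\n",
              x$reference_index, x$positive_label))
  for (nm in c("sensitivity", "specificity", "ppv", "npv",
               "lr_positive", "lr_negative")) {
    cat(sprintf("  %-12s %s\n", nm,
                if (x$defined[[nm]]) sprintf("%.3f", x[[nm]]) else "undefined"))
  }
  invisible(x)
}

# Large-sample variance multiplier of the binary intraclass kappa at a given
# prevalence (Bloch-Kraemer form).
bk_variance_q <- function(kappa, prevalence) {
  (1 - kappa) * ((1 - kappa) * (1 - 2 * kappa) +
                   kappa * (2 - kappa) / (2 * prevalence * (1 - prevalence)))
}

#' Sample size to detect a kappa above a null value
#'
#' Number of subjects needed to detect an alternative kappa `kappa1` against
#' the null `kappa0` for a binary rating with the given prevalence of positive
#' ratings, using the Bloch-Kraemer large-sample variance of the intraclass
#' kappa: n = ceiling(((z_alpha sqrt(Q0) + z_beta sqrt(Q1)) / (kappa1 -
#' kappa0))^2) with Q(kappa) = (1 - kappa) * ((1 - kappa)(1 - 2 kappa) +
#' kappa (2 - kappa) / (2 p (1 - p))).
#'
#' @param kappa0,kappa1 null and alternative kappa, each in (-1, 1), differing
#'   by at least `min_difference`.
#' @param prevalence expected proportion of positive ratings, in (0, 1).
#' @param alpha significance level, default 0.05.
#' @param power target power, default 0.80.
#' @param sides 1 or 2 (default 2, two-sided test).
#' @param min_difference smallest detectable |kappa1 - kappa0| accepted before
#'   the required n diverges; default 1e-3.
#' @return Required number of subjects (integer).
#' @export
kappa_sample_size <- function(kappa0, kappa1, prevalence,
                              alpha = 0.05, power = 0.80, sides = 2,
                              min_difference = 1e-3) {
  for (k in c(kappa0, kappa1)) {
    if (!is.numeric(k) || length(k) != 1L || abs(k) >= 1) {
      stop("kappa values must lie in (-1, 1)", call. = FALSE)
    }
  }
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("'prevalence' must lie strictly between 0 and 1", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("'alpha' and 'power' must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!sides %in% c(1, 2)) stop("'sides' must be 1 or 2", call. = FALSE)
  if (abs(kappa1 - kappa0) < min_difference) {
    stop("kappa1 - kappa0 below the minimum detectable difference; required n diverges",
         call. = FALSE)
  }
  za <- stats::qnorm(1 - alpha / sides)
  zb <- stats::qnorm(power)
  q0 <- bk_variance_q(kappa0, prevalence)
  q1 <- bk_variance_q(kappa1, prevalence)
  as.integer(ceiling(((za * sqrt(q0) + zb * sqrt(q1)) / (kappa1 - kappa0))^2))
}

#' Long-format rating panel
#'
#' Ratings indexed by case, rater, timepoint and index name; the unit of all
#' reliability analyses. Values are stored as character so categorical labels
#' and numeric scores can share one column; [panel_matrix()] converts numeric
#' slices.
#'
#' @param df data.frame with columns `case_id`, `rater_id`, `timepoint`,
#'   `index`, `value`; keys must be unique.
#' @return An object of class `rating_panel` (also a data.frame).
#' @export
rating_panel <- function(df) {
  need <- c("case_id", "rater_id", "timepoint", "index", "value")
  if (!all(need %in% names(df))) {
    stop(sprintf("rating panel needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  key <- do.call(paste, c(df[c("case_id", "rater_id", "timepoint", "index")], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (case, rater, timepoint, index) keys in rating panel", call. = FALSE)
  }
  df$value <- as.character(df$value)
  class(df) <- c("rating_panel", "data.frame")
  df
}

#' Intrarater agreement (Cohen's kappa between two timepoints)
#'
#' For each rater, pairs that rater's categorical ratings of every case at two
#' timepoints and computes Cohen's kappa.
#'
#' @param panel a [rating_panel()].
#' @param index categorical index name (e.g. `"kpg_class"`).
#' @param timepoints length-2 vector of the timepoints to pair; defaults to
#'   the panel's first two.
#' @return Named numeric vector of kappas, one per rater.
#' @export
intrarater_kappa <- function(panel, index, timepoints = NULL) {
  stopifnot(inherits(panel, "rating_panel"))
  sl <- panel[panel$index == index, , drop = FALSE]
  if (is.null(timepoints)) timepoints <- sort(unique(sl$timepoint))[1:2]
  if (length(timepoints) != 2L || anyNA(timepoints)) {
    stop("need exactly two timepoints for intrarater kappa", call. = FALSE)
  }
  raters <- sort(unique(sl$rater_id))
  out <- vapply(raters, function(r) {
    s1 <- sl[sl$rater_id == r & sl$timepoint == timepoints[1], ]
    s2 <- sl[sl$rater_id == r & sl$timepoint == timepoints[2], ]
    s2 <- s2[match(s1$case_id, s2$case_id), ]
    cohens_kappa(s1$value, s2$value)
  }, numeric(1))
  names(out) <- raters
  out
}

#' Interrater agreement (Kendall's W per timepoint)
#'
#' @param panel a [rating_panel()].
#' @param index numeric index name (e.g. `"kpg_total"`).
#' @param timepoint timepoint to analyse.
#' @return Kendall's W across raters at that timepoint.
#' @export
interrater_w <- function(panel, index, timepoint) {
  kendalls_w(panel_matrix(panel, index, timepoint))
}
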