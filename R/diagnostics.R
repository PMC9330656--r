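#' Construct a 2x2 contingency table
#'
#' Two layouts share the storage. Unpaired: rows are the two groups,
#' columns are (positive, negative) counts, so `a`/`b` are group 1's
#' positives/negatives and `c`/`d` group 2's. Paired: `a` = positive by
#' both tests, `b` = test1+/test2-, `c` = test1-/test2+, `d` = negative by
#' both.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param layout `"unpaired"` or `"paired"`; recorded for printing only,
#'   each statistic documents the layout it expects.
#' @return A 2x2 integer matrix of class `quic_table2x2`.
#' @export
table2x2 <- function(a, b, c, d, layout = c("unpaired", "paired")) {
  layout <- rlang::arg_match(layout)
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    quic_abort("cells must be non-negative integers", "rtquic_validation_error")
  }
  if (sum(cells) < 1) {
    quic_abort("table total must be >= 1", "rtquic_validation_error")
  }
  m <- matrix(as.integer(round(cells)), nrow = 2, byrow = TRUE)
  structure(m, class = c("quic_table2x2", class(m)), layout = layout)
}

as_cells <- function(tab) {
  if (is.matrix(tab) && all(dim(tab) == c(2, 2))) {
    c(a = unname(tab[1, 1]), b = unname(tab[1, 2]),
      c = unname(tab[2, 1]), d = unname(tab[2, 2]))
  } else if (is.numeric(tab) && length(tab) == 4) {
    c(a = unname(tab[1]), b = unname(tab[2]),
      c = unname(tab[3]), d = unname(tab[4]))
  } else {
    quic_abort("expected a 2x2 table or 4 cell counts", "rtquic_validation_error")
  }
}

#' Positive-call proportion with exact confidence interval
#'
#' The workhorse behind sensitivity, specificity and positivity rates: the
#' binomial point estimate with its exact 95% Clopper-Pearson interval,
#' plus the integer percent (rounded half-up) as printed in results tables.
#'
#' @param n_positive Number of positive calls.
#' @param n_total Number of subjects tested (>= 1).
#' @param conf_level Confidence level, default 0.95.
#' @return A list of class `quic_accuracy`: `n_positive`, `n_total`,
#'   `estimate`, `ci_low`, `ci_high`, `percent_rounded`.
#' @examples
#' sensitivity(27, 32) # 84%
#' @export
sensitivity <- function(n_positive, n_total, conf_level = 0.95) {
  if (n_total < 1) quic_abort("n_total must be >= 1", "rtquic_validation_error")
  if (n_positive < 0 || n_positive > n_total) {
    quic_abort("need 0 <= n_positive <= n_total", "rtquic_validation_error")
  }
  ci <- stats::binom.test(n_positive, n_total,
                          conf.level = conf_level)$conf.int
  structure(
    list(
      n_positive = as.integer(n_positive),
      n_total = as.integer(n_total),
      estimate = n_positive / n_total,
      ci_low = ci[1],
      ci_high = ci[2],
      percent_rounded = as.integer(round_half_up(100 * n_positive / n_total))
    ),
    class = "quic_accuracy"
  )
}

#' @rdname sensitivity
#' @param n_negative Number of negative calls among disease-negative
#'   subjects.
#' @export
specificity <- function(n_negative, n_total, conf_level = 0.95) {
  sensitivity(n_negative, n_total, conf_level)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric probabilities of
#' every table whose point probability does not exceed the observed one
#' (point-probability two-sided convention, with a 1 + 1e-7 relative guard
#' against ties lost to floating point).
#'
#' @param tab Unpaired 2x2 table ([table2x2()], matrix, or 4 counts a,b,c,d
#'   row-wise).
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(table2x2(27, 5, 5, 6)) # 0.018
#' @export
fisher_exact <- function(tab) {
  x <- as_cells(tab)
  a <- x["a"]; b <- x["b"]; c <- x["c"]; d <- x["d"]
  n <- a + b + c + d
  if (n < 1) quic_abort("empty table", "rtquic_validation_error")
  r1 <- a + b
  c1 <- a + c
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Cramer's V effect size for a 2x2 table
#'
#' For a 2x2 table Cramer's V equals the absolute phi coefficient,
#' `|ad - bc| / sqrt(r1 r2 c1 c2)`.
#'
#' @param tab Unpaired 2x2 table; both margins must be nonzero.
#' @return Effect size in \[0, 1\].
#' @examples
#' cramers_v(table2x2(27, 5, 5, 6)) # 0.39
#' @export
cramers_v <- function(tab) {
  x <- as_cells(tab)
  a <- x["a"]; b <- x["b"]; c <- x["c"]; d <- x["d"]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    quic_abort("Cramer's V undefined with a zero margin", "rtquic_validation_error")
  }
  unname(abs(a * d - b * c) / sqrt(r1 * r2 * c1 * c2))
}

#' Exact McNemar test for paired binary calls
#'
#' Exact two-sided binomial test on the discordant pairs:
#' `p = min(1, 2 P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`. With
#' no discordant pairs the test is degenerate and p = 1 by convention.
#'
#' @param tab Paired 2x2 table (`b` and `c` are the discordant cells).
#' @return The exact two-sided p-value.
#' @examples
#' mcnemar_exact(table2x2(9, 9, 1, 4, layout = "paired")) # 0.021
#' @export
mcnemar_exact <- function(tab) {
  x <- as_cells(tab)
  b <- x[["b"]]; c <- x[["c"]]
  if (b + c == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
}

#' Cohen's kappa for paired binary calls
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' asymptotic large-sample standard error of Fleiss, Cohen and Everitt
#' (1969) and a Wald 95% CI clipped to \[-1, 1\]. When expected agreement
#' is 1 the statistic is degenerate: kappa is defined as 1 if observed
#' agreement is also 1 and 0 otherwise, and flagged. The exact McNemar
#' p-value and discordant-pair count are reported alongside, since the two
#' statistics are read together when comparing paired tests.
#'
#' @param tab Paired 2x2 table.
#' @param conf_level Confidence level, default 0.95.
#' @return A list of class `quic_agreement`: `kappa`, `se_kappa`, `ci_low`,
#'   `ci_high`, `mcnemar_p`, `n_discordant`, `n`, `degenerate`.
#' @examples
#' cohens_kappa(table2x2(9, 9, 1, 4, layout = "paired")) # kappa 0.19
#' @export
cohens_kappa <- function(tab, conf_level = 0.95) {
  x <- as_cells(tab)
  a <- x[["a"]]; b <- x[["b"]]; c <- x[["c"]]; d <- x[["d"]]
  n <- a + b + c + d
  if (n < 1) quic_abort("empty table", "rtquic_validation_error")
  p <- matrix(c(a, b, c, d), 2, byrow = TRUE) / n
  row_m <- rowSums(p)
  col_m <- colSums(p)
  p_o <- p[1, 1] + p[2, 2]
  p_e <- sum(row_m * col_m)
  degenerate <- abs(1 - p_e) < .Machine$double.eps^0.5
  if (degenerate) {
    kappa <- if (abs(1 - p_o) < .Machine$double.eps^0.5) 1 else 0
    se <- NA_real_
    ci <- c(NA_real_, NA_real_)
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
    # Fleiss-Cohen-Everitt (1969) large-sample variance
    diag_term <- sum(diag(p) * (1 - (row_m + col_m) * (1 - kappa))^2)
    off <- (1 - kappa)^2 *
      (p[1, 2] * (col_m[1] + row_m[2])^2 + p[2, 1] * (col_m[2] + row_m[1])^2)
    var_k <- (diag_term + off - (kappa - p_e * (1 - kappa))^2) /
      (n * (1 - p_e)^2)
    se <- sqrt(max(var_k, 0))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- pmin(pmax(kappa + c(-1, 1) * z * se, -1), 1)
  }
  structure(
    list(
      kappa = unname(kappa), se_kappa = unname(se),
      ci_low = unname(ci[1]), ci_high = unname(ci[2]),
      mcnemar_p = mcnemar_exact(x), n_discordant = as.integer(b + c),
      n = as.integer(n), degenerate = degenerate
    ),
    class = "quic_agreement"
  )
}

#' Build an unpaired 2x2 table from sample calls
#'
#' Cross-tabulates positive/negative calls by a two-level grouping column,
#' in the order of the factor levels present (or order of appearance).
#'
#' @param calls A `quic_calls` tibble (or any data frame with a `call`
#'   column of "positive"/"negative").
#' @param group_by Name of the grouping column, default `"specimen"`.
#' @return A `quic_table2x2` (rows = groups, columns = positive, negative)
#'   with attribute `groups` naming the rows.
#' @export
build_unpaired_table <- function(calls, group_by = "specimen") {
  g <- calls[[group_by]]
  g <- if (is.factor(g)) droplevels(g) else factor(g, levels = unique(g))
  if (nlevels(g) != 2) {
    quic_abort(
      sprintf("need exactly 2 groups in '%s', found %d",
              group_by, nlevels(g)),
      "rtquic_validation_error"
    )
  }
  pos <- calls$call == "positive"
  counts <- table(g, factor(pos, levels = c(TRUE, FALSE)))
  out <- table2x2(counts[1, 1], counts[1, 2], counts[2, 1], counts[2, 2])
  attr(out, "groups") <- levels(g)
  out
}

#' Build a paired 2x2 table from two call sets on the same subjects
#'
#' @param calls1,calls2 Data frames with `subject` and `call` columns; one
#'   call per subject each.
#' @return A paired `quic_table2x2` (`a` both+, `b` test1+/test2-, `c`
#'   test1-/test2+, `d` both-), with attribute `n_excluded` counting
#'   subjects missing from either set (excluded with a warning).
#' @export
build_paired_table <- function(calls1, calls2) {
  m <- merge(calls1[, c("subject", "call")], calls2[, c("subject", "call")],
             by = "subject", suffixes = c("_1", "_2"))
  n_excluded <- length(union(calls1$subject, calls2$subject)) - nrow(m)
  if (n_excluded > 0) {
    rlang::warn(sprintf(
      "%d subject(s) lacked a call from one of the two tests and were excluded",
      n_excluded
    ))
  }
  if (nrow(m) == 0) {
    quic_abort("no subjects with both calls", "rtquic_validation_error")
  }
  p1 <- m$call_1 == "positive"
  p2 <- m$call_2 == "positive"
  out <- table2x2(sum(p1 & p2), sum(p1 & !p2), sum(!p1 & p2), sum(!p1 & !p2),
                  layout = "paired")
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Combine two tests with an either-positive rule
#'
#' A subject is combined-positive when either test called them positive —
#' the double-tissue testing strategy (e.g. CSF plus olfactory mucosa).
#' Subjects missing a call from one test are excluded with a warning.
#'
#' @param calls1,calls2 Data frames with `subject`, `diagnosis` and `call`
#'   columns, one call per subject each.
#' @return A tibble with one row per diagnosis group: `diagnosis`,
#'   `n_positive`, `n_total`, `estimate`, `ci_low`, `ci_high`,
#'   `percent_rounded`, plus attribute `n_excluded`.
#' @export
combine_or_rule <- function(calls1, calls2) {
  m <- merge(calls1[, c("subject", "diagnosis", "call")],
             calls2[, c("subject", "call")],
             by = "subject", suffixes = c("_1", "_2"))
  n_excluded <- length(union(calls1$subject, calls2$subject)) - nrow(m)
  if (n_excluded > 0) {
    rlang::warn(sprintf(
      "%d subject(s) lacked a call from one of the two tests and were excluded",
      n_excluded
    ))
  }
  if (nrow(m) == 0) {
    quic_abort("no subjects with both calls", "rtquic_validation_error")
  }
  m$combined <- m$call_1 == "positive" | m$call_2 == "positive"
  groups <- split(m, droplevels(factor(m$diagnosis)))
  rows <- lapply(names(groups), function(gname) {
    g <- groups[[gname]]
    s <- sensitivity(sum(g$combined), nrow(g))
    tibble::tibble(
      diagnosis = gname, n_positive = s$n_positive, n_total = s$n_total,
      estimate = s$estimate, ci_low = s$ci_low, ci_high = s$ci_high,
      percent_rounded = s$percent_rounded
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' @export
print.quic_accuracy <- function(x, ...) {
  cat(sprintf("%d/%d = %.3f (%d%%), 95%% CI [%.3f, %.3f]\n",
              x$n_positive, x$n_total, x$estimate, x$percent_rounded,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
print.quic_agreement <- function(x, ...) {
  cat(sprintf(
    "Cohen's kappa %.3f (SE %.3f, 95%% CI [%.2f, %.2f]); exact McNemar p = %.4g (%d discordant of %d)\n",
    x$kappa, x$se_kappa, x$ci_low, x$ci_high, x$mcnemar_p,
    x$n_discordant, x$n
  ))
  invisible(x)
}
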