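#' Quartile cutoffs
#'
#' 25th and 75th percentiles under linear interpolation between order
#' statistics (`stats::quantile` type 7), the convention used throughout
#' the package. The bottom group of an extreme-quartile comparison is
#' `values <= q1`, the top group `values >= q3` (ties included).
#'
#' @param values Numeric vector, at least 4 values.
#' @return Named numeric `c(q1, q3)`.
#' @export
quartile_cutoffs <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L)
    stop(errorCondition("need at least 4 values for quartile cutoffs",
                        class = c("hrvrqa_insufficient_data", "hrvrqa_error")))
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  c(q1 = q[1L], q3 = q[2L])
}

#' Descriptive summaries
#'
#' Mean, standard deviation, median and quartiles under the package's
#' quantile convention.
#'
#' @param values Numeric vector, non-empty.
#' @return Named list: `mean`, `sd`, `median`, `q1`, `q3`.
#' @export
descriptive_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop(errorCondition("empty input",
                        class = c("hrvrqa_insufficient_data", "hrvrqa_error")))
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       median = q[2L], q1 = q[1L], q3 = q[3L])
}

#' Extreme-quartile follow-up comparison
#'
#' The cohort hypothesis test: recordings are ranked by one RQA (or entropy)
#' variable, the bottom- and top-quartile groups are formed (`<= q1`,
#' `>= q3`, ties included), and follow-up time (`months_post_tx`) is
#' compared between the two groups. If both groups pass a Shapiro--Wilk
#' normality check at alpha = 0.05 an unpaired two-sided Student's t-test is
#' used, otherwise a two-sided Mann--Whitney (Wilcoxon rank-sum) test.
#'
#' @param table Data frame with `months_post_tx` and the variable column;
#'   no missing values in either.
#' @param variable Column name to split on (e.g. `"lmean"`, `"sampen"`).
#' @return A `quartile_comparison`: variable, cutoffs, per-group follow-up
#'   summaries (mean, sd, median, n), `test_used` (`"t_test"` or
#'   `"mann_whitney"`), two-sided `p_value`, and a `degenerate` flag (TRUE,
#'   with `p_value = NA`, when the variable has no spread so both "extreme"
#'   groups are the whole sample).
#' @export
compare_extreme_quartiles <- function(table, variable) {
  if (!is.data.frame(table) || !"months_post_tx" %in% names(table))
    stop("`table` must be a data.frame with a months_post_tx column",
         call. = FALSE)
  if (!variable %in% names(table))
    stop(sprintf("variable '%s' not in table", variable), call. = FALSE)
  v <- table[[variable]]
  mo <- table$months_post_tx
  if (anyNA(v) || anyNA(mo))
    stop("missing values in tested columns", call. = FALSE)
  cut <- quartile_cutoffs(v)
  lo <- mo[v <= cut[["q1"]]]
  hi <- mo[v >= cut[["q3"]]]
  degenerate <- cut[["q1"]] == cut[["q3"]]
  res <- list(variable = variable,
              q1_cutoff = cut[["q1"]], q4_cutoff = cut[["q3"]],
              group_q1 = group_summary(lo), group_q4 = group_summary(hi),
              test_used = NA_character_, p_value = NA_real_,
              degenerate = degenerate)
  if (degenerate) {
    warning(sprintf("variable '%s' has identical quartile cutoffs; no test performed",
                    variable))
    return(structure(res, class = "quartile_comparison"))
  }
  if (length(lo) < 2L || length(hi) < 2L)
    stop(errorCondition("an extreme-quartile group has fewer than 2 recordings",
                        class = c("hrvrqa_insufficient_data", "hrvrqa_error")))
  gaussian <- is_gaussian(lo) && is_gaussian(hi)
  if (gaussian) {
    res$test_used <- "t_test"
    res$p_value <- stats::t.test(lo, hi)$p.value
  } else {
    res$test_used <- "mann_whitney"
    res$p_value <- stats::wilcox.test(lo, hi, exact = FALSE)$p.value
  }
  structure(res, class = "quartile_comparison")
}

group_summary <- function(x) {
  list(mean = mean(x),
       sd = if (length(x) > 1L) stats::sd(x) else 0,
       median = stats::median(x), n = length(x))
}

# Shapiro-Wilk at alpha = .05; constant groups are not Gaussian-testable,
# treat as non-Gaussian so the rank test is used
is_gaussian <- function(x, alpha = 0.05) {
  if (length(unique(x)) < 3L) return(FALSE)
  stats::shapiro.test(x)$p.value > alpha
}

#' @export
print.quartile_comparison <- function(x, ...) {
  cat(sprintf("<quartile_comparison: %s>\n", x$variable))
  if (x$degenerate) {
    cat("  degenerate: no spread in the variable, no test performed\n")
    return(invisible(x))
  }
  cat(sprintf("  cutoffs: Q1 <= %.4g, Q4 >= %.4g\n", x$q1_cutoff, x$q4_cutoff))
  cat(sprintf("  follow-up Q1: %.2f +/- %.2f months (median %.2f, n = %d)\n",
              x$group_q1$mean, x$group_q1$sd, x$group_q1$median, x$group_q1$n))
  cat(sprintf("  follow-up Q4: %.2f +/- %.2f months (median %.2f, n = %d)\n",
              x$group_q4$mean, x$group_q4$sd, x$group_q4$median, x$group_q4$n))
  cat(sprintf("  %s, two-sided P = %.4g\n", x$test_used, x$p_value))
  invisible(x)
}

#' Per-recording RQA + SampEn table for a cohort
#'
#' Runs the full nonlinear pipeline (embedding, recurrence matrix, seven RQA
#' measures, sample entropy) on each tachogram and assembles the table the
#' quartile comparison consumes.
#'
#' @param tachograms List of `rr_tachogram` (each carrying
#'   `months_post_tx`).
#' @param m,tau,radius,radius_type,norm,lmin,vmin Passed to [rqa_series()].
#' @param sampen_m,sampen_r Passed to [sample_entropy()].
#' @return Data frame: `recording_id`, `months_post_tx`, `rec_pct`,
#'   `det_pct`, `lmean`, `lmax`, `entr`, `lam_pct`, `tt`, `sampen`.
#' @export
cohort_rqa_table <- function(tachograms, m = 10, tau = 1, radius = 70,
                             radius_type = "meanpct", norm = "euclidean",
                             lmin = 2, vmin = 2,
                             sampen_m = 2, sampen_r = 0.2) {
  rows <- lapply(tachograms, function(t) {
    res <- rqa_series(t, m = m, tau = tau, radius = radius,
                      radius_type = radius_type, norm = norm,
                      lmin = lmin, vmin = vmin)
    cbind(data.frame(recording_id = t$patient_id,
                     months_post_tx = t$months_post_tx),
          as.data.frame(res)[-1L],
          data.frame(sampen = sample_entropy(t, m = sampen_m,
                                             r_frac = sampen_r)))
  })
  do.call(rbind, rows)
}

#' Table-shaped quartile report over several variables
#'
#' One [compare_extreme_quartiles()] row per variable; no multiple-testing
#' correction by default (each variable is reported on its own), optionally
#' Holm-adjusted.
#'
#' @param table A cohort table (see [cohort_rqa_table()]).
#' @param variables Character vector of columns to test.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Data frame: variable, cutoffs, group means/SDs/medians/sizes,
#'   test used, p-value (adjusted if requested).
#' @export
quartile_report <- function(table,
                            variables = c("det_pct", "rec_pct", "lmean",
                                          "entr", "sampen"),
                            adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  comps <- lapply(variables, function(v) compare_extreme_quartiles(table, v))
  out <- do.call(rbind, lapply(comps, function(x) {
    data.frame(variable = x$variable,
               q1_cutoff = x$q1_cutoff, q4_cutoff = x$q4_cutoff,
               q1_mean = x$group_q1$mean, q1_sd = x$group_q1$sd,
               q1_median = x$group_q1$median, q1_n = x$group_q1$n,
               q4_mean = x$group_q4$mean, q4_sd = x$group_q4$sd,
               q4_median = x$group_q4$median, q4_n = x$group_q4$n,
               test_used = x$test_used, p_value = x$p_value)
  }))
  if (adjust == "holm") out$p_value <- stats::p.adjust(out$p_value, "holm")
  rownames(out) <- NULL
  out
}
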