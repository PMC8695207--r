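# Group-comparison machinery: per-descriptor two-sample t-tests, Fisher's
# exact test on formal-charge classes, and distribution summaries.

# descriptors entering the t-test comparison (formal charge is handled by
# the Fisher test on charge classes instead)
.comparison_descriptors <- function() {
  c("molar_mass", "aromatic_pct", "rotatable_bonds", "hba74", "hbd74",
    "psa", "logd74", "logs", "logp")
}

#' Per-descriptor two-sample t-tests between compound groups
#'
#' Compares two compound groups descriptor by descriptor (molar mass,
#' aromatic %, rotatable bonds, H-bond acceptors and donors, PSA, log D,
#' log S, log P) with a two-sample t-test; count descriptors are tested
#' as printed values despite their discreteness. The default is the
#' pooled-variance Student's t; set \code{variant = "welch"} for the
#' unequal-variance form.
#'
#' @param group_a,group_b Data frames of compounds with descriptor
#'   columns; each must have at least 2 rows.
#' @param alpha Significance level for the \code{significant} flag.
#' @param variant \code{"pooled"} (Student's, equal variances) or
#'   \code{"welch"}.
#' @return Data frame with one row per descriptor: group means, sds and
#'   sizes, \code{t_stat}, \code{p_value}, \code{significant}. The
#'   chosen variant is recorded in the \code{"variant"} attribute.
#' @export
compare_descriptors <- function(group_a, group_b, alpha = 0.05,
                                variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (!is.data.frame(group_a) || nrow(group_a) < 2L ||
      !is.data.frame(group_b) || nrow(group_b) < 2L) {
    stop(errorCondition("each group needs at least 2 records",
                        class = c("hl_stats_error", "hl_error")))
  }
  rows <- lapply(.comparison_descriptors(), function(d) {
    for (g in list(group_a, group_b)) {
      if (!d %in% names(g) || anyNA(g[[d]])) {
        stop(errorCondition(paste0("descriptor ", d, " missing from a group"),
                            class = c("hl_stats_error", "hl_error")))
      }
    }
    a <- group_a[[d]]; b <- group_b[[d]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      tt <- list(statistic = 0, p.value = 1)   # degenerate: identical constants
    } else {
      tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
    }
    data.frame(descriptor = d,
               mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
               mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
               t_stat = unname(tt$statistic), p_value = unname(tt$p.value),
               significant = unname(tt$p.value) < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "variant") <- variant
  attr(out, "alpha") <- alpha
  out
}

#' Fisher's exact test on formal-charge classes
#'
#' Dichotomises the pH 7.4 formal charge as positive (>= +1) versus
#' non-positive (<= 0) in each group and runs the two-sided Fisher's
#' exact test on the resulting 2 x 2 table (two-sided by summation of
#' tables with probability at most that of the observed table).
#'
#' @param group_a,group_b Non-empty data frames with a
#'   \code{formal_charge74} column.
#' @return List with \code{table} (2 x 2 counts, rows charge class,
#'   columns group), \code{p_value}, \code{odds_ratio} (conditional MLE,
#'   may be 0 or Inf).
#' @export
fisher_charge_test <- function(group_a, group_b) {
  for (g in list(group_a, group_b)) {
    if (!is.data.frame(g) || nrow(g) == 0L ||
        !"formal_charge74" %in% names(g) || anyNA(g$formal_charge74)) {
      stop(errorCondition(
        "both groups must be non-empty with formal_charge74 present",
        class = c("hl_stats_error", "hl_error")))
    }
  }
  tab <- cbind(
    A = c(positive = sum(group_a$formal_charge74 >= 1),
          non_positive = sum(group_a$formal_charge74 <= 0)),
    B = c(sum(group_b$formal_charge74 >= 1),
          sum(group_b$formal_charge74 <= 0)))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, p_value = unname(ft$p.value),
       odds_ratio = unname(ft$estimate))
}

#' Empirical cumulative distribution of formal charge
#'
#' For each integer charge in the observed range, the fraction of
#' compounds with charge at most that value; non-decreasing and ending
#' at 1.
#'
#' @param records Non-empty data frame with \code{formal_charge74}.
#' @return Data frame with columns \code{charge} and \code{cum_fraction}.
#' @export
charge_cdf <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L ||
      !"formal_charge74" %in% names(records) || anyNA(records$formal_charge74)) {
    stop(errorCondition("need a non-empty group with formal_charge74",
                        class = c("hl_stats_error", "hl_error")))
  }
  q <- as.integer(records$formal_charge74)
  grid <- seq.int(min(q), max(q))
  data.frame(charge = grid,
             cum_fraction = vapply(grid, function(c) mean(q <= c), numeric(1)))
}

#' Central percentile interval of a descriptor
#'
#' The empirical interval holding a stated central probability mass,
#' i.e. the ((1 - m)/2, 1 - (1 - m)/2) quantiles (linear interpolation
#' between order statistics, \code{stats::quantile} type 7). With
#' \code{central_mass = 0.8} this is the 10th-90th percentile envelope
#' used to summarise descriptor clouds.
#'
#' @param records Non-empty data frame.
#' @param descriptor Descriptor column name.
#' @param central_mass Fraction of the distribution to enclose, in
#'   (0, 1).
#' @return Named numeric vector \code{c(low, high)}.
#' @export
percentile_interval <- function(records, descriptor, central_mass = 0.8) {
  stopifnot(is.numeric(central_mass), central_mass > 0, central_mass < 1)
  if (!is.data.frame(records) || nrow(records) == 0L ||
      !descriptor %in% names(records) || anyNA(records[[descriptor]])) {
    stop(errorCondition(
      paste0("descriptor ", descriptor, " absent or incomplete"),
      class = c("hl_stats_error", "hl_error")))
  }
  tail_p <- (1 - central_mass) / 2
  q <- stats::quantile(records[[descriptor]], c(tail_p, 1 - tail_p),
                       names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Histogram of herbicide-likeness scores
#'
#' Bins scores into half-point-aligned bins covering at least the
#' default-rule range [-12, 18] (extended outward in whole bins if
#' scores fall outside). Bins are left-open, right-closed except the
#' first which includes its lower edge, so counts always sum to the
#' number of scores.
#'
#' @param scores Non-empty numeric vector of totals.
#' @param bin_width Bin width in score points (a positive multiple of
#'   0.5).
#' @return Data frame with \code{bin_low}, \code{bin_high},
#'   \code{count}.
#' @export
score_histogram <- function(scores, bin_width = 1) {
  stopifnot(length(scores) > 0L, is.numeric(scores),
            bin_width > 0, abs(bin_width * 2 - round(bin_width * 2)) < 1e-9)
  lo <- -12
  hi <- 18
  while (lo > min(scores)) lo <- lo - bin_width
  while (hi < max(scores)) hi <- hi + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  h <- graphics::hist(scores, breaks = breaks, plot = FALSE,
                      right = TRUE, include.lowest = TRUE)
  data.frame(bin_low = breaks[-length(breaks)],
             bin_high = breaks[-1],
             count = h$counts)
}

#' Plot the score distribution of a library under a reference model
#'
#' Scores \code{newdata} with the model and draws the score histogram.
#'
#' @param x An \code{hl_reference}.
#' @param newdata Data frame of compounds with descriptor columns.
#' @param rules An \code{hl_rules}.
#' @param bin_width Histogram bin width in points.
#' @param ... Passed to \code{graphics::barplot}.
#' @return The histogram data frame, invisibly.
#' @export
plot.hl_reference <- function(x, newdata, rules = default_rules(),
                              bin_width = 1, ...) {
  sc <- score_library(newdata, x, rules)$scores
  hg <- score_histogram(sc$total, bin_width)
  graphics::barplot(hg$count,
                    names.arg = sprintf("(%g,%g]", hg$bin_low, hg$bin_high),
                    xlab = "herbicide-likeness score", ylab = "compounds",
                    las = 2, ...)
  invisible(hg)
}
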