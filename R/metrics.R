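#' Dice overlap between two segmentations
#'
#' The reliability workflow compares whole segmentations between raters, so
#' the score is computed on the binarized foreground (any label > 0):
#' `2 |Fa intersect Fb| / (|Fa| + |Fb|)`. Two empty masks score 1 by
#' convention. With `per_region = TRUE` an instance-matched variant is
#' returned instead: for each region of `a`, the Dice against the region of
#' `b` with the largest overlap (this variant is informative but is not the
#' reliability gate).
#'
#' @param a,b [label_volume()]s of identical shape.
#' @param per_region return a per-region matched data.frame instead of the
#'   single foreground score.
#' @return A number in `[0, 1]`, or for `per_region = TRUE` a data.frame with
#'   columns `label_a`, `label_b` (`NA` if nothing overlaps), `dice`.
#' @export
dice <- function(a, b, per_region = FALSE) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  if (!identical(dim(a$data), dim(b$data)))
    stop("label volumes have different shapes", call. = FALSE)
  if (!per_region) {
    fa <- a$data > 0L
    fb <- b$data > 0L
    na <- sum(fa); nb <- sum(fb)
    if (na + nb == 0L) return(1)
    return(2 * sum(fa & fb) / (na + nb))
  }
  labs_a <- region_labels(a)
  out <- lapply(labs_a, function(la) {
    mask <- a$data == la
    size_a <- sum(mask)
    hit <- b$data[mask]
    hit <- hit[hit > 0L]
    if (length(hit) == 0L)
      return(data.frame(label_a = la, label_b = NA_integer_, dice = 0))
    counts <- table(hit)
    lb <- as.integer(names(counts)[which.max(counts)])
    overlap <- max(counts)
    data.frame(label_a = la, label_b = lb,
               dice = 2 * overlap / (size_a + sum(b$data == lb)))
  })
  do.call(rbind, out)
}

#' Number of regions in a label volume
#'
#' @param labels a [label_volume()].
#' @return Count of distinct positive labels present.
#' @export
count_regions <- function(labels) {
  length(region_labels(labels))
}

#' Rater reliability gate
#'
#' New annotators train against a gold-standard segmentation until their
#' foreground Dice reaches the threshold (default 0.85) *and* their nucleus
#' count is within the count tolerance (default +/- 1) of the gold standard.
#'
#' @param a,b [label_volume()]s of identical shape (trainee vs gold standard).
#' @param dice_threshold minimum acceptable Dice (default 0.85).
#' @param count_tolerance maximum allowed absolute difference in region
#'   counts (default 1).
#' @return A `reliability_report` list: `dice`, `count_a`, `count_b`,
#'   `passed`.
#' @export
reliability_check <- function(a, b, dice_threshold = 0.85,
                              count_tolerance = 1L) {
  d <- dice(a, b)
  ca <- count_regions(a); cb <- count_regions(b)
  structure(list(
    dice = d, count_a = ca, count_b = cb,
    dice_threshold = dice_threshold,
    count_tolerance = as.integer(count_tolerance),
    passed = d >= dice_threshold && abs(ca - cb) <= count_tolerance
  ), class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf(
    "<reliability_report> Dice %.4f (gate >= %g), counts %d vs %d (+/- %d): %s\n",
    x$dice, x$dice_threshold, x$count_a, x$count_b, x$count_tolerance,
    if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}

#' Percent reduction between two mean times
#'
#' `100 * (mean_a - mean_b) / mean_a`, reported to one decimal -- the
#' headline efficiency statistic of the annotation-time case study.
#'
#' @param mean_a baseline mean (e.g. minutes), must be positive.
#' @param mean_b comparison mean.
#' @return Percent reduction, rounded to one decimal.
#' @export
percent_reduction <- function(mean_a, mean_b) {
  if (!is.finite(mean_a) || mean_a <= 0)
    stop("`mean_a` must be positive", call. = FALSE)
  round(100 * (mean_a - mean_b) / mean_a, 1)
}

#' Paired two-tailed t-test on per-image annotation times
#'
#' Compares matched per-image times under two conditions (the case-study
#' design: the same images annotated under each condition). Returns the full
#' comparison: means, mean difference, percent reduction, two-tailed paired
#' t statistic and p-value, and the 95% confidence interval of the mean
#' difference from the Student t distribution with `n - 1` degrees of
#' freedom. Degenerate zero-variance differences are handled explicitly:
#' all-zero differences give `t = NaN`, `p = 1`; a constant nonzero
#' difference gives `t = +/-Inf`, `p = 0`, and a degenerate CI at the
#' difference.
#'
#' @param times_a,times_b numeric vectors of equal length `n >= 2`, no
#'   missing values (e.g. minutes per image).
#' @return A `case_study_stats` list: `mean_a`, `mean_b`, `mean_difference`,
#'   `percent_reduction`, `t_statistic`, `df`, `p_value`, `ci95`.
#' @export
paired_t_test <- function(times_a, times_b) {
  if (length(times_a) != length(times_b))
    stop("`times_a` and `times_b` must have equal length", call. = FALSE)
  n <- length(times_a)
  if (n < 2L) stop("need at least 2 paired observations", call. = FALSE)
  if (anyNA(times_a) || anyNA(times_b))
    stop("missing values are not allowed", call. = FALSE)
  d <- times_a - times_b
  md <- mean(d)
  ma <- mean(times_a); mb <- mean(times_b)
  if (sd(d) == 0) {
    if (md == 0) {
      tt <- NaN; p <- 1
    } else {
      tt <- sign(md) * Inf; p <- 0
    }
    ci <- c(md, md)
  } else {
    ht <- stats::t.test(times_a, times_b, paired = TRUE, conf.level = 0.95)
    tt <- unname(ht$statistic)
    p <- ht$p.value
    ci <- as.numeric(ht$conf.int)
  }
  structure(list(
    mean_a = ma, mean_b = mb, mean_difference = md,
    percent_reduction = if (ma > 0) percent_reduction(ma, mb) else NA_real_,
    t_statistic = tt, df = n - 1L,
    p_value = p, ci95 = ci
  ), class = "case_study_stats")
}

#' @export
print.case_study_stats <- function(x, ...) {
  cat(sprintf("<case_study_stats> mean A = %.4g, mean B = %.4g\n",
              x$mean_a, x$mean_b))
  cat(sprintf("  mean difference = %.4g (95%% CI [%.4g, %.4g])\n",
              x$mean_difference, x$ci95[1], x$ci95[2]))
  if (!is.na(x$percent_reduction))
    cat(sprintf("  percent reduction = %.1f%%\n", x$percent_reduction))
  cat(sprintf("  paired t = %.4g, df = %d, p = %s\n",
              x$t_statistic, x$df, format(signif(x$p_value, 5))))
  invisible(x)
}
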