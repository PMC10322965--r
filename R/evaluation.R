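# Diagnostic-accuracy and step-cost evaluation of algorithm outputs against
# the consensus reference: confusion tables, one-vs-rest sensitivity /
# specificity / predictive values / Youden index, over-/under-triage
# proportions, step-count medians with IQR, ROC points, and the
# unequal-variance step-count comparison.

.CAT_LABELS <- c("SK I", "SK II", "SK III")

#' Cross-classify predictions against the reference standard
#'
#' Builds the 3x3 table of reference category (rows) by predicted category
#' (columns).  Abstained or out-of-scale results (for example EX/deceased
#' terminals of prehospital algorithms, which the in-hospital comparison
#' scale excludes) are counted in the \code{excluded} attribute, never in
#' the cells.
#'
#' @param predictions data.frame from [run_triage()] for one algorithm.
#' @param reference data.frame from [median_consensus()].
#' @return 3x3 integer matrix of class \code{triage_confusion} with
#'   attributes \code{excluded} (count) and \code{algorithm}.
#' @export
confusion_table <- function(predictions, reference) {
  missing_ids <- setdiff(predictions$vignette_id, reference$vignette_id)
  if (length(missing_ids)) {
    stop("vignette id(s) without reference rating: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "),
         call. = FALSE)
  }
  ref <- reference$category[match(predictions$vignette_id,
                                  reference$vignette_id)]
  ok <- predictions$status == "ok" & !is.na(predictions$category)
  tab <- table(factor(ref[ok], levels = 1:3),
               factor(predictions$category[ok], levels = 1:3))
  m <- matrix(as.integer(tab), 3L, 3L,
              dimnames = list(reference = .CAT_LABELS,
                              predicted = .CAT_LABELS))
  structure(m, excluded = sum(!ok),
            algorithm = predictions$algorithm[1L],
            class = c("triage_confusion", class(m)))
}

#' @export
print.triage_confusion <- function(x, ...) {
  cat("Confusion table", if (!is.null(attr(x, "algorithm")))
    paste0("(", attr(x, "algorithm"), ")"), "\n")
  print(unclass(x)[, , drop = FALSE])
  cat("excluded (abstained/out-of-scale):", attr(x, "excluded"), "\n")
  invisible(x)
}

#' Youden index
#'
#' \code{J = sensitivity + specificity - 1}, a single-number discrimination
#' measure in \code{[-1, 1]} that weights sensitivity and specificity
#' equally.
#'
#' @param sensitivity,specificity proportions in \code{[0, 1]} (vectors
#'   recycle).
#' @return numeric vector of Youden indices.
#' @export
#' @examples
#' youden(1.00, 0.89)  # 0.89
youden <- function(sensitivity, specificity) {
  chk <- c(sensitivity, specificity)
  if (any(!is.na(chk) & (chk < 0 | chk > 1)))
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  sensitivity + specificity - 1
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Over-/under-triage proportions for one reference category
#'
#' Among vignettes whose reference category is \code{category}, the
#' proportion triaged correctly, to a more urgent category (over-triage)
#' and to a less urgent one (under-triage).  The three proportions sum
#' to 1.  Structurally, SK I can only be under-triaged and SK III only
#' over-triaged.
#'
#' @param tab a [confusion_table()].
#' @param category reference category (1, 2 or 3).
#' @return named numeric vector \code{c(correct, overtriage, undertriage)};
#'   all \code{NA} when the reference stratum is empty.
#' @export
triage_error_rates <- function(tab, category) {
  stopifnot(category %in% 1:3)
  row <- unclass(tab)[category, ]
  n <- sum(row)
  if (n == 0) return(c(correct = NA_real_, overtriage = NA_real_,
                       undertriage = NA_real_))
  pred <- 1:3
  c(correct = row[[category]] / n,
    overtriage = sum(row[pred < category]) / n,   # more urgent = lower ordinal
    undertriage = sum(row[pred > category]) / n)
}

#' One-vs-rest diagnostic accuracy for one category
#'
#' Treats \code{category} as the positive class: sensitivity
#' \code{TP/(TP+FN)}, specificity \code{TN/(TN+FP)}, PPV \code{TP/(TP+FP)},
#' NPV \code{TN/(TN+FN)}, and the Youden index from the unrounded
#' sensitivity and specificity.  Zero denominators yield \code{NA} (an
#' explicit undefined sentinel, rendered as a dash), never an error.
#' Triage-error proportions from [triage_error_rates()] are included.
#'
#' @param tab a [confusion_table()].
#' @param category the positive category (1, 2 or 3).
#' @return object of class \code{category_metrics}: a list with fields
#'   \code{category}, \code{algorithm}, \code{n_reference},
#'   \code{sensitivity}, \code{specificity}, \code{ppv}, \code{npv},
#'   \code{youden}, \code{correct_prop}, \code{overtriage_prop},
#'   \code{undertriage_prop}.
#' @export
one_vs_rest_metrics <- function(tab, category) {
  stopifnot(category %in% 1:3)
  m <- unclass(tab)
  tp <- m[category, category]
  fn <- sum(m[category, ]) - tp
  fp <- sum(m[, category]) - tp
  tn <- sum(m) - tp - fn - fp
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  err <- triage_error_rates(tab, category)
  structure(list(
    category = category,
    algorithm = attr(tab, "algorithm"),
    n_reference = sum(m[category, ]),
    sensitivity = sens,
    specificity = spec,
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    youden = if (is.na(sens) || is.na(spec)) NA_real_ else youden(sens, spec),
    correct_prop = err[["correct"]],
    overtriage_prop = err[["overtriage"]],
    undertriage_prop = err[["undertriage"]]),
    class = "category_metrics")
}

#' @export
print.category_metrics <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.2f", v))
  pct <- function(v) ifelse(is.na(v), "-", sprintf("%.1f %%", 100 * v))
  cat(sprintf("%s, detection of %s (n ref = %d)\n",
              if (is.null(x$algorithm)) "algorithm" else x$algorithm,
              .CAT_LABELS[x$category], x$n_reference))
  cat("  sensitivity", fmt(x$sensitivity),
      " specificity", fmt(x$specificity),
      " PPV", fmt(x$ppv), " NPV", fmt(x$npv),
      " Youden", fmt(x$youden), "\n")
  cat("  over-triage", pct(x$overtriage_prop),
      " under-triage", pct(x$undertriage_prop), "\n")
  invisible(x)
}

#' Step-count summary (median and IQR) for a stratum
#'
#' Summarises how many query nodes an algorithm evaluated before deciding,
#' within one reference category (or all) and one correctness stratum.
#' Quartiles use linear interpolation on fractional ranks by default
#' (\code{quantile} type 7); \code{"weighted"} switches to the
#' weighted-average definition (type 6, the SPSS default) for
#' cross-checks.  An empty stratum yields the none-sentinel (\code{NA}
#' median, n = 0), printed as \code{"none"}.
#'
#' @param results data.frame from [run_triage()] for one algorithm.
#' @param reference data.frame from [median_consensus()].
#' @param category reference category to condition on, or \code{NULL} for
#'   all categories.
#' @param stratum \code{"overall"}, \code{"correct"}, \code{"overtriaged"}
#'   or \code{"undertriaged"} (relative to the reference).
#' @param quartile_method \code{"linear"} (type 7) or \code{"weighted"}
#'   (type 6).
#' @return object of class \code{step_summary}: list with \code{stratum},
#'   \code{category}, \code{median}, \code{q1}, \code{q3}, \code{n}.
#' @export
step_summary <- function(results, reference, category = NULL,
                         stratum = c("overall", "correct", "overtriaged",
                                     "undertriaged"),
                         quartile_method = c("linear", "weighted")) {
  stratum <- match.arg(stratum)
  quartile_method <- match.arg(quartile_method)
  ref <- reference$category[match(results$vignette_id,
                                  reference$vignette_id)]
  keep <- results$status == "ok" & !is.na(results$category)
  if (!is.null(category)) keep <- keep & ref == category
  keep <- keep & switch(stratum,
                        overall = TRUE,
                        correct = results$category == ref,
                        overtriaged = results$category < ref,
                        undertriaged = results$category > ref)
  steps <- results$steps[keep]
  if (!length(steps)) {
    return(structure(list(stratum = stratum, category = category,
                          median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                          n = 0L),
                     class = "step_summary"))
  }
  qt <- if (quartile_method == "linear") 7L else 6L
  q <- stats::quantile(steps, c(0.25, 0.75), type = qt, names = FALSE)
  structure(list(stratum = stratum, category = category,
                 median = stats::median(steps), q1 = q[1L], q3 = q[2L],
                 n = length(steps)),
            class = "step_summary")
}

#' @export
format.step_summary <- function(x, ...) {
  if (x$n == 0L) return("none")
  num <- function(v) format(round(v, 2), trim = TRUE)
  sprintf("%s (%s-%s)", num(x$median), num(x$q1), num(x$q3))
}

#' @export
print.step_summary <- function(x, ...) {
  cat(sprintf("steps [%s%s]: %s, n = %d\n",
              if (is.null(x$category)) "all SK" else .CAT_LABELS[x$category],
              paste0(", ", x$stratum), format(x), x$n))
  invisible(x)
}

#' ROC points for a set of algorithms
#'
#' One labelled point per algorithm in the (1 - specificity, sensitivity)
#' plane, for one detection category.  Algorithms with undefined
#' sensitivity or specificity are omitted with a message.
#'
#' @param metrics list of [one_vs_rest_metrics()] objects (or a
#'   \code{triage_eval} object, from which the per-algorithm metrics for
#'   \code{category} are taken).
#' @param category detection category (1, 2 or 3).
#' @return data.frame with columns \code{algorithm}, \code{fpr},
#'   \code{tpr}.
#' @export
roc_points <- function(metrics, category = 1L) {
  if (inherits(metrics, "triage_eval")) {
    metrics <- metrics$metrics[[category]]
  }
  rows <- lapply(metrics, function(m) {
    if (is.na(m$sensitivity) || is.na(m$specificity)) {
      message("omitting ", m$algorithm,
              ": undefined sensitivity or specificity")
      return(NULL)
    }
    data.frame(algorithm = if (is.null(m$algorithm)) NA_character_
                           else m$algorithm,
               fpr = 1 - m$specificity, tpr = m$sensitivity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(algorithm = character(),
                                      fpr = numeric(), tpr = numeric())
  rownames(out) <- NULL
  out
}

welch_guard <- function(v) {
  # zero-variance groups are tolerated: floor the variance at a tiny
  # positive value so the Welch weights stay finite; equal constant groups
  # then give a null statistic, different ones an extreme statistic
  pmax(v, 1e-12)
}

welch_anova <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, 0L)
  m <- vapply(groups, mean, 0)
  s2 <- welch_guard(vapply(groups, stats::var, 0))
  w <- n / s2
  mw <- sum(w * m) / sum(w)
  a <- sum(w * (m - mw)^2) / (k - 1)
  lam <- sum((1 - w / sum(w))^2 / (n - 1))
  b <- 1 + 2 * (k - 2) / (k^2 - 1) * lam
  f <- a / b
  df2 <- (k^2 - 1) / (3 * lam)
  stats::pf(f, k - 1, df2, lower.tail = FALSE)
}

welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- welch_guard(stats::var(x)); vy <- welch_guard(stats::var(y))
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, diff = mean(x) - mean(y))
}

#' Compare step counts across algorithms under unequal variances
#'
#' Omnibus heterogeneity by Welch's one-way ANOVA (valid without equal
#' variances), followed by all pairwise comparisons with a Dunnett-T3-type
#' procedure: Welch t statistics with Satterthwaite degrees of freedom,
#' referred to the studentized-maximum-modulus bound (implemented as the
#' Sidak-style bound \code{1 - (2 * pt(|t|) - 1)^m} over the \code{m}
#' comparisons, which equals the SMM tail for independent statistics and is
#' conservative otherwise).  \code{method = "games_howell"} instead refers
#' \code{|t| * sqrt(2)} to the studentized range.
#'
#' @param step_groups named list of numeric step-count vectors, one per
#'   algorithm; at least two groups of two or more counts.  Zero-variance
#'   groups are tolerated.
#' @param alpha familywise significance level.
#' @param method pairwise procedure.
#' @return object of class \code{step_comparison}: list with
#'   \code{omnibus_p}, \code{pairwise} (data.frame \code{a}, \code{b},
#'   \code{diff}, \code{t}, \code{df}, \code{p}, \code{significant}),
#'   \code{alpha}, \code{method}.
#' @export
compare_step_counts <- function(step_groups, alpha = 0.05,
                                method = c("dunnett_t3", "games_howell")) {
  method <- match.arg(method)
  if (length(step_groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(vapply(step_groups, length, 0L) < 2L))
    stop("every group needs n >= 2", call. = FALSE)
  if (is.null(names(step_groups)))
    names(step_groups) <- paste0("group", seq_along(step_groups))
  k <- length(step_groups)
  pairs <- utils::combn(names(step_groups), 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    wt <- welch_t(step_groups[[a]], step_groups[[b]])
    p <- if (method == "dunnett_t3") {
      inner <- 2 * stats::pt(abs(wt$t), wt$df) - 1
      min(1, 1 - inner^m)
    } else {
      stats::ptukey(abs(wt$t) * sqrt(2), k, wt$df, lower.tail = FALSE)
    }
    data.frame(a = a, b = b, diff = wt$diff, t = wt$t, df = wt$df, p = p,
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$significant <- pw$p < alpha
  structure(list(omnibus_p = welch_anova(step_groups), pairwise = pw,
                 alpha = alpha, method = method),
            class = "step_comparison")
}

#' @export
print.step_comparison <- function(x, ...) {
  cat(sprintf("Welch ANOVA omnibus p = %.4g; pairwise (%s, alpha = %g):\n",
              x$omnibus_p, x$method, x$alpha))
  pw <- x$pairwise
  pw$p <- signif(pw$p, 3)
  pw$t <- round(pw$t, 2); pw$df <- round(pw$df, 1)
  pw$diff <- round(pw$diff, 2)
  print(pw, row.names = FALSE)
  invisible(x)
}
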