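# Central evaluation object: run every algorithm over a vignette set,
# cross-classify against the consensus reference, and hold the
# per-category accuracy metrics, step summaries and exclusion counts in
# one classed object with print / summary / plot methods.

#' Evaluate triage algorithms against a reference standard
#'
#' The package's main entry point.  Runs each algorithm over the vignette
#' set, builds per-algorithm confusion tables against the median-consensus
#' reference, and computes one-vs-rest diagnostic accuracy (sensitivity,
#' specificity, PPV, NPV, Youden index), over-/under-triage proportions and
#' step-count summaries for every category.
#'
#' @param set a [vignette_set()].
#' @param algorithms list of \code{triage_algorithm} objects (default the
#'   seven shipped encodings).
#' @param reference data.frame from [median_consensus()] (or a rating
#'   matrix, which is reduced by median consensus with the default tie
#'   policy first).
#' @param unknown_policy passed to [run_triage()].
#' @param quartile_method passed to [step_summary()].
#' @return object of class \code{triage_eval} with components
#'   \code{results} (all raw triage results), \code{reference},
#'   \code{confusion} (list by algorithm), \code{metrics} (list by
#'   category of lists by algorithm of [one_vs_rest_metrics()]),
#'   \code{steps} (data.frame of step summaries), \code{excluded} (named
#'   counts), \code{n_vignettes}, and the policies used.
#' @export
#' @examples
#' oracle <- shipped_algorithms("BER")[[1]]
#' sim <- generate_vignettes(60, oracle, seed = 1)
#' ratings <- simulate_panel(sim$truth, n_raters = 5, seed = 2)
#' ev <- triage_eval(sim$set, shipped_algorithms(c("BER", "mSTaRT")),
#'                   median_consensus(ratings))
#' summary(ev, category = 1)
triage_eval <- function(set, algorithms = shipped_algorithms(),
                        reference,
                        unknown_policy = c("as_no", "as_yes", "abstain"),
                        quartile_method = c("linear", "weighted")) {
  unknown_policy <- match.arg(unknown_policy)
  quartile_method <- match.arg(quartile_method)
  if (is.matrix(reference)) reference <- median_consensus(reference)
  if (is.null(names(algorithms)))
    names(algorithms) <- vapply(algorithms, `[[`, "", "name")

  results <- run_triage_all(algorithms, set, unknown_policy)
  confusion <- list()
  metrics <- list(list(), list(), list())
  steps <- list()
  excluded <- integer()
  strata <- list("1" = c("correct", "undertriaged", "overall"),
                 "2" = c("correct", "overtriaged", "undertriaged",
                         "overall"),
                 "3" = c("correct", "overtriaged", "overall"))
  for (nm in names(algorithms)) {
    pred <- results[results$algorithm == algorithms[[nm]]$name, ]
    tab <- confusion_table(pred, reference)
    confusion[[nm]] <- tab
    excluded[nm] <- attr(tab, "excluded")
    for (k in 1:3) {
      metrics[[k]][[nm]] <- one_vs_rest_metrics(tab, k)
      for (st in strata[[as.character(k)]]) {
        s <- step_summary(pred, reference, category = k, stratum = st,
                          quartile_method = quartile_method)
        steps[[length(steps) + 1L]] <-
          data.frame(algorithm = nm, category = k, stratum = st,
                     median = s$median, q1 = s$q1, q3 = s$q3, n = s$n,
                     stringsAsFactors = FALSE)
      }
    }
    s <- step_summary(pred, reference, category = NULL,
                      stratum = "overall", quartile_method = quartile_method)
    steps[[length(steps) + 1L]] <-
      data.frame(algorithm = nm, category = NA_integer_,
                 stratum = "overall", median = s$median, q1 = s$q1,
                 q3 = s$q3, n = s$n, stringsAsFactors = FALSE)
  }
  structure(list(results = results, reference = reference,
                 confusion = confusion, metrics = metrics,
                 steps = do.call(rbind, steps), excluded = excluded,
                 n_vignettes = nrow(set),
                 unknown_policy = unknown_policy,
                 quartile_method = quartile_method),
            class = "triage_eval")
}

#' @export
print.triage_eval <- function(x, ...) {
  cat(sprintf(paste0("Triage evaluation: %d algorithms x %d vignettes ",
                     "(unknown items %s)\n"),
              length(x$confusion), x$n_vignettes, x$unknown_policy))
  if (any(x$excluded > 0)) {
    ex <- x$excluded[x$excluded > 0]
    cat("Excluded results (abstained/out-of-scale):",
        paste(sprintf("%s %d", names(ex), ex), collapse = ", "), "\n")
  }
  y <- vapply(x$metrics[[1]], function(m)
    ifelse(is.na(m$youden), NA_real_, m$youden), 0)
  cat("Youden index, detection of SK I (red):\n")
  print(round(sort(y, decreasing = TRUE, na.last = TRUE), 2))
  invisible(x)
}

#' Category report table for a triage evaluation
#'
#' Renders the accuracy and step-count block for one detection category as
#' a metric-by-algorithm character table: proportions to two decimals,
#' triage-error percentages to one decimal, step medians as
#' \code{"median (q1-q3)"} with empty strata shown as \code{"none"} and
#' undefined metrics as \code{"-"}.
#'
#' @param object a \code{triage_eval}.
#' @param category detection category (1, 2 or 3).
#' @param ... unused.
#' @return character matrix (invisibly returned by the print method);
#'   rows are metrics, columns algorithms.
#' @export
summary.triage_eval <- function(object, category = 1L, ...) {
  stopifnot(category %in% 1:3)
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.2f", v))
  pct <- function(v) ifelse(is.na(v), "-", sprintf("%.1f %%", 100 * v))
  algs <- names(object$confusion)
  ms <- object$metrics[[category]]
  rows <- list(
    Sensitivity = vapply(ms, function(m) fmt(m$sensitivity), ""),
    Specificity = vapply(ms, function(m) fmt(m$specificity), ""),
    PPV = vapply(ms, function(m) fmt(m$ppv), ""),
    NPV = vapply(ms, function(m) fmt(m$npv), ""),
    `Youden index` = vapply(ms, function(m) fmt(m$youden), ""))
  if (category > 1L)
    rows[["Over-triage"]] <- vapply(ms, function(m)
      pct(m$overtriage_prop), "")
  if (category < 3L)
    rows[["Under-triage"]] <- vapply(ms, function(m)
      pct(m$undertriage_prop), "")
  fmt_steps <- function(st) {
    sel <- object$steps[object$steps$stratum == st &
                          !is.na(object$steps$category) &
                          object$steps$category == category, ]
    vapply(algs, function(a) {
      r <- sel[sel$algorithm == a, ]
      if (!nrow(r) || r$n == 0L) return("none")
      num <- function(v) format(round(v, 2), trim = TRUE)
      sprintf("%s (%s-%s)", num(r$median), num(r$q1), num(r$q3))
    }, "")
  }
  rows[["Steps, correct"]] <- fmt_steps("correct")
  if (category > 1L) rows[["Steps, over-triaged"]] <- fmt_steps("overtriaged")
  if (category < 3L) rows[["Steps, under-triaged"]] <-
      fmt_steps("undertriaged")
  rows[["Steps, overall"]] <- fmt_steps("overall")
  out <- do.call(rbind, rows)
  colnames(out) <- algs
  structure(out, category = category, class = "summary.triage_eval")
}

#' @export
print.summary.triage_eval <- function(x, ...) {
  cat("Detection of", .CAT_LABELS[attr(x, "category")], "\n")
  print(unclass(x), quote = FALSE)
  invisible(x)
}

#' @param x a \code{triage_eval}.
#' @param category detection category for the ROC plane.
#' @param ... further arguments to \code{plot}.
#' @rdname triage_eval
#' @export
plot.triage_eval <- function(x, category = 1L, ...) {
  pts <- roc_points(x, category)
  plot(pts$fpr, pts$tpr, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "Sensitivity",
       main = paste("Detection of", .CAT_LABELS[category]),
       pch = 19, ...)
  graphics::abline(0, 1, lty = 3)
  graphics::text(pts$fpr, pts$tpr, pts$algorithm, pos = 4, cex = 0.8,
                 xpd = NA)
  invisible(pts)
}
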