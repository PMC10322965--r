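# Confusion tables, one-vs-rest accuracy, triage-error identities, step
# summaries and the unequal-variance step comparison.

toy_table <- function() {
  confusion_table(fake_predictions(c(1L, 2L, 2L, 3L, 2L, 3L)),
                  fake_reference(c(1L, 1L, 2L, 3L, 3L, 3L)))
}

test_that("confusion table cells match a hand count", {
  tab <- toy_table()
  m <- unclass(tab)
  expect_equal(m["SK I", "SK I"], 1L)
  expect_equal(m["SK I", "SK II"], 1L)
  expect_equal(m["SK II", "SK II"], 1L)
  expect_equal(m["SK III", "SK III"], 2L)
  expect_equal(m["SK III", "SK II"], 1L)
  expect_equal(sum(m), 6L)
  expect_equal(attr(tab, "excluded"), 0L)
})

test_that("perfect predictions give a diagonal table", {
  ref <- c(1L, 2L, 3L, 2L, 1L)
  tab <- confusion_table(fake_predictions(ref), fake_reference(ref))
  expect_equal(sum(diag(unclass(tab))), 5L)
  expect_equal(sum(unclass(tab)), 5L)
})

test_that("abstained results are excluded, never counted", {
  tab <- confusion_table(fake_predictions(c(1L, NA, 3L)),
                         fake_reference(c(1L, 2L, 3L)))
  expect_equal(attr(tab, "excluded"), 1L)
  expect_equal(sum(unclass(tab)), 2L)
})

test_that("unmatched vignette ids are named in the error", {
  expect_error(
    confusion_table(fake_predictions(c(1L, 2L), ids = c("V1", "VX")),
                    fake_reference(1L, ids = "V1")),
    "VX")
})

test_that("one-vs-rest metrics match the worked example and handle zeros", {
  m <- one_vs_rest_metrics(toy_table(), 1L)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$ppv, 1.0)
  expect_equal(m$youden, 0.5)

  # degenerate constant-red predictor
  tab <- confusion_table(fake_predictions(rep(1L, 6)),
                         fake_reference(c(1L, 1L, 2L, 3L, 3L, 3L)))
  m1 <- one_vs_rest_metrics(tab, 1L)
  expect_equal(m1$sensitivity, 1)
  expect_equal(m1$specificity, 0)
  expect_equal(m1$youden, 0)
  expect_true(is.na(m1$npv))  # no negative calls at all

  # empty reference stratum -> undefined sentinel, no error
  tab2 <- confusion_table(fake_predictions(c(1L, 3L)),
                          fake_reference(c(1L, 3L)))
  expect_true(is.na(one_vs_rest_metrics(tab2, 2L)$sensitivity))
  expect_true(all(is.na(triage_error_rates(tab2, 2L))))
})

test_that("youden reproduces printed pairs and rejects bad input", {
  expect_equal(youden(1.00, 0.89), 0.89)
  expect_equal(round(youden(0.16, 0.73), 2), -0.11)
  expect_equal(youden(0.5, 0.5), 0)
  expect_error(youden(1.2, 0.5), "\\[0, 1\\]")
})

test_that("triage-error identities hold on random tables", {
  tab <- toy_table()
  e3 <- triage_error_rates(tab, 3L)
  expect_equal(e3[["overtriage"]], 1 / 3)
  expect_equal(e3[["undertriage"]], 0)

  set.seed(31)
  for (rep in 1:200) {
    n <- sample(3:50, 1)
    ref <- sample(1:3, n, replace = TRUE)
    pred <- sample(1:3, n, replace = TRUE)
    tab <- confusion_table(fake_predictions(pred), fake_reference(ref))
    for (k in 1:3) {
      e <- triage_error_rates(tab, k)
      m <- one_vs_rest_metrics(tab, k)
      if (!any(ref == k)) next
      # the three proportions partition the reference stratum
      expect_equal(e[["correct"]] + e[["overtriage"]] + e[["undertriage"]],
                   1)
      expect_equal(e[["correct"]], m$sensitivity)
    }
    # structural zeros and their sensitivity complements
    expect_equal(triage_error_rates(tab, 1L)[["overtriage"]],
                 if (any(ref == 1)) 0 else NA_real_)
    expect_equal(triage_error_rates(tab, 3L)[["undertriage"]],
                 if (any(ref == 3)) 0 else NA_real_)
    if (any(ref == 1))
      expect_equal(triage_error_rates(tab, 1L)[["undertriage"]],
                   1 - one_vs_rest_metrics(tab, 1L)$sensitivity)
    if (any(ref == 3))
      expect_equal(triage_error_rates(tab, 3L)[["overtriage"]],
                   1 - one_vs_rest_metrics(tab, 3L)$sensitivity)
  }
})

test_that("metrics agree with a brute-force oracle and Bayes' rule", {
  set.seed(32)
  for (rep in 1:200) {
    n <- sample(5:50, 1)
    ref <- sample(1:3, n, replace = TRUE)
    pred <- sample(1:3, n, replace = TRUE)
    tab <- confusion_table(fake_predictions(pred), fake_reference(ref))
    for (k in 1:3) {
      m <- one_vs_rest_metrics(tab, k)
      b <- brute_metrics(ref, pred, k)
      expect_equal(m$sensitivity, b$sensitivity)
      expect_equal(m$specificity, b$specificity)
      expect_equal(m$ppv, b$ppv)
      expect_equal(m$npv, b$npv)
      expect_equal(m$overtriage_prop, b$overtriage)
      expect_equal(m$undertriage_prop, b$undertriage)
      # PPV via Bayes from sensitivity, specificity and prevalence
      if (!is.na(m$ppv) && !is.na(m$sensitivity) && !is.na(m$specificity)) {
        pi <- mean(ref == k)
        bayes <- m$sensitivity * pi /
          (m$sensitivity * pi + (1 - m$specificity) * (1 - pi))
        expect_equal(m$ppv, bayes)
      }
    }
  }
})

test_that("step summaries use the declared quartile definitions", {
  res <- fake_predictions(rep(2L, 5), steps = c(2L, 3L, 3L, 4L, 6L))
  ref <- fake_reference(rep(2L, 5))
  s <- step_summary(res, ref, category = 2L, stratum = "correct")
  expect_equal(s$median, 3)
  expect_equal(c(s$q1, s$q3), c(3, 4))  # type-7 linear interpolation
  s6 <- step_summary(res, ref, category = 2L, stratum = "correct",
                     quartile_method = "weighted")
  expect_equal(c(s6$q1, s6$q3),
               unname(quantile(c(2, 3, 3, 4, 6), c(.25, .75), type = 6)))

  empty <- step_summary(res, ref, category = 1L, stratum = "correct")
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$median))
  expect_equal(format(empty), "none")

  single <- step_summary(fake_predictions(1L, steps = 5L),
                         fake_reference(1L), category = 1L,
                         stratum = "correct")
  expect_equal(c(single$median, single$q1, single$q3), c(5, 5, 5))
})

test_that("ROC points are (1 - specificity, sensitivity) with omissions", {
  ms <- list(
    structure(list(algorithm = "BER", sensitivity = 1.00,
                   specificity = 0.89), class = "category_metrics"),
    structure(list(algorithm = "perfect", sensitivity = 1,
                   specificity = 1), class = "category_metrics"),
    structure(list(algorithm = "undef", sensitivity = NA_real_,
                   specificity = 0.5), class = "category_metrics"))
  expect_message(pts <- roc_points(ms), "undef")
  expect_equal(nrow(pts), 2L)
  expect_equal(pts$fpr[pts$algorithm == "BER"], 0.11)
  expect_equal(pts$tpr[pts$algorithm == "BER"], 1.00)
  expect_equal(unlist(pts[pts$algorithm == "perfect", c("fpr", "tpr")]),
               c(fpr = 0, tpr = 1))
  # chance-level inputs fall on the diagonal
  chance <- structure(list(algorithm = "coin", sensitivity = 0.3,
                           specificity = 0.7), class = "category_metrics")
  p <- roc_points(list(chance))
  expect_equal(p$fpr, p$tpr)
})

test_that("step comparison flags real differences, not identical groups", {
  same <- list(a = rep(3, 10), b = rep(3, 10))
  cmp <- compare_step_counts(same)
  expect_false(any(cmp$pairwise$significant))
  expect_gt(cmp$omnibus_p, 0.9)

  set.seed(1)
  g <- list(short = round(rnorm(50, 3, 1)), long = round(rnorm(50, 10, 1)))
  cmp2 <- compare_step_counts(g)
  expect_lt(cmp2$omnibus_p, 0.001)
  expect_true(all(cmp2$pairwise$significant))
  gh <- compare_step_counts(g, method = "games_howell")
  expect_true(all(gh$pairwise$significant))

  expect_error(compare_step_counts(list(a = 1:3)), "two groups")
  expect_error(compare_step_counts(list(a = 1, b = 1:3)), "n >= 2")
})

test_that("familywise error stays controlled under the null", {
  set.seed(33)
  reps <- 400
  hits <- 0
  for (r in seq_len(reps)) {
    groups <- lapply(1:4, function(i) sample(1:8, 20, replace = TRUE))
    names(groups) <- paste0("g", 1:4)
    cmp <- compare_step_counts(groups)
    if (any(cmp$pairwise$significant)) hits <- hits + 1
  }
  fwer <- hits / reps
  # allow ~2.5 binomial standard errors above the nominal level
  expect_lte(fwer, 0.05 + 2.5 * sqrt(0.05 * 0.95 / reps))
})
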