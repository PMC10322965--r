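# Expert-consensus reference standard: Delphi-stage bookkeeping and median
# consensus over the rating matrix.
#
# The study design: a small panel (6 experts) pre-screens candidate
# vignettes in a two-stage Delphi process, removing duplicates and vignettes
# without consensus; the surviving set then goes to a wide panel (36
# triage-experienced emergency physicians) whose per-vignette median rating
# on the ordinal scale SK I < SK II < SK III is the gold standard.  Only
# SK I-III are assignable at the hospital entrance.

#' Read an expert rating matrix
#'
#' CSV with a \code{vignette_id} column and one column per rater; cells are
#' the ordinal categories 1 (SK I, red), 2 (SK II, yellow), 3 (SK III,
#' green).
#'
#' @param path CSV path.
#' @return integer matrix, rows named by vignette id, columns by rater id.
#' @export
read_ratings <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!"vignette_id" %in% names(tab))
    stop("no 'vignette_id' column in ", path, call. = FALSE)
  ids <- as.character(tab$vignette_id)
  m <- as.matrix(tab[setdiff(names(tab), "vignette_id")])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  validate_ratings(m)
  m
}

validate_ratings <- function(ratings) {
  if (!is.matrix(ratings) || !length(ratings))
    stop("ratings must be a non-empty vignette x rater matrix",
         call. = FALSE)
  if (anyNA(ratings))
    stop("rating matrix is incomplete (NA cells)", call. = FALSE)
  if (!all(ratings %in% 1:3))
    stop("ratings outside the ordinal scale 1-3", call. = FALSE)
  invisible(ratings)
}

#' Median consensus category per vignette
#'
#' The reference category of each vignette is the median of its expert
#' ratings.  With an even panel the median can fall between two categories
#' (half-integral); such ties are resolved by \code{tie_policy}:
#' \code{"toward_urgent"} (default) rounds to the more urgent (lower)
#' category — the triage-safety convention of preferring over- to
#' under-triage in the reference — and \code{"toward_less_urgent"} rounds
#' the other way.  Tied vignettes are flagged so they can be reported.
#'
#' @param ratings vignette x rater matrix of ratings in 1-3 (rows named by
#'   vignette id), as from [read_ratings()] or [simulate_panel()].
#' @param tie_policy resolution of half-integral medians.
#' @return data.frame with columns \code{vignette_id}, \code{median_value},
#'   \code{tied}, \code{category}, in the input row order.
#' @export
median_consensus <- function(ratings,
                             tie_policy = c("toward_urgent",
                                            "toward_less_urgent")) {
  tie_policy <- match.arg(tie_policy)
  validate_ratings(ratings)
  med <- apply(ratings, 1L, stats::median)
  tied <- med %% 1 != 0
  category <- if (tie_policy == "toward_urgent") floor(med) else ceiling(med)
  ids <- rownames(ratings)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(ratings)))
  data.frame(vignette_id = ids, median_value = unname(med),
             tied = unname(tied), category = as.integer(category),
             stringsAsFactors = FALSE)
}

#' Delphi pre-filter of candidate vignettes
#'
#' Implements the first-stage bookkeeping of the vignette preparation: a
#' small expert panel rates every candidate independently; duplicates are
#' dropped outright, vignettes meeting the agreement rule are kept, and the
#' rest go to a discussion round.  The returned partition is exhaustive and
#' disjoint over the input.
#'
#' @param stage1 vignette x rater matrix of first-stage ratings in 1-3
#'   (rows named by vignette id; the study panel had 6 members).
#' @param duplicate logical vector flagging duplicate vignettes.
#' @param rule \code{"unanimity"} (default: all raters agree) or
#'   \code{"majority"}.
#' @param min_agree for \code{rule = "majority"}, the minimum count of the
#'   modal rating needed to keep a vignette without discussion.
#' @return list with character-vector elements \code{keep}, \code{discuss},
#'   \code{drop}.
#' @export
delphi_prefilter <- function(stage1, duplicate = FALSE,
                             rule = c("unanimity", "majority"),
                             min_agree = NULL) {
  rule <- match.arg(rule)
  validate_ratings(stage1)
  duplicate <- rep_len(as.logical(duplicate), nrow(stage1))
  ids <- rownames(stage1)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(stage1)))
  agrees <- apply(stage1, 1L, function(r) {
    if (rule == "unanimity") length(unique(r)) == 1L
    else max(tabulate(r, nbins = 3L)) >= min_agree
  })
  list(keep = ids[agrees & !duplicate],
       discuss = ids[!agrees & !duplicate],
       drop = ids[duplicate])
}
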