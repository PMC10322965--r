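# Seeded synthetic vignettes and expert panels.
#
# The study's 210 vignettes and 7560 expert ratings are not published, so
# every pipeline stage is exercised on generated data: a category is drawn
# from a prevalence distribution, a root-to-terminal path of an oracle
# algorithm reaching that category is sampled, the queried items along the
# path are forced to take that path (so the planted truth is identifiable
# and exactly recoverable in the noiseless limit), and off-path items are
# randomized.  Expert panels are simulated by drawing each rating from a
# row-stochastic confusion matrix given the planted truth.

#' Enumerate root-to-terminal paths of an algorithm
#'
#' Depth-first enumeration of all consistent root-to-terminal paths.  A
#' path is a set of item-state constraints; paths requiring contradictory
#' states of the same item are dropped.  Resource-test constraints are
#' intersected over the admissible levels.
#'
#' @param alg a \code{triage_algorithm}.
#' @return list of paths, each a list with \code{items} (named character
#'   vector of required states), \code{resource_levels} (admissible
#'   levels, or \code{NULL} if unconstrained), \code{raw} (terminal
#'   output), \code{category} (mapped category or \code{NA}), \code{nodes}
#'   (node-id trace), \code{steps}.
#' @export
enumerate_paths <- function(alg) {
  res_all <- c("none", "one", "many")
  out <- list()
  walk <- function(node_id, items, res_levels, trace) {
    nd <- alg$nodes[[node_id]]
    trace <- c(trace, node_id)
    for (state in c("yes", "no")) {
      items2 <- items
      res2 <- res_levels
      if (!is.na(nd$test)) {
        hit <- switch(nd$test,
                      none = res_all == "none",
                      one = res_all == "one",
                      many = res_all == "many",
                      at_least_one = res_all %in% c("one", "many"))
        allowed <- res_all[if (state == "yes") hit else !hit]
        res2 <- if (is.null(res2)) allowed else intersect(res2, allowed)
        if (!length(res2)) next
      } else {
        prev <- items2[nd$item]
        if (!is.na(prev) && prev != state) next
        items2[nd$item] <- state
      }
      ref <- if (state == "yes") nd$on_yes else nd$on_no
      if (!is.null(ref$goto)) {
        walk(ref$goto, items2, res2, trace)
      } else {
        raw <- as.character(ref$out)
        cat <- unname(alg$scale_map[raw])
        out[[length(out) + 1L]] <<- list(
          items = items2[!is.na(items2)],
          resource_levels = res2, raw = raw,
          category = if (is.na(cat)) NA_integer_ else as.integer(cat),
          nodes = trace, steps = length(trace))
      }
    }
    invisible()
  }
  walk(alg$root, stats::setNames(rep(NA_character_, 0), character()),
       NULL, character())
  out
}

#' Generate a synthetic vignette set with planted truth
#'
#' For each vignette a category is drawn from \code{prevalence}, a path of
#' the \code{oracle} algorithm reaching that category is sampled uniformly,
#' and the items queried along that path are set to force it.  Off-path
#' items start at \code{"no"}, flip to \code{"yes"} with probability
#' \code{feature_noise}, and are masked to \code{"unknown"} with
#' probability \code{unknown_rate}; on-path items are never perturbed, so
#' with zero noise the oracle reproduces the planted truth exactly.  The
#' default prevalence 20/30/50 % reflects reported scenario-dependent
#' category distributions in mass-casualty incidents.
#'
#' @param n number of vignettes (the study scale is 210).
#' @param oracle a \code{triage_algorithm} used as generating truth.
#' @param prevalence probabilities of SK I, II, III.
#' @param feature_noise probability of flipping an off-path item away from
#'   its baseline state.
#' @param unknown_rate probability of masking an off-path item to unknown.
#' @param baseline_states named character vector of baseline (benign)
#'   states for off-path items; items not named default to \code{"no"}
#'   (a pathological finding is absent unless the path requires it).
#'   Normally-present findings — spontaneous breathing and a palpable
#'   radial pulse — default to \code{"yes"}.
#' @param items item universe for the set; defaults to the oracle's queried
#'   items.  Pass a \code{feature_vocabulary} (or character vector) to get
#'   a wider universe whose extra columns are randomized off-path items.
#' @param seed integer seed; identical configurations give identical
#'   output.
#' @param id_prefix prefix for generated vignette ids.
#' @return list with elements \code{set} (a [vignette_set()]) and
#'   \code{truth} (named integer vector: vignette id -> planted category).
#' @export
generate_vignettes <- function(n, oracle,
                               prevalence = c(0.2, 0.3, 0.5),
                               feature_noise = 0, unknown_rate = 0,
                               items = NULL, seed = NULL,
                               baseline_states = c(breathing_present = "yes",
                                                   radial_pulse = "yes"),
                               id_prefix = "V") {
  stopifnot(inherits(oracle, "triage_algorithm"), n >= 1)
  if (length(prevalence) != 3 || any(prevalence < 0) ||
      abs(sum(prevalence) - 1) > 1e-9)
    stop("prevalence must be three probabilities summing to 1",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(items, "feature_vocabulary")) items <- items$items
  items <- union(algorithm_items(oracle), items)
  items <- setdiff(items, "esi_resources")

  paths <- enumerate_paths(oracle)
  by_cat <- lapply(1:3, function(k)
    Filter(function(p) !is.na(p$category) && p$category == k, paths))
  missing <- which(vapply(by_cat, length, 0L) == 0L)
  if (length(missing)) {
    stop("oracle has no terminal for categor",
         if (length(missing) > 1) "ies " else "y ",
         paste(.CAT_LABELS[missing], collapse = ", "), call. = FALSE)
  }

  truth <- sample.int(3L, n, replace = TRUE, prob = prevalence)
  ids <- sprintf("%s%0*d", id_prefix, nchar(n), seq_len(n))
  baseline <- stats::setNames(rep("no", length(items)), items)
  known <- intersect(names(baseline_states), items)
  baseline[known] <- baseline_states[known]
  feat <- matrix(rep(baseline, each = n), nrow = n,
                 dimnames = list(NULL, items))
  resources <- rep("none", n)
  for (i in seq_len(n)) {
    cand <- by_cat[[truth[i]]]
    path <- cand[[sample.int(length(cand), 1L)]]
    off <- setdiff(items, names(path$items))
    if (length(off)) {
      flips <- stats::runif(length(off)) < feature_noise
      states <- ifelse(flips,
                       ifelse(baseline[off] == "yes", "no", "yes"),
                       baseline[off])
      masked <- stats::runif(length(off)) < unknown_rate
      states[masked] <- "unknown"
      feat[i, off] <- states
    }
    if (length(path$items)) feat[i, names(path$items)] <- path$items
    resources[i] <- if (!is.null(path$resource_levels)) {
      path$resource_levels[sample.int(length(path$resource_levels), 1L)]
    } else if (stats::runif(1) < feature_noise) {
      sample(c("one", "many"), 1L)
    } else "none"
  }
  set <- vignette_set(ids,
                      as.data.frame(feat, optional = TRUE,
                                    check.names = FALSE),
                      resources,
                      provenance = sprintf(
                        "synthetic (oracle %s, noise %g, unknown %g)",
                        oracle$name, feature_noise, unknown_rate))
  list(set = set, truth = stats::setNames(truth, ids))
}

#' Off-by-one rater confusion matrix
#'
#' Symmetric rater noise on the ordinal scale: with probability \code{eps}
#' a rater misclassifies by one category (split equally to both neighbours
#' for the middle category).
#'
#' @param eps total off-by-one error probability per rating.
#' @return 3x3 row-stochastic matrix (row = true category).
#' @export
offby1_confusion <- function(eps = 0.2) {
  stopifnot(eps >= 0, eps <= 1)
  matrix(c(1 - eps, eps, 0,
           eps / 2, 1 - eps, eps / 2,
           0, eps, 1 - eps),
         nrow = 3, byrow = TRUE,
         dimnames = list(truth = 1:3, rating = 1:3))
}

#' Simulate an expert rating panel
#'
#' Each rating is drawn independently from the confusion row of the
#' vignette's true category, emulating the study's complete 36-rater
#' matrix (response rate 100 %).
#'
#' @param truth named integer vector (vignette id -> category 1-3).
#' @param n_raters panel size (study scale 36).
#' @param confusion 3x3 row-stochastic matrix; default identity (perfectly
#'   accurate raters).
#' @param seed integer seed.
#' @return integer matrix vignettes x raters with values 1-3, rows named
#'   by vignette id.
#' @export
simulate_panel <- function(truth, n_raters = 36, confusion = diag(3),
                           seed = NULL) {
  stopifnot(n_raters >= 1)
  confusion <- unname(as.matrix(confusion))
  if (!all(dim(confusion) == c(3, 3)) || any(confusion < 0) ||
      any(abs(rowSums(confusion) - 1) > 1e-9))
    stop("confusion must be a 3x3 row-stochastic matrix", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- t(vapply(truth, function(k) {
    sample.int(3L, n_raters, replace = TRUE, prob = confusion[k, ])
  }, integer(n_raters)))
  if (n_raters == 1L) m <- matrix(m, ncol = 1L)  # vapply drops to vector
  dimnames(m) <- list(names(truth), paste0("R", seq_len(n_raters)))
  m
}

#' Write a rating matrix as CSV
#'
#' @param ratings vignette x rater matrix.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  out <- data.frame(vignette_id = rownames(ratings), ratings,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Expand a canonical vignette table into raw columns
#'
#' Inverse exercise of [consolidate_columns()]: each canonical item is
#' split into one or more raw columns such that consolidating the result
#' reproduces the input.  A yes item places its \code{"1"} in one randomly
#' chosen raw column (the others read \code{"0"}); no items emit all
#' \code{"0"}, unknown items all \code{"n"}.
#'
#' @param set a [vignette_set()].
#' @param split_spec named list: canonical item -> character vector of raw
#'   column names (each item needs at least one).  Items absent from the
#'   spec keep their canonical name.
#' @param seed integer seed for the placement of yes codes.
#' @return data.frame of raw cell codes with \code{vignette_id} and
#'   \code{esi_resources} columns.
#' @export
generate_raw_table <- function(set, split_spec = list(), seed = NULL) {
  stopifnot(inherits(set, "vignette_set"))
  if (!is.null(seed)) set.seed(seed)
  items <- vignette_items(set)
  out <- data.frame(vignette_id = set$vignette_id,
                    esi_resources = encode_resource(set$esi_resources),
                    stringsAsFactors = FALSE)
  for (item in items) {
    raws <- split_spec[[item]]
    if (is.null(raws)) raws <- item
    cols <- matrix("0", nrow = nrow(set), ncol = length(raws),
                   dimnames = list(NULL, raws))
    for (i in seq_len(nrow(set))) {
      st <- set[[item]][i]
      if (st == "yes") {
        cols[i, sample.int(length(raws), 1L)] <- "1"
      } else if (st == "unknown") {
        cols[i, ] <- "n"
      }
    }
    for (j in raws) out[[j]] <- cols[, j]
  }
  out
}
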