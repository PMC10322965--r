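# Batch pipeline: file-based orchestration of simulate -> triage ->
# evaluate -> workload, with a config echo and reproducible outputs.  These
# functions (plus the package API they wrap) are the scripting interface;
# each writes plain-text CSV/JSON artifacts so that reruns with the same
# configuration and seed are byte-identical.

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Simulate a full study data set to disk
#'
#' Generates a synthetic vignette set with planted truth and a simulated
#' expert panel, and writes \code{vignettes.csv}, \code{truth.csv} and
#' \code{ratings.csv} to \code{out_dir}.  Deterministic per seed.
#'
#' @param out_dir output directory (created if absent).
#' @param n number of vignettes (study scale 210).
#' @param oracle generating-truth algorithm; default the Berlin encoding.
#' @param prevalence category prevalence (SK I, II, III).
#' @param feature_noise,unknown_rate see [generate_vignettes()].
#' @param n_raters panel size (study scale 36).
#' @param rater_noise off-by-one rater error probability (see
#'   [offby1_confusion()]).
#' @param seed integer seed for both stages.
#' @return invisibly, a list with the written paths and the truth vector.
#' @export
simulate_study <- function(out_dir, n = 210,
                           oracle = shipped_algorithms("BER")[[1]],
                           prevalence = c(0.2, 0.3, 0.5),
                           feature_noise = 0.05, unknown_rate = 0.05,
                           n_raters = 36, rater_noise = 0.1,
                           seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_vignettes(n, oracle, prevalence = prevalence,
                            feature_noise = feature_noise,
                            unknown_rate = unknown_rate,
                            items = default_vocabulary(), seed = seed)
  ratings <- simulate_panel(sim$truth, n_raters = n_raters,
                            confusion = offby1_confusion(rater_noise),
                            seed = seed + 1L)
  paths <- file.path(out_dir, c("vignettes.csv", "truth.csv",
                                "ratings.csv"))
  write_vignettes(sim$set, paths[1L])
  utils::write.csv(data.frame(vignette_id = names(sim$truth),
                              category = unname(sim$truth)),
                   paths[2L], row.names = FALSE, quote = FALSE)
  write_ratings(ratings, paths[3L])
  invisible(list(paths = paths, truth = sim$truth))
}

#' Evaluate algorithms on a study data set and write reports
#'
#' Reads a coded vignette table and an expert rating matrix, forms the
#' median-consensus reference, runs the algorithms, and writes one
#' metric-by-algorithm CSV per detection category
#' (\code{metrics_SK1.csv} .. \code{metrics_SK3.csv}), the ROC points
#' (\code{roc_points.csv}), the pairwise step-count comparison
#' (\code{step_comparison.csv}) and a JSON run log with unrounded metrics,
#' exclusion counts and a config echo (\code{run_log.json}).
#'
#' @param vignettes_path CSV of coded vignettes ([read_vignettes()]).
#' @param ratings_path CSV rating matrix ([read_ratings()]).
#' @param out_dir output directory (created if absent).
#' @param algorithms list of algorithms; default the seven shipped
#'   encodings.
#' @param vocabulary feature vocabulary for reading the vignette table.
#' @param unknown_policy,quartile_method passed to [triage_eval()].
#' @param tie_policy passed to [median_consensus()].
#' @param alpha significance level for the step-count comparison.
#' @return the \code{triage_eval} object, invisibly.
#' @export
evaluate_study <- function(vignettes_path, ratings_path, out_dir,
                           algorithms = shipped_algorithms(),
                           vocabulary = default_vocabulary(),
                           unknown_policy = "as_no",
                           tie_policy = "toward_urgent",
                           quartile_method = "linear",
                           alpha = 0.05) {
  for (p in c(vignettes_path, ratings_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set <- read_vignettes(vignettes_path, vocabulary)
  ratings <- read_ratings(ratings_path)
  reference <- median_consensus(ratings, tie_policy = tie_policy)
  ev <- triage_eval(set, algorithms, reference,
                    unknown_policy = unknown_policy,
                    quartile_method = quartile_method)
  config <- list(vignettes = basename(vignettes_path),
                 ratings = basename(ratings_path),
                 algorithms = names(ev$confusion),
                 unknown_policy = unknown_policy, tie_policy = tie_policy,
                 quartile_method = quartile_method, alpha = alpha)
  hash <- config_hash(config)

  for (k in 1:3) {
    tab <- summary(ev, category = k)
    df <- data.frame(metric = rownames(tab), unclass(tab),
                     check.names = FALSE, stringsAsFactors = FALSE)
    path <- file.path(out_dir, sprintf("metrics_SK%d.csv", k))
    con <- file(path, "w", encoding = "UTF-8")
    writeLines(paste0("# config ", hash), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  roc <- roc_points(ev, 1L)
  con <- file(file.path(out_dir, "roc_points.csv"), "w", encoding = "UTF-8")
  writeLines(paste0("# config ", hash), con)
  utils::write.csv(roc, con, row.names = FALSE)
  close(con)

  groups <- split(ev$results$steps[ev$results$status == "ok"],
                  ev$results$algorithm[ev$results$status == "ok"])
  groups <- groups[vapply(groups, length, 0L) >= 2L]
  if (length(groups) >= 2L) {
    cmp <- compare_step_counts(groups, alpha = alpha)
    pw <- cmp$pairwise
    pw$omnibus_p <- cmp$omnibus_p
    con <- file(file.path(out_dir, "step_comparison.csv"), "w",
                encoding = "UTF-8")
    writeLines(paste0("# config ", hash), con)
    utils::write.csv(pw, con, row.names = FALSE)
    close(con)
  }

  unrounded <- lapply(1:3, function(k) {
    lapply(ev$metrics[[k]], function(m) m[c(
      "sensitivity", "specificity", "ppv", "npv", "youden",
      "correct_prop", "overtriage_prop", "undertriage_prop",
      "n_reference")])
  })
  names(unrounded) <- c("SK I", "SK II", "SK III")
  log <- list(config = config, config_hash = hash,
              package_version = as.character(
                utils::packageVersion("mcitriage")),
              n_vignettes = ev$n_vignettes,
              excluded = as.list(ev$excluded),
              tied_references = sum(reference$tied),
              metrics = unrounded)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(ev)
}

#' Compute and write a workload report
#'
#' Wraps [category_workload()] for a named profile and casemix from a
#' workload configuration document and writes \code{workload.csv} and
#' \code{workload.json}.
#'
#' @param profile name of a time profile in the config (or a
#'   [time_profile()]).
#' @param mix name of a casemix in the config (or a [casemix()]).
#' @param n_patients cohort size.
#' @param out_dir output directory.
#' @param config parsed [read_workload_config()] list.
#' @return the [category_workload()] report, invisibly.
#' @export
workload_study <- function(profile, mix, n_patients = 100, out_dir,
                           config = read_workload_config()) {
  if (is.character(profile)) {
    if (!profile %in% names(config$profiles))
      stop("unknown time profile '", profile, "'", call. = FALSE)
    profile <- config$profiles[[profile]]
  }
  if (is.character(mix)) {
    if (!mix %in% names(config$casemixes))
      stop("unknown casemix '", mix, "'", call. = FALSE)
    mix <- config$casemixes[[mix]]
  }
  rep <- category_workload(profile, mix, n_patients)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(category = names(rep$minutes),
                   minutes = round(unname(rep$minutes)),
                   share_pct = round(100 * unname(rep$share)))
  utils::write.csv(df, file.path(out_dir, "workload.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(algorithm = rep$algorithm, n_patients = rep$n_patients,
         minutes = as.list(rep$minutes), share = as.list(rep$share),
         total_minutes = rep$total_minutes),
    file.path(out_dir, "workload.json"), auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
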