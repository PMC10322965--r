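# Casemix-weighted triage-time accounting.
#
# Per-patient triage times per category (seconds, from external timing
# studies of PRIOR and mSTaRT) are combined with a casemix distribution
# over SK I-III and EX to give per-category minutes and shares of the total
# triage time.  Deceased patients (EX) consume no algorithm time.

#' Per-category triage time profile
#'
#' @param name algorithm name.
#' @param seconds named numeric vector with elements \code{"SK I"},
#'   \code{"SK II"}, \code{"SK III"}: per-patient triage duration in
#'   seconds.
#' @return object of class \code{time_profile}.
#' @export
#' @examples
#' time_profile("PRIOR", c("SK I" = 27, "SK II" = 28, "SK III" = 42))
time_profile <- function(name, seconds) {
  seconds <- unlist(seconds)
  need <- c("SK I", "SK II", "SK III")
  if (!all(need %in% names(seconds)))
    stop("seconds must name SK I, SK II and SK III", call. = FALSE)
  seconds <- seconds[need]
  if (any(seconds < 0)) stop("negative triage time", call. = FALSE)
  structure(list(name = name, seconds = seconds), class = "time_profile")
}

#' Casemix distribution over triage categories
#'
#' @param sk1,sk2,sk3 proportions of SK I, SK II, SK III patients.
#' @param ex proportion of deceased (EX); contributes no triage time.
#' @return object of class \code{casemix} (named numeric vector summing
#'   to 1).
#' @export
#' @examples
#' casemix(0.15, 0.20, 0.60, ex = 0.05)
casemix <- function(sk1, sk2, sk3, ex = 0) {
  p <- c("SK I" = sk1, "SK II" = sk2, "SK III" = sk3, "EX" = ex)
  if (any(p < 0 | p > 1)) stop("proportions must lie in [0, 1]",
                               call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("casemix proportions must sum to 1 (got ", sum(p), ")",
         call. = FALSE)
  structure(p, class = "casemix")
}

#' Casemix-weighted triage workload
#'
#' For \code{n_patients} patients distributed as \code{mix} and triaged
#' with \code{profile}, the triage time spent on category c is
#' \code{n * p_c * t_c / 60} minutes.  Shares are each category's fraction
#' of the total triage time (independent of n).
#'
#' @param profile a [time_profile()].
#' @param mix a [casemix()].
#' @param n_patients number of patients.
#' @return object of class \code{workload_report}: list with
#'   \code{minutes} (named, SK I-III), \code{share}, \code{total_minutes},
#'   \code{n_patients}, \code{algorithm}.
#' @export
#' @examples
#' category_workload(
#'   time_profile("PRIOR", c("SK I" = 27, "SK II" = 28, "SK III" = 42)),
#'   casemix(0.15, 0.20, 0.60, ex = 0.05), 100)
category_workload <- function(profile, mix, n_patients) {
  stopifnot(inherits(profile, "time_profile"), inherits(mix, "casemix"),
            n_patients >= 0)
  p <- unclass(mix)[names(profile$seconds)]
  minutes <- n_patients * p * profile$seconds / 60
  total <- sum(minutes)
  share <- if (total > 0) minutes / total else
    stats::setNames(rep(NA_real_, length(minutes)), names(minutes))
  structure(list(minutes = minutes, share = share, total_minutes = total,
                 n_patients = n_patients, algorithm = profile$name),
            class = "workload_report")
}

#' Share of triage time per category
#'
#' \code{share_c = p_c * t_c / sum(p_k * t_k)}; independent of the cohort
#' size.  All-zero total time yields \code{NA} shares.
#'
#' @inheritParams category_workload
#' @return named numeric vector of shares over SK I-III.
#' @export
#' @examples
#' time_share(
#'   time_profile("PRIOR", c("SK I" = 27, "SK II" = 28, "SK III" = 42)),
#'   casemix(0.07, 0.19, 0.74))
time_share <- function(profile, mix) {
  category_workload(profile, mix, n_patients = 1)$share
}

#' @export
print.workload_report <- function(x, ...) {
  cat(sprintf("Triage workload, %s, %d patients: total %.0f min\n",
              x$algorithm, x$n_patients, x$total_minutes))
  for (k in names(x$minutes)) {
    cat(sprintf("  %-7s %3.0f min  (%s of triage time)\n", k, x$minutes[[k]],
                if (is.na(x$share[[k]])) "-" else
                  sprintf("%.0f %%", 100 * x$share[[k]])))
  }
  invisible(x)
}

#' Read named time profiles and casemixes from a config document
#'
#' The YAML document has a \code{profiles} map (name -> seconds for
#' \code{sk1}/\code{sk2}/\code{sk3}) and a \code{casemixes} map (name ->
#' proportions \code{sk1}/\code{sk2}/\code{sk3}/optional \code{ex}).  The
#' shipped \code{workload.yaml} carries the published PRIOR and mSTaRT
#' timing profiles and two reference casemixes.
#'
#' @param path YAML path; default the shipped configuration.
#' @return list with elements \code{profiles} (list of [time_profile()])
#'   and \code{casemixes} (list of [casemix()]).
#' @export
read_workload_config <- function(path = system.file("extdata",
                                                    "workload.yaml",
                                                    package = "mcitriage",
                                                    mustWork = TRUE)) {
  doc <- yaml::read_yaml(path)
  profiles <- lapply(names(doc$profiles), function(nm) {
    p <- doc$profiles[[nm]]
    time_profile(nm, c("SK I" = p$sk1, "SK II" = p$sk2, "SK III" = p$sk3))
  })
  names(profiles) <- names(doc$profiles)
  mixes <- lapply(doc$casemixes, function(m) {
    casemix(m$sk1, m$sk2, m$sk3, ex = if (is.null(m$ex)) 0 else m$ex)
  })
  list(profiles = profiles, casemixes = mixes)
}
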