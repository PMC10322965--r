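# Tri-state vignette feature tables: coding, vocabulary, consolidation, I/O.
#
# Cells are coded "1" (query answered yes), "0" (no) and "n" (not derivable
# from the case record); the ESI resource item additionally uses "2" (many
# resources).  In memory, states are the words "yes"/"no"/"unknown" and
# resource levels "none"/"one"/"many"/"unknown".

.TRISTATE_CODES <- c("0" = "no", "1" = "yes", "n" = "unknown")
.TRISTATE_STATES <- c(no = "0", yes = "1", unknown = "n")
.RESOURCE_CODES <- c("0" = "none", "1" = "one", "2" = "many", "n" = "unknown")
.RESOURCE_LEVELS <- c(none = "0", one = "1", many = "2", unknown = "n")

#' Decode tri-state cell codes
#'
#' Maps the cell codes \code{"1"}, \code{"0"}, \code{"n"} to the states
#' \code{"yes"}, \code{"no"}, \code{"unknown"}.  Empty cells and \code{NA}
#' decode to \code{"unknown"}: a finding that the case record does not
#' mention cannot be answered either way.
#'
#' @param codes character vector of cell codes.
#' @return character vector of states.
#' @seealso [encode_tristate()] for the inverse.
#' @export
#' @examples
#' decode_tristate(c("1", "0", "n", ""))
decode_tristate <- function(codes) {
  codes <- as.character(codes)
  codes[is.na(codes) | codes == ""] <- "n"
  bad <- !codes %in% names(.TRISTATE_CODES)
  if (any(bad)) {
    stop("invalid tri-state code(s): ",
         paste(unique(codes[bad]), collapse = ", "),
         " (expected \"0\", \"1\" or \"n\")", call. = FALSE)
  }
  unname(.TRISTATE_CODES[codes])
}

#' @rdname decode_tristate
#' @param states character vector of states (\code{"yes"}, \code{"no"},
#'   \code{"unknown"}).
#' @export
encode_tristate <- function(states) {
  bad <- !states %in% names(.TRISTATE_STATES)
  if (any(bad)) {
    stop("invalid tri-state state(s): ",
         paste(unique(states[bad]), collapse = ", "), call. = FALSE)
  }
  unname(.TRISTATE_STATES[states])
}

decode_resource <- function(codes) {
  codes <- as.character(codes)
  codes[is.na(codes) | codes == ""] <- "n"
  bad <- !codes %in% names(.RESOURCE_CODES)
  if (any(bad)) {
    stop("invalid resource code(s): ",
         paste(unique(codes[bad]), collapse = ", "),
         " (expected \"0\", \"1\", \"2\" or \"n\")", call. = FALSE)
  }
  unname(.RESOURCE_CODES[codes])
}

encode_resource <- function(levels) {
  bad <- !levels %in% names(.RESOURCE_LEVELS)
  if (any(bad)) {
    stop("invalid resource level(s): ",
         paste(unique(levels[bad]), collapse = ", "), call. = FALSE)
  }
  unname(.RESOURCE_LEVELS[levels])
}

#' Feature vocabulary: canonical items and raw-column merge map
#'
#' The raw vignette database uses algorithm-specific column names; similar
#' queries from different algorithms (for example an unstable pelvis and a
#' pelvic fracture) are consolidated into a single canonical item so that
#' every algorithm addresses features by a stable name.  A vocabulary lists
#' the canonical items and a merge map from raw column names to canonical
#' items.  Canonical items always map to themselves, so a table that is
#' already canonical is accepted unchanged.
#'
#' @param items character vector of canonical item identifiers (ASCII slugs).
#' @param merge_map named character vector: names are raw column names,
#'   values the canonical item each one folds into.  May be empty.
#' @return an object of class \code{feature_vocabulary}.
#' @seealso [read_vocabulary()], [default_vocabulary()]
#' @export
feature_vocabulary <- function(items, merge_map = character()) {
  items <- as.character(items)
  if (anyDuplicated(items)) stop("duplicate canonical items", call. = FALSE)
  merge_map <- unlist(merge_map)
  if (length(merge_map) && is.null(names(merge_map)))
    stop("merge_map must be named (raw column -> canonical item)",
         call. = FALSE)
  bad <- setdiff(unname(merge_map), items)
  if (length(bad)) {
    stop("merge_map targets are not canonical items: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  # identity entries for canonical items keep the map total over them
  full <- c(merge_map, stats::setNames(items, items))
  full <- full[!duplicated(names(full))]
  structure(list(items = items, merge_map = full),
            class = "feature_vocabulary")
}

#' Read a vocabulary document
#'
#' @param path YAML (or JSON) document with fields \code{items} and
#'   \code{merge_map}.
#' @return a \code{feature_vocabulary}.
#' @export
read_vocabulary <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$items)) stop("vocabulary document lacks 'items'",
                               call. = FALSE)
  feature_vocabulary(unlist(doc$items), doc$merge_map)
}

#' Shipped vocabularies
#'
#' \code{default_vocabulary()} returns the study vocabulary, including the
#' consolidations of similar queries (unstable pelvis into pelvic fracture,
#' respiratory rate > 20/min into > 29/min, FAST positive/negative into a
#' single FAST item).  \code{strict = TRUE} returns a variant that keeps
#' respiratory rate > 20/min as its own item, for algorithms that genuinely
#' query the lower threshold.
#'
#' @param strict keep the lower respiratory-rate threshold as a separate
#'   canonical item instead of folding it into the > 29/min item.
#' @return a \code{feature_vocabulary}.
#' @export
default_vocabulary <- function(strict = FALSE) {
  f <- if (strict) "vocabulary_strict.yaml" else "vocabulary.yaml"
  read_vocabulary(system.file("extdata", f, package = "mcitriage",
                              mustWork = TRUE))
}

#' @export
print.feature_vocabulary <- function(x, ...) {
  cat("Feature vocabulary:", length(x$items), "canonical items,",
      sum(names(x$merge_map) != unname(x$merge_map)),
      "raw-column consolidations\n")
  invisible(x)
}

#' Consolidate raw columns into canonical items
#'
#' Columns whose raw names share a canonical target are combined cell-wise:
#' the merged cell is \code{"1"} if any source cell is \code{"1"}, else
#' \code{"0"} if any source is \code{"0"}, else \code{"n"} — a positive
#' finding in either source column is a positive finding for the merged
#' item.  The output has exactly one column per canonical item of the
#' vocabulary; items with no source column are all-\code{"n"}.
#'
#' @param raw data.frame of cell codes (\code{"0"}/\code{"1"}/\code{"n"})
#'   whose column names are raw item names.  Identifier and resource
#'   columns must be removed before calling.
#' @param vocabulary a \code{feature_vocabulary}.
#' @return data.frame of codes with one column per canonical item, same
#'   row count and order as \code{raw}.
#' @export
consolidate_columns <- function(raw, vocabulary) {
  stopifnot(inherits(vocabulary, "feature_vocabulary"))
  unmapped <- setdiff(names(raw), names(vocabulary$merge_map))
  if (length(unmapped)) {
    stop("raw column(s) not in the merge map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  out <- lapply(vocabulary$items, function(item) {
    src <- names(vocabulary$merge_map)[vocabulary$merge_map == item]
    src <- intersect(src, names(raw))
    if (!length(src)) return(rep("n", n))
    cells <- lapply(raw[src], function(col) {
      col <- as.character(col)
      col[is.na(col) | col == ""] <- "n"
      col
    })
    m <- do.call(cbind, cells)
    apply(m, 1L, function(r) {
      if (any(r == "1")) "1" else if (any(r == "0")) "0" else "n"
    })
  })
  names(out) <- vocabulary$items
  as.data.frame(out, optional = TRUE, check.names = FALSE)
}

#' Construct a vignette set
#'
#' A vignette set holds one row per simulated patient: a unique id, an ESI
#' resource-need level, and the tri-state answer to every canonical query
#' item.
#'
#' @param vignette_id character vector of unique ids.
#' @param features data.frame of states (\code{"yes"}/\code{"no"}/
#'   \code{"unknown"}), one column per canonical item.
#' @param resource_need resource level per vignette (\code{"none"},
#'   \code{"one"}, \code{"many"}, \code{"unknown"}); recycled if length 1.
#' @param provenance free-text origin note, stored as an attribute.
#' @return object of class \code{vignette_set} (a data.frame).
#' @export
vignette_set <- function(vignette_id, features,
                         resource_need = "unknown",
                         provenance = "") {
  vignette_id <- as.character(vignette_id)
  dup <- vignette_id[duplicated(vignette_id)]
  if (length(dup)) {
    stop("duplicate vignette id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(features) != length(vignette_id))
    stop("features and vignette_id disagree in length", call. = FALSE)
  for (col in names(features)) {
    bad <- !features[[col]] %in% names(.TRISTATE_STATES)
    if (any(bad)) stop("invalid state in feature column ", col, call. = FALSE)
  }
  resource_need <- rep_len(as.character(resource_need), length(vignette_id))
  if (any(!resource_need %in% names(.RESOURCE_LEVELS)))
    stop("invalid resource level", call. = FALSE)
  out <- cbind(data.frame(vignette_id = vignette_id,
                          esi_resources = resource_need,
                          stringsAsFactors = FALSE),
               features)
  rownames(out) <- NULL
  structure(out, provenance = provenance,
            class = c("vignette_set", "data.frame"))
}

#' @export
print.vignette_set <- function(x, ...) {
  cat("Vignette set:", nrow(x), "vignettes,",
      ncol(x) - 2L, "canonical items\n")
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat("Provenance:", prov, "\n")
  NextMethod()
}

vignette_items <- function(set) setdiff(names(set),
                                        c("vignette_id", "esi_resources"))

#' Read a coded vignette table
#'
#' Reads a CSV with an id column \code{vignette_id}, an optional resource
#' column \code{esi_resources} (codes \code{"0"}/\code{"1"}/\code{"2"}/
#' \code{"n"}) and one column of tri-state codes per raw query item.  Raw
#' columns are consolidated through the vocabulary's merge map before
#' decoding; missing cells read as \code{"n"}.
#'
#' @param path CSV file path (UTF-8, comma-separated, header row).
#' @param vocabulary a \code{feature_vocabulary}.
#' @return a [vignette_set()].
#' @export
read_vignettes <- function(path, vocabulary = default_vocabulary()) {
  tab <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (!"vignette_id" %in% names(tab))
    stop("no 'vignette_id' column in ", path, call. = FALSE)
  ids <- tab$vignette_id
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate vignette id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  res <- if ("esi_resources" %in% names(tab)) {
    tryCatch(decode_resource(tab$esi_resources),
             error = function(e) stop("column esi_resources: ",
                                      conditionMessage(e), call. = FALSE))
  } else "unknown"
  raw <- tab[setdiff(names(tab), c("vignette_id", "esi_resources"))]
  # locate bad cells before consolidation so errors name row and column
  for (col in names(raw)) {
    cells <- raw[[col]]
    cells[is.na(cells) | cells == ""] <- "n"
    bad <- which(!cells %in% names(.TRISTATE_CODES))
    if (length(bad)) {
      stop("invalid code \"", cells[bad[1L]], "\" at row ", bad[1L],
           ", column ", col, call. = FALSE)
    }
  }
  codes <- consolidate_columns(raw, vocabulary)
  features <- as.data.frame(lapply(codes, decode_tristate),
                            optional = TRUE, check.names = FALSE)
  if (nrow(tab) > 0 && nrow(features) == 0)  # zero-item edge
    features <- data.frame(row.names = seq_len(nrow(tab)))
  vignette_set(ids, features, res, provenance = path)
}

#' Write a vignette set as a coded CSV
#'
#' Inverse of [read_vignettes()]: states are encoded back to
#' \code{"0"}/\code{"1"}/\code{"n"} (resources \code{"0"}/\code{"1"}/
#' \code{"2"}/\code{"n"}) so that reading the file back reproduces the set
#' exactly.
#'
#' @param set a \code{vignette_set}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_vignettes <- function(set, path) {
  stopifnot(inherits(set, "vignette_set"))
  items <- vignette_items(set)
  out <- data.frame(vignette_id = set$vignette_id,
                    esi_resources = encode_resource(set$esi_resources),
                    stringsAsFactors = FALSE)
  for (col in items) out[[col]] <- encode_tristate(set[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
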