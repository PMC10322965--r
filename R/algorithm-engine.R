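# Declarative decision-tree triage algorithms: document loader, validator,
# interpreter with step accounting, and output-scale mapping.
#
# An algorithm document is YAML with fields name, setting, root, nodes[] and
# scale_map.  Each node queries one canonical item (or the ESI resource
# item) and routes to a successor node ({goto: <id>}) or a terminal
# ({out: <raw category>}).  Terminals are raw outputs on the algorithm's
# native scale (SK categories, ESI levels, or an extended scale with
# EX/deceased); scale_map sends them onto the common comparison scale
# SK I (1, red) > SK II (2, yellow) > SK III (3, green).  Extended outputs
# such as EX may stay unmapped: results carrying them are flagged
# out-of-scale and excluded from accuracy tables, because the in-hospital
# reference scale is SK I-III only.

.EXTENDED_OUTPUTS <- c("EX", "SK IV")
.RESOURCE_TESTS <- c("none", "one", "many", "at_least_one")

#' Load a triage-algorithm document
#'
#' Parses and validates a YAML decision-tree document.  Validation checks
#' that every successor reference resolves, that the node graph is a rooted
#' DAG (no cycles, every path reaches a terminal), and that every terminal
#' output is either in the domain of \code{scale_map} or one of the
#' recognised extended outputs (\code{"EX"}, \code{"SK IV"}), which are
#' representable but excluded from the comparison scale.
#'
#' @param path path to the YAML document.
#' @param disable_tags character vector of node tags to splice out of the
#'   tree (the node's \code{on_no} branch replaces it).  Used for optional
#'   blocks such as the ESI vital-sign danger-zone uprating.
#' @return an object of class \code{triage_algorithm}.
#' @export
read_algorithm <- function(path, disable_tags = NULL) {
  doc <- yaml::read_yaml(path)
  as_triage_algorithm(doc, disable_tags = disable_tags, source = path)
}

#' @rdname read_algorithm
#' @param doc a list with fields \code{name}, \code{setting}, \code{root},
#'   \code{nodes}, \code{scale_map}, as produced by parsing a document.
#' @param source free-text origin note.
#' @export
as_triage_algorithm <- function(doc, disable_tags = NULL, source = "") {
  for (f in c("name", "root", "nodes", "scale_map")) {
    if (is.null(doc[[f]])) stop("algorithm document lacks '", f, "'",
                                call. = FALSE)
  }
  nodes <- lapply(doc$nodes, function(nd) {
    if (is.null(nd$id) || is.null(nd$item))
      stop("node without id or item in algorithm ", doc$name, call. = FALSE)
    list(id = as.character(nd$id),
         item = as.character(nd$item),
         test = if (is.null(nd$test)) NA_character_ else as.character(nd$test),
         label = if (is.null(nd$label)) nd$item else nd$label,
         on_yes = nd$on_yes, on_no = nd$on_no,
         unknown = if (is.null(nd$unknown)) NA_character_
                   else as.character(nd$unknown),
         tag = if (is.null(nd$tag)) NA_character_ else as.character(nd$tag))
  })
  names(nodes) <- vapply(nodes, `[[`, "", "id")
  if (anyDuplicated(names(nodes)))
    stop("duplicate node id in algorithm ", doc$name, call. = FALSE)

  if (length(disable_tags)) {
    nodes <- splice_tagged_nodes(nodes, disable_tags, doc$root)
    doc$root <- attr(nodes, "root")
    attr(nodes, "root") <- NULL
  }

  scale_map <- unlist(doc$scale_map)
  if (!all(scale_map %in% 1:3))
    stop("scale_map values must be the comparison categories 1, 2, 3",
         call. = FALSE)
  scale_map <- stats::setNames(as.integer(scale_map), names(scale_map))

  alg <- structure(
    list(name = as.character(doc$name),
         setting = if (is.null(doc$setting)) "unspecified" else doc$setting,
         scale = if (is.null(doc$scale)) "SK" else doc$scale,
         provisional = isTRUE(doc$provisional),
         root = as.character(doc$root),
         nodes = nodes,
         scale_map = scale_map,
         source = source),
    class = "triage_algorithm")
  validate_algorithm(alg)
  alg
}

splice_tagged_nodes <- function(nodes, tags, root) {
  drop <- names(nodes)[vapply(nodes, function(nd) nd$tag %in% tags,
                              NA)]
  resolve <- function(ref) {
    # follow goto chains through dropped nodes via their on_no branch
    while (!is.null(ref$goto) && ref$goto %in% drop)
      ref <- nodes[[ref$goto]]$on_no
    ref
  }
  kept <- nodes[setdiff(names(nodes), drop)]
  kept <- lapply(kept, function(nd) {
    nd$on_yes <- resolve(nd$on_yes); nd$on_no <- resolve(nd$on_no); nd
  })
  root_ref <- resolve(list(goto = root))
  if (is.null(root_ref$goto))
    stop("disabling tags removed the whole tree", call. = FALSE)
  structure(kept, root = root_ref$goto)
}

branch_kind <- function(ref, node_id) {
  if (is.list(ref) && !is.null(ref$goto)) return("goto")
  if (is.list(ref) && !is.null(ref$out)) return("out")
  stop("node ", node_id,
       ": branch must be {goto: <node id>} or {out: <category>}",
       call. = FALSE)
}

#' @rdname read_algorithm
#' @param alg a \code{triage_algorithm}.
#' @export
validate_algorithm <- function(alg) {
  stopifnot(inherits(alg, "triage_algorithm"))
  ids <- names(alg$nodes)
  if (!length(ids)) stop("algorithm has no nodes", call. = FALSE)
  if (!alg$root %in% ids)
    stop("root node '", alg$root, "' is not defined", call. = FALSE)
  for (nd in alg$nodes) {
    for (side in c("on_yes", "on_no")) {
      ref <- nd[[side]]
      kind <- branch_kind(ref, nd$id)
      if (kind == "goto" && !ref$goto %in% ids) {
        stop("node ", nd$id, ": successor '", ref$goto,
             "' does not exist", call. = FALSE)
      }
      if (kind == "out") {
        out <- as.character(ref$out)
        if (!out %in% names(alg$scale_map) &&
            !out %in% .EXTENDED_OUTPUTS) {
          stop("node ", nd$id, ": terminal output '", out,
               "' is neither in scale_map nor an extended output",
               call. = FALSE)
        }
      }
    }
    if (!is.na(nd$test) && !nd$test %in% .RESOURCE_TESTS)
      stop("node ", nd$id, ": unknown resource test '", nd$test, "'",
           call. = FALSE)
    if (!is.na(nd$unknown) && !nd$unknown %in% c("as_yes", "as_no", "abstain"))
      stop("node ", nd$id, ": invalid unknown-policy override", call. = FALSE)
  }
  # acyclicity by colour DFS from the root
  colour <- stats::setNames(rep(0L, length(ids)), ids)
  visit <- function(id) {
    if (colour[[id]] == 1L)
      stop("cycle detected through node ", id, call. = FALSE)
    if (colour[[id]] == 2L) return(invisible())
    colour[[id]] <<- 1L
    for (side in c("on_yes", "on_no")) {
      ref <- alg$nodes[[id]][[side]]
      if (!is.null(ref$goto)) visit(ref$goto)
    }
    colour[[id]] <<- 2L
    invisible()
  }
  visit(alg$root)
  invisible(alg)
}

#' @export
print.triage_algorithm <- function(x, ...) {
  cat(sprintf("Triage algorithm %s (%s, %s scale): %d nodes, root %s%s\n",
              x$name, x$setting, x$scale, length(x$nodes), x$root,
              if (x$provisional) " [provisional encoding]" else ""))
  invisible(x)
}

#' Items queried by an algorithm
#'
#' @param alg a \code{triage_algorithm}.
#' @return character vector of canonical item names (excluding the ESI
#'   resource item, which is queried through resource tests).
#' @export
algorithm_items <- function(alg) {
  unique(vapply(alg$nodes, `[[`, "", "item"))
}

#' Map a raw algorithm output onto the comparison scale
#'
#' ESI levels 1 and 2 map to SK I (red) and SK II (yellow); ESI levels 3-5
#' are pooled into SK III (green).  Outputs outside the map's domain (for
#' example EX/deceased on the extended scale) are flagged out-of-scale
#' rather than silently coerced.
#'
#' @param raw character vector of raw outputs.
#' @param scale_map named integer vector (raw output -> category 1/2/3).
#' @return integer vector of categories, \code{NA} where out of scale, with
#'   attribute \code{out_of_scale} marking the flagged positions.
#' @export
map_output_scale <- function(raw, scale_map) {
  cat <- unname(scale_map[raw])
  structure(as.integer(cat), out_of_scale = is.na(cat))
}

eval_node_state <- function(nd, vignette_row) {
  if (!is.na(nd$test)) {
    lev <- vignette_row$esi_resources
    if (lev == "unknown") return("unknown")
    hit <- switch(nd$test,
                  none = lev == "none",
                  one = lev == "one",
                  many = lev == "many",
                  at_least_one = lev %in% c("one", "many"))
    return(if (hit) "yes" else "no")
  }
  if (!nd$item %in% names(vignette_row))
    stop("algorithm queries item '", nd$item,
         "' which the vignette set does not carry", call. = FALSE)
  vignette_row[[nd$item]]
}

run_one <- function(alg, vignette_row, unknown_policy) {
  trace <- character()
  node_id <- alg$root
  repeat {
    nd <- alg$nodes[[node_id]]
    trace <- c(trace, node_id)
    state <- eval_node_state(nd, vignette_row)
    if (state == "unknown") {
      pol <- if (!is.na(nd$unknown)) nd$unknown else unknown_policy
      if (pol == "abstain") {
        return(list(raw = NA_character_, category = NA_integer_,
                    status = "abstained", steps = length(trace),
                    trace = trace))
      }
      state <- if (pol == "as_yes") "yes" else "no"
    }
    ref <- if (state == "yes") nd$on_yes else nd$on_no
    if (!is.null(ref$goto)) {
      node_id <- ref$goto
    } else {
      out <- as.character(ref$out)
      cat <- map_output_scale(out, alg$scale_map)
      return(list(raw = out, category = unname(cat[1L]),
                  status = if (is.na(cat[1L])) "out_of_scale" else "ok",
                  steps = length(trace), trace = trace))
    }
  }
}

#' Run a triage algorithm over a vignette set
#'
#' Walks the decision tree for every vignette, counting one step per
#' evaluated query node (terminal assignment is not a step).  Query items
#' whose state is unknown are resolved by the node's override if present,
#' else by \code{unknown_policy}: \code{"as_no"} (default; a finding not
#' derivable from the record is treated as absent), \code{"as_yes"}, or
#' \code{"abstain"}, which stops with a partial trace and no category.
#'
#' @param alg a \code{triage_algorithm}.
#' @param set a [vignette_set()] (or a single-row slice of one).
#' @param unknown_policy how to resolve unknown item states.
#' @return data.frame with one row per vignette: \code{vignette_id},
#'   \code{algorithm}, \code{raw}, \code{category} (1/2/3 or \code{NA}),
#'   \code{status} (\code{ok}/\code{abstained}/\code{out_of_scale}),
#'   \code{steps}, and \code{trace} (node ids joined by \code{">"}).
#' @export
run_triage <- function(alg, set,
                       unknown_policy = c("as_no", "as_yes", "abstain")) {
  stopifnot(inherits(alg, "triage_algorithm"))
  unknown_policy <- match.arg(unknown_policy)
  if (nrow(set) == 0L) stop("empty vignette set", call. = FALSE)
  rows <- lapply(seq_len(nrow(set)), function(i) {
    r <- tryCatch(run_one(alg, set[i, , drop = FALSE], unknown_policy),
                  error = function(e) {
                    stop("vignette ", set$vignette_id[i], ", algorithm ",
                         alg$name, ": ", conditionMessage(e), call. = FALSE)
                  })
    data.frame(vignette_id = set$vignette_id[i], algorithm = alg$name,
               raw = r$raw, category = r$category, status = r$status,
               steps = r$steps, trace = paste(r$trace, collapse = ">"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run several algorithms over a vignette set
#'
#' @param algs list of \code{triage_algorithm} objects.
#' @inheritParams run_triage
#' @return row-bound data.frame of [run_triage()] results, one row per
#'   (algorithm, vignette), vignette order preserved within algorithm.
#' @export
run_triage_all <- function(algs, set,
                           unknown_policy = c("as_no", "as_yes", "abstain")) {
  unknown_policy <- match.arg(unknown_policy)
  if (!length(algs)) stop("no algorithms given", call. = FALSE)
  do.call(rbind, lapply(algs, run_triage, set = set,
                        unknown_policy = unknown_policy))
}

#' Render an algorithm as Graphviz DOT
#'
#' Emits the decision tree in DOT syntax for visual audit of an encoding
#' against its source publication.
#'
#' @param alg a \code{triage_algorithm}.
#' @return a single DOT string.
#' @export
algorithm_dot <- function(alg) {
  esc <- function(s) gsub('"', '\\\\"', s)
  lines <- c(sprintf("digraph \"%s\" {", esc(alg$name)),
             "  node [shape=box];")
  term_n <- 0L
  for (nd in alg$nodes) {
    lines <- c(lines, sprintf('  "%s" [label="%s"];', nd$id, esc(nd$label)))
    for (side in c("on_yes", "on_no")) {
      ref <- nd[[side]]
      lab <- if (side == "on_yes") "yes" else "no"
      if (!is.null(ref$goto)) {
        lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s"];',
                                  nd$id, ref$goto, lab))
      } else {
        term_n <- term_n + 1L
        tid <- paste0("t", term_n)
        lines <- c(lines,
                   sprintf('  "%s" [label="%s" shape=oval];', tid,
                           esc(as.character(ref$out))),
                   sprintf('  "%s" -> "%s" [label="%s"];', nd$id, tid, lab))
      }
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Shipped algorithm encodings
#'
#' Loads the packaged decision-tree documents.  The seven encodings cover
#' mSTaRT, PRIOR, the Berlin algorithm (BER), the Manchester Triage System
#' MCI module (MTS-MANV), the Emergency Severity Index (ESI), and the
#' Jordanian-German project algorithms JorD (in-hospital) and PETRA
#' (prehospital).  Encodings transcribed without access to the original
#' flow charts are marked provisional in their document headers.
#'
#' @param names algorithms to load; default all seven.
#' @param disable_tags passed to [read_algorithm()] (for example
#'   \code{"danger_zone"} to disable the ESI vital-sign uprating block).
#' @return named list of \code{triage_algorithm} objects.
#' @export
shipped_algorithms <- function(names = c("mSTaRT", "PRIOR", "BER",
                                         "MTS-MANV", "ESI", "JorD", "PETRA"),
                               disable_tags = NULL) {
  files <- c("mSTaRT" = "mstart.yaml", "PRIOR" = "prior.yaml",
             "BER" = "ber.yaml", "MTS-MANV" = "mts-manv.yaml",
             "ESI" = "esi.yaml", "JorD" = "jord.yaml", "PETRA" = "petra.yaml")
  unknown <- setdiff(names, names(files))
  if (length(unknown))
    stop("no shipped encoding for: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- lapply(files[names], function(f) {
    read_algorithm(system.file("extdata", "algorithms", f,
                               package = "mcitriage", mustWork = TRUE),
                   disable_tags = disable_tags)
  })
  stats::setNames(out, names)
}
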