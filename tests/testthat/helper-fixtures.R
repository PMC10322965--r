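# Shared fixtures: toy decision trees, an independent exhaustive evaluator,
# random tree generation, and a brute-force accuracy oracle.

# Three-node sieve: walking -> green; else tachypnoea -> red; else absent
# radial pulse -> red, present -> yellow.
toy_tree <- function() {
  as_triage_algorithm(list(
    name = "toy", setting = "prehospital", scale = "SK", root = "n1",
    nodes = list(
      list(id = "n1", item = "walking",
           on_yes = list(out = "SK III"), on_no = list(goto = "n2")),
      list(id = "n2", item = "resp_rate_gt29",
           on_yes = list(out = "SK I"), on_no = list(goto = "n3")),
      list(id = "n3", item = "radial_pulse",
           on_yes = list(out = "SK II"), on_no = list(out = "SK I"))),
    scale_map = list("SK I" = 1, "SK II" = 2, "SK III" = 3)))
}

toy_vignette <- function(walking = "no", resp_rate_gt29 = "no",
                         radial_pulse = "yes", resources = "none",
                         id = "V1") {
  vignette_set(id,
               data.frame(walking = walking,
                          resp_rate_gt29 = resp_rate_gt29,
                          radial_pulse = radial_pulse,
                          stringsAsFactors = FALSE),
               resources)
}

# Independent exhaustive evaluator: plain recursive descent over the node
# list for one complete yes/no assignment (plus a resource level), kept
# free of the interpreter's policy and trace machinery.
exhaustive_eval <- function(alg, assignment, resource = "none") {
  descend <- function(node_id, depth) {
    nd <- alg$nodes[[node_id]]
    yes <- if (!is.na(nd$test)) {
      switch(nd$test,
             none = resource == "none", one = resource == "one",
             many = resource == "many",
             at_least_one = resource %in% c("one", "many"))
    } else assignment[[nd$item]] == "yes"
    ref <- if (yes) nd$on_yes else nd$on_no
    if (!is.null(ref$goto)) return(descend(ref$goto, depth + 1L))
    cat <- alg$scale_map[as.character(ref$out)]
    list(category = if (is.na(cat)) NA_integer_ else as.integer(cat),
         steps = depth)
  }
  descend(alg$root, 1L)
}

all_assignments <- function(items) {
  grid <- expand.grid(rep(list(c("yes", "no")), length(items)),
                      stringsAsFactors = FALSE)
  names(grid) <- items
  grid
}

# Random rooted tree over k items: node j routes each branch to a strictly
# later node or a random terminal, which guarantees acyclicity.
random_tree <- function(k, categories = c("SK I", "SK II", "SK III")) {
  items <- paste0("item", seq_len(k))
  nodes <- lapply(seq_len(k), function(j) {
    branch <- function() {
      if (j < k && stats::runif(1) < 0.6) {
        succ <- (j + 1):k
        if (length(succ) > 1L) succ <- sample(succ, 1L)
        list(goto = paste0("n", succ))
      } else {
        list(out = sample(categories, 1L))
      }
    }
    list(id = paste0("n", j), item = items[j],
         on_yes = branch(), on_no = branch())
  })
  as_triage_algorithm(list(
    name = paste0("rand", k), root = "n1", nodes = nodes,
    scale_map = list("SK I" = 1, "SK II" = 2, "SK III" = 3)))
}

# Brute-force one-vs-rest accuracy from raw category vectors, explicit
# loops only.
brute_metrics <- function(ref, pred, category) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(ref)) {
    if (ref[i] == category && pred[i] == category) tp <- tp + 1
    if (ref[i] != category && pred[i] == category) fp <- fp + 1
    if (ref[i] != category && pred[i] != category) tn <- tn + 1
    if (ref[i] == category && pred[i] != category) fn <- fn + 1
  }
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  nref <- over <- under <- 0
  for (i in seq_along(ref)) {
    if (ref[i] == category) {
      nref <- nref + 1
      if (pred[i] < ref[i]) over <- over + 1
      if (pred[i] > ref[i]) under <- under + 1
    }
  }
  list(sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
       ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
       overtriage = div(over, nref), undertriage = div(under, nref))
}

# Predictions data.frame shaped like run_triage() output, from bare
# category vectors.
fake_predictions <- function(categories, ids = NULL, algorithm = "toy",
                             status = NULL, steps = NULL) {
  n <- length(categories)
  if (is.null(ids)) ids <- paste0("V", seq_len(n))
  if (is.null(status)) status <- ifelse(is.na(categories), "abstained",
                                        "ok")
  if (is.null(steps)) steps <- rep(1L, n)
  data.frame(vignette_id = ids, algorithm = algorithm,
             raw = as.character(categories), category = categories,
             status = status, steps = steps, trace = "",
             stringsAsFactors = FALSE)
}

fake_reference <- function(categories, ids = NULL) {
  n <- length(categories)
  if (is.null(ids)) ids <- paste0("V", seq_len(n))
  data.frame(vignette_id = ids, median_value = as.numeric(categories),
             tied = FALSE, category = as.integer(categories),
             stringsAsFactors = FALSE)
}
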