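# Decision-tree loader, validator, interpreter and scale mapping.

test_that("toy tree traces, categories and step counts are exact", {
  alg <- toy_tree()
  r <- run_triage(alg, toy_vignette(walking = "yes"))
  expect_equal(r$category, 3L)
  expect_equal(r$steps, 1L)
  expect_equal(r$trace, "n1")

  r <- run_triage(alg, toy_vignette("no", "no", "yes"))
  expect_equal(r$category, 2L)
  expect_equal(r$steps, 3L)
  expect_equal(r$trace, "n1>n2>n3")

  r <- run_triage(alg, toy_vignette("unknown", "yes"), "as_no")
  expect_equal(r$category, 1L)
  expect_equal(r$steps, 2L)
  expect_equal(r$trace, "n1>n2")
})

test_that("unknown policies resolve or abstain as configured", {
  alg <- toy_tree()
  v <- toy_vignette(walking = "unknown")
  expect_equal(run_triage(alg, v, "as_yes")$category, 3L)
  ab <- run_triage(alg, v, "abstain")
  expect_equal(ab$status, "abstained")
  expect_true(is.na(ab$category))
  expect_equal(ab$trace, "n1")
  expect_equal(ab$steps, 1L)
  # per-node override beats the call-level policy
  alg2 <- toy_tree()
  alg2$nodes$n1$unknown <- "as_yes"
  expect_equal(run_triage(alg2, v, "as_no")$category, 3L)
})

test_that("validation names dangling successors, cycles and bad terminals", {
  bad <- list(name = "bad", root = "n1",
              nodes = list(list(id = "n1", item = "walking",
                                on_yes = list(goto = "n99"),
                                on_no = list(out = "SK I"))),
              scale_map = list("SK I" = 1))
  expect_error(as_triage_algorithm(bad), "n99")

  cyc <- list(name = "cyc", root = "n1",
              nodes = list(
                list(id = "n1", item = "a", on_yes = list(goto = "n2"),
                     on_no = list(out = "SK I")),
                list(id = "n2", item = "b", on_yes = list(goto = "n1"),
                     on_no = list(out = "SK I"))),
              scale_map = list("SK I" = 1))
  expect_error(as_triage_algorithm(cyc), "cycle")

  unmapped <- list(name = "um", root = "n1",
                   nodes = list(list(id = "n1", item = "a",
                                     on_yes = list(out = "SK IX"),
                                     on_no = list(out = "SK I"))),
                   scale_map = list("SK I" = 1))
  expect_error(as_triage_algorithm(unmapped), "SK IX")
})

test_that("ESI levels map onto the comparison scale as specified", {
  esi <- shipped_algorithms("ESI")[[1]]
  expect_equal(unname(esi$scale_map[c("ESI 1", "ESI 2")]), c(1L, 2L))
  expect_equal(unname(esi$scale_map[c("ESI 3", "ESI 4", "ESI 5")]),
               c(3L, 3L, 3L))
  m <- map_output_scale(c("ESI 1", "ESI 4", "EX"), esi$scale_map)
  expect_equal(as.integer(m), c(1L, 3L, NA))
  expect_equal(attr(m, "out_of_scale"), c(FALSE, FALSE, TRUE))
})

test_that("resource tests drive the ESI levels 3-5", {
  esi <- shipped_algorithms("ESI")[[1]]
  base <- data.frame(immediate_life_threat = "no",
                     high_risk_presentation = "no",
                     resp_rate_gt29 = "no", hr_gt120 = "no",
                     stringsAsFactors = FALSE)
  for (case in list(c("many", "ESI 3"), c("one", "ESI 4"),
                    c("none", "ESI 5"))) {
    v <- vignette_set("V1", base, case[1])
    expect_equal(run_triage(esi, v)$raw, case[2])
  }
})

test_that("the ESI danger-zone block can be disabled by tag", {
  esi <- shipped_algorithms("ESI", disable_tags = "danger_zone")[[1]]
  expect_false(any(vapply(esi$nodes, function(n)
    identical(n$tag, "danger_zone"), NA)))
  v <- vignette_set("V1",
                    data.frame(immediate_life_threat = "no",
                               high_risk_presentation = "no",
                               resp_rate_gt29 = "yes", hr_gt120 = "yes",
                               stringsAsFactors = FALSE),
                    "none")
  expect_equal(run_triage(esi, v)$raw, "ESI 5")
  with_dz <- shipped_algorithms("ESI")[[1]]
  expect_equal(run_triage(with_dz, v)$raw, "ESI 2")
})

test_that("out-of-scale terminals are flagged, not coerced", {
  mstart <- shipped_algorithms("mSTaRT")[[1]]
  items <- algorithm_items(mstart)
  feats <- as.data.frame(as.list(stats::setNames(rep("no", length(items)),
                                                 items)),
                         optional = TRUE, stringsAsFactors = FALSE)
  v <- vignette_set("V1", feats, "none")  # not walking, not breathing
  r <- run_triage(mstart, v)
  expect_equal(r$raw, "EX")
  expect_equal(r$status, "out_of_scale")
  expect_true(is.na(r$category))
})

test_that("run over a set yields one result per algorithm and vignette", {
  alg <- toy_tree()
  set <- vignette_set(paste0("V", 1:3),
                      data.frame(walking = c("yes", "no", "no"),
                                 resp_rate_gt29 = c("no", "yes", "no"),
                                 radial_pulse = c("yes", "yes", "no"),
                                 stringsAsFactors = FALSE))
  alg2 <- toy_tree(); alg2$name <- "toy2"
  out <- run_triage_all(list(alg, alg2), set)
  expect_equal(nrow(out), 6L)
  expect_equal(out$vignette_id[1:3], set$vignette_id)
  expect_equal(out$category[1:3], c(3L, 1L, 1L))
  expect_error(run_triage(alg, set[0, ]), "empty")
  expect_error(run_triage_all(list(), set), "no algorithms")
})

test_that("querying an item the set lacks names the item", {
  alg <- toy_tree()
  v <- vignette_set("V1", data.frame(walking = "no",
                                     stringsAsFactors = FALSE))
  expect_error(run_triage(alg, v), "resp_rate_gt29")
})

test_that("interpreter is deterministic and steps respect the depth bound", {
  algs <- shipped_algorithms()
  for (alg in algs) {
    sim <- generate_vignettes(20, alg, seed = 5)
    r1 <- run_triage(alg, sim$set)
    r2 <- run_triage(alg, sim$set)
    expect_identical(r1, r2)
    depth <- max(vapply(enumerate_paths(alg), `[[`, 0L, "steps"))
    expect_true(all(r1$steps >= 1 & r1$steps <= depth))
  }
})

test_that("interpreter agrees with the exhaustive oracle on toy trees", {
  alg <- toy_tree()
  grid <- all_assignments(algorithm_items(alg))
  for (i in seq_len(nrow(grid))) {
    v <- vignette_set("V1", grid[i, , drop = FALSE])
    got <- run_triage(alg, v)
    want <- exhaustive_eval(alg, as.list(grid[i, ]))
    expect_equal(got$category, want$category)
    expect_equal(got$steps, want$steps)
  }
})

test_that("interpreter matches the oracle on random trees and replayed traces", {
  set.seed(123)
  for (rep in 1:10) {
    k <- sample(3:6, 1)
    alg <- random_tree(k)
    grid <- all_assignments(algorithm_items(alg))
    for (i in seq_len(nrow(grid))) {
      v <- vignette_set("V1", grid[i, , drop = FALSE])
      got <- run_triage(alg, v)
      want <- exhaustive_eval(alg, as.list(grid[i, ]))
      expect_equal(got$category, want$category)
      expect_equal(got$steps, want$steps)
      # trace validity: consecutive nodes connected by the taken branch
      trace <- strsplit(got$trace, ">")[[1]]
      for (j in seq_len(length(trace) - 1)) {
        nd <- alg$nodes[[trace[j]]]
        succ <- c(nd$on_yes$goto, nd$on_no$goto)
        expect_true(trace[j + 1] %in% succ)
      }
    }
  }
})

test_that("shipped encodings validate and reach all comparison categories", {
  algs <- shipped_algorithms()
  expect_named(algs, c("mSTaRT", "PRIOR", "BER", "MTS-MANV", "ESI",
                       "JorD", "PETRA"))
  for (alg in algs) {
    expect_silent(validate_algorithm(alg))
    cats <- vapply(enumerate_paths(alg), `[[`, NA_integer_, "category")
    expect_setequal(stats::na.omit(cats), 1:3)
  }
})

test_that("DOT rendering covers every node", {
  alg <- shipped_algorithms("BER")[[1]]
  dot <- algorithm_dot(alg)
  expect_match(dot, "^digraph")
  for (id in names(alg$nodes)) expect_match(dot, paste0('"', id, '"'))
})
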