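makeLibrary <- function(n, names) {
  lapply(seq_len(n), function(k)
    list(label = sprintf("mod%02d", k),
         descriptorDelta = setNames(rep(0.1 * k, length(names)), names)))
}

test_that("candidate enumeration is deterministic and well-labelled", {
  tmpl <- list(id = "T", descriptors = c(A = 1, B = 2))
  identity <- list(list(label = "identity", descriptorDelta = c(A = 0, B = 0)))
  cand <- enumerateCandidates(tmpl, identity, n = 1, seed = 1)
  expect_identical(cand[[1]]$id, "T.1")
  expect_identical(cand[[1]]$descriptors, tmpl$descriptors)
  lib <- makeLibrary(200, c("A", "B"))
  c200 <- enumerateCandidates(tmpl, lib, n = 200, seed = 5)
  expect_identical(vapply(c200, `[[`, "", "id"), paste0("T.", 1:200))
  expect_length(unique(vapply(c200, `[[`, "", "id")), 200)
  c200b <- enumerateCandidates(tmpl, lib, n = 200, seed = 5)
  expect_identical(c200, c200b)
  expect_error(enumerateCandidates(tmpl, lib[1:3], n = 5, seed = 1),
               "replace")
  withRep <- enumerateCandidates(tmpl, lib[1:3], n = 5, seed = 1,
                                 replace = TRUE)
  expect_length(withRep, 5)
})

test_that("ranking follows the primary model with id tie-breaks", {
  plant <- new("LinearQsarModel", intercept = 0, coefficients = c(A = 2, B = -1),
               stats = list(), provenance = "planted")
  tmpl <- list(id = "T", descriptors = c(A = 0, B = 0))
  lib <- list(
    list(label = "big", descriptorDelta = c(A = 3, B = 0)),    # score 6
    list(label = "mid", descriptorDelta = c(A = 1, B = 0)),    # score 2
    list(label = "neg", descriptorDelta = c(A = 0, B = 4)),    # score -4
    list(label = "tie", descriptorDelta = c(A = 1, B = 0)))    # score 2 (tie)
  cand <- enumerateCandidates(tmpl, lib, n = 4, seed = 2)
  run <- predictAndRank(cand, list(hm = plant), template = "T")
  expect_s4_class(run, "DesignRun")
  # the largest planted-direction perturbation ranks first
  labs <- run@table$provenance[order(run@table$rank)]
  expect_match(labs[1], "big")
  # the two tied candidates order lexicographically by id
  tied <- run@table$id[run@table$hm == 2]
  expect_identical(tied, sort(tied))
  expect_identical(nrow(run@table), 4L)
})

test_that("multi-model scoring keeps going past missing inputs", {
  plant <- new("LinearQsarModel", intercept = 9, coefficients = c(A = 1),
               stats = list(), provenance = "planted")
  tree <- parseExpression("A + 1")
  cands <- list(list(id = "T.1", provenance = "ok", descriptors = c(A = 2)),
                list(id = "T.2", provenance = "no-desc", descriptors = NULL))
  expect_warning(run <- predictAndRank(cands, list(hm = plant, gep = tree),
                                       primaryModel = "hm"), "unavailable")
  tab <- run@table
  expect_equal(tab$hm[tab$id == "T.1"], 11)
  expect_equal(tab$gep[tab$id == "T.1"], 3)
  expect_true(is.na(tab$hm[tab$id == "T.2"]))
  expect_identical(tab$id[1], "T.1")   # NA candidates sort last
  # the template itself gets no special treatment when included
  tmplCand <- list(id = "T.0", provenance = "template", descriptors = c(A = 0))
  run2 <- predictAndRank(c(list(tmplCand), cands[1]), list(hm = plant),
                         primaryModel = "hm")
  expect_identical(run2@table$id, c("T.1", "T.0"))
})

test_that("prediction is read-only on the models", {
  plant <- new("LinearQsarModel", intercept = 0, coefficients = c(A = 1),
               stats = list(r2 = 0.5), provenance = "planted")
  before <- plant
  cands <- list(list(id = "c.1", provenance = "x", descriptors = c(A = 1)))
  invisible(predictAndRank(cands, list(hm = plant), primaryModel = "hm"))
  expect_identical(plant, before)
})
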