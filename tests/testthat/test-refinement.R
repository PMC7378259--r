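# helper: blank LC matrix with labels painted in
paint <- function(nrow = 15, ncol = 20, ..., provenance = "classifier") {
  lab <- matrix("LC", nrow, ncol)
  spots <- list(...)
  for (cls in names(spots)) lab[spots[[cls]]] <- cls
  label_matrix(lab, provenance)
}

test_that("occurrence counting covers exactly the discriminant classes", {
  expect_equal(count_occurrences(paint()), c(EA = 0L, LV = 0L, MA = 0L, HE = 0L))
  m <- paint(HE = 1:120, EA = 121:125, LR = 200:220)
  expect_equal(count_occurrences(m), c(EA = 5L, LV = 0L, MA = 0L, HE = 120L))
  # counting is order-free: transposed content gives identical counts
  expect_equal(count_occurrences(label_matrix(t(matrix(as.character(m), 15, 20)))),
               count_occurrences(m))
})

test_that("organ ranking is count-descending with the fixed tie priority", {
  expect_equal(rank_organs(c(EA = 5, LV = 0, MA = 0, HE = 120)),
               c("Heart", "ElasticArtery"))
  expect_equal(rank_organs(c(EA = 0, LV = 0, MA = 0, HE = 0)), character())
  expect_warning(
    ranked <- rank_organs(c(EA = 7, LV = 7, MA = 0, HE = 0)),
    "tie"
  )
  expect_equal(ranked, c("ElasticArtery", "LargeVein"))
})

test_that("rule construction enumerates higher-rank to lower-rank pairs", {
  r1 <- build_rules(c("Heart", "ElasticArtery"))
  expect_equal(nrow(r1), 1)
  expect_equal(r1$subject, "Heart")
  expect_equal(r1$predicate, "hasPresenceOf")
  expect_equal(r1$object, "ElasticArtery")

  expect_equal(nrow(build_rules("Heart")), 0)
  expect_equal(nrow(build_rules(character())), 0)

  # the worked four-organ ranking reproduces the printed query list
  r4 <- build_rules(c("Heart", "LargeVein", "ElasticArtery", "MuscularArtery"))
  expect_equal(nrow(r4), 4 * 3 / 2)
  key <- paste(r4$subject, r4$object)
  expect_true(all(c(
    "Heart ElasticArtery", "Heart LargeVein",
    "LargeVein ElasticArtery", "LargeVein MuscularArtery"
  ) %in% key))
  # rule-count law for every k
  for (k in 2:4) {
    expect_equal(nrow(build_rules(kb_vocabulary()$organs[seq_len(k)])), k * (k - 1) / 2)
  }
})

test_that("empty presence answers reclassify exactly the object organ cells", {
  kb <- default_kb()
  m <- paint(HE = 1:120, EA = c(150, 160, 170, 180, 190))
  counts <- count_occurrences(m)
  rules <- build_rules(rank_organs(counts))
  out <- apply_rules(m, rules, kb)
  expect_equal(sum(as.character(out) == "EA"), 0)
  expect_equal(sum(as.character(out) == "HE"), 120) # subject untouched
  changed <- which(as.character(out) != as.character(m))
  expect_equal(sort(changed), c(150, 160, 170, 180, 190))
  expect_true(all(as.character(out)[changed] == "LC"))
  expect_true(all(attr(out, "provenance")[changed] == "corrected"))

  # single-organ matrix: no rules fire, nothing changes
  solo <- paint(HE = 1:120)
  expect_equal(as.character(apply_rules(solo, build_rules(rank_organs(count_occurrences(solo))), kb)),
               as.character(solo))

  # a non-empty answer validates the initial classification
  kb2 <- kb_assert(kb, "Heart", "hasPresenceOf", "ElasticArtery")
  out2 <- apply_rules(m, rules, kb2)
  expect_equal(sum(as.character(out2) == "EA"), 5)
})

test_that("light components respect 4-connectivity and the size threshold", {
  # straight run of 9: below the ten-block limit
  expect_length(find_light_components(paint(LR = cbind(5, 3:11))), 0)
  # run of 10: accepted
  comps <- find_light_components(paint(LR = cbind(5, 3:12)))
  expect_length(comps, 1)
  expect_equal(comps[[1]]$size, 10)
  # L-shaped set of 12 touching cells closes into one component
  lcells <- rbind(cbind(3:10, 4), cbind(10, 5:8))
  comps <- find_light_components(paint(LR = lcells))
  expect_length(comps, 1)
  expect_equal(comps[[1]]$size, 12)
  # two separate runs are two components, sorted by size descending
  comps <- find_light_components(paint(LR = rbind(cbind(2, 1:10), cbind(8, 1:12))))
  expect_equal(vapply(comps, `[[`, numeric(1), "size"), c(12, 10))
})

test_that("lumen candidacy requires muscle in the neighbourhood", {
  m <- paint(LR = cbind(5, 3:12)) # surrounded by LC only
  comp <- find_light_components(m)[[1]]
  expect_false(qualifies_for_epithelium(comp, m))
  # one adjacent muscular-artery cell suffices
  m2 <- paint(LR = cbind(5, 3:12), MA = cbind(4, 5))
  comp2 <- find_light_components(m2)[[1]]
  expect_true(qualifies_for_epithelium(comp2, m2))
  # a component hugging only the matrix border does not qualify
  m3 <- paint(LR = cbind(1, 1:12))
  comp3 <- find_light_components(m3)[[1]]
  expect_false(qualifies_for_epithelium(comp3, m3))
})

test_that("epithelium appears exactly on the lumen/muscle boundary", {
  fx <- generate_organ_image(organ_layout("ElasticArtery", seed = 2), keep_image = FALSE)
  pred <- classifier_view(fx$truth)
  out <- detect_epithelium(pred, default_kb())
  expect_equal(as.character(out), as.character(fx$truth))
  ep <- which(as.character(out) == "EP")
  expect_true(all(attr(out, "provenance")[ep] == "epithelium"))
  # every EP cell was LR and had a muscle 4-neighbor (exhaustive scan)
  m <- nrow(out)
  for (idx in ep) {
    expect_equal(as.character(pred)[idx], "LR")
    i <- (idx - 1) %% m + 1
    j <- (idx - 1) %/% m + 1
    nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= m & nb[, 2] >= 1 & nb[, 2] <= ncol(out), , drop = FALSE]
    expect_true(any(as.character(pred)[(nb[, 2] - 1) * m + nb[, 1]] %in% discriminant_labels()))
  }
  # interior lumen cells stay LR
  expect_true(sum(as.character(out) == "LR") > 0)

  # no light region, or no epithelium facts: unchanged
  noLR <- paint(HE = 1:100)
  expect_equal(as.character(detect_epithelium(noLR, default_kb())), as.character(noLR))
  expect_equal(as.character(detect_epithelium(pred, kb_new())), as.character(pred))
})

test_that("refinement composes correction then epithelium and is idempotent", {
  kb <- default_kb()
  for (s in 1:4) {
    organ <- kb_vocabulary()$organs[s]
    fx <- generate_organ_image(organ_layout(organ, seed = s), keep_image = FALSE)
    pred <- classifier_view(fx$truth)
    cor <- corrupt_labels(pred, 0.1, foreign_label = label_for_organ(
      kb_vocabulary()$organs[s %% 4 + 1]), seed = s)
    once <- refine(cor$matrix, kb)
    twice <- refine(once, kb)
    expect_equal(as.character(twice), as.character(once))
    # corruption-free fixture: only change is the epithelial ring
    clean <- refine(pred, kb)
    expect_equal(as.character(clean), as.character(fx$truth))
    # corrupted fixture: both corrections applied, recovering the truth
    expect_equal(as.character(once), as.character(fx$truth))
  }
})

test_that("refinement only makes muscle-to-LC and LR-to-EP transitions", {
  kb <- default_kb()
  set.seed(77)
  for (trial in 1:10) {
    lab <- matrix(sample(classifier_labels(), 15 * 20, TRUE,
                         prob = c(.1, .1, .1, .2, .3, .2)), 15, 20)
    before <- label_matrix(lab)
    after <- refine(before, kb)
    expect_equal(dim(after), dim(before))
    moved <- which(as.character(after) != as.character(before))
    for (idx in moved) {
      from <- as.character(before)[idx]
      to <- as.character(after)[idx]
      expect_true(
        (from %in% discriminant_labels() && to == "LC") ||
          (from == "LR" && to == "EP")
      )
    }
  }
})

test_that("threshold calibration minimises the Hamming error with small-t ties", {
  # a problem whose output at t = 10 equals the truth exactly
  problem <- generate_calibration_problem(seed = 1)
  res <- calibrate_threshold(problem)
  expect_equal(res$t_star, 10)
  expect_equal(unname(res$ae["10"]), 0)
  # tie goes to the smaller threshold
  truth <- paint(LR = cbind(5, 3:12))
  same <- function(t) list(truth)
  p2 <- calibration_problem(list(truth), same, candidates = c(7, 3))
  expect_equal(calibrate_threshold(p2)$t_star, 3)
  expect_error(calibration_problem(list(), same, 1:3), "at least one")
  expect_error(calibrate_threshold(structure(list(), class = "calibration_problem")),
               "empty candidate")
  expect_error(hamming_distance(paint(), paint(nrow = 5, ncol = 5)), "shape mismatch")
})
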