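test_that("block textures are deterministic and class-distinct", {
  b1 <- generate_block("HE", seed = 7)
  b2 <- generate_block("HE", seed = 7)
  expect_identical(b1, b2)
  expect_false(identical(generate_block("HE", seed = 8), b1))
  expect_false(identical(generate_block("MA", seed = 7), b1))
  expect_equal(dim(b1), c(100, 100, 3))
  expect_true(all(b1 >= 0 & b1 <= 255))
  expect_error(generate_block("EP", seed = 1), "derived label")
  # the six classifier classes have pairwise-distinct orientation/frequency
  spec <- texture_specs()
  expect_equal(anyDuplicated(spec[, c("angle_deg", "freq")]), 0)
})

test_that("light regions have the lowest pixel variance of all classes", {
  for (s in 1:50) {
    v <- vapply(classifier_labels(), function(cl) {
      var(as.vector(to_grayscale(generate_block(cl, seed = s))))
    }, numeric(1))
    expect_equal(names(which.min(v)), "LR")
  }
})

test_that("organ layouts produce consistent truth, texture and EP ring", {
  layout <- organ_layout("Heart", seed = 3)
  fx <- generate_organ_image(layout)
  expect_equal(dim(fx$truth), c(15, 20)) # 2048x1536 -> 20 cols x 15 rows
  expect_equal(dim(fx$image), c(1536, 2048, 3))
  expect_equal(nrow(fx$corruption), 0) # corruption 0 -> empty record

  truth <- as.character(fx$truth)
  texture <- as.character(fx$texture)
  # texture equals truth except the EP ring, which renders as light region
  ep <- truth == "EP"
  expect_true(any(ep))
  expect_true(all(texture[ep] == "LR"))
  expect_equal(truth[!ep], texture[!ep])
  # the lumen is one 4-connected component of at least min_lumen cells
  comps <- find_light_components(fx$texture, min_size = 1)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$size, sum(texture == "LR"))
  expect_gte(comps[[1]]$size, layout$min_lumen)
  # every EP cell borders the muscle annulus
  expect_equal(
    as.character(detect_epithelium(classifier_view(fx$truth), default_kb())),
    truth
  )
})

test_that("layout validation rejects impossible geometry", {
  expect_error(organ_layout("Heart", lumen_radius = 10), "overflows")
  expect_error(organ_layout("Heart", lumen_radius = 1), "lumen has only")
  expect_error(organ_layout("Heart", corruption_rate = 1.5), "corruption_rate")
  expect_error(organ_layout("Lung"), "unregistered")
})

test_that("corruption swaps texture on connective cells, preserving truth", {
  layout <- organ_layout("ElasticArtery", corruption_rate = 0.15, seed = 9)
  fx <- generate_organ_image(layout, keep_image = FALSE)
  rec <- fx$corruption
  expect_gt(nrow(rec), 0)
  expect_equal(nrow(rec), round(0.15 * sum(as.character(fx$truth) == "LC")))
  idx <- (rec$col - 1) * nrow(fx$truth) + rec$row
  expect_true(all(as.character(fx$truth)[idx] == "LC"))
  expect_true(all(as.character(fx$texture)[idx] == layout$foreign_class))
  # same layout, same seed: bit-identical corruption record
  fx2 <- generate_organ_image(layout, keep_image = FALSE)
  expect_identical(fx2$corruption, rec)
})

test_that("datasets split at the image level with no block leakage", {
  ds <- generate_dataset(K = 4, split = 0.7, seed = 11,
                         width = 1500, height = 1300)
  # floor(0.7 * 4) = 2 train images, remainder validation
  expect_equal(sum(ds$manifest$split == "train"), 2)
  expect_equal(sum(ds$manifest$split == "validation"), 2)
  expect_equal(ds$manifest$organ[1:4],
               c("Heart", "ElasticArtery", "MuscularArtery", "LargeVein"))
  blocks_per_image <- (1300 %/% 100) * (1500 %/% 100)
  expect_equal(nrow(ds$train$descriptors), 2 * blocks_per_image)
  expect_equal(nrow(ds$validation$descriptors), 2 * blocks_per_image)
  expect_length(intersect(unique(ds$train$image), unique(ds$validation$image)), 0)
  expect_equal(length(ds$train$labels), nrow(ds$train$descriptors))
  # dataset generation is reproducible from (K, split, seed)
  ds2 <- generate_dataset(K = 4, split = 0.7, seed = 11,
                          width = 1500, height = 1300)
  expect_identical(ds2$train$descriptors, ds$train$descriptors)
  expect_identical(ds2$manifest, ds$manifest)
  expect_error(generate_dataset(K = 1), "at least 2")
})

test_that("label-level corruption hits only connective cells", {
  fx <- generate_organ_image(organ_layout("MuscularArtery", seed = 4), keep_image = FALSE)
  pred <- classifier_view(fx$truth)
  cor <- corrupt_labels(pred, 0.2, "HE", seed = 5)
  expect_true(all(as.character(pred)[cor$cells] == "LC"))
  expect_true(all(as.character(cor$matrix)[cor$cells] == "HE"))
  untouched <- setdiff(seq_along(pred), cor$cells)
  expect_equal(as.character(cor$matrix)[untouched], as.character(pred)[untouched])
  expect_length(corrupt_labels(pred, 0, "HE")$cells, 0)
})
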