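test_that("grayscale conversion follows BT.601 luminance", {
  # gray input is a fixed point
  g <- array(rep(matrix(c(0, 100, 255, 42), 2, 2), 3), dim = c(2, 2, 3))
  expect_equal(to_grayscale(g), matrix(c(0, 100, 255, 42), 2, 2))
  # pure red: round(0.299 * 255)
  expect_equal(as.vector(to_grayscale(array(c(255, 0, 0), dim = c(1, 1, 3)))), 76)
  expect_error(to_grayscale(array(0, dim = c(0, 3, 3))), "empty image")
  expect_error(to_grayscale(array(0, dim = c(2, 2, 4))), "RGB")
})

test_that("lbp_code implements the sign-sum definition with s(0) = 1", {
  expect_equal(lbp_code(100, rep(100, 8)), 255) # s(0) = 1 forces all bits
  expect_equal(lbp_code(200, rep(0, 8)), 0)
  expect_equal(lbp_code(100, c(90, 110, 100, 95, 120, 80, 100, 101)), 214)
  # agrees with the brute-force oracle on random center/neighbor draws
  set.seed(11)
  for (k in 1:50) {
    ctr <- sample(0:255, 1)
    nb <- sample(0:255, 8, replace = TRUE)
    expect_equal(lbp_code(ctr, nb), oracle_lbp_code(ctr, nb))
  }
})

test_that("min_rotation canonicalizes to the orbit minimum", {
  expect_equal(min_rotation(0), 0)
  expect_equal(min_rotation(255), 255)
  expect_equal(min_rotation(128), 1)
  expect_equal(min_rotation(6), 3)
  # exhaustive agreement with the bit-vector oracle
  expect_equal(min_rotation(0:255), vapply(0:255, oracle_min_rotation, numeric(1)))
  # idempotent and never larger than its argument
  canon <- min_rotation(0:255)
  expect_equal(min_rotation(canon), canon)
  expect_true(all(canon <= 0:255))
  expect_error(min_rotation(256), "out of range")
  expect_error(min_rotation(-1), "out of range")
})

test_that("ri mapping partitions the 256 codes into 36 rotation orbits", {
  m <- build_ri_mapping()
  expect_equal(m$n_classes, 36)
  expect_equal(length(m$table), 256)
  expect_setequal(unique(m$table), 0:35)
  # class 0 belongs to canonical code 0
  expect_equal(m$table[1], 0L)
  # every rotation of every code shares its class: all 256 x 8 pairs
  for (r in 0:7) {
    rotated <- bitwAnd(bitwOr(bitwShiftR(0:255, r), bitwShiftL(0:255, 8 - r)), 255L)
    expect_equal(m$table[rotated + 1], m$table)
  }
  # orbit partition matches an independent brute-force grouping
  oracle_canon <- vapply(0:255, oracle_min_rotation, numeric(1))
  expect_equal(length(unique(oracle_canon)), 36)
  expect_equal(m$table + 1L, match(oracle_canon, sort(unique(oracle_canon))))
})

test_that("lbp_histogram counts interior pixels and matches the loop oracle", {
  const <- matrix(100, 100, 100)
  h <- lbp_histogram(const)
  expect_equal(length(h), 256)
  expect_equal(h[256], 98 * 98) # every interior pixel codes to 255
  expect_equal(sum(h), 9604)
  # random blocks: conservation plus exact agreement with the double loop
  for (s in 1:5) {
    b <- random_gray_block(12, seed = s)
    h <- lbp_histogram(b)
    expect_equal(sum(h), 10 * 10)
    expect_equal(h, oracle_lbp_histogram(b))
  }
  expect_error(lbp_histogram(matrix(0, 2, 5)), "too small")
  expect_error(lbp_histogram(matrix(0, 100, 100), params = list(P = 4, R = 1)),
               "only P = 8")
})

test_that("lbpri_histogram is the push-forward of the LBP histogram", {
  m <- build_ri_mapping()
  const <- matrix(7, 50, 50)
  ri <- lbpri_histogram(const)
  expect_equal(length(ri), 36)
  expect_equal(ri[m$table[256] + 1], 48 * 48) # all mass at the class of code 255
  for (s in 6:10) {
    b <- random_gray_block(20, seed = s)
    lbp <- lbp_histogram(b)
    ri <- lbpri_histogram(b)
    expect_equal(sum(ri), sum(lbp))
    # brute-force aggregation by orbit class
    agg <- vapply(0:35, function(k) sum(lbp[m$table == k]), numeric(1))
    expect_equal(ri, as.integer(agg))
  }
})

test_that("describe_block yields the 292-value normalized descriptor", {
  b <- random_gray_block(100, seed = 21)
  d <- describe_block(b)
  expect_length(d, 292)
  expect_named(d, descriptor_names())
  expect_true(all(d >= 0))
  expect_equal(sum(d[1:256]), 1)
  expect_equal(sum(d[257:292]), 1)
  # raw mode preserves counts
  raw <- describe_block(b, normalize = FALSE)
  expect_equal(sum(raw[1:256]), 98 * 98)
  expect_error(describe_block(matrix(0, 2, 2)), "too small")
})

test_that("LBPri part of the descriptor is invariant to 90-degree rotation", {
  for (s in 1:20) {
    b <- random_gray_block(30, seed = 100 + s)
    expect_identical(lbpri_histogram(rot90cw(b)), lbpri_histogram(b))
    d1 <- describe_block(b)
    d2 <- describe_block(rot90cw(b))
    expect_equal(d2[257:292], d1[257:292])
  }
})

test_that("descriptor CSV round trip keeps values and column order", {
  set.seed(3)
  x <- rbind(describe_block(random_gray_block(20)), describe_block(random_gray_block(20)))
  path <- tempfile(fileext = ".csv")
  write_descriptors(x, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_equal(gsub("\"", "", header), descriptor_names())
  back <- read_descriptors(path)
  expect_equal(unname(back), unname(x))
})
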