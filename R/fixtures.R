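# Deterministic synthetic fixtures: per-class oriented-grating textures that
# an LBP + SVM pipeline can separate by construction, organ-like concentric
# layouts (lumen / muscle annulus / connective surround), and controllable
# texture corruption to exercise the refinement stage. Realism is
# deliberately minimal: the textures emulate coarse stain color statistics
# and per-class texture distinctness, not actual H&E appearance.

#' Per-class texture specifications for the fixture generator
#'
#' Each of the six classifier classes gets a pairwise-distinct combination
#' of grating orientation and spatial frequency, a stain-palette base color
#' (pink/violet tones for muscle, pale blue for loose connective tissue,
#' near-white for light regions) and a noise amplitude. `LR` has the lowest
#' pixel variance of all classes (flat, faint noise), matching how lumina
#' look on a slide.
#'
#' @return Data frame with one row per classifier class: `class`,
#'   `angle_deg`, `freq` (cycles per 100 px), `amp`, `noise_sd`, `r`, `g`,
#'   `b` (base color, 0-255).
#' @export
texture_specs <- function() {
  data.frame(
    class = c("HE", "MA", "EA", "LV", "LC", "LR"),
    angle_deg = c(0, 45, 90, 135, 30, 0),
    freq = c(9, 14, 22, 5, 2, 0),
    amp = c(60, 55, 50, 55, 18, 0),
    noise_sd = c(12, 12, 10, 12, 8, 3),
    r = c(205, 160, 235, 220, 170, 248),
    g = c(120, 110, 150, 200, 190, 246),
    b = c(150, 200, 90, 120, 230, 250),
    stringsAsFactors = FALSE
  )
}

# draw one block texture from the current RNG stream
generate_block_texture <- function(class, size = 100) {
  spec <- texture_specs()
  row <- spec[spec$class == class, ]
  if (nrow(row) != 1) stopf("no texture spec for class '%s'", class)
  theta <- row$angle_deg * pi / 180
  phase <- runif(1, 0, 2 * pi)
  xs <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  ys <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  carrier <- if (row$freq > 0) {
    row$amp * sin(2 * pi * row$freq * (xs * cos(theta) + ys * sin(theta)) / 100 + phase)
  } else {
    matrix(0, size, size)
  }
  noise <- matrix(rnorm(size * size, sd = row$noise_sd), size, size)
  base <- c(row$r, row$g, row$b)
  img <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) {
    img[, , ch] <- pmin(pmax(round(base[ch] + carrier + noise), 0), 255)
  }
  img
}

#' Generate one synthetic tissue block
#'
#' Draws a deterministic `size x size` RGB texture block for one of the six
#' classifier classes: an oriented sinusoidal grating plus Gaussian noise on
#' a stain-palette base color, per [texture_specs()]. `EP` has no texture of
#' its own (it is a label derived by refinement, not a tissue the classifier
#' sees) and is rejected.
#'
#' @param class One of [classifier_labels()].
#' @param seed Integer seed; the same `(class, seed)` pair always yields a
#'   bit-identical block.
#' @param size Block side in pixels (default 100).
#' @return RGB array `size x size x 3`, values 0-255.
#' @examples
#' b1 <- generate_block("HE", seed = 7)
#' b2 <- generate_block("HE", seed = 7)
#' identical(b1, b2) # TRUE
#' @export
generate_block <- function(class, seed, size = 100) {
  if (identical(class, "EP")) {
    stopf("EP has no generator texture: it is a derived label, not a classifier class")
  }
  check_labels(class, allowed = classifier_labels())
  spec_ix <- match(class, texture_specs()$class)
  with_seed(child_seed(seed, spec_ix), generate_block_texture(class, size = size))
}

#' Describe an organ-like image layout
#'
#' Concentric block-level geometry: a light-region lumen disk, a muscle
#' annulus of the organ's discriminant class, and a loose-connective
#' surround. All geometry is expressed in block units on the tiling grid of
#' the requested image size.
#'
#' @param organ Organ term (`"Heart"`, `"ElasticArtery"`, `"MuscularArtery"`,
#'   `"LargeVein"`).
#' @param width,height Image size in pixels (default 2048 x 1536, the
#'   reference 10x capture geometry, which tiles to a 15 x 20 block grid).
#' @param block_size Block side in pixels.
#' @param center Lumen center `c(row, col)` in block coordinates.
#' @param lumen_radius Lumen disk radius in blocks.
#' @param annulus_width Muscle annulus thickness in blocks.
#' @param corruption_rate Fraction of loose-connective cells whose *texture*
#'   is swapped to a foreign organ class (their truth label stays `LC`),
#'   emulating the connective-tissue false positives the refinement stage
#'   corrects.
#' @param foreign_class Discriminant label used for corrupted textures
#'   (default: the next organ, cyclically).
#' @param min_lumen Minimum admissible lumen size in blocks (default 10).
#' @param seed Integer seed.
#' @return A list of class `organ_layout`.
#' @export
organ_layout <- function(organ, width = 2048, height = 1536, block_size = 100,
                         center = NULL, lumen_radius = 3, annulus_width = 3,
                         corruption_rate = 0, foreign_class = NULL,
                         min_lumen = 10, seed = 1L) {
  check_term(organ, "organs", "organ")
  m <- height %/% block_size
  n <- width %/% block_size
  if (m < 3 || n < 3) stopf("grid %dx%d too small for an organ layout", m, n)
  center <- center %||% c((m + 1) / 2, (n + 1) / 2)
  if (is.null(foreign_class)) {
    organs <- kb_vocabulary()$organs
    foreign_class <- label_for_organ(organs[(match(organ, organs) %% length(organs)) + 1])
  }
  if (corruption_rate < 0 || corruption_rate > 1) stopf("corruption_rate must lie in [0, 1]")
  layout <- structure(
    list(
      organ = organ, width = width, height = height, block_size = block_size,
      grid_nrow = m, grid_ncol = n, center = center,
      lumen_radius = lumen_radius, annulus_width = annulus_width,
      corruption_rate = corruption_rate, foreign_class = foreign_class,
      min_lumen = min_lumen, seed = as.integer(seed)
    ),
    class = "organ_layout"
  )
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  r_out <- layout$lumen_radius + layout$annulus_width
  lo_r <- layout$center[1] - r_out
  hi_r <- layout$center[1] + r_out
  lo_c <- layout$center[2] - r_out
  hi_c <- layout$center[2] + r_out
  if (lo_r < 0.5 || hi_r > layout$grid_nrow + 0.5 ||
      lo_c < 0.5 || hi_c > layout$grid_ncol + 0.5) {
    stopf(
      "layout overflows the %dx%d block grid: lumen + annulus spans rows %.1f..%.1f, cols %.1f..%.1f",
      layout$grid_nrow, layout$grid_ncol, lo_r, hi_r, lo_c, hi_c
    )
  }
  lumen_cells <- sum(layout_regions(layout) == "LR")
  if (lumen_cells < layout$min_lumen) {
    stopf("lumen has only %d block(s); at least %d required", lumen_cells, layout$min_lumen)
  }
  invisible(layout)
}

# block-level region map: LR lumen disk, organ annulus, LC surround
layout_regions <- function(layout) {
  m <- layout$grid_nrow
  n <- layout$grid_ncol
  rows <- matrix(seq_len(m), m, n)
  cols <- matrix(rep(seq_len(n), each = m), m, n)
  d <- sqrt((rows - layout$center[1])^2 + (cols - layout$center[2])^2)
  organ_lab <- label_for_organ(layout$organ)
  regions <- matrix("LC", m, n)
  regions[d <= layout$lumen_radius + layout$annulus_width] <- organ_lab
  regions[d <= layout$lumen_radius] <- "LR"
  regions
}

#' Generate a synthetic organ image with ground truth
#'
#' Assembles a block-wise image from the layout's region map: light-region
#' textures in the lumen, the organ's muscle texture in the annulus, loose
#' connective tissue outside (and in the partial-block margins that the
#' tiler discards). The ground-truth label matrix marks lumen cells
#' 4-adjacent to muscle as `EP` — the epithelial lining a perfect annotator
#' would draw at the lumen boundary. Corruption (if any) swaps the texture
#' of randomly chosen `LC` cells to a foreign organ class while leaving
#' their truth label `LC`, recording each swap; a classifier trained on
#' clean textures will mislabel exactly those cells, which is the error mode
#' the knowledge-base correction removes.
#'
#' @param layout An [organ_layout()].
#' @param keep_image Assemble and return the pixel image (default `TRUE`);
#'   with `FALSE` only the block-level matrices are produced (the
#'   `descriptors` path in [generate_dataset()] re-creates identical blocks
#'   on the fly).
#' @return A list of class `organ_fixture`: `image` (RGB array or `NULL`),
#'   `truth` (label_matrix, provenance `"truth"`), `texture` (label_matrix
#'   of the classes actually rendered, provenance `"classifier"`),
#'   `corruption` (data.frame `row`, `col`, `truth`, `texture`), `layout`.
#' @examples
#' fx <- generate_organ_image(organ_layout("Heart", seed = 3))
#' dim(fx$truth) # 15 x 20
#' @export
generate_organ_image <- function(layout, keep_image = TRUE) {
  stopifnot(inherits(layout, "organ_layout"))
  validate_layout(layout)
  truth <- layout_regions(layout)
  m <- nrow(truth)
  n <- ncol(truth)

  # epithelial ring: lumen cells touching the muscle annulus
  organ_lab <- label_for_organ(layout$organ)
  lr_idx <- which(truth == "LR")
  cells <- cbind((lr_idx - 1L) %% m + 1L, (lr_idx - 1L) %/% m + 1L)
  nb <- neighbor_cells(cells, m, n)
  touches <- truth[(nb$nb[, 2] - 1L) * m + nb$nb[, 1]] == organ_lab
  ep_cells <- lr_idx[unique(nb$src[touches])]
  truth_ep <- truth
  truth_ep[ep_cells] <- "EP"

  # texture map: what is actually rendered (EP ring renders as lumen)
  texture <- truth
  corruption <- data.frame(row = integer(), col = integer(),
                           truth = character(), texture = character(),
                           stringsAsFactors = FALSE)
  with_seed(child_seed(layout$seed, 9991L), {
    if (layout$corruption_rate > 0) {
      lc_idx <- which(truth == "LC")
      k <- round(layout$corruption_rate * length(lc_idx))
      if (k > 0) {
        hit <- sample(lc_idx, k)
        texture[hit] <- layout$foreign_class
        corruption <- data.frame(
          row = (hit - 1L) %% m + 1L, col = (hit - 1L) %/% m + 1L,
          truth = "LC", texture = layout$foreign_class,
          stringsAsFactors = FALSE
        )
      }
    }
  })

  image <- NULL
  if (keep_image) {
    s <- layout$block_size
    image <- array(0, dim = c(layout$height, layout$width, 3))
    with_seed(child_seed(layout$seed, 17L), {
      for (i in seq_len(m)) {
        for (j in seq_len(n)) {
          blk <- generate_block_texture(texture[i, j], size = s)
          image[((i - 1) * s + 1):(i * s), ((j - 1) * s + 1):(j * s), ] <- blk
        }
      }
      # partial-block margins (discarded by the tiler) rendered as LC
      if (layout$height > m * s) {
        pad <- generate_block_texture("LC", size = s)
        for (j in seq_len(ceiling(layout$width / s))) {
          cc <- ((j - 1) * s + 1):min(j * s, layout$width)
          image[(m * s + 1):layout$height, cc, ] <-
            pad[seq_len(layout$height - m * s), seq_along(cc), ]
        }
      }
      if (layout$width > n * s) {
        pad <- generate_block_texture("LC", size = s)
        image[seq_len(layout$height), (n * s + 1):layout$width, ] <-
          pad[rep_len(seq_len(s), layout$height), seq_len(layout$width - n * s), ]
      }
    })
  }

  structure(
    list(
      image = image,
      truth = label_matrix(truth_ep, "truth"),
      texture = label_matrix(texture, "classifier"),
      corruption = corruption,
      layout = layout
    ),
    class = "organ_fixture"
  )
}

# descriptors + labels for every block of a fixture, without keeping pixels.
# RNG stream and block order match generate_organ_image(keep_image = TRUE).
fixture_descriptors <- function(layout) {
  fx <- generate_organ_image(layout, keep_image = FALSE)
  texture <- fx$texture
  m <- nrow(texture)
  n <- ncol(texture)
  X <- matrix(0, m * n, 292)
  labs <- character(m * n)
  k <- 1L
  with_seed(child_seed(layout$seed, 17L), {
    for (i in seq_len(m)) {
      for (j in seq_len(n)) {
        blk <- generate_block_texture(texture[i, j], size = layout$block_size)
        X[k, ] <- describe_block(to_grayscale(blk))
        labs[k] <- texture[i, j]
        k <- k + 1L
      }
    }
  })
  colnames(X) <- descriptor_names()
  list(descriptors = X, labels = labs, fixture = fx)
}

#' Generate a train/validation block dataset from synthetic organ images
#'
#' Emulates the reference study conditions: `K` images (organs assigned
#' round-robin) at the 10x capture geometry, split into training and
#' validation *at the image level* before tiling (`floor(split * K)` train
#' images, remainder validation), then tiled into 100x100 blocks — 20 images
#' of 2048x1536 px yield 6000 blocks. Per-image layouts vary lumen center
#' and radii within safe bounds, deterministically from `seed`.
#'
#' @param K Number of images (default 20).
#' @param split Training fraction at image level (default 0.7).
#' @param seed Integer seed; the whole dataset is reproducible from
#'   `(K, split, seed)`.
#' @param width,height,block_size Image geometry (defaults 2048, 1536, 100).
#' @param corruption_rate Texture corruption rate passed to every layout.
#' @return List of class `block_dataset` with `train` and `validation`
#'   (each: `descriptors` `n x 292`, `labels`, `image` index vector),
#'   `manifest` (data.frame: image, organ, split, seed) and `fixtures`
#'   (the per-image `organ_fixture`s, without pixel images).
#' @export
generate_dataset <- function(K = 20, split = 0.7, seed = 1L,
                             width = 2048, height = 1536, block_size = 100,
                             corruption_rate = 0) {
  if (K < 2) stopf("need at least 2 images")
  if (split <= 0 || split >= 1) stopf("split fraction must lie in (0, 1)")
  organs <- kb_vocabulary()$organs
  n_train <- floor(split * K)
  m <- height %/% block_size
  n <- width %/% block_size

  sets <- list(train = list(), validation = list())
  manifest <- data.frame(image = integer(), organ = character(), split = character(),
                         seed = integer(), stringsAsFactors = FALSE)
  fixtures <- vector("list", K)
  for (img in seq_len(K)) {
    img_seed <- child_seed(seed, img)
    # geometry scales with the grid so lumen + annulus always fit; at the
    # reference 15 x 20 grid: lumen radius 2.4-3.2, annulus 2.2-3.0 blocks
    geom <- with_seed(child_seed(img_seed, 5L), list(
      center = c(
        runif(1, (m + 1) / 2 - 0.5, (m + 1) / 2 + 0.5),
        runif(1, n / 2 - n / 10, n / 2 + n / 10)
      ),
      lumen_radius = runif(1, 0.16 * m, 0.213 * m),
      annulus_width = runif(1, 0.147 * m, 0.2 * m)
    ))
    layout <- organ_layout(
      organ = organs[(img - 1) %% length(organs) + 1],
      width = width, height = height, block_size = block_size,
      center = geom$center, lumen_radius = geom$lumen_radius,
      annulus_width = geom$annulus_width,
      corruption_rate = corruption_rate, seed = img_seed
    )
    part <- fixture_descriptors(layout)
    fixtures[[img]] <- part$fixture
    side <- if (img <= n_train) "train" else "validation"
    sets[[side]][[length(sets[[side]]) + 1]] <- list(
      descriptors = part$descriptors, labels = part$labels,
      image = rep(img, length(part$labels))
    )
    manifest <- rbind(manifest, data.frame(
      image = img, organ = layout$organ, split = side, seed = img_seed,
      stringsAsFactors = FALSE
    ))
  }
  bind_side <- function(side) {
    list(
      descriptors = do.call(rbind, lapply(sets[[side]], `[[`, "descriptors")),
      labels = unlist(lapply(sets[[side]], `[[`, "labels")),
      image = unlist(lapply(sets[[side]], `[[`, "image"))
    )
  }
  structure(
    list(train = bind_side("train"), validation = bind_side("validation"),
         manifest = manifest, fixtures = fixtures),
    class = "block_dataset"
  )
}

#' Inject classifier-style label corruption into a label matrix
#'
#' Simulates the classifier's characteristic error mode at the label level:
#' a fraction of the loose-connective (`LC`) cells is relabeled with a
#' foreign organ's discriminant class. Used to exercise the refinement stage
#' without running the classifier.
#'
#' @param matrix A [label_matrix()] (typically a fixture truth matrix).
#' @param rate Fraction of `LC` cells to corrupt, in \[0, 1\].
#' @param foreign_label Discriminant label to inject.
#' @param seed Integer seed.
#' @return List: `matrix` (corrupted [label_matrix()]), `cells` (linear
#'   indices of the corrupted cells).
#' @export
corrupt_labels <- function(matrix, rate, foreign_label, seed = 1L) {
  check_labels(foreign_label, allowed = discriminant_labels())
  if (rate < 0 || rate > 1) stopf("rate must lie in [0, 1]")
  lc <- which(as.character(matrix) == "LC")
  k <- round(rate * length(lc))
  if (k == 0) return(list(matrix = matrix, cells = integer()))
  hit <- with_seed(seed, sample(lc, k))
  list(matrix = set_cells(matrix, hit, foreign_label, "classifier"), cells = hit)
}

#' Generate a threshold-calibration problem from known lumen geometry
#'
#' Builds `n_matrices` classifier-style label matrices containing straight
#' light-region runs of known lengths embedded in muscular-artery tissue on
#' a loose-connective background, plus the ground truths a perfect annotator
#' using lumen-size threshold `true_t` would produce (runs of at least
#' `true_t` blocks become epithelium-lined lumina; shorter runs stay plain
#' light regions). Run lengths always include `true_t - 1` and `true_t`, so
#' the generating threshold is exactly recoverable; remaining lengths are
#' drawn at random. The returned problem sweeps `candidates` through the
#' full refinement pass.
#'
#' @param seed Integer seed.
#' @param n_matrices Number of matrix/truth pairs (default 2).
#' @param true_t Generating lumen-size threshold (default 10).
#' @param candidates Candidate thresholds for the sweep (default `2:20`).
#' @param kb Knowledge base used by the refinement pass.
#' @return A [calibration_problem()].
#' @export
generate_calibration_problem <- function(seed = 1L, n_matrices = 2, true_t = 10,
                                         candidates = 2:20, kb = default_kb()) {
  m <- 15
  n <- 20
  rows_avail <- c(2, 5, 8, 11, 14)
  build_one <- function(lengths) {
    raw <- matrix("LC", m, n)
    truth <- matrix("LC", m, n)
    for (q in seq_along(lengths)) {
      len <- lengths[q]
      r <- rows_avail[q]
      start <- sample(2:(n - len), 1)
      cc <- start:(start + len - 1)
      box_cc <- (start - 1):(start + len)
      for (rr in c(r - 1, r, r + 1)) {
        raw[rr, box_cc] <- "MA"
        truth[rr, box_cc] <- "MA"
      }
      raw[r, cc] <- "LR"
      truth[r, cc] <- if (len >= true_t) "EP" else "LR"
    }
    list(raw = label_matrix(raw), truth = label_matrix(truth, "truth"))
  }
  pairs <- with_seed(child_seed(seed, 23L), {
    lapply(seq_len(n_matrices), function(i) {
      n_runs <- sample(3:5, 1)
      lengths <- c(true_t - 1, true_t,
                   sample(4:(true_t + 3), n_runs - 2, replace = TRUE))
      build_one(sample(lengths))
    })
  })
  raws <- lapply(pairs, `[[`, "raw")
  truths <- lapply(pairs, `[[`, "truth")
  calibration_problem(
    truths = truths,
    outputs = function(t) lapply(raws, refine, kb = kb, min_size = t),
    candidates = candidates
  )
}
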