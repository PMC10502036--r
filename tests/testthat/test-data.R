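test_that("sample generation is deterministic in (seed, index) and distinct across indices", {
  spec <- synth_spec(seed = 5)
  a <- generate_sample(spec, 3L)
  b <- generate_sample(spec, 3L)
  expect_identical(a, b)
  c3 <- generate_sample(spec, 4L)
  expect_false(identical(a$image, c3$image))
  expect_true(all(a$mask %in% c(0, 1)))
  expect_equal(dim(a$image), c(64, 64, 3))
  expect_true(all(a$image >= 0 & a$image <= 1))
})

test_that("zero boundary softness produces a step edge at the mask boundary", {
  spec <- synth_spec(seed = 9, boundary_sigma = 0, noise_amplitude = 0,
                     glare_prob = 0, n_polyps = c(1, 1))
  s <- generate_sample(spec, 0L)
  img <- apply(s$image, c(1, 2), mean)
  gx <- abs(img[-1, ] - img[-nrow(img), ])
  # boundary pixels: mask changes between vertically adjacent pixels
  bnd <- s$mask[-1, ] != s$mask[-nrow(s$mask), ]
  expect_gt(max(gx[bnd]), max(gx[!bnd]))
})

test_that("blob areas follow the requested radius across seeds", {
  areas <- vapply(1:100, function(i) {
    spec <- synth_spec(seed = i, n_polyps = c(1, 1), radius = c(0.2, 0.2))
    sum(generate_sample(spec, 0L)$mask)
  }, numeric(1))
  expected <- pi * (0.2 * 64)^2
  expect_true(all(areas >= 0.7 * expected & areas <= 1.3 * expected))
})

test_that("each blob support is connected (star-convex construction)", {
  # flood fill from one foreground pixel must reach the whole single blob
  for (seed in 1:5) {
    spec <- synth_spec(seed = seed, n_polyps = c(1, 1))
    m <- generate_sample(spec, 0L)$mask
    start <- which(m == 1)[1]
    h <- nrow(m)
    frontier <- start
    seen <- logical(length(m))
    seen[start] <- TRUE
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (p in frontier) {
        i <- (p - 1) %% h + 1; j <- (p - 1) %/% h + 1
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          ii <- i + d[1]; jj <- j + d[2]
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= ncol(m)) {
            q <- (jj - 1) * h + ii
            if (m[q] == 1 && !seen[q]) { seen[q] <- TRUE; nxt <- c(nxt, q) }
          }
        }
      }
      frontier <- nxt
    }
    expect_equal(sum(seen), sum(m))
  }
})

test_that("dataset writing and loading round-trips masks exactly", {
  root <- withr::local_tempdir()
  ds <- generate_dataset(synth_spec(seed = 2, size = 32), 4)
  expect_length(ds$samples, 4)
  write_dataset(ds, root)
  expect_true(file.exists(file.path(root, "manifest.json")))
  back <- load_folder(root)
  expect_length(back$samples, 4)
  expect_length(back$exceptions, 0)
  for (i in 1:4) {
    expect_equal(back$samples[[i]]$mask, ds$samples[[i]]$mask)
    expect_lt(max(abs(back$samples[[i]]$image - ds$samples[[i]]$image)),
              1 / 255)  # 8-bit quantization only
  }
  # regeneration from the manifest is byte-identical
  man <- jsonlite::read_json(file.path(root, "manifest.json"),
                             simplifyVector = TRUE)
  spec2 <- do.call(synth_spec, man$spec[names(man$spec) != "size"] |>
                     (\(x) c(list(size = man$spec$size), x))())
  ds2 <- generate_dataset(spec2, man$n)
  expect_identical(ds2$samples[[2]]$image, ds$samples[[2]]$image)
})

test_that("empty and mismatched folders are handled", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "images")); dir.create(file.path(root, "masks"))
  expect_length(load_folder(root)$samples, 0)
  png::writePNG(matrix(0.5, 8, 8), file.path(root, "images", "orphan.png"))
  got <- load_folder(root)
  expect_length(got$samples, 0)
  expect_equal(got$exceptions, "orphan")
  expect_error(load_folder(file.path(root, "nope")), "images/")
})

test_that("RGB-stored grayscale masks collapse to one channel", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "images")); dir.create(file.path(root, "masks"))
  m <- matrix(c(0, 1), 8, 8)
  png::writePNG(array(runif(8 * 8 * 3), dim = c(8, 8, 3)),
                file.path(root, "images", "a.png"))
  png::writePNG(array(rep(m, 3), dim = c(8, 8, 3)),
                file.path(root, "masks", "a.png"))
  got <- load_folder(root)
  expect_equal(dim(got$samples[[1]]$mask), c(8, 8))
  expect_equal(got$samples[[1]]$mask, m)
})

test_that("augmentation applies the same transform to image and mask", {
  # encode coordinates in the image; the mask marks one pixel
  img <- array(0, dim = c(6, 6, 3))
  img[, , 1] <- matrix(rep(1:6, times = 6) / 6, 6, 6)        # row coord
  img[, , 2] <- matrix(rep(1:6, each = 6) / 6, 6, 6)         # col coord
  mask <- matrix(0, 6, 6); mask[2, 5] <- 1
  s <- list(image = img, mask = mask)
  for (ops in list(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                   c(FALSE, FALSE, TRUE), c(TRUE, TRUE, TRUE))) {
    out <- augment(s, force = ops)
    at <- which(out$mask == 1, arr.ind = TRUE)
    expect_equal(out$image[at[1], at[2], 1], img[2, 5, 1])
    expect_equal(out$image[at[1], at[2], 2], img[2, 5, 2])
  }
  # identity and involution
  expect_identical(augment(s, force = c(FALSE, FALSE, FALSE)), s)
  twice <- augment(augment(s, force = c(TRUE, FALSE, FALSE)),
                   force = c(TRUE, FALSE, FALSE))
  expect_identical(twice, s)
})

test_that("augmentation op frequencies are near one half", {
  spec <- synth_spec(seed = 3, size = 16)
  s <- generate_sample(spec, 0L)
  set.seed(271828)
  n <- 10000
  counts <- c(h = 0, v = 0, r = 0)
  for (i in seq_len(n)) {
    draws <- stats::runif(3) < 0.5
    counts <- counts + draws
  }
  expect_true(all(counts / n >= 0.48 & counts / n <= 0.52))
  # and augment() consumes exactly those draws
  set.seed(271828)
  a1 <- augment(s)
  set.seed(271828)
  d <- stats::runif(3) < 0.5
  a2 <- augment(s, force = d)
  expect_identical(a1, a2)
})

test_that("color exchange transfers per-channel statistics", {
  spec <- synth_spec(seed = 4, size = 32)
  a <- generate_sample(spec, 0L)
  b <- generate_sample(spec, 1L)
  self <- color_exchange(a, a)
  expect_equal(self$image, a$image, tolerance = 1e-12)
  moved <- color_exchange(a, b)
  for (ch in 1:3) {
    expect_equal(mean(moved$image[, , ch]), mean(b$image[, , ch]),
                 tolerance = 1e-12)
    expect_equal(sd(moved$image[, , ch]), sd(b$image[, , ch]),
                 tolerance = 1e-12)
  }
  expect_identical(moved$mask, a$mask)
  # a constant recipient channel passes through unchanged
  flat <- a; flat$image[, , 2] <- 0.5
  out <- color_exchange(flat, b)
  expect_equal(out$image[, , 2], flat$image[, , 2])
})

test_that("multi-scale resize draws sizes with the prescribed probabilities", {
  set.seed(314159)
  n <- 10000
  draws <- vapply(seq_len(n), function(i) {
    base::sample(c(256L, 288L, 320L, 352L), 1L, prob = c(0.1, 0.2, 0.3, 0.4))
  }, integer(1))
  freq <- table(factor(draws, levels = c(256, 288, 320, 352))) / n
  expect_true(all(abs(as.numeric(freq) - c(0.1, 0.2, 0.3, 0.4)) <= 0.02))
  # the op itself: forcing 352 is resize-only; masks stay binary
  s <- generate_sample(synth_spec(seed = 6, size = 48), 0L)
  r352 <- multiscale_resize(s, force = 352L)
  expect_equal(dim(r352$image)[1:2], c(352L, 352L))
  expect_true(all(r352$mask %in% c(0, 1)))
  r256 <- multiscale_resize(s, force = 256L)
  expect_equal(dim(r256$mask), c(256L, 256L))
  expect_true(all(r256$mask %in% c(0, 1)))
})
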