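#' Specification of the synthetic endoscopy-style sample generator
#'
#' The generator emulates the challenges polyp segmentation networks face:
#' polyp-like blobs (Fourier-perturbed ellipses) whose color blends into a
#' textured, speckled mucosal background over a soft gradient band
#' (ambiguous boundaries), plus optional specular glare disks. Masks are
#' the exact pre-blend blob supports.
#'
#' @param size image side in pixels (square images).
#' @param n_polyps integer range `c(min, max)` of blob count per image.
#' @param radius range of blob radius as a fraction of the image side,
#'   within `(0, 0.5)`.
#' @param boundary_sigma width (pixels) of the mask-to-appearance intensity
#'   gradient; 0 gives a hard step edge at the mask boundary.
#' @param texture_scale spatial scale of the background mucosa texture, in
#'   cells across the image.
#' @param noise_amplitude amplitude of multiplicative speckle noise.
#' @param glare_prob probability that an image receives specular glare.
#' @param glare_intensity peak added intensity of a glare disk.
#' @param seed base seed; together with the sample index it fully
#'   determines each sample.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(size = 64L, n_polyps = c(1L, 2L),
                       radius = c(0.12, 0.25), boundary_sigma = 2.5,
                       texture_scale = 6, noise_amplitude = 0.03,
                       glare_prob = 0.3, glare_intensity = 0.5,
                       seed = 1L) {
  stopifnot(radius[1] > 0, radius[2] < 0.5, boundary_sigma >= 0,
            glare_prob >= 0, glare_prob <= 1, size >= 16)
  structure(list(size = as.integer(size),
                 n_polyps = as.integer(rep(n_polyps, length.out = 2L)),
                 radius = as.numeric(rep(radius, length.out = 2L)),
                 boundary_sigma = boundary_sigma,
                 texture_scale = texture_scale,
                 noise_amplitude = noise_amplitude,
                 glare_prob = glare_prob, glare_intensity = glare_intensity,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# smooth value noise: coarse uniform grid, bilinearly upsampled
value_noise <- function(size, cells) {
  g <- matrix(stats::runif(cells * cells), cells, cells)
  resize_image(array(g, dim = c(cells, cells, 1L)), size, size)[, , 1]
}

# signed "distance" field of a Fourier-perturbed ellipse: negative inside.
# Star-convex by construction, so each blob's support is connected.
blob_field <- function(size, cx, cy, r, aspect, rot, amp, phase) {
  xs <- matrix(rep(seq_len(size), each = size), size, size)  # cols
  ys <- matrix(rep(seq_len(size), times = size), size, size) # rows
  dx <- (xs - cx); dy <- (ys - cy)
  ca <- cos(rot); sa <- sin(rot)
  u <- (ca * dx + sa * dy) / aspect
  v <- (-sa * dx + ca * dy) * aspect
  dist <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  rad <- r * (1 + amp[1] * cos(2 * theta + phase[1]) +
                amp[2] * cos(3 * theta + phase[2]) +
                amp[3] * cos(5 * theta + phase[3]))
  dist - rad
}

#' Generate one synthetic image/mask pair
#'
#' Deterministic in `(spec$seed, index)`.
#'
#' @param spec a [synth_spec()].
#' @param index sample index (non-negative integer).
#' @return a `seg_sample`: list with `image` (`size x size x 3` in `[0,1]`),
#'   `mask` (`size x size` binary matrix), and `meta` (seed, index,
#'   generator parameters).
#' @export
generate_sample <- function(spec, index = 0L) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(mix_seed(spec$seed, index))
  s <- spec$size
  # mucosal background: pinkish base + low-frequency texture + vignette
  base <- c(0.72, 0.40, 0.36) + stats::runif(3, -0.06, 0.06)
  tex <- value_noise(s, max(2L, as.integer(spec$texture_scale)))
  tex <- (tex - mean(tex))
  img <- array(0, dim = c(s, s, 3L))
  for (ch in 1:3) img[, , ch] <- base[ch] + 0.35 * tex * (0.6 + 0.4 * ch / 3)
  # polyps
  n_blob <- sample(spec$n_polyps[1]:spec$n_polyps[2], 1L)
  mask <- matrix(0, s, s)
  for (b in seq_len(n_blob)) {
    r <- stats::runif(1, spec$radius[1], spec$radius[2]) * s
    margin <- min(r * 1.3 + 2, s / 2 - 1)
    cx <- stats::runif(1, margin, s - margin)
    cy <- stats::runif(1, margin, s - margin)
    aspect <- exp(stats::runif(1, -0.1, 0.1))
    rot <- stats::runif(1, 0, pi)
    amp <- stats::runif(3, 0, c(0.08, 0.05, 0.03))
    phase <- stats::runif(3, 0, 2 * pi)
    f <- blob_field(s, cx, cy, r, aspect, rot, amp, phase)
    support <- f < 0
    mask[support] <- 1
    # polyp appearance: lighter, redder, gently shaded toward the rim
    alpha <- if (spec$boundary_sigma > 0) {
      clamp(0.5 - f / spec$boundary_sigma, 0, 1)
    } else {
      support * 1
    }
    shade <- clamp(1 - pmax(-f, 0) / (2.5 * r), 0.55, 1)
    pcol <- c(0.88, 0.52, 0.44) + stats::runif(3, -0.05, 0.05)
    for (ch in 1:3) {
      img[, , ch] <- (1 - alpha) * img[, , ch] + alpha * pcol[ch] * shade
    }
  }
  # speckle noise (multiplicative)
  if (spec$noise_amplitude > 0) {
    sp <- 1 + spec$noise_amplitude * matrix(stats::rnorm(s * s), s, s)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * sp
  }
  # specular glare: small saturated disks with soft falloff
  if (stats::runif(1) < spec$glare_prob) {
    for (gdisk in seq_len(sample(1:3, 1L))) {
      gr <- stats::runif(1, 0.02, 0.05) * s
      gx <- stats::runif(1, gr, s - gr); gy <- stats::runif(1, gr, s - gr)
      xs <- matrix(rep(seq_len(s), each = s), s, s)
      ys <- matrix(rep(seq_len(s), times = s), s, s)
      d2 <- ((xs - gx)^2 + (ys - gy)^2) / gr^2
      glow <- spec$glare_intensity * exp(-d2)
      for (ch in 1:3) img[, , ch] <- img[, , ch] + glow
    }
  }
  img <- clamp(img, 0, 1)
  structure(list(image = img, mask = mask,
                 meta = list(seed = spec$seed, index = as.integer(index),
                             spec = unclass(spec))),
            class = "seg_sample")
}

#' Generate a dataset of synthetic samples
#'
#' @param spec a [synth_spec()].
#' @param n number of samples.
#' @return a list with `samples` (list of `seg_sample`) and `manifest`
#'   (spec, n, and the train/validation split by index parity).
#' @export
generate_dataset <- function(spec, n) {
  samples <- lapply(seq_len(n) - 1L, function(i) generate_sample(spec, i))
  manifest <- list(spec = unclass(spec), n = as.integer(n),
                   split = list(train = which(seq_len(n) %% 2L == 1L) - 1L,
                                val = which(seq_len(n) %% 2L == 0L) - 1L))
  list(samples = samples, manifest = manifest)
}

#' Write a dataset to a Kvasir-SEG-style folder
#'
#' Layout: `root/images/*.png`, `root/masks/*.png` (single-channel masks),
#' plus `root/manifest.json` recording the generator spec, from which the
#' dataset can be regenerated byte-identically.
#'
#' @param dataset result of [generate_dataset()].
#' @param root output directory.
#' @return `root`, invisibly.
#' @export
write_dataset <- function(dataset, root) {
  dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    nm <- sprintf("sample_%04d.png", s$meta$index %||% (i - 1L))
    png::writePNG(s$image, file.path(root, "images", nm))
    png::writePNG(s$mask, file.path(root, "masks", nm))
  }
  jsonlite::write_json(dataset$manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(root)
}
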