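read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    # RGB(A) stored grayscale collapses to one channel
    x <- apply(x[, , 1:min(3L, dim(x)[3]), drop = FALSE], c(1L, 2L), mean)
  }
  x
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package", call. = FALSE)
    }
    x <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(x)) == 3L) x <- aperm(x, c(2L, 1L, 3L)) else x <- t(x)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (length(dim(x)) == 2L) {
    x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  } else if (dim(x)[3] == 4L) {
    x <- x[, , 1:3, drop = FALSE]
  }
  x
}

#' Load an images/masks dataset folder
#'
#' Expects the common benchmark layout `root/images/*` and `root/masks/*`
#' with matching basenames (PNG or JPEG images, PNG masks). Images are
#' scaled to `[0,1]`; masks are binarized at gray level 127/255. Files
#' without a counterpart are skipped and reported.
#'
#' @param root dataset directory.
#' @return a list with `samples` (list of `seg_sample`) and `exceptions`
#'   (character vector of unmatched basenames).
#' @export
load_folder <- function(root) {
  img_dir <- file.path(root, "images")
  mask_dir <- file.path(root, "masks")
  if (!dir.exists(img_dir) || !dir.exists(mask_dir)) {
    stop("expected ", root, " to contain images/ and masks/", call. = FALSE)
  }
  imgs <- list.files(img_dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE)
  masks <- list.files(mask_dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE)
  key <- function(f) tools::file_path_sans_ext(f)
  shared <- intersect(key(imgs), key(masks))
  exceptions <- c(setdiff(key(imgs), shared), setdiff(key(masks), shared))
  samples <- lapply(sort(shared), function(k) {
    img_f <- imgs[key(imgs) == k][1]
    mask_f <- masks[key(masks) == k][1]
    image <- read_image_file(file.path(img_dir, img_f))
    m <- read_gray_png(file.path(mask_dir, mask_f))
    mask <- (m > 127 / 255) * 1
    structure(list(image = image, mask = mask,
                   meta = list(source = img_f)),
              class = "seg_sample")
  })
  list(samples = samples, exceptions = exceptions)
}

# min-max normalize an attention/feature map to [0,1] for PNG export
normalize01 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(x * 0)
  (x - rng[1]) / diff(rng)
}

write_attention_png <- function(map3, path) {
  # channel-averaged grayscale export of a (H,W,C) attention map
  m <- if (length(dim(map3)) == 3L) apply(map3, c(1L, 2L), mean) else map3
  png::writePNG(normalize01(m), path)
  invisible(path)
}
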