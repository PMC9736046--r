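# Fundus preprocessing: graying -> CLAHE -> gamma correction, plus the
# training-time augmentations (right-angle rotation, flips, random erase).

#' Preprocessing configuration
#'
#' @param gray_mode `"green"` (default; the green channel carries the highest
#'   vessel contrast in fundus photography) or `"luminance"`
#'   (0.299R + 0.587G + 0.114B).
#' @param clahe_clip CLAHE clip limit (contrast amplification cap).
#' @param clahe_tile CLAHE grid side: the image is equalized over a
#'   `clahe_tile` x `clahe_tile` grid of tiles.
#' @param gamma gamma-correction exponent (> 0); values above 1 darken
#'   mid-tones, which deepens vessels against the background.
#' @param rotate,erase,flip_ud,flip_lr augmentation switches.
#' @param erase_frac length-2 range of the erased-rectangle area as a
#'   fraction of the patch area.
#' @return a list of class `vs_preprocess_config`.
#' @export
preprocess_config <- function(gray_mode = c("green", "luminance"),
                              clahe_clip = 2.0, clahe_tile = 8L, gamma = 1.2,
                              rotate = TRUE, erase = TRUE,
                              flip_ud = TRUE, flip_lr = TRUE,
                              erase_frac = c(0.02, 0.08)) {
  gray_mode <- match.arg(gray_mode)
  stopifnot(gamma > 0, clahe_tile >= 1, clahe_clip > 0)
  structure(list(gray_mode = gray_mode, clahe_clip = clahe_clip,
                 clahe_tile = as.integer(clahe_tile), gamma = gamma,
                 rotate = rotate, erase = erase, flip_ud = flip_ud,
                 flip_lr = flip_lr, erase_frac = erase_frac),
            class = "vs_preprocess_config")
}

#' Convert an RGB fundus image to a single channel
#'
#' @param image (H,W,3) array on the 0..255 or [0,1] scale.
#' @param mode `"green"` or `"luminance"`.
#' @return (H,W) matrix in [0,1].
#' @export
to_gray <- function(image, mode = c("green", "luminance")) {
  mode <- match.arg(mode)
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) {
    stop("to_gray expects a 3-channel (H,W,3) image, got dims ",
         paste(d, collapse = "x"))
  }
  if (max(image) > 1) image <- image / 255
  g <- switch(mode,
    green = image[, , 2],
    luminance = 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  )
  pmin(pmax(g, 0), 1)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Thin wrapper over EBImage's CLAHE with the package's (H,W) orientation.
#' A constant image is returned unchanged (its histogram is degenerate and
#' there is no contrast to equalize).
#'
#' @param image (H,W) matrix in [0,1].
#' @param clip_limit contrast clip limit.
#' @param tile grid side (number of tiles per image side).
#' @return (H,W) matrix in [0,1].
#' @export
clahe_equalize <- function(image, clip_limit = 2.0, tile = 8L) {
  d <- dim(image)
  if (tile > min(d)) stop("CLAHE tile grid (", tile, ") exceeds image size ",
                          paste(d, collapse = "x"))
  if (diff(range(image)) == 0) return(image)
  out <- EBImage::clahe(EBImage::as.Image(t(image)), nx = tile, ny = tile,
                        limit = clip_limit)
  res <- t(EBImage::imageData(out))
  pmin(pmax(res, 0), 1)
}

#' Gamma correction
#' @param image (H,W) values in [0,1].
#' @param gamma exponent, > 0.
#' @return `image ^ gamma`.
#' @export
gamma_correct <- function(image, gamma = 1.2) {
  if (gamma <= 0) stop("gamma must be positive")
  image^gamma
}

#' Full preprocessing pipeline for one record
#'
#' graying -> CLAHE -> gamma correction; returns the record with `image`
#' replaced by the single-channel (H,W) array in [0,1].
#'
#' @param record a `vs_record` (see [load_record()]).
#' @param config a [preprocess_config()].
#' @return the record with preprocessed `$image`.
#' @export
preprocess_record <- function(record, config = preprocess_config()) {
  g <- to_gray(record$image, config$gray_mode)
  g <- clahe_equalize(g, config$clahe_clip, config$clahe_tile)
  g <- gamma_correct(g, config$gamma)
  record$image <- g
  record
}

rot90k <- function(m, k) {
  k <- ((k %% 4) + 4) %% 4
  for (i in seq_len(k)) {
    m <- t(m)
    m <- m[nrow(m):1, , drop = FALSE]   # 90 degrees counter-clockwise
  }
  m
}

#' Apply training-time augmentations
#'
#' The same geometric transform (right-angle rotation and/or flips) is
#' applied to the image, vessel mask and FOV mask; random erase blanks a
#' rectangle of the image only (set to the image mean), never the masks.
#' Deterministic for a fixed `seed`.
#'
#' @param image (H,W) preprocessed image.
#' @param vessel_gt,fov binary masks of the same shape (either may be NULL).
#' @param config a [preprocess_config()].
#' @param seed integer RNG seed for this draw.
#' @return list(image, vessel_gt, fov, transform) where `transform` records
#'   the sampled operations.
#' @export
augment <- function(image, vessel_gt = NULL, fov = NULL,
                    config = preprocess_config(), seed = 1L) {
  stopifnot(is.null(vessel_gt) || all(dim(vessel_gt) == dim(image)),
            is.null(fov) || all(dim(fov) == dim(image)))
  with_preserved_seed(seed, {
    k <- if (config$rotate) sample.int(4L, 1L) - 1L else 0L
    do_ud <- config$flip_ud && stats::runif(1) < 0.5
    do_lr <- config$flip_lr && stats::runif(1) < 0.5
    tf <- function(m) {
      if (is.null(m)) return(NULL)
      if (k > 0) m <- rot90k(m, k)
      if (do_ud) m <- m[nrow(m):1, , drop = FALSE]
      if (do_lr) m <- m[, ncol(m):1, drop = FALSE]
      m
    }
    image <- tf(image); vessel_gt <- tf(vessel_gt); fov <- tf(fov)
    er <- NULL
    if (config$erase && stats::runif(1) < 0.5) {
      H <- nrow(image); W <- ncol(image)
      area <- stats::runif(1, config$erase_frac[1], config$erase_frac[2]) * H * W
      asp <- stats::runif(1, 0.5, 2)
      eh <- max(1L, min(H, as.integer(round(sqrt(area * asp)))))
      ew <- max(1L, min(W, as.integer(round(sqrt(area / asp)))))
      r0 <- sample.int(H - eh + 1L, 1L)
      c0 <- sample.int(W - ew + 1L, 1L)
      image[r0:(r0 + eh - 1L), c0:(c0 + ew - 1L)] <- mean(image)
      er <- c(r0, c0, eh, ew)
    }
    list(image = image, vessel_gt = vessel_gt, fov = fov,
         transform = list(rot = k, flip_ud = do_ud, flip_lr = do_lr, erase = er))
  })
}

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream (the previous .Random.seed is restored afterwards).
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
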