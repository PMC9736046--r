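# Collaborative patch geometry: one small s x s target patch plus five large
# l x l neighbourhood patches that all contain the target region, realized
# everywhere in the image through reflective padding.  Also the training-grid
# sampler and tiled inference with mean stitching.
#
# All origins/offsets are 0-based (row, col); ranges are half-open.

#' Default placements of the target region inside the five large patches
#'
#' Center plus the four corners, so whichever side of the target carries the
#' relevant neighbourhood, at least one large patch covers it:
#' `{((l-s)/2,(l-s)/2), (0,0), (0,l-s), (l-s,0), (l-s,l-s)}` (integer
#' division).
#'
#' @param s small-patch side (pixels).
#' @param l large-patch side, l > s.
#' @return 5 x 2 integer matrix of (row, col) offsets of the target region's
#'   top-left corner inside each large patch.
#' @export
default_placements <- function(s, l) {
  if (l <= s) stop("large-patch side l must exceed small-patch side s")
  if (l - s < 2) {
    stop("l - s must be at least 2 so the five default placements are distinct")
  }
  d <- l - s
  m <- rbind(c(d %/% 2L, d %/% 2L), c(0L, 0L), c(0L, d), c(d, 0L), c(d, d))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(c("center", "nw", "ne", "sw", "se"), c("row", "col"))
  m
}

#' Collaborative patch geometry
#'
#' @param s small-patch side; the full-scale default is 72.
#' @param l large-patch side (default `2 * s`).
#' @param placements 5 x 2 matrix of offsets (default [default_placements()]).
#' @param context_scale integer downsampling factor applied to the large
#'   patches before the context networks (see the network module).
#' @return list of class `vs_patch_geometry`.
#' @export
patch_geometry <- function(s = 72L, l = 2L * s, placements = NULL,
                           context_scale = 4L) {
  s <- as.integer(s); l <- as.integer(l)
  if (l <= s) stop("large-patch side l must exceed small-patch side s")
  if (is.null(placements)) placements <- default_placements(s, l)
  placements <- matrix(as.integer(placements), ncol = 2,
                       dimnames = dimnames(placements))
  if (nrow(placements) != 5) stop("exactly 5 placements are required")
  if (any(placements < 0L) || any(placements > l - s)) {
    stop("placements must lie in [0, l - s] in both coordinates")
  }
  if (anyDuplicated(split(placements, row(placements)))) {
    stop("the five placements must be pairwise distinct")
  }
  structure(list(s = s, l = l, placements = placements,
                 context_scale = as.integer(context_scale)),
            class = "vs_patch_geometry")
}

# Reflective padding of a (H,W) matrix by `p` pixels on all sides.
reflect_pad <- function(m, p) {
  H <- nrow(m); W <- ncol(m)
  if (p >= H || p >= W) stop("reflective pad width exceeds image size")
  ri <- c((p + 1L):2L, 1L:H, (H - 1L):(H - p))
  ci <- c((p + 1L):2L, 1L:W, (W - 1L):(W - p))
  m[ri, ci, drop = FALSE]
}

#' Extract one collaborative patch set
#'
#' Returns the small target patch and the five large patches.  Near image
#' borders the large patches are completed by reflective padding of width
#' `l - s`, so all five placements always exist and the small patch equals
#' the sub-array of every large patch at its recorded offset, bitwise.
#'
#' @param image (H,W) matrix (preprocessed image or mask).
#' @param target_origin length-2 integer, 0-based (row, col) of the target
#'   region's top-left corner; must satisfy `origin + s <= dim(image)`.
#' @param geometry a [patch_geometry()].
#' @return list of class `vs_patch_set`: `small` (s x s), `larges` (list of
#'   five l x l matrices), `target_origin`, `offsets` (the placements).
#' @export
extract_collaborative <- function(image, target_origin, geometry) {
  s <- geometry$s; l <- geometry$l
  H <- nrow(image); W <- ncol(image)
  r0 <- as.integer(target_origin[1]); c0 <- as.integer(target_origin[2])
  if (r0 < 0 || c0 < 0 || r0 + s > H || c0 + s > W) {
    stop("target_origin (", r0, ",", c0, ") does not fit an ", s, "x", s,
         " window in a ", H, "x", W, " image")
  }
  p <- l - s
  padded <- reflect_pad(image, p)
  small <- image[(r0 + 1L):(r0 + s), (c0 + 1L):(c0 + s), drop = FALSE]
  larges <- vector("list", 5L)
  for (i in 1:5) {
    off <- geometry$placements[i, ]
    # large-patch origin in original coords, then into padded coords (+p)
    lr <- r0 - off[1] + p
    lc <- c0 - off[2] + p
    larges[[i]] <- padded[(lr + 1L):(lr + l), (lc + 1L):(lc + l), drop = FALSE]
  }
  structure(list(small = small, larges = larges,
                 target_origin = c(r0, c0), offsets = geometry$placements),
            class = "vs_patch_set")
}

#' Cut the target region out of a (possibly downsampled) feature map
#'
#' Pure indexing, no interpolation.  `offset` and `s` are given at the
#' feature map's scale: at a downsampling factor q, pass `offset / q` and
#' `s / q` (both must be integers; a fractional value means the patch
#' geometry is incompatible with the network stride and is rejected).
#'
#' @param feature (h, w) matrix or (h, w, C) array.
#' @param offset length-2, 0-based (row, col) at the feature scale.
#' @param s side of the cut at the feature scale.
#' @return the s x s (x C) contiguous sub-array.
#' @export
cut_region <- function(feature, offset, s) {
  if (any(abs(offset - round(offset)) > 1e-9) || abs(s - round(s)) > 1e-9) {
    stop("cut offset/side are not integers at this feature scale; ",
         "the patch geometry is incompatible with the network stride")
  }
  offset <- as.integer(round(offset)); s <- as.integer(round(s))
  d <- dim(feature)
  if (any(offset < 0L) || offset[1] + s > d[1] || offset[2] + s > d[2]) {
    stop("cut region exceeds the feature map")
  }
  rows <- (offset[1] + 1L):(offset[1] + s)
  cols <- (offset[2] + 1L):(offset[2] + s)
  if (length(d) == 2) feature[rows, cols, drop = FALSE]
  else feature[rows, cols, , drop = FALSE]
}

#' Sample target origins for training
#'
#' Union of a regular grid with the given stride (clamped so the final
#' row/column of windows touches the image border) and `n_random` uniform
#' draws inside the FOV bounding box.  Deterministic for a fixed seed.
#'
#' @param image_shape c(H, W).
#' @param s small-patch side.
#' @param stride grid step, >= 1.
#' @param n_random number of additional uniform origins.
#' @param fov optional binary mask; random origins are confined to its
#'   bounding box.
#' @param seed RNG seed for the random origins.
#' @return integer matrix (n x 2) of 0-based origins, duplicates removed.
#' @export
sample_training_grid <- function(image_shape, s, stride, n_random = 0L,
                                 fov = NULL, seed = 1L) {
  H <- image_shape[1]; W <- image_shape[2]
  if (s > H || s > W) stop("image is smaller than the patch size")
  if (stride < 1) stop("stride must be >= 1")
  gr <- unique(c(seq(0L, H - s, by = stride), H - s))
  gc <- unique(c(seq(0L, W - s, by = stride), W - s))
  grid <- cbind(rep(gr, times = length(gc)), rep(gc, each = length(gr)))
  if (n_random > 0) {
    if (!is.null(fov) && any(fov > 0)) {
      rr <- range(which(rowSums(fov) > 0)) - 1L
      cr <- range(which(colSums(fov) > 0)) - 1L
    } else {
      rr <- c(0L, H - 1L); cr <- c(0L, W - 1L)
    }
    lo_r <- rr[1]; hi_r <- min(rr[2], H - s)
    lo_c <- cr[1]; hi_c <- min(cr[2], W - s)
    rnd <- with_preserved_seed(seed, cbind(
      sample(lo_r:max(lo_r, hi_r), n_random, replace = TRUE),
      sample(lo_c:max(lo_c, hi_c), n_random, replace = TRUE)
    ))
    grid <- rbind(grid, rnd)
  }
  grid <- unique(grid)
  storage.mode(grid) <- "integer"
  colnames(grid) <- c("row", "col")
  grid
}

#' Stitch patch predictions into a whole-image probability map
#'
#' Per-pixel average over all covering patches.  Every pixel must be covered
#' at least once.
#'
#' @param predictions list of `list(origin = c(row, col) 0-based,
#'   patch = s x s matrix)`.
#' @param image_shape c(H, W).
#' @return (H, W) matrix in [0,1].
#' @export
stitch_patches <- function(predictions, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  acc <- matrix(0, H, W)
  cnt <- matrix(0L, H, W)
  for (p in predictions) {
    o <- p$origin
    s1 <- nrow(p$patch); s2 <- ncol(p$patch)
    rows <- (o[1] + 1L):(o[1] + s1)
    cols <- (o[2] + 1L):(o[2] + s2)
    if (o[1] < 0 || o[2] < 0 || o[1] + s1 > H || o[2] + s2 > W) {
      stop("patch at origin (", o[1], ",", o[2], ") exceeds the image")
    }
    acc[rows, cols] <- acc[rows, cols] + p$patch
    cnt[rows, cols] <- cnt[rows, cols] + 1L
  }
  if (any(cnt == 0L)) {
    miss <- which(cnt == 0L, arr.ind = TRUE)[1, ]
    stop("pixel (", miss[1] - 1L, ",", miss[2] - 1L,
         ") is covered by no patch")
  }
  acc / cnt
}
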