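# Synthetic fundus-like images with exactly known vessel ground truth.
#
# Branching vessel trees radiate from a disc (the optic-disc analogue) as
# width-tapering random-walk curves, rasterized inside a circular FOV.  The
# image is a bright noisy background with vessels darker by a configurable
# contrast, Gaussian-blurred to soften boundaries -- the dark-vessel-on-
# bright-background polarity of the fundus green channel, with the low
# vessel/background contrast and fine calibres that make real segmentation
# hard.  Everything (mask, edge map, FOV) is consistent by construction and
# fully determined by the seed.

#' Synthetic vessel image specification
#'
#' @param image_size c(H, W).
#' @param n_trees vessel trees (arcade analogues).
#' @param branch_depth bifurcation levels per tree.
#' @param root_width root calibre in pixels.
#' @param width_decay calibre ratio per bifurcation.
#' @param tortuosity angular jitter (radians, per step) of the random walk.
#' @param vessel_contrast intensity gap vessel vs background, in (0, 1].
#' @param background_noise_sigma Gaussian noise sd of the background.
#' @param fov_radius_frac FOV disc radius as a fraction of `min(H,W)/2`.
#' @param blur_sigma Gaussian blur applied to the rendered image.
#' @param seed RNG seed; the record is fully determined by it.
#' @return list of class `vs_vessel_spec`.
#' @export
vessel_spec <- function(image_size = c(192L, 192L), n_trees = 5L,
                        branch_depth = 3L, root_width = 3, width_decay = 0.72,
                        tortuosity = 0.18, vessel_contrast = 0.35,
                        background_noise_sigma = 0.03,
                        fov_radius_frac = 0.92, blur_sigma = 1, seed = 1L) {
  stopifnot(vessel_contrast > 0, vessel_contrast <= 1,
            fov_radius_frac > 0, fov_radius_frac <= 1, n_trees >= 1)
  structure(list(image_size = as.integer(image_size),
                 n_trees = as.integer(n_trees),
                 branch_depth = as.integer(branch_depth),
                 root_width = root_width, width_decay = width_decay,
                 tortuosity = tortuosity, vessel_contrast = vessel_contrast,
                 background_noise_sigma = background_noise_sigma,
                 fov_radius_frac = fov_radius_frac, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "vs_vessel_spec")
}

# Stamp a disc of the given radius at (r, c) into a logical mask, clipped to
# the image; returns the updated mask.
stamp_disc <- function(mask, r, c, radius) {
  H <- nrow(mask); W <- ncol(mask)
  ir <- max(1L, floor(r - radius)):min(H, ceiling(r + radius))
  ic <- max(1L, floor(c - radius)):min(W, ceiling(c + radius))
  if (!length(ir) || !length(ic)) return(mask)
  dd <- outer((ir - r)^2, (ic - c)^2, "+")
  mask[ir, ic] <- mask[ir, ic] | (dd <= radius^2)
  mask
}

#' Generate one synthetic fundus record
#'
#' @param spec a [vessel_spec()].
#' @return a `vs_record` (RGB `image` on 0..255, binary `vessel_gt`, `fov`)
#'   with an extra `edge_gt` element (morphological gradient of the vessel
#'   mask).
#' @export
generate_fundus <- function(spec = vessel_spec()) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  R <- spec$fov_radius_frac * min(H, W) / 2
  fov <- (outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, "+") <= R^2) * 1

  with_preserved_seed(spec$seed, {
    gt <- matrix(FALSE, H, W)
    # root positions on a small disc off-centre (optic-disc analogue)
    disc_r <- 0.25 * R
    disc_ang <- stats::runif(1, 0, 2 * pi)
    dy <- cy + 0.55 * R * sin(disc_ang)
    dx <- cx + 0.55 * R * cos(disc_ang)
    draw_branch <- function(r, c, ang, width, len, depth) {
      nst <- max(4L, as.integer(len))
      for (i in seq_len(nst)) {
        ang <- ang + stats::rnorm(1, sd = spec$tortuosity)
        r <- r + sin(ang); c <- c + cos(ang)
        if ((r - cy)^2 + (c - cx)^2 > (0.97 * R)^2) return(invisible(NULL))
        gt <<- stamp_disc(gt, r, c, max(0.5, width / 2))
      }
      if (depth < spec$branch_depth) {
        split <- stats::runif(1, 0.35, 0.7)
        draw_branch(r, c, ang + split, width * spec$width_decay, len * 0.85,
                    depth + 1L)
        draw_branch(r, c, ang - split, width * spec$width_decay, len * 0.85,
                    depth + 1L)
      }
      invisible(NULL)
    }
    for (t in seq_len(spec$n_trees)) {
      a0 <- stats::runif(1, 0, 2 * pi)
      r0 <- dy + disc_r * sin(a0)
      c0 <- dx + disc_r * cos(a0)
      # grow away from the root disc, roughly across the FOV
      ang <- atan2(cy - dy, cx - dx) + stats::rnorm(1, sd = 0.9)
      draw_branch(r0, c0, ang, spec$root_width, 0.35 * min(H, W), 1L)
    }
    gt <- gt & (fov > 0)
    if (!any(gt)) stop("specification produced zero vessel pixels")
    gt <- gt * 1

    img <- 0.55 + matrix(stats::rnorm(H * W, sd = spec$background_noise_sigma),
                         H, W)
    img[gt > 0] <- img[gt > 0] - spec$vessel_contrast
    img[fov == 0] <- 0.02
    if (spec$blur_sigma > 0) {
      img <- t(EBImage::imageData(EBImage::gblur(EBImage::as.Image(t(img)),
                                                 sigma = spec$blur_sigma)))
    }
    img <- pmin(pmax(img, 0), 1)
    rgb <- array(0, dim = c(H, W, 3))
    rgb[, , 1] <- pmin(1, img * 1.15)   # fundus photographs are red-dominant
    rgb[, , 2] <- img
    rgb[, , 3] <- img * 0.6
    structure(list(image = rgb * 255, vessel_gt = gt, fov = fov,
                   edge_gt = edge_target(gt),
                   id = paste0("synthetic_seed", spec$seed)),
              class = "vs_record")
  })
}

#' Write a miniature synthetic dataset in the DRIVE-like layout
#'
#' `out_dir/images/<id>.png`, `out_dir/gt/<id>.png`, `out_dir/fov/<id>.png`
#' plus `manifest.json` recording every spec, so the suite can be
#' regenerated bit-identically.  A subset of records uses fine calibres
#' (root width 1.5-2 px) for small-vessel sensitivity checks.
#'
#' @param out_dir destination directory (created).
#' @param n_train,n_test record counts.
#' @param image_size c(H, W).
#' @param seed base seed; record i uses `seed + i`.
#' @param fine_fraction fraction of records drawn with fine calibres.
#' @return invisible list with `layout_train`, `layout_test`, `manifest`.
#' @export
make_fixture_suite <- function(out_dir, n_train = 12L, n_test = 4L,
                               image_size = c(192L, 192L), seed = 1L,
                               fine_fraction = 0.25) {
  for (sub in c("images", "gt", "fov")) {
    dir.create(file.path(out_dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  n <- n_train + n_test
  specs <- lapply(seq_len(n), function(i) {
    fine <- (i %% ceiling(1 / fine_fraction)) == 0
    vessel_spec(image_size = image_size,
                root_width = if (fine) 1.8 else 3,
                n_trees = if (fine) 6L else 5L,
                seed = seed + i)
  })
  ids <- sprintf("%s%02d", rep(c("train", "test"), c(n_train, n_test)),
                 c(seq_len(n_train), seq_len(n_test)))
  for (i in seq_len(n)) {
    rec <- generate_fundus(specs[[i]])
    write_image_file(rec$image, file.path(out_dir, "images", paste0(ids[i], ".png")))
    write_mask(rec$vessel_gt, file.path(out_dir, "gt", paste0(ids[i], ".png")))
    write_mask(rec$fov, file.path(out_dir, "fov", paste0(ids[i], ".png")))
  }
  manifest <- list(image_size = image_size, seed = seed,
                   ids = ids, specs = lapply(specs, unclass))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  lt <- if (n_train > 0) discover_dataset(out_dir, "images/train*.png") else NULL
  te <- if (n_test > 0) discover_dataset(out_dir, "images/test*.png") else NULL
  invisible(list(layout_train = lt, layout_test = te, manifest = manifest))
}
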