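# Reading and writing fundus images, vessel annotations and FOV masks.
#
# Conventions used throughout the package:
#   * images are numeric arrays with dim (H, W) or (H, W, C), row-major
#     display order (row 1 = top);
#   * raw reads are on the 0..255 intensity scale; preprocessing maps to [0,1];
#   * masks hold only {0, 1};
#   * all pixel coordinates are 0-based (row, col) and patch ranges are
#     half-open, fixed once so the cut/stitch arithmetic is unambiguous.

#' Read a raster image file
#'
#' Supports PNG, TIFF and the PNM family (PGM/PPM, both ASCII and binary).
#' Returns intensities on the 0..255 scale regardless of source bit depth.
#'
#' @param path file path.
#' @return numeric array, dim (H, W) or (H, W, C).
#' @export
read_image_file <- function(path) {
  if (!file.exists(path)) stop("cannot read image, file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path) * 255,
    pgm = ,
    ppm = ,
    pnm = read_pnm(path),
    stop("unsupported image format '", ext, "' for: ", path)
  )
  # drop an alpha channel if present
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  if (length(dim(img)) == 3 && dim(img)[3] == 1) dim(img) <- dim(img)[1:2]
  img
}

#' Write a raster image file (PNG, TIFF or PGM/PPM)
#'
#' @param img numeric array on either the [0,1] or 0..255 scale.
#' @param path destination; format chosen by extension.
#' @export
write_image_file <- function(img, path) {
  mx <- max(img)
  v <- if (mx > 1) img / 255 else img
  v <- pmin(pmax(v, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(v, path),
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 16L),
    pgm = ,
    ppm = write_pnm(v * 255, path),
    stop("unsupported image format '", ext, "' for: ", path)
  )
  invisible(path)
}

# Minimal PNM (P2/P3/P5/P6) reader; returns 0..255 values.
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) stop("truncated PNM file: ", path)
      if (ch == "#") { repeat { c2 <- readChar(con, 1, useBytes = TRUE); if (!length(c2) || c2 == "\n") break } ; next }
      if (!grepl("[ \t\r\n]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (!length(ch) || grepl("[ \t\r\n]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P3", "P5", "P6")) stop("not a supported PNM file: ", path)
  W <- as.integer(tok()); H <- as.integer(tok()); maxv <- as.integer(tok())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- W * H * nch
  vals <- if (magic %in% c("P5", "P6")) {
    as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE))
  } else {
    v <- numeric(0)
    while (length(v) < n) {
      line <- readLines(con, 1)
      if (!length(line)) break
      line <- sub("#.*", "", line)
      v <- c(v, as.numeric(strsplit(trimws(line), "[ \t]+")[[1]]))
    }
    v[seq_len(n)]
  }
  vals <- vals / maxv * 255
  if (nch == 1L) {
    matrix(vals, nrow = H, ncol = W, byrow = TRUE)
  } else {
    a <- array(0, dim = c(H, W, 3))
    m <- matrix(vals, ncol = 3, byrow = TRUE)  # pixel-major RGB
    for (c in 1:3) a[, , c] <- matrix(m[, c], nrow = H, ncol = W, byrow = TRUE)
    a
  }
}

# Binary PGM (P5) / PPM (P6) writer; input on 0..255 scale.
write_pnm <- function(img, path) {
  d <- dim(img)
  nch <- if (length(d) == 3) d[3] else 1L
  magic <- if (nch == 3) "P6" else "P5"
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", magic, d[2], d[1]), con, eos = NULL)
  v <- round(pmin(pmax(img, 0), 255))
  if (nch == 1) {
    bytes <- as.integer(t(v))
  } else {
    m <- cbind(as.vector(t(v[, , 1])), as.vector(t(v[, , 2])), as.vector(t(v[, , 3])))
    bytes <- as.integer(t(m))
  }
  writeBin(as.raw(bytes), con)
  invisible(path)
}

binarize_mask <- function(m, threshold = 127) {
  if (length(dim(m)) == 3) m <- m[, , 1]
  if (max(m) <= 1) m <- m * 255
  (m > threshold) * 1
}

#' Load one fundus image with its annotations
#'
#' Builds an image record: the RGB image (0..255), the binary vessel ground
#' truth (if available) and the binary field-of-view mask.  Grayscale images
#' are replicated to three channels; masks are binarized at 127 on the 8-bit
#' scale.  When no FOV file is given the mask is estimated with
#' [estimate_fov()].
#'
#' @param image_path path of the fundus image (PNG/TIFF/PGM/PPM).
#' @param gt_path optional vessel annotation mask path.
#' @param fov_path optional FOV mask path.
#' @param id record identifier; defaults to the image file stem.
#' @return a list of class `vs_record` with elements `image` (H,W,3),
#'   `vessel_gt` (H,W or NULL), `fov` (H,W), `id`.
#' @export
load_record <- function(image_path, gt_path = NULL, fov_path = NULL, id = NULL) {
  img <- read_image_file(image_path)
  if (length(dim(img)) == 2) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  }
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop("image must decode to 2-D grayscale or 3-channel RGB: ", image_path)
  }
  hw <- dim(img)[1:2]
  gt <- NULL
  if (!is.null(gt_path)) {
    gt <- binarize_mask(read_image_file(gt_path))
    if (!all(dim(gt) == hw)) {
      stop("vessel mask shape ", paste(dim(gt), collapse = "x"),
           " does not match image shape ", paste(hw, collapse = "x"))
    }
  }
  if (!is.null(fov_path)) {
    fov <- binarize_mask(read_image_file(fov_path))
    if (!all(dim(fov) == hw)) {
      stop("FOV mask shape ", paste(dim(fov), collapse = "x"),
           " does not match image shape ", paste(hw, collapse = "x"))
    }
  } else {
    fov <- estimate_fov(img)
  }
  structure(list(image = img, vessel_gt = gt, fov = fov,
                 id = id %||% tools::file_path_sans_ext(basename(image_path))),
            class = "vs_record")
}

#' @export
print.vs_record <- function(x, ...) {
  cat(sprintf("<vs_record '%s' %dx%d gt=%s fov=%.1f%%>\n", x$id,
              nrow(x$fov), ncol(x$fov),
              if (is.null(x$vessel_gt)) "absent" else "present",
              100 * mean(x$fov)))
  invisible(x)
}

#' Estimate a field-of-view mask from image intensity
#'
#' A plumbing substitute for dataset-provided FOV masks: thresholds the red
#' channel (fundus photographs are brightest in red inside the imaged disc)
#' at a fraction of its maximum, keeps the largest connected component, and
#' closes it morphologically (disc radius 5 px).  The FOV only gates which
#' pixels enter evaluation, so a coarse estimate suffices.
#'
#' @param image (H,W,3) or (H,W) array, 0..255 or [0,1].
#' @param threshold_frac threshold as a fraction of the maximum intensity.
#' @param close_radius structuring-element radius for the closing.
#' @return binary (H,W) mask, a single connected component (or all zeros,
#'   with a warning, for an all-dark image).
#' @export
estimate_fov <- function(image, threshold_frac = 0.1, close_radius = 5) {
  ch <- if (length(dim(image)) == 3) image[, , 1] else image
  mx <- max(ch)
  if (mx <= 0) {
    warning("all-dark image: FOV estimate is empty")
    return(array(0, dim = dim(ch)))
  }
  m <- ch > threshold_frac * mx
  if (!any(m)) {
    warning("no pixel above the FOV threshold: FOV estimate is empty")
    return(array(0, dim = dim(ch)))
  }
  # EBImage works in (x, y) = (W, H); transpose both ways
  lab <- EBImage::bwlabel(EBImage::as.Image(t(m * 1)))
  labm <- EBImage::imageData(lab)
  tab <- tabulate(labm[labm > 0])
  keep <- which.max(tab)
  m2 <- (labm == keep) * 1
  brush <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")
  m3 <- EBImage::closing(EBImage::as.Image(m2), brush)
  out <- t(EBImage::imageData(m3))
  (out > 0.5) * 1
}

#' Write a binary mask as an 8-bit image (0/255)
#'
#' Round-trips exactly through [load_record()]'s binarization.
#' @param mask binary matrix.
#' @param path destination (PNG/PGM).
#' @export
write_mask <- function(mask, path) {
  write_image_file((mask > 0.5) * 255, path)
}

#' Discover a DRIVE-style dataset layout
#'
#' Lists records from a directory layout described by glob-style templates
#' containing `{id}` placeholders, as read from a YAML/JSON config or given
#' directly.
#'
#' @param root dataset root directory.
#' @param image_glob glob (relative to `root`) matching the image files.
#' @param gt_template,fov_template templates with `{id}` for the matching
#'   annotation/FOV files, or NULL when absent.
#' @return data.frame with columns id, image, gt, fov (file paths; NA when a
#'   file is absent).
#' @export
discover_dataset <- function(root, image_glob = "images/*.png",
                             gt_template = "gt/{id}.png",
                             fov_template = "fov/{id}.png") {
  imgs <- Sys.glob(file.path(root, image_glob))
  if (!length(imgs)) stop("no images match ", file.path(root, image_glob))
  ids <- tools::file_path_sans_ext(basename(imgs))
  fill <- function(tmpl, id) {
    if (is.null(tmpl)) return(NA_character_)
    p <- file.path(root, gsub("{id}", id, tmpl, fixed = TRUE))
    if (file.exists(p)) p else NA_character_
  }
  data.frame(
    id = ids,
    image = imgs,
    gt = vapply(ids, fill, character(1), tmpl = gt_template),
    fov = vapply(ids, fill, character(1), tmpl = fov_template),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Load every record of a discovered dataset
#' @param layout data.frame from [discover_dataset()].
#' @return list of `vs_record`.
#' @export
load_dataset <- function(layout) {
  lapply(seq_len(nrow(layout)), function(i) {
    load_record(layout$image[i],
                gt_path = if (is.na(layout$gt[i])) NULL else layout$gt[i],
                fov_path = if (is.na(layout$fov[i])) NULL else layout$fov[i],
                id = layout$id[i])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
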