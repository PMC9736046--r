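# Spatial operations on (H, W, C) feature arrays for the autodiff engine.
# Convolutions use a cached im2col index plus a BLAS GEMM; the input gradient
# of a same-padded, stride-1, odd-kernel convolution is itself a convolution
# of the output gradient with the spatially flipped, channel-transposed kernel.

# im2col gather index for input (H, W, C) and odd kernel k with same padding.
# Returns an (H*W) x (k*k*C) integer matrix of linear indices into the
# zero-padded array of dim (H+k-1, W+k-1, C).  Column order: kernel row
# fastest, then kernel col, then input channel -- matching a kernel array of
# dim (k, k, Cin, Cout) flattened column-major.
im2col_index <- function(H, W, C, k) {
  key <- paste(H, W, C, k, sep = "x")
  hit <- .ag$cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + k - 1L
  Wp <- W + k - 1L
  pr <- rep(seq_len(H), times = W)              # output pixel rows (col-major)
  pc <- rep(seq_len(W), each = H)
  base <- pr + (pc - 1L) * Hp                   # top-left of window in padded
  off <- integer(k * k * C)
  m <- 1L
  offs <- integer(0)
  for (c in seq_len(C)) {
    for (dj in 0:(k - 1L)) {
      for (di in 0:(k - 1L)) {
        offs[m] <- di + dj * Hp + (c - 1L) * Hp * Wp
        m <- m + 1L
      }
    }
  }
  idx <- outer(base, offs, "+")
  storage.mode(idx) <- "integer"
  .ag$cache[[key]] <- idx
  idx
}

pad_zero_hw <- function(x, p) {
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

im2col <- function(x, k) {
  d <- dim(x)
  p <- (k - 1L) %/% 2L
  xp <- if (p > 0) pad_zero_hw(x, p) else x
  idx <- im2col_index(d[1], d[2], d[3], k)
  M <- xp[as.vector(idx)]   # vector indexing (a matrix index would be read as coordinates)
  dim(M) <- dim(idx)
  M
}

# 2-D convolution ("same", stride 1).  x: (H,W,Cin); W kernel array
# (k,k,Cin,Cout); b length Cout or NULL.
ag_conv2d <- function(x, Wt, b = NULL, k = NULL) {
  xv <- ag_val(x)
  Wv <- ag_val(Wt)
  kd <- dim(Wv)
  if (is.null(k)) k <- kd[1]
  stopifnot(kd[1] == kd[2], k %% 2L == 1L)
  cin <- kd[3]; cout <- kd[4]
  d <- dim(xv)
  stopifnot(d[3] == cin)
  Wm <- Wv
  dim(Wm) <- c(k * k * cin, cout)
  Xc <- im2col(xv, k)
  Y <- Xc %*% Wm
  if (!is.null(b)) Y <- sweep(Y, 2, ag_val(b), "+")
  dim(Y) <- c(d[1], d[2], cout)
  parents <- if (is.null(b)) list(x, Wt) else list(x, Wt, b)
  ag_node(Y, parents, function(g) {
    gm <- g
    dim(gm) <- c(d[1] * d[2], cout)
    dW <- crossprod(Xc, gm)
    dim(dW) <- c(k, k, cin, cout)
    # input gradient: convolve g with flipped kernel, in/out channels swapped
    Wr <- Wv[k:1, k:1, , , drop = FALSE]
    Wr <- aperm(Wr, c(1, 2, 4, 3))            # (k,k,Cout,Cin)
    dim(Wr) <- c(k * k * cout, cin)
    Gc <- im2col(g, k)
    dX <- Gc %*% Wr
    dim(dX) <- c(d[1], d[2], cin)
    out <- list(dX, dW)
    if (!is.null(b)) out[[3]] <- colSums(gm)
    out
  })
}

# 2x2 max pooling, stride 2.  H, W must be even.
ag_maxpool2 <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  stopifnot(d[1] %% 2L == 0L, d[2] %% 2L == 0L)
  ro <- seq(1L, d[1], by = 2L); re <- ro + 1L
  co <- seq(1L, d[2], by = 2L); ce <- co + 1L
  a <- xv[ro, co, , drop = FALSE]
  b <- xv[ro, ce, , drop = FALSE]
  cc <- xv[re, co, , drop = FALSE]
  dd <- xv[re, ce, , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  w1 <- a == m
  w2 <- (b == m) & !w1
  w3 <- (cc == m) & !(w1 | w2)
  w4 <- !(w1 | w2 | w3)
  ag_node(m, list(x), function(g) {
    gx <- array(0, dim = d)
    gx[ro, co, ] <- g * w1
    gx[ro, ce, ] <- g * w2
    gx[re, co, ] <- g * w3
    gx[re, ce, ] <- g * w4
    list(gx)
  })
}

# Nearest-neighbour 2x upsampling.
ag_upsample2 <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  y <- xv[ri, ci, , drop = FALSE]
  ro <- seq(1L, 2L * d[1], by = 2L); re <- ro + 1L
  co <- seq(1L, 2L * d[2], by = 2L); ce <- co + 1L
  ag_node(y, list(x), function(g) {
    gx <- g[ro, co, , drop = FALSE] + g[ro, ce, , drop = FALSE] +
      g[re, co, , drop = FALSE] + g[re, ce, , drop = FALSE]
    list(gx)
  })
}

# Zero-pad spatially to (H + pb + pt, W + pl + pr).
ag_pad_hw <- function(x, pt, pb, pl, pr) {
  xv <- ag_val(x)
  d <- dim(xv)
  y <- array(0, dim = c(d[1] + pt + pb, d[2] + pl + pr, d[3]))
  y[pt + seq_len(d[1]), pl + seq_len(d[2]), ] <- xv
  ag_node(y, list(x), function(g) {
    list(g[pt + seq_len(d[1]), pl + seq_len(d[2]), , drop = FALSE])
  })
}

# Crop rows r0..(r0+h-1), cols c0..(c0+w-1) (1-based).  This is the `cut`
# operator of the collaborative correction path expressed on the autodiff tape.
ag_crop_hw <- function(x, r0, c0, h, w) {
  xv <- ag_val(x)
  d <- dim(xv)
  stopifnot(r0 >= 1, c0 >= 1, r0 + h - 1 <= d[1], c0 + w - 1 <= d[2])
  rows <- r0:(r0 + h - 1L)
  cols <- c0:(c0 + w - 1L)
  y <- xv[rows, cols, , drop = FALSE]
  ag_node(y, list(x), function(g) {
    gx <- array(0, dim = d)
    gx[rows, cols, ] <- g
    list(gx)
  })
}

# Cyclic spatial roll (positive = towards larger indices), used by the
# shifted-window attention pair.
ag_roll_hw <- function(x, dr, dc) {
  xv <- ag_val(x)
  d <- dim(xv)
  ri <- ((seq_len(d[1]) - 1L - dr) %% d[1]) + 1L
  ci <- ((seq_len(d[2]) - 1L - dc) %% d[2]) + 1L
  y <- xv[ri, ci, , drop = FALSE]
  ag_node(y, list(x), function(g) {
    rb <- ((seq_len(d[1]) - 1L + dr) %% d[1]) + 1L
    cb <- ((seq_len(d[2]) - 1L + dc) %% d[2]) + 1L
    list(g[rb, cb, , drop = FALSE])
  })
}

# Concatenate along channels.
ag_concat_c <- function(xs) {
  vals <- lapply(xs, ag_val)
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  y <- array(0, dim = c(d1[1], d1[2], sum(cs)))
  at <- 0L
  for (v in vals) {
    cv <- dim(v)[3]
    y[, , at + seq_len(cv)] <- v
    at <- at + cv
  }
  ag_node(y, xs, function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      cv <- cs[i]
      out[[i]] <- g[, , at + seq_len(cv), drop = FALSE]
      at <- at + cv
    }
    out
  })
}

# ---- pooling encoders (directional + global) -------------------------------

# Mean over height: (H,W,C) -> (W,C).
ag_pool_h_avg <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  y <- colMeans(xv, dims = 1)
  ag_node(y, list(x), function(g) {
    gx <- array(rep(g, each = d[1]) / d[1], dim = d)
    list(gx)
  })
}

# Max over height: (H,W,C) -> (W,C); first maximum wins on ties.
ag_pool_h_max <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  m <- xv[1, , , drop = TRUE]
  dim(m) <- d[2:3]
  arg <- array(1L, dim = d[2:3])
  if (d[1] > 1) for (i in 2:d[1]) {
    cur <- xv[i, , , drop = TRUE]
    dim(cur) <- d[2:3]
    upd <- cur > m
    m[upd] <- cur[upd]
    arg[upd] <- i
  }
  ag_node(m, list(x), function(g) {
    gx <- array(0, dim = d)
    wc <- as.vector(slice.index(arg, 1))        # w index 1..W
    cc <- as.vector(slice.index(arg, 2))        # c index 1..C
    lin <- as.vector(arg) + (wc - 1L) * d[1] + (cc - 1L) * d[1] * d[2]
    gx[lin] <- as.vector(g)
    dim(gx) <- d
    list(gx)
  })
}

# Mean over width: (H,W,C) -> (H,C).
ag_pool_w_avg <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  y <- apply(xv, c(1, 3), mean)
  ag_node(y, list(x), function(g) {
    gx <- aperm(array(g, dim = c(d[1], d[3], d[2])), c(1, 3, 2)) / d[2]
    list(gx)
  })
}

# Max over width: (H,W,C) -> (H,C).
ag_pool_w_max <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  m <- xv[, 1, , drop = TRUE]
  dim(m) <- d[c(1, 3)]
  arg <- array(1L, dim = d[c(1, 3)])
  if (d[2] > 1) for (j in 2:d[2]) {
    cur <- xv[, j, , drop = TRUE]
    dim(cur) <- d[c(1, 3)]
    upd <- cur > m
    m[upd] <- cur[upd]
    arg[upd] <- j
  }
  ag_node(m, list(x), function(g) {
    gx <- array(0, dim = d)
    hc <- as.vector(slice.index(arg, 1))
    cc <- as.vector(slice.index(arg, 2))
    lin <- hc + (as.vector(arg) - 1L) * d[1] + (cc - 1L) * d[1] * d[2]
    gx[lin] <- as.vector(g)
    dim(gx) <- d
    list(gx)
  })
}

# Global average pool: (H,W,C) -> length-C vector.
ag_global_avg <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  y <- colMeans(xv, dims = 2)
  ag_node(y, list(x), function(g) {
    gx <- array(rep(g, each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
    list(gx)
  })
}

# ---- broadcast gatings -----------------------------------------------------

# Per-channel scaling: y[,,c] = x[,,c] * s[c]  (SE-style gate).
ag_mul_channel <- function(x, s) {
  xv <- ag_val(x); sv <- ag_val(s)
  d <- dim(xv)
  sb <- array(rep(sv, each = d[1] * d[2]), dim = d)
  ag_node(xv * sb, list(x, s), function(g) {
    list(g * sb, colSums(g * xv, dims = 2))
  })
}

# Directional gate of the coordinate attention output:
# y[i,j,c] = x[i,j,c] * fh[i,c] * fw[j,c],   fh: (H,C), fw: (W,C).
ag_mul_gate_hw <- function(x, fh, fw) {
  xv <- ag_val(x); fhv <- ag_val(fh); fwv <- ag_val(fw)
  d <- dim(xv)
  fhb <- aperm(array(fhv, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  fwb <- array(rep(fwv, each = d[1]), dim = d)
  y <- xv * fhb * fwb
  ag_node(y, list(x, fh, fw), function(g) {
    dfh <- apply(g * xv * fwb, c(1, 3), sum)
    dfw <- colSums(g * xv * fhb, dims = 1)
    list(g * fhb * fwb, dfh, dfw)
  })
}
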