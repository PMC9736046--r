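# Attention modules.
#
# Adaptive coordinate attention (ACA): each channel is encoded along height
# and width by BOTH average and max 1-D pooling; the two pooled encodings are
# passed through a shared bottleneck transform, recombined with learnable
# scalar weights g1, g2, and mapped to per-height and per-width sigmoid gates
# that multiply the feature map.  The max branch keeps thin, high-contrast
# structures (capillaries) from being averaged into the background.
#
# Gated self-attention (GSA): windowed multi-head self-attention whose
# relative position bias B is multiplied by a learnable scalar gate, applied
# as an unshifted/shifted pair of transformer blocks (LN + PSA + residual,
# LN + 2-layer MLP + residual).
#
# Baselines with the same interface: SE (squeeze-and-excitation channel
# gate), CA (average-pooling-only coordinate attention, i.e. ACA with the
# max branch off), SW (window attention with the bias gate fixed at 1).

# ---- adaptive coordinate attention -----------------------------------------

#' Directional pooling encodings of a feature map
#'
#' For a (H, W, C) feature map, returns the four 1-D pooled descriptors:
#' average and maximum over height for every width position (C x W), and
#' average and maximum over width for every height position (C x H).
#'
#' @param x numeric (H, W, C) array (a matrix is treated as C = 1).
#' @return list with `k_w_avg`, `k_w_max` (C x W), `k_h_avg`, `k_h_max`
#'   (C x H).
#' @export
aca_encode <- function(x) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] < 1 || d[2] < 1) stop("empty spatial dimensions")
  list(
    k_w_avg = t(ag_val(ag_pool_h_avg(ag_tensor(x)))),
    k_w_max = t(ag_val(ag_pool_h_max(ag_tensor(x)))),
    k_h_avg = t(ag_val(ag_pool_w_avg(ag_tensor(x)))),
    k_h_max = t(ag_val(ag_pool_w_max(ag_tensor(x))))
  )
}

#' Coordinate attention gate computation
#'
#' Implements the bottleneck-and-split pipeline on a directional encoding:
#' the average-branch pair and max-branch pair are each concatenated along
#' the spatial axis, passed through the shared transform F1 with a
#' non-linearity, recombined as `g1 * z_avg + g2 * z_max`, split back into
#' height and width parts, and mapped through Fh / Fw with a sigmoid.
#'
#' @param enc encoding list from [aca_encode()] (C x W and C x H matrices).
#' @param params list with `F1` (C x Cr matrix), `F1_b` (length Cr), `Fh`,
#'   `Fw` (Cr x C), `Fh_b`, `Fw_b` (length C), scalars `g1`, `g2`; entries
#'   may be plain or `ag_tensor`s.
#' @param delta activation after F1: `"hardswish"` (default) or `"relu"`.
#' @return list with `f_h` (C x H) and `f_w` (C x W), entries in (0, 1).
#' @export
aca_weights <- function(enc, params, delta = c("hardswish", "relu")) {
  delta <- match.arg(delta)
  out <- aca_weights_ag(
    kha = ag_tensor(t(enc$k_h_avg)), kwa = ag_tensor(t(enc$k_w_avg)),
    khm = ag_tensor(t(enc$k_h_max)), kwm = ag_tensor(t(enc$k_w_max)),
    params = lapply(params, function(p) if (is_ag(p)) p else ag_tensor(p)),
    delta = delta
  )
  list(f_h = t(ag_val(out$f_h)), f_w = t(ag_val(out$f_w)))
}

# Internal autodiff path of Eqs. 5-10.  Inputs are (H,C)/(W,C) matrices.
aca_weights_ag <- function(kha, kwa, khm, kwm, params, delta = "hardswish") {
  H <- nrow(ag_val(kha)); W <- nrow(ag_val(kwa))
  act <- if (delta == "hardswish") ag_hardswish else ag_relu
  cat_a <- ag_node(rbind(ag_val(kha), ag_val(kwa)), list(kha, kwa), function(g) {
    list(g[seq_len(H), , drop = FALSE], g[H + seq_len(W), , drop = FALSE])
  })
  cat_m <- ag_node(rbind(ag_val(khm), ag_val(kwm)), list(khm, kwm), function(g) {
    list(g[seq_len(H), , drop = FALSE], g[H + seq_len(W), , drop = FALSE])
  })
  za <- act(ag_linear(cat_a, params$F1, params$F1_b))   # (H+W) x Cr
  zm <- act(ag_linear(cat_m, params$F1, params$F1_b))
  z <- ag_axpby(params$g1, za, params$g2, zm)           # Eqs. 7-8
  zh <- ag_node(ag_val(z)[seq_len(H), , drop = FALSE], list(z), function(g) {
    gz <- matrix(0, H + W, ncol(g)); gz[seq_len(H), ] <- g; list(gz)
  })
  zw <- ag_node(ag_val(z)[H + seq_len(W), , drop = FALSE], list(z), function(g) {
    gz <- matrix(0, H + W, ncol(g)); gz[H + seq_len(W), ] <- g; list(gz)
  })
  list(f_h = ag_sigmoid(ag_linear(zh, params$Fh, params$Fh_b)),   # (H, C)
       f_w = ag_sigmoid(ag_linear(zw, params$Fw, params$Fw_b)))   # (W, C)
}

#' Apply coordinate attention gates to a feature map
#'
#' `y[i,j,c] = x[i,j,c] * f_h[c,i] * f_w[c,j]`.
#'
#' @param x (H, W, C) array.
#' @param f_h C x H gate matrix.
#' @param f_w C x W gate matrix.
#' @return gated (H, W, C) array.
#' @export
aca_apply <- function(x, f_h, f_w) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (ncol(f_h) != d[1] || ncol(f_w) != d[2] ||
      nrow(f_h) != d[3] || nrow(f_w) != d[3]) {
    stop("gate shapes do not match the feature map")
  }
  ag_val(ag_mul_gate_hw(ag_tensor(x), t(f_h), t(f_w)))
}

#' Adaptive coordinate attention block
#'
#' @param C channel count of the gated feature map.
#' @param r channel reduction ratio of the bottleneck (`Cr = ceiling(C/r)`).
#' @param variant `"adaptive"` (learnable g1/g2 mixing average and max
#'   pooling; the full module) or `"avg_only"` (the classical coordinate
#'   attention baseline: g1 fixed at 1, g2 at 0).
#' @param delta bottleneck activation.
#' @return module; run with [aca_forward()].
#' @export
aca_block <- function(C, r = 8L, variant = c("adaptive", "avg_only"),
                      delta = "hardswish") {
  variant <- match.arg(variant)
  Cr <- max(1L, as.integer(ceiling(C / r)))
  params <- list(
    F1 = new_param(matrix(stats::rnorm(C * Cr, sd = sqrt(2 / C)), C, Cr)),
    F1_b = new_param(numeric(Cr)),
    Fh = new_param(matrix(stats::rnorm(Cr * C, sd = sqrt(2 / Cr)), Cr, C)),
    Fh_b = new_param(numeric(C)),
    Fw = new_param(matrix(stats::rnorm(Cr * C, sd = sqrt(2 / Cr)), Cr, C)),
    Fw_b = new_param(numeric(C))
  )
  if (variant == "adaptive") {
    params$g1 <- new_param(0.5)
    params$g2 <- new_param(0.5)
  }
  vs_module(params = params, C = C, Cr = Cr, variant = variant, delta = delta,
            kind = "aca")
}

#' Forward pass of an ACA (or CA) block
#' @param block from [aca_block()].
#' @param x input, `ag_tensor` or plain (H, W, C) array.
#' @return gated map of the same type and shape as `x`.
#' @export
aca_forward <- function(block, x) {
  plain <- !is_ag(x)
  xt <- if (plain) ag_tensor(x) else x
  p <- block$params
  if (block$variant == "avg_only") {
    p$g1 <- ag_tensor(1)
    p$g2 <- ag_tensor(0)
  }
  enc <- list(kha = ag_pool_w_avg(xt), kwa = ag_pool_h_avg(xt),
              khm = ag_pool_w_max(xt), kwm = ag_pool_h_max(xt))
  w <- aca_weights_ag(enc$kha, enc$kwa, enc$khm, enc$kwm, p, block$delta)
  y <- ag_mul_gate_hw(xt, w$f_h, w$f_w)
  if (plain) ag_val(y) else y
}

# ---- squeeze-and-excitation baseline ---------------------------------------

#' Squeeze-and-excitation channel attention block
#' @param C channels; @param r reduction ratio.
#' @return module; run with [se_forward()].
#' @export
se_block <- function(C, r = 8L) {
  Cr <- max(1L, as.integer(ceiling(C / r)))
  vs_module(params = list(
    W1 = new_param(matrix(stats::rnorm(C * Cr, sd = sqrt(2 / C)), C, Cr)),
    b1 = new_param(numeric(Cr)),
    W2 = new_param(matrix(stats::rnorm(Cr * C, sd = sqrt(2 / Cr)), Cr, C)),
    b2 = new_param(numeric(C))
  ), C = C, kind = "se")
}

#' @rdname se_block
#' @param block,x module and input ((H,W,C) array or `ag_tensor`).
#' @export
se_forward <- function(block, x) {
  plain <- !is_ag(x)
  xt <- if (plain) ag_tensor(x) else x
  p <- block$params
  s <- ag_global_avg(xt)
  s <- ag_reshape(s, c(1L, length(ag_val(s))))
  s <- ag_relu(ag_linear(s, p$W1, p$b1))
  s <- ag_sigmoid(ag_linear(s, p$W2, p$b2))
  y <- ag_mul_channel(xt, ag_reshape(s, ncol(ag_val(s))))
  if (plain) ag_val(y) else y
}

# ---- windowed self-attention -----------------------------------------------

#' Relative-position index map for an M x M window
#'
#' Token order is column-major over the window (row index fastest).  Entry
#' (p, q) is the 1-based linear index into the flattened (2M-1) x (2M-1)
#' bias table for displacement (row_q - row_p, col_q - col_p); token pairs
#' with equal displacement share an index.
#'
#' @param M window side.
#' @return M^2 x M^2 integer matrix.
#' @export
rel_pos_index <- function(M) {
  ii <- rep(seq_len(M), times = M)
  jj <- rep(seq_len(M), each = M)
  dr <- outer(ii, ii, function(a, b) b - a) + M - 1L   # 0 .. 2M-2
  dc <- outer(jj, jj, function(a, b) b - a) + M - 1L
  idx <- dr + dc * (2L * M - 1L) + 1L
  storage.mode(idx) <- "integer"
  idx
}

#' Partition a token map into non-overlapping windows
#'
#' When `shifted`, the map is cyclically rolled by `floor(M/2)` in both
#' spatial axes before partitioning (the shifted-window pairing); the
#' returned `inverse` function restores the original layout bit-exactly.
#'
#' @param x (H, W, C) array with H, W divisible by M.
#' @param M window side.
#' @param shifted logical.
#' @return list(windows = list of M^2 x C matrices (column-major window
#'   order), inverse = function(list of windows) -> (H, W, C)).
#' @export
window_partition <- function(x, M, shifted = FALSE) {
  d <- dim(x)
  if (M > d[1] || M > d[2]) stop("window side M exceeds the token map")
  if (d[1] %% M != 0 || d[2] %% M != 0) {
    stop("token map (", d[1], "x", d[2], ") is not divisible by M = ", M)
  }
  sft <- if (shifted) M %/% 2L else 0L
  xs <- if (sft > 0) ag_val(ag_roll_hw(ag_tensor(x), -sft, -sft)) else x
  nwr <- d[1] %/% M; nwc <- d[2] %/% M
  windows <- vector("list", nwr * nwc)
  k <- 1L
  for (wj in seq_len(nwc)) {
    for (wi in seq_len(nwr)) {
      blk <- xs[(wi - 1L) * M + seq_len(M), (wj - 1L) * M + seq_len(M), ,
                drop = FALSE]
      dim(blk) <- c(M * M, d[3])
      windows[[k]] <- blk
      k <- k + 1L
    }
  }
  inverse <- function(wins) {
    out <- array(0, dim = d)
    k <- 1L
    for (wj in seq_len(nwc)) {
      for (wi in seq_len(nwr)) {
        blk <- wins[[k]]
        dim(blk) <- c(M, M, d[3])
        out[(wi - 1L) * M + seq_len(M), (wj - 1L) * M + seq_len(M), ] <- blk
        k <- k + 1L
      }
    }
    if (sft > 0) out <- ag_val(ag_roll_hw(ag_tensor(out), sft, sft))
    out
  }
  list(windows = windows, inverse = inverse)
}

#' Gated windowed self-attention on one window
#'
#' `Attention(Q,K,V) = Softmax(Q K^t / sqrt(d) + ga * B) V`, softmax over the
#' key axis, with B gathered from the bias table through [rel_pos_index()].
#'
#' @param Q,K,V M^2 x d matrices.
#' @param B_table numeric vector/matrix of length (2M-1)^2 (the learnable
#'   table), or an M^2 x M^2 matrix used as B directly.
#' @param ga scalar gate on the bias.
#' @return M^2 x d output matrix.
#' @export
patch_self_attention <- function(Q, K, V, B_table, ga = 1) {
  d <- ncol(Q)
  if (is.null(d) || d == 0) stop("key/query dimension d must be positive")
  n <- nrow(Q)
  M <- as.integer(round(sqrt(n)))
  B <- if (is.matrix(B_table) && all(dim(B_table) == c(n, n))) {
    B_table
  } else {
    matrix(as.vector(B_table)[rel_pos_index(M)], n, n)
  }
  logits <- Q %*% t(K) / sqrt(d) + ga * B
  m <- logits - apply(logits, 1, max)
  p <- exp(m) / rowSums(exp(m))
  p %*% V
}

# Autodiff PSA on one window's tokens (n x C), multi-head.
psa_forward_ag <- function(tok, p, relidx, heads, gate) {
  C <- ncol(ag_val(tok))
  dh <- C %/% heads
  qkv <- ag_linear(tok, p$Wqkv, p$bqkv)           # n x 3C
  n <- nrow(ag_val(tok))
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    colsQ <- (h - 1L) * dh + seq_len(dh)
    colsK <- C + colsQ
    colsV <- 2L * C + colsQ
    slice <- function(z, cols) {
      ag_node(ag_val(z)[, cols, drop = FALSE], list(z), function(g) {
        gz <- matrix(0, n, 3L * C); gz[, cols] <- g; list(gz)
      })
    }
    Qh <- slice(qkv, colsQ); Kh <- slice(qkv, colsK); Vh <- slice(qkv, colsV)
    logits <- ag_scale(ag_matmul(Qh, ag_node(t(ag_val(Kh)), list(Kh),
                                             function(g) list(t(g)))),
                       1 / sqrt(dh))
    if (gate != "none") {
      tabh <- p[[paste0("B", h)]]
      B <- ag_gather(tabh, as.vector(relidx), out_dim = c(n, n))
      gaB <- switch(gate,
        learnable = ag_mul(B, ag_node(array(ag_val(p$ga), dim = c(n, n)),
                                      list(p$ga), function(g) list(sum(g)))),
        fixed1 = B
      )
      logits <- ag_add(logits, gaB)
    }
    A <- ag_softmax_rows(logits)
    outs[[h]] <- ag_matmul(A, Vh)
  }
  o <- if (heads == 1) outs[[1]] else {
    ag_node(do.call(cbind, lapply(outs, ag_val)), outs, function(g) {
      lapply(seq_len(heads), function(h) g[, (h - 1L) * dh + seq_len(dh), drop = FALSE])
    })
  }
  ag_linear(o, p$Wproj, p$bproj)
}

#' Gated self-attention block
#'
#' An unshifted/shifted pair of transformer sub-blocks on a (H, W, C) token
#' map: `t~ = PSA(LN(t)) + t; t = MLP(LN(t~)) + t~`, first with regular
#' window partitioning, then with a cyclic shift of `floor(M/2)`.  Token
#' maps not divisible by M are zero-padded and cropped back.
#'
#' @param C channels (the token embedding dimension).
#' @param M window side (default 6).
#' @param heads attention heads (default one per 32 channels).
#' @param mlp_ratio hidden expansion of the 2-layer MLP.
#' @param gate `"learnable"` (scalar ga, init 1), `"fixed1"` (the
#'   Swin-style baseline: bias always fully on), or `"none"` (no relative
#'   position bias at all).
#' @return module; run with [gsa_forward()].
#' @export
gsa_block <- function(C, M = 6L, heads = max(1L, C %/% 32L), mlp_ratio = 4,
                      gate = c("learnable", "fixed1", "none")) {
  gate <- match.arg(gate)
  if (C %% heads != 0) stop("C must be divisible by the number of heads")
  nb <- (2L * M - 1L)^2
  sub <- function() {
    p <- list(
      ln1_g = new_param(rep(1, C)), ln1_b = new_param(numeric(C)),
      Wqkv = new_param(matrix(stats::rnorm(C * 3L * C, sd = sqrt(1 / C)), C, 3L * C)),
      bqkv = new_param(numeric(3L * C)),
      Wproj = new_param(matrix(stats::rnorm(C * C, sd = sqrt(1 / C)), C, C)),
      bproj = new_param(numeric(C)),
      ln2_g = new_param(rep(1, C)), ln2_b = new_param(numeric(C)),
      Wm1 = new_param(matrix(stats::rnorm(C * mlp_ratio * C, sd = sqrt(2 / C)),
                             C, mlp_ratio * C)),
      bm1 = new_param(numeric(mlp_ratio * C)),
      Wm2 = new_param(matrix(stats::rnorm(mlp_ratio * C * C,
                                          sd = sqrt(1 / (mlp_ratio * C))),
                             mlp_ratio * C, C)),
      bm2 = new_param(numeric(C))
    )
    for (h in seq_len(heads)) {
      p[[paste0("B", h)]] <- new_param(stats::rnorm(nb, sd = 0.02))
    }
    if (gate == "learnable") p$ga <- new_param(1)
    vs_module(params = p)
  }
  vs_module(modules = list(unshifted = sub(), shifted = sub()),
            C = C, M = M, heads = heads, gate = gate,
            relidx = rel_pos_index(M), kind = "gsa")
}

# One transformer sub-block (Eqs. "t~ = PSA(LN(t)) + t; t = MLP(LN(t~)) + t~")
gsa_sub_forward <- function(block, sub, xt, shifted) {
  d <- dim(ag_val(xt))
  M <- block$M
  p <- sub$params
  sft <- if (shifted) M %/% 2L else 0L
  xs <- if (sft > 0) ag_roll_hw(xt, -sft, -sft) else xt
  nwr <- d[1] %/% M; nwc <- d[2] %/% M
  outs <- list()
  k <- 1L
  for (wj in seq_len(nwc)) {
    for (wi in seq_len(nwr)) {
      r0 <- (wi - 1L) * M + 1L; c0 <- (wj - 1L) * M + 1L
      blk <- ag_crop_hw(xs, r0, c0, M, M)
      tok <- ag_reshape(blk, c(M * M, d[3]))
      tok_ln <- ag_layernorm(tok, p$ln1_g, p$ln1_b)
      att <- psa_forward_ag(tok_ln, p, block$relidx, block$heads, block$gate)
      outs[[k]] <- list(wi = wi, wj = wj, t = att)
      k <- k + 1L
    }
  }
  # merge windows back to a map
  merged <- ag_node({
    out <- array(0, dim = d)
    for (o in outs) {
      blk <- ag_val(o$t)
      dim(blk) <- c(M, M, d[3])
      out[(o$wi - 1L) * M + seq_len(M), (o$wj - 1L) * M + seq_len(M), ] <- blk
    }
    out
  }, lapply(outs, `[[`, "t"), function(g) {
    lapply(outs, function(o) {
      blk <- g[(o$wi - 1L) * M + seq_len(M), (o$wj - 1L) * M + seq_len(M), ,
               drop = FALSE]
      dim(blk) <- c(M * M, d[3])
      blk
    })
  })
  att_map <- if (sft > 0) ag_roll_hw(merged, sft, sft) else merged
  t1 <- ag_add(att_map, xt)                                  # PSA + residual
  tok1 <- ag_reshape(t1, c(d[1] * d[2], d[3]))
  z <- ag_layernorm(tok1, p$ln2_g, p$ln2_b)
  z <- ag_linear(z, p$Wm1, p$bm1)
  z <- ag_relu(z)
  z <- ag_linear(z, p$Wm2, p$bm2)
  ag_reshape(ag_add(z, tok1), d)                             # MLP + residual
}

#' Forward pass of a GSA (or SW) block
#' @param block from [gsa_block()].
#' @param x (H, W, C) array or `ag_tensor`.
#' @return same type/shape as input.
#' @export
gsa_forward <- function(block, x) {
  plain <- !is_ag(x)
  xt <- if (plain) ag_tensor(x) else x
  d <- dim(ag_val(xt))
  M <- block$M
  ph <- (M - d[1] %% M) %% M
  pw <- (M - d[2] %% M) %% M
  if (ph > 0 || pw > 0) xt <- ag_pad_hw(xt, 0L, ph, 0L, pw)
  y <- gsa_sub_forward(block, block$modules$unshifted, xt, shifted = FALSE)
  y <- gsa_sub_forward(block, block$modules$shifted, y, shifted = TRUE)
  if (ph > 0 || pw > 0) y <- ag_crop_hw(y, 1L, 1L, d[1], d[2])
  if (plain) ag_val(y) else y
}

#' Reference attention baselines (SE, CA, SW)
#'
#' Constructors for the ablation baselines sharing the ACA/GSA interfaces:
#' SE (global-average-pool channel gating), CA (average-only coordinate
#' attention) and SW (window attention with the bias gate fixed at 1).
#'
#' @param C channels.
#' @param r reduction ratio (SE/CA).
#' @param M,heads window side and heads (SW).
#' @return list of three constructors' results with a common `$forward`.
#' @export
baseline_blocks <- function(C, r = 8L, M = 6L, heads = max(1L, C %/% 32L)) {
  se <- se_block(C, r)
  ca <- aca_block(C, r, variant = "avg_only")
  sw <- gsa_block(C, M, heads, gate = "fixed1")
  list(
    SE = list(block = se, forward = function(x) se_forward(se, x)),
    CA = list(block = ca, forward = function(x) aca_forward(ca, x)),
    SW = list(block = sw, forward = function(x) gsa_forward(sw, x))
  )
}
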