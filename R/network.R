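# The multi-feature segmentation network.
#
# Two cascaded U-Nets segment the small target patch: a pre-segmentation
# sub-network produces a rough vessel map, and a main-segmentation
# sub-network -- with adaptive coordinate attention after every encoder
# stage and a gated self-attention block at the bottleneck -- refines it.
# A shallow edge-extraction branch (Sobel-initialized, learnable) feeds a
# vessel-edge probability into the main encoder input.
#
# The collaborative path processes the five large neighbourhood patches with
# dedicated lightweight context networks at 1/context_scale resolution:
# their pre-stage features are fused (shared 3x3 conv -> cut to the target
# region -> concat -> channel attention -> 1x1 conv) into an associated
# feature f_plt that joins the main input, and their main-stage features are
# cut, concatenated and channel-gated into a correction feature f_mlt that
# joins the final two-conv segmentation head.  Keeping the context path
# coarse and narrow is what makes the collaborative forward only marginally
# more expensive than the single-patch forward while still injecting the
# neighbourhood information lost at patch borders.

#' Network configuration
#'
#' @param geometry a [patch_geometry()]; `geometry$s` must be divisible by
#'   `2^(length(main_channels)-1)` and `geometry$l` by
#'   `context_scale * 2^(length(context_channels)-1)`.
#' @param main_channels encoder ladder of the main sub-network.
#' @param pre_channels encoder ladder of the pre-segmentation sub-network.
#' @param context_channels encoder ladder of the light context networks that
#'   process the (downsampled) large patches.
#' @param fuse_channels per-patch channels of the associated-information
#'   fusion conv.
#' @param fuse_out channels of the fused associated feature f_plt.
#' @param corr_channels per-patch channels of the correction conv; f_mlt has
#'   `5 * corr_channels` channels.
#' @param edge_channels hidden width of the edge branch.
#' @param aca_r reduction ratio of the coordinate-attention bottlenecks.
#' @param gsa_M,gsa_heads window side and head count of the bottleneck
#'   self-attention (heads default: one per 32 channels).
#' @param use_edge_branch,use_collaborative,use_aca,use_gsa ablation flags.
#' @return list of class `vs_mfnet_config`.
#' @export
mfnet_config <- function(geometry = patch_geometry(72L),
                         main_channels = c(32L, 64L, 128L, 256L),
                         pre_channels = c(16L, 32L, 64L),
                         context_channels = c(6L, 12L, 24L),
                         fuse_channels = 16L, fuse_out = 16L,
                         corr_channels = 8L, edge_channels = 8L,
                         aca_r = 8L, gsa_M = 6L,
                         gsa_heads = max(1L, main_channels[length(main_channels)] %/% 32L),
                         use_edge_branch = TRUE, use_collaborative = TRUE,
                         use_aca = TRUE, use_gsa = TRUE) {
  if (any(diff(main_channels) <= 0) || any(diff(pre_channels) <= 0) ||
      any(diff(context_channels) <= 0)) {
    stop("encoder channel ladders must be strictly increasing")
  }
  s <- geometry$s; l <- geometry$l; q <- geometry$context_scale
  if (bitwAnd(q, q - 1L) != 0L) stop("context_scale must be a power of 2")
  div_main <- 2L^(length(main_channels) - 1L)
  div_pre <- 2L^(length(pre_channels) - 1L)
  div_ctx <- 2L^(length(context_channels) - 1L)
  if (s %% div_main != 0L) stop("patch size s must be divisible by ", div_main)
  if (s %% div_pre != 0L) stop("patch size s must be divisible by ", div_pre)
  if (l %% (q * div_ctx) != 0L) {
    stop("large-patch size l must be divisible by context_scale * ", div_ctx)
  }
  if (any(geometry$placements %% q != 0L) || s %% q != 0L) {
    stop("placements and s must be divisible by context_scale (the cut ",
         "offsets must be integers at the context feature scale)")
  }
  mc <- main_channels[length(main_channels)]
  if (mc %% gsa_heads != 0L) stop("bottleneck channels must divide into heads")
  structure(list(geometry = geometry, main_channels = as.integer(main_channels),
                 pre_channels = as.integer(pre_channels),
                 context_channels = as.integer(context_channels),
                 fuse_channels = as.integer(fuse_channels),
                 fuse_out = as.integer(fuse_out),
                 corr_channels = as.integer(corr_channels),
                 edge_channels = as.integer(edge_channels),
                 aca_r = as.integer(aca_r), gsa_M = as.integer(gsa_M),
                 gsa_heads = as.integer(gsa_heads),
                 use_edge_branch = use_edge_branch,
                 use_collaborative = use_collaborative,
                 use_aca = use_aca, use_gsa = use_gsa),
            class = "vs_mfnet_config")
}

# ---- U-Net builder ---------------------------------------------------------

# Two 3x3 conv + ReLU layers per stage, 2x2 max-pool between encoder stages,
# nearest upsampling + skip concat in the decoder.  Optional coordinate
# attention after each encoder stage and self-attention at the bottleneck.
build_unet <- function(in_ch, channels, aca_r = NULL, gsa = NULL) {
  D <- length(channels)
  mods <- list()
  cin <- in_ch
  for (i in seq_len(D)) {
    mods[[paste0("enc", i, "a")]] <- conv_layer(cin, channels[i])
    mods[[paste0("enc", i, "b")]] <- conv_layer(channels[i], channels[i])
    if (!is.null(aca_r)) {
      mods[[paste0("aca", i)]] <- aca_block(channels[i], aca_r)
    }
    cin <- channels[i]
  }
  if (!is.null(gsa)) {
    mods$gsa <- gsa_block(channels[D], M = gsa$M, heads = gsa$heads)
  }
  for (i in seq.int(D - 1L, 1L)) {
    mods[[paste0("dec", i, "a")]] <- conv_layer(channels[i + 1L] + channels[i],
                                                channels[i])
    mods[[paste0("dec", i, "b")]] <- conv_layer(channels[i], channels[i])
  }
  vs_module(modules = mods, D = D, channels = channels, in_ch = in_ch,
            has_aca = !is.null(aca_r), has_gsa = !is.null(gsa), kind = "unet")
}

unet_forward <- function(net, x) {
  D <- net$D
  m <- net$modules
  skips <- vector("list", D)
  h <- x
  for (i in seq_len(D)) {
    h <- ag_relu(conv_fwd(m[[paste0("enc", i, "a")]], h))
    h <- ag_relu(conv_fwd(m[[paste0("enc", i, "b")]], h))
    if (net$has_aca) h <- aca_forward(m[[paste0("aca", i)]], h)
    skips[[i]] <- h
    if (i < D) h <- ag_maxpool2(h)
  }
  if (net$has_gsa) h <- gsa_forward(m$gsa, h)
  for (i in seq.int(D - 1L, 1L)) {
    h <- ag_upsample2(h)
    h <- ag_concat_c(list(h, skips[[i]]))
    h <- ag_relu(conv_fwd(m[[paste0("dec", i, "a")]], h))
    h <- ag_relu(conv_fwd(m[[paste0("dec", i, "b")]], h))
  }
  h   # (H, W, channels[1])
}

# Sobel-pair initialisation of the edge branch's first layer.
sobel_kernels <- function() {
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) / 8
  sy <- t(sx)
  K <- array(0, dim = c(3, 3, 1, 4))
  K[, , 1, 1] <- sx; K[, , 1, 2] <- -sx
  K[, , 1, 3] <- sy; K[, , 1, 4] <- -sy
  K
}

#' Build the multi-feature network
#'
#' Constructs all sub-networks and heads from a configuration.  Weight
#' initialisation consumes R's RNG stream; seed beforehand for
#' reproducibility.
#'
#' @param config a [mfnet_config()].
#' @return model (class `vs_mfnet`); run with [mfnet_forward()].
#' @export
build_mfnet <- function(config) {
  g <- config$geometry
  mods <- list()
  mods$pre <- build_unet(1L, config$pre_channels)
  mods$pre_head <- conv_layer(config$pre_channels[1], 1L, k = 1L)
  e <- conv_layer(1L, 4L)
  e$params$W$value <- sobel_kernels()
  e$params$b$value <- numeric(4)
  mods$edge1 <- e
  mods$edge2 <- conv_layer(4L, config$edge_channels)
  mods$edge3 <- conv_layer(config$edge_channels, 1L, k = 1L)
  mods$ctx_pre <- build_unet(1L, config$context_channels)
  mods$ctx_pre_head <- conv_layer(config$context_channels[1], 1L, k = 1L)
  mods$fuse_conv <- conv_layer(config$context_channels[1], config$fuse_channels)
  mods$fuse_ca <- se_block(5L * config$fuse_channels, r = 4L)
  mods$fuse_out <- conv_layer(5L * config$fuse_channels, config$fuse_out, k = 1L)
  mods$ctx_main <- build_unet(config$context_channels[1], config$context_channels)
  mods$ctx_main_head <- conv_layer(config$corr_channels, 1L, k = 1L)
  mods$corr_conv <- conv_layer(config$context_channels[1], config$corr_channels)
  mods$corr_ca <- se_block(5L * config$corr_channels, r = 4L)
  main_in <- 1L + config$pre_channels[1] + config$fuse_out + 1L
  mods$main <- build_unet(main_in, config$main_channels,
                          aca_r = if (config$use_aca) config$aca_r else NULL,
                          gsa = if (config$use_gsa) {
                            list(M = config$gsa_M, heads = config$gsa_heads)
                          } else NULL)
  mods$final1 <- conv_layer(config$main_channels[1] + 5L * config$corr_channels,
                            config$main_channels[1])
  mods$final2 <- conv_layer(config$main_channels[1], 1L, k = 1L)
  structure(vs_module(modules = mods, config = config), class = c("vs_mfnet", "vs_module"))
}

#' @export
print.vs_mfnet <- function(x, ...) {
  cat(sprintf("<vs_mfnet s=%d l=%d params=%s aca=%s gsa=%s collab=%s edge=%s>\n",
              x$config$geometry$s, x$config$geometry$l,
              format(n_params(x), big.mark = ","),
              x$config$use_aca, x$config$use_gsa,
              x$config$use_collaborative, x$config$use_edge_branch))
  invisible(x)
}

# Block-mean downsampling of a (H,W) matrix by integer factor q (plain data
# path; the large-patch pixels are inputs, not learnable).
downsample_mean <- function(m, q) {
  H <- nrow(m); W <- ncol(m)
  stopifnot(H %% q == 0L, W %% q == 0L)
  x <- array(m, dim = c(q, H %/% q, q, W %/% q))
  colMeans(aperm(x, c(1, 3, 2, 4)), dims = 2)
}

as_hw1 <- function(m) { a <- as.numeric(m); dim(a) <- c(nrow(m), ncol(m), 1L); a }

upsample_by <- function(t, q) {
  while (q > 1L) { t <- ag_upsample2(t); q <- q %/% 2L }
  t
}

#' Forward pass over one collaborative patch set
#'
#' Runs the pre-segmentation network on the small patch and (when the
#' collaborative path is on) the context networks on the five large patches,
#' fuses the associated features, runs the edge branch and the attention-
#' equipped main network, and applies the correction head.
#'
#' @param model from [build_mfnet()].
#' @param patch_set a `vs_patch_set` (see [extract_collaborative()]) holding
#'   preprocessed [0,1] pixels.
#' @param collaborative override of `config$use_collaborative` (used by the
#'   ablation harness).
#' @return a "forward bundle" list: `S_s` (s x s final probability), `S_l`
#'   (list of five l x l auxiliary probabilities or NULL), `pre_prob`
#'   (s x s pre-segmentation probability), `pre_prob_l` (list or NULL),
#'   `edge_map` (s x s), `f_plt`, `f_mlt` feature tensors, and -- while a
#'   tape is recording -- the underlying `ag_tensor`s for loss building.
#' @export
mfnet_forward <- function(model, patch_set, collaborative = NULL) {
  cfg <- model$config
  g <- cfg$geometry
  s <- g$s; l <- g$l; q <- g$context_scale
  collab <- collaborative %||% cfg$use_collaborative
  m <- model$modules
  sp <- ag_tensor(as_hw1(patch_set$small))

  f_pre <- unet_forward(m$pre, sp)
  pre_prob <- ag_sigmoid(conv_fwd(m$pre_head, f_pre))

  if (cfg$use_edge_branch) {
    eh <- ag_relu(conv_fwd(m$edge1, sp))
    eh <- ag_relu(conv_fwd(m$edge2, eh))
    edge_map <- ag_sigmoid(conv_fwd(m$edge3, eh))
  } else {
    edge_map <- ag_tensor(array(0, dim = c(s, s, 1L)))
  }

  sq <- s %/% q
  if (collab) {
    f_pl <- vector("list", 5L)
    pre_prob_l <- vector("list", 5L)
    fuse_cut <- vector("list", 5L)
    for (i in 1:5) {
      lg <- ag_tensor(as_hw1(downsample_mean(patch_set$larges[[i]], q)))
      f_pl[[i]] <- unet_forward(m$ctx_pre, lg)
      pre_prob_l[[i]] <- upsample_by(ag_sigmoid(conv_fwd(m$ctx_pre_head, f_pl[[i]])), q)
      fc <- ag_relu(conv_fwd(m$fuse_conv, f_pl[[i]]))
      off <- patch_set$offsets[i, ] %/% q
      fuse_cut[[i]] <- ag_crop_hw(fc, off[1] + 1L, off[2] + 1L, sq, sq)
    }
    fused <- ag_concat_c(fuse_cut)
    fused <- se_forward(m$fuse_ca, fused)
    f_plt <- upsample_by(ag_relu(conv_fwd(m$fuse_out, fused)), q)

    f_ml <- vector("list", 5L)
    S_l <- vector("list", 5L)
    corr_cut <- vector("list", 5L)
    for (i in 1:5) {
      f_ml[[i]] <- unet_forward(m$ctx_main, f_pl[[i]])
      fm <- ag_relu(conv_fwd(m$corr_conv, f_ml[[i]]))
      S_l[[i]] <- upsample_by(ag_sigmoid(conv_fwd(m$ctx_main_head, fm)), q)
      off <- patch_set$offsets[i, ] %/% q
      corr_cut[[i]] <- ag_crop_hw(fm, off[1] + 1L, off[2] + 1L, sq, sq)
    }
    corr <- ag_concat_c(corr_cut)
    corr <- se_forward(m$corr_ca, corr)
    f_mlt <- upsample_by(corr, q)
  } else {
    f_plt <- ag_tensor(array(0, dim = c(s, s, cfg$fuse_out)))
    f_mlt <- ag_tensor(array(0, dim = c(s, s, 5L * cfg$corr_channels)))
    pre_prob_l <- NULL
    S_l <- NULL
  }

  main_in <- ag_concat_c(list(sp, f_pre, f_plt, edge_map))
  f_ms <- unet_forward(m$main, main_in)

  h <- ag_relu(conv_fwd(m$final1, ag_concat_c(list(f_ms, f_mlt))))
  S_s <- ag_sigmoid(conv_fwd(m$final2, h))

  list(S_s = S_s, S_l = S_l, pre_prob = pre_prob, pre_prob_l = pre_prob_l,
       edge_map = edge_map, f_plt = f_plt, f_mlt = f_mlt, f_ms = f_ms,
       collaborative = collab)
}

# Plain-array view of a bundle (probabilities as matrices).
bundle_values <- function(bundle) {
  drop2 <- function(t) { v <- ag_val(t); dim(v) <- dim(v)[1:2]; v }
  list(S_s = drop2(bundle$S_s),
       S_l = if (!is.null(bundle$S_l)) lapply(bundle$S_l, drop2) else NULL,
       pre_prob = drop2(bundle$pre_prob),
       pre_prob_l = if (!is.null(bundle$pre_prob_l)) lapply(bundle$pre_prob_l, drop2) else NULL,
       edge_map = drop2(bundle$edge_map))
}

# ---- static compute profile ------------------------------------------------

conv_macs <- function(k, cin, cout, h, w) as.numeric(k)^2 * cin * cout * h * w

unet_macs <- function(in_ch, channels, H, W, aca_r = NULL, gsa = NULL) {
  D <- length(channels)
  macs <- 0; act <- 0
  cin <- in_ch; h <- H; w <- W
  for (i in seq_len(D)) {
    macs <- macs + conv_macs(3, cin, channels[i], h, w) +
      conv_macs(3, channels[i], channels[i], h, w)
    act <- act + 2 * h * w * channels[i]
    if (!is.null(aca_r)) {
      Cr <- max(1, ceiling(channels[i] / aca_r))
      macs <- macs + (h + w) * channels[i] * Cr * 2 +  # shared F1, two branches
        (h + w) * Cr * channels[i]                     # Fh / Fw
      act <- act + h * w * channels[i]
    }
    cin <- channels[i]
    if (i < D) { h <- h %/% 2L; w <- w %/% 2L }
  }
  if (!is.null(gsa)) {
    M <- gsa$M
    hp <- ceiling(h / M) * M; wp <- ceiling(w / M) * M
    n <- hp * wp; C <- channels[D]
    per_block <- n * C * 3 * C + n * C * C +      # qkv + proj
      2 * (hp * wp / (M * M)) * (M^2 * M^2 * C) + # QK^t and AV over windows
      n * C * 4 * C * 2                           # MLP
    macs <- macs + 2 * per_block
    act <- act + 4 * n * C
  }
  for (i in seq.int(D - 1L, 1L)) {
    h <- h * 2L; w <- w * 2L
    macs <- macs + conv_macs(3, channels[i + 1L] + channels[i], channels[i], h, w) +
      conv_macs(3, channels[i], channels[i], h, w)
    act <- act + 2 * h * w * channels[i]
  }
  list(macs = macs, act = act)
}

unet_params <- function(in_ch, channels, aca_r = NULL, gsa = NULL) {
  D <- length(channels)
  p <- 0; cin <- in_ch
  for (i in seq_len(D)) {
    p <- p + 9 * cin * channels[i] + channels[i] + 9 * channels[i]^2 + channels[i]
    if (!is.null(aca_r)) {
      Cr <- max(1, ceiling(channels[i] / aca_r))
      p <- p + channels[i] * Cr + Cr + 2 * (Cr * channels[i] + channels[i]) + 2
    }
    cin <- channels[i]
  }
  if (!is.null(gsa)) {
    C <- channels[D]; M <- gsa$M
    per <- 2 * 2 * C +                         # two LayerNorms
      C * 3 * C + 3 * C + C * C + C +          # qkv + proj
      C * 4 * C + 4 * C + 4 * C * C + C +      # MLP
      gsa$heads * (2 * M - 1)^2 + 1            # bias tables + gate
    p <- p + 2 * per
  }
  for (i in seq.int(D - 1L, 1L)) {
    p <- p + 9 * (channels[i + 1L] + channels[i]) * channels[i] + channels[i] +
      9 * channels[i]^2 + channels[i]
  }
  p
}

#' Static compute profile of the network
#'
#' Deterministic closed-form multiply-accumulate (MAC), parameter and
#' activation-memory counts for one forward pass.  Three regimes:
#' `"single"` -- the small patch alone through pre + edge + main + head (the
#' non-collaborative forward); `"collaborative"` -- additionally the five
#' large patches through the context networks with fusion and correction;
#' `"whole"` -- the single-patch architecture applied to a full image of the
#' given size (spatial dims are padded up to the required divisibility).
#'
#' @param config a [mfnet_config()].
#' @param regime one of `"single"`, `"collaborative"`, `"whole"`.
#' @param input_shape c(H, W); defaults to the geometry's patch size, or the
#'   image size for `"whole"`.
#' @return list with `flops` (MACs), `params`, `activation_memory` (floats).
#' @export
count_flops_params <- function(config,
                               regime = c("collaborative", "single", "whole"),
                               input_shape = NULL) {
  regime <- match.arg(regime)
  g <- config$geometry
  s <- g$s; l <- g$l; q <- g$context_scale
  aca <- if (config$use_aca) config$aca_r else NULL
  gsa <- if (config$use_gsa) list(M = config$gsa_M, heads = config$gsa_heads) else NULL
  main_in <- 1L + config$pre_channels[1] + config$fuse_out + 1L
  cpre1 <- config$context_channels[1]

  small_path <- function(H, W) {
    pre <- unet_macs(1, config$pre_channels, H, W)
    mn <- unet_macs(main_in, config$main_channels, H, W, aca, gsa)
    macs <- pre$macs + mn$macs + conv_macs(1, config$pre_channels[1], 1, H, W)
    act <- pre$act + mn$act
    if (config$use_edge_branch) {
      macs <- macs + conv_macs(3, 1, 4, H, W) +
        conv_macs(3, 4, config$edge_channels, H, W) +
        conv_macs(1, config$edge_channels, 1, H, W)
      act <- act + H * W * (4 + config$edge_channels + 1)
    }
    macs <- macs + conv_macs(3, config$main_channels[1] + 5 * config$corr_channels,
                             config$main_channels[1], H, W) +
      conv_macs(1, config$main_channels[1], 1, H, W)
    act <- act + H * W * (config$main_channels[1] + 1)
    list(macs = macs, act = act)
  }

  params <- unet_params(1, config$pre_channels) +
    1 * config$pre_channels[1] + 1 +
    unet_params(main_in, config$main_channels, aca, gsa) +
    (9 * 1 * 4 + 4) + (9 * 4 * config$edge_channels + config$edge_channels) +
    (config$edge_channels + 1) +
    unet_params(1, config$context_channels) +
    cpre1 + 1 +
    unet_params(cpre1, config$context_channels) +
    (9 * cpre1 * config$fuse_channels + config$fuse_channels) +
    se_params(5 * config$fuse_channels, 4) +
    (5 * config$fuse_channels * config$fuse_out + config$fuse_out) +
    (9 * cpre1 * config$corr_channels + config$corr_channels) +
    (config$corr_channels + 1) +
    se_params(5 * config$corr_channels, 4) +
    (9 * (config$main_channels[1] + 5 * config$corr_channels) *
       config$main_channels[1] + config$main_channels[1]) +
    (config$main_channels[1] + 1)

  if (regime == "whole") {
    hw <- input_shape %||% c(584L, 565L)
    div <- 2L^(max(length(config$main_channels), length(config$pre_channels)) - 1L)
    H <- as.integer(ceiling(hw[1] / div) * div)
    W <- as.integer(ceiling(hw[2] / div) * div)
    sp <- small_path(H, W)
    return(list(flops = sp$macs, params = params, activation_memory = sp$act))
  }

  hw <- input_shape %||% c(s, s)
  sp <- small_path(hw[1], hw[2])
  if (regime == "single") {
    return(list(flops = sp$macs, params = params, activation_memory = sp$act))
  }

  lq <- l %/% q; sq <- s %/% q
  ctx_pre <- unet_macs(1, config$context_channels, lq, lq)
  ctx_main <- unet_macs(cpre1, config$context_channels, lq, lq)
  per_large <- ctx_pre$macs + ctx_main$macs +
    conv_macs(1, cpre1, 1, lq, lq) +                       # ctx pre head
    conv_macs(3, cpre1, config$fuse_channels, lq, lq) +    # fusion conv
    conv_macs(3, cpre1, config$corr_channels, lq, lq) +    # correction conv
    conv_macs(1, config$corr_channels, 1, lq, lq)          # aux head
  fuse <- conv_macs(1, 5 * config$fuse_channels, config$fuse_out, sq, sq) +
    se_macs(5 * config$fuse_channels, 4) + se_macs(5 * config$corr_channels, 4)
  macs <- sp$macs + 5 * per_large + fuse
  act <- sp$act + 5 * (ctx_pre$act + ctx_main$act +
                         lq * lq * (config$fuse_channels + config$corr_channels)) +
    sq * sq * (5 * config$fuse_channels + config$fuse_out + 5 * config$corr_channels)
  list(flops = macs, params = params, activation_memory = act)
}

se_params <- function(C, r) {
  Cr <- max(1, ceiling(C / r))
  C * Cr + Cr + Cr * C + C
}

se_macs <- function(C, r) {
  Cr <- max(1, ceiling(C / r))
  C * Cr + Cr * C
}
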