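# Network assembly: U-Net contracts, edge branch, fusion/correction paths,
# full forward bundle and the static compute profile.

test_that("pre-segmentation U-Net is a fully convolutional sigmoid head", {
  set.seed(51)
  net <- build_unet(1L, c(4L, 8L))
  head <- vesselseg:::conv_layer(4L, 1L, k = 1L)
  fwd <- function(hw) {
    x <- ag_tensor(array(runif(hw * hw), c(hw, hw, 1)))
    f <- unet_forward(net, x)
    list(f = ag_val(f), p = ag_val(ag_sigmoid(conv_fwd(head, f))))
  }
  a <- fwd(16)
  expect_equal(dim(a$f), c(16, 16, 4))       # same spatial size as the input
  expect_true(all(a$p >= 0 & a$p <= 1))
  b <- fwd(32)                               # doubling input doubles output
  expect_equal(dim(b$p), c(32, 32, 1))
})

test_that("edge branch responds on a step edge and is silent on constants", {
  set.seed(52)
  cfg <- smoke_config()
  mdl <- build_mfnet(cfg)
  m <- mdl$modules
  edge_fwd <- function(img) {
    x <- ag_tensor(array(img, c(dim(img), 1)))
    h <- ag_relu(conv_fwd(m$edge1, x))
    list(first = ag_val(h),
         out = ag_val(ag_sigmoid(conv_fwd(m$edge3, ag_relu(conv_fwd(m$edge2, h))))))
  }
  # Sobel first layer: derivative of a constant is exactly zero away from
  # the zero-padded border
  cst <- edge_fwd(matrix(0.7, 16, 16))
  expect_true(all(abs(cst$first[2:15, 2:15, ]) < 1e-12))
  # step edge: mean |first-layer response| larger on the edge than off it
  step <- matrix(0.2, 16, 16); step[, 9:16] <- 0.8
  r <- edge_fwd(step)
  on_edge <- abs(r$first[2:15, 8:9, ])
  off_edge <- abs(r$first[2:15, c(3:6, 11:14), ])
  expect_gt(mean(on_edge), mean(off_edge) + 0.05)
  expect_true(all(r$out >= 0 & r$out <= 1))
  expect_equal(dim(r$out), c(16, 16, 1))
})

test_that("fusion path is permutation-symmetric for identical inputs and linear in zeros", {
  set.seed(53)
  cfg <- smoke_config()
  mdl <- build_mfnet(cfg)
  rec <- tiny_record()
  geo <- cfg$geometry
  ps <- extract_collaborative(rec$image, c(20L, 20L), geo)
  # five identical large patches -> f_plt invariant to their order
  ps_same <- ps
  for (i in 1:5) ps_same$larges[[i]] <- ps$larges[[1]]
  b1 <- mfnet_forward(mdl, ps_same)
  ps_perm <- ps_same
  ps_perm$larges <- ps_same$larges[c(3, 1, 5, 2, 4)]
  # permuting identical inputs cannot change the fused feature
  b2 <- mfnet_forward(mdl, ps_perm)
  expect_equal(ag_val(b1$f_plt), ag_val(b2$f_plt), tolerance = 1e-12)
})

test_that("the full forward bundle satisfies its contracts", {
  set.seed(54)
  cfg <- smoke_config()
  mdl <- build_mfnet(cfg)
  rec <- tiny_record()
  ps <- extract_collaborative(rec$image, c(24L, 16L), cfg$geometry)
  b <- mfnet_forward(mdl, ps)
  v <- bundle_values(b)
  s <- cfg$geometry$s; l <- cfg$geometry$l
  expect_equal(dim(v$S_s), c(s, s))
  expect_true(all(v$S_s >= 0 & v$S_s <= 1))
  expect_equal(length(v$S_l), 5)
  for (i in 1:5) {
    expect_equal(dim(v$S_l[[i]]), c(l, l))
    expect_true(all(v$S_l[[i]] >= 0 & v$S_l[[i]] <= 1))
  }
  expect_true(all(v$pre_prob >= 0 & v$pre_prob <= 1))
  expect_true(all(v$edge_map >= 0 & v$edge_map <= 1))
  # eval-mode determinism
  b2 <- mfnet_forward(mdl, ps)
  expect_identical(v$S_s, bundle_values(b2)$S_s)
})

test_that("disabling the collaborative path keeps the output contract", {
  set.seed(55)
  cfg <- smoke_config(use_collaborative = FALSE)
  mdl <- build_mfnet(cfg)
  rec <- tiny_record()
  ps <- extract_collaborative(rec$image, c(0L, 0L), cfg$geometry)
  b <- mfnet_forward(mdl, ps)
  v <- bundle_values(b)
  expect_equal(dim(v$S_s), c(48, 48))
  expect_null(v$S_l)
  expect_true(all(ag_val(b$f_mlt) == 0))
})

test_that("gradients reach every learnable parameter from the composite loss", {
  set.seed(56)
  cfg <- smoke_config()
  mdl <- build_mfnet(cfg)
  rec <- tiny_record()
  ex <- vesselseg:::make_training_example(rec, c(12L, 12L), cfg$geometry)
  params <- collect_params(mdl)
  vesselseg:::zero_grads(params)
  ag_record()
  b <- mfnet_forward(mdl, ex$patch_set)
  L <- build_loss(b, ex$targets, train_config())
  ag_backward(L)
  missing <- names(params)[vapply(params, function(p) is.null(p$grad),
                                  logical(1))]
  expect_identical(missing, character(0))
  nonzero <- vapply(params, function(p) any(p$grad != 0), logical(1))
  expect_gt(mean(nonzero), 0.98)
})

test_that("batched forwards are independent: permuting inputs permutes outputs", {
  set.seed(57)
  cfg <- smoke_config()
  mdl <- build_mfnet(cfg)
  rec <- tiny_record()
  origins <- list(c(0L, 0L), c(24L, 24L), c(48L, 40L))
  pss <- lapply(origins, function(o) extract_collaborative(rec$image, o, cfg$geometry))
  outs <- lapply(pss, function(p) bundle_values(mfnet_forward(mdl, p))$S_s)
  outs_perm <- lapply(pss[c(3, 1, 2)], function(p) bundle_values(mfnet_forward(mdl, p))$S_s)
  expect_identical(outs[[3]], outs_perm[[1]])
  expect_identical(outs[[1]], outs_perm[[2]])
})

test_that("static counts: closed form for a single conv and invariances", {
  # a single 3x3 conv 1 -> 32 on 72x72: 320 params, 9*1*32*72*72 MACs
  expect_equal(vesselseg:::conv_macs(3, 1, 32, 72, 72), 9 * 32 * 72 * 72)
  expect_equal(9 * 1 * 32 + 32, 320)
  cfg <- mfnet_config()
  c1 <- count_flops_params(cfg, "collaborative")
  c2 <- count_flops_params(cfg, "collaborative")
  expect_identical(c1, c2)                          # deterministic
  s1 <- count_flops_params(cfg, "single")
  w1 <- count_flops_params(cfg, "whole", input_shape = c(584, 565))
  expect_identical(s1$params, c1$params)            # params input-size free
  expect_identical(s1$params, w1$params)
  expect_gt(w1$flops, s1$flops)
})

test_that("analytic parameter count matches the built model", {
  set.seed(58)
  cfg <- smoke_config()
  mdl <- build_mfnet(cfg)
  expect_equal(count_flops_params(cfg, "single")$params, n_params(mdl))
})

test_that("checkpoint save/load round-trips parameters and predictions", {
  set.seed(59)
  cfg <- smoke_config()
  mdl <- build_mfnet(cfg)
  rec <- tiny_record()
  ps <- extract_collaborative(rec$image, c(10L, 30L), cfg$geometry)
  before <- bundle_values(mfnet_forward(mdl, ps))$S_s
  f <- tempfile(fileext = ".json")
  save_checkpoint(mdl, f)
  mdl2 <- load_checkpoint(f)
  after <- bundle_values(mfnet_forward(mdl2, ps))$S_s
  expect_equal(after, before, tolerance = 1e-12)
  unlink(f)
})
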