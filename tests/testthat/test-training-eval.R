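# Loss, schedule, metrics (with the pairwise AUC oracle) and short training
# behaviour.

test_that("learning-rate schedule follows the published decay arithmetic", {
  expect_equal(lr_schedule(0, 0.0025, 0.8, 20), 0.0025)
  expect_equal(lr_schedule(8, 0.002, 0.8, 8), 0.0016)
  expect_equal(lr_schedule(39, 0.0025, 0.8, 20), 0.0025 * 0.8)
  expect_equal(lr_schedule(40, 0.0025, 0.8, 20), 0.0025 * 0.8^2)
})

test_that("composite loss is near zero for perfect predictions and ln 2 + const at 0.5", {
  set.seed(61)
  s <- 8
  gt <- matrix(rbinom(s * s, 1, 0.5), s, s)
  mk <- function(p) ag_tensor(array(p, c(s, s, 1)))
  bundle <- list(S_s = mk(ifelse(gt > 0, 1 - 1e-9, 1e-9)), S_l = NULL,
                 pre_prob = mk(ifelse(gt > 0, 1 - 1e-9, 1e-9)),
                 pre_prob_l = NULL, edge_map = mk(0.5))
  tc <- train_config(lambda_edge = 0, lambda_large = 0)
  L <- build_loss(bundle, list(small_gt = gt), tc)
  expect_lt(ag_val(L), 1e-4)
  # uniform 0.5 on balanced targets: BCE component is exactly ln 2
  gt_bal <- matrix(rep(c(0, 1), s * s / 2), s, s)
  b2 <- list(S_s = mk(0.5), S_l = NULL, pre_prob = mk(0.5),
             pre_prob_l = NULL, edge_map = mk(0.5))
  tc2 <- train_config(lambda_pre = 0, lambda_edge = 0, lambda_large = 0)
  L2 <- ag_val(build_loss(b2, list(small_gt = gt_bal), tc2))
  dice_at_half <- 1 - (2 * sum(0.5 * gt_bal) + 1) / (sum(0.5) * s * s + sum(gt_bal) + 1)
  expect_equal(L2, log(2) + dice_at_half, tolerance = 1e-9)
})

test_that("loss decreases over 20 optimizer steps on one fixed batch", {
  set.seed(62)
  cfg <- smoke_config()
  mdl <- build_mfnet(cfg)
  rec <- tiny_record()
  ex <- vesselseg:::make_training_example(rec, c(24L, 24L), cfg$geometry)
  params <- collect_params(mdl)
  opt <- adam_optimizer(params, lr = 0.0025)
  losses <- numeric(20)
  for (i in 1:20) {
    vesselseg:::zero_grads(params)
    ag_record()
    b <- mfnet_forward(mdl, ex$patch_set)
    L <- build_loss(b, ex$targets, train_config())
    losses[i] <- ag_val(L)
    ag_backward(L)
    adam_step(opt)
  }
  expect_lt(losses[20], losses[1])
  expect_true(all(is.finite(losses)))
})

test_that("confusion counts and metrics reproduce the closed forms", {
  # hand case: TP=8 FP=2 TN=85 FN=5 on a 10x10 full-FOV image
  prob <- matrix(0, 10, 10)
  gt <- matrix(0, 10, 10)
  gt[1:13] <- 1
  prob[1:8] <- 0.9          # 8 true positives
  prob[14:15] <- 0.9        # 2 false positives
  m <- compute_metrics(prob, gt, matrix(1, 10, 10), 0.5)
  expect_equal(m$counts, list(TP = 8L, FP = 2L, TN = 85L, FN = 5L),
               tolerance = 0)
  expect_equal(m$SE, 8 / 13, tolerance = 1e-12)
  expect_equal(m$SP, 85 / 87, tolerance = 1e-12)
  expect_equal(m$ACC, 0.93, tolerance = 1e-12)
  expect_equal(m$F1, 16 / 23, tolerance = 1e-12)
  # perfect classifier
  p2 <- gt
  m2 <- compute_metrics(p2, gt, matrix(1, 10, 10), 0.5)
  expect_equal(unlist(m2[c("ACC", "SE", "SP", "F1", "AUC")]),
               c(ACC = 1, SE = 1, SP = 1, F1 = 1, AUC = 1))
})

test_that("metrics only count FOV pixels", {
  prob <- matrix(1, 6, 6)         # everything called vessel...
  gt <- matrix(0, 6, 6)
  gt[, 1:3] <- 1
  fov <- matrix(0, 6, 6)
  fov[, 1:3] <- 1                 # ...but only vessel columns are in FOV
  m <- suppressWarnings(compute_metrics(prob, gt, fov))
  expect_equal(m$SE, 1)
  expect_equal(m$ACC, 1)
  expect_true(is.nan(m$AUC))      # single-class inside FOV
  expect_error(compute_metrics(prob, gt, matrix(0, 6, 6)), "empty")
})

test_that("AUC equals the O(n^2) pairwise concordance oracle, with ties", {
  set.seed(63)
  for (rep in 1:5) {
    n <- 200
    labels <- rbinom(n, 1, 0.4)
    scores <- round(runif(n), 2)         # duplicates force tie handling
    prob <- matrix(scores, 10, 20)
    gt <- matrix(labels, 10, 20)
    m <- compute_metrics(prob, gt, matrix(1, 10, 20))
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    conc <- 0
    for (a in pos) conc <- conc + sum(a > neg) + 0.5 * sum(a == neg)
    expect_equal(m$AUC, conc / (length(pos) * length(neg)), tolerance = 1e-9)
  }
  # independent cross-check against pROC
  skip_if_not_installed("pROC")
  set.seed(630)
  scores <- runif(300); labels <- rbinom(300, 1, 0.35)
  m <- compute_metrics(matrix(scores, 15, 20), matrix(labels, 15, 20),
                       matrix(1, 15, 20))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(m$AUC, ref, tolerance = 1e-9)
})

test_that("metric identities hold on 500 random confusion configurations", {
  set.seed(64)
  for (i in 1:500) {
    cc <- as.list(rmultinom(1, 400, runif(4, 0.05, 1))[, 1])
    names(cc) <- c("TP", "FP", "TN", "FN")
    P <- cc$TP + cc$FN; N <- cc$TN + cc$FP
    ACC <- (cc$TP + cc$TN) / 400
    SE <- cc$TP / P; SP <- cc$TN / N
    F1 <- 2 * cc$TP / (2 * cc$TP + cc$FN + cc$FP)
    # ACC = (SE*P + SP*N) / (P+N)
    expect_equal(ACC, (SE * P + SP * N) / (P + N), tolerance = 1e-12)
    # F1 from counts is consistent with precision/recall harmonic mean
    prec <- cc$TP / (cc$TP + cc$FP)
    if (is.finite(prec) && prec + SE > 0) {
      expect_equal(F1, 2 * prec * SE / (prec + SE), tolerance = 1e-12)
    }
  }
})

test_that("AUC is invariant under strictly monotone transforms and threshold sweeps are monotone", {
  set.seed(65)
  prob <- matrix(runif(400), 20, 20)
  gt <- matrix(rbinom(400, 1, 0.3), 20, 20)
  fov <- matrix(rbinom(400, 1, 0.9), 20, 20)
  m1 <- compute_metrics(prob, gt, fov)
  m2 <- compute_metrics(1 / (1 + exp(-6 * (prob - 0.5))), gt, fov)
  expect_equal(m1$AUC, m2$AUC, tolerance = 1e-12)
  ths <- seq(0.1, 0.9, by = 0.1)
  ms <- lapply(ths, function(t) compute_metrics(prob, gt, fov, t))
  se <- vapply(ms, `[[`, numeric(1), "SE")
  sp <- vapply(ms, `[[`, numeric(1), "SP")
  expect_true(all(diff(se) <= 1e-12))
  expect_true(all(diff(sp) >= -1e-12))
})

test_that("edge target is the morphological gradient: inside dilation, outside erosion", {
  set.seed(66)
  gt <- matrix(0, 20, 20); gt[5:15, 8:13] <- 1
  e <- edge_target(gt)
  k <- matrix(1, 3, 3)
  dil <- t(EBImage::imageData(EBImage::dilate(EBImage::as.Image(t(gt)), k)))
  ero <- t(EBImage::imageData(EBImage::erode(EBImage::as.Image(t(gt)), k)))
  expect_true(all(e <= dil))
  expect_true(all(e * ero == 0))
})

test_that("a 2-epoch run writes log and checkpoint and is seed-deterministic", {
  set.seed(67)
  cfg <- smoke_config()
  recs <- fixture_suite()$train[1:4]
  run_once <- function() {
    set.seed(99)
    mdl <- build_mfnet(cfg)
    d <- tempfile(); dir.create(d)
    fit <- train_mfnet(mdl, recs,
                       train_config(epochs = 2L, batch_size = 2L,
                                    patches_per_image = 1L, n_random = 1L,
                                    val_images = 1L, seed = 5L),
                       log_csv = file.path(d, "metrics.csv"),
                       checkpoint = file.path(d, "ckpt.json"))
    list(fit = fit, dir = d)
  }
  r1 <- run_once()
  expect_true(file.exists(file.path(r1$dir, "metrics.csv")))
  expect_true(file.exists(file.path(r1$dir, "ckpt.json")))
  expect_equal(nrow(r1$fit$log), 2)
  r2 <- run_once()
  expect_equal(r1$fit$log$loss[1], r2$fit$log$loss[1], tolerance = 1e-12)
  unlink(c(r1$dir, r2$dir), recursive = TRUE)
  expect_error(train_mfnet(build_mfnet(cfg), list()), "empty")
})

test_that("the ablation harness trains variants under a shared seed and tabulates finite metrics", {
  recs <- lapply(1:4, function(i) {
    preprocess_record(generate_fundus(vessel_spec(image_size = c(96L, 96L),
                                                  n_trees = 3L, seed = 70 + i)))
  })
  tab <- run_ablation(recs[1:3], recs[4],
                      base_config = smoke_config(),
                      tconfig = train_config(epochs = 1L, batch_size = 2L,
                                             patches_per_image = 1L,
                                             n_random = 0L, val_images = 1L,
                                             seed = 3L),
                      variants = list(base = list(use_aca = FALSE, use_gsa = FALSE),
                                      aca_gsa = list(use_aca = TRUE, use_gsa = TRUE)))
  expect_equal(tab$variant, c("base", "aca_gsa"))
  expect_true(all(is.finite(tab$F1)))
  expect_true(all(is.finite(tab$ACC)))
  expect_lt(tab$params[1], tab$params[2])
})

test_that("ablation flags change parameter counts in the expected direction", {
  set.seed(68)
  n_full <- n_params(build_mfnet(smoke_config()))
  n_noaca <- n_params(build_mfnet(smoke_config(use_aca = FALSE)))
  n_nogsa <- n_params(build_mfnet(smoke_config(use_gsa = FALSE)))
  expect_lt(n_noaca, n_full)
  expect_lt(n_nogsa, n_full)
})
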