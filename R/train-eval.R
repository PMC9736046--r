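# Loss construction, the optimiser schedule, the training loop, tiled
# inference, and FOV-restricted evaluation metrics.

#' Training configuration
#'
#' Defaults follow the published schedule for DRIVE-style data: Adam,
#' initial learning rate 0.0025 decayed by 0.8 every 20 epochs, weight decay
#' 7e-6.  (The STARE-style schedule is lr 0.002 decayed every 8 epochs.)
#'
#' @param lr0 initial learning rate.
#' @param decay_factor multiplicative decay, in (0, 1].
#' @param decay_every epochs between decays.
#' @param weight_decay L2 coefficient on the Adam gradients.
#' @param epochs training epochs.
#' @param batch_size patch sets per optimiser step (gradient accumulation).
#' @param lambda_main,lambda_pre,lambda_large,lambda_edge loss weights of
#'   the final head, the pre-segmentation heads, the five auxiliary
#'   large-patch heads and the edge head.
#' @param patches_per_image grid patches sampled per image per epoch.
#' @param n_random extra random patch origins per image per epoch.
#' @param augment apply the training-time augmentations.
#' @param val_images images held out for checkpoint selection (by F1).
#' @param seed RNG seed controlling sampling and augmentation.
#' @return list of class `vs_train_config`.
#' @export
train_config <- function(lr0 = 0.0025, decay_factor = 0.8, decay_every = 20L,
                         weight_decay = 7e-6, epochs = 30L, batch_size = 8L,
                         lambda_main = 1, lambda_pre = 0.4, lambda_large = 0.2,
                         lambda_edge = 0.2, patches_per_image = 2L,
                         n_random = 1L, augment = TRUE, val_images = 2L,
                         seed = 1L) {
  stopifnot(lambda_main > 0, lambda_pre >= 0, lambda_large >= 0,
            lambda_edge >= 0, decay_factor > 0, decay_factor <= 1)
  structure(list(lr0 = lr0, decay_factor = decay_factor,
                 decay_every = as.integer(decay_every),
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lambda_main = lambda_main, lambda_pre = lambda_pre,
                 lambda_large = lambda_large, lambda_edge = lambda_edge,
                 patches_per_image = as.integer(patches_per_image),
                 n_random = as.integer(n_random), augment = augment,
                 val_images = as.integer(val_images), seed = as.integer(seed)),
            class = "vs_train_config")
}

#' Stepwise learning-rate schedule
#'
#' `lr = lr0 * decay_factor ^ floor(epoch / decay_every)` with 0-based
#' epochs.
#'
#' @param epoch 0-based epoch index.
#' @param lr0,decay_factor,decay_every schedule parameters.
#' @return the learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, lr0 = 0.0025, decay_factor = 0.8,
                        decay_every = 20L) {
  stopifnot(epoch >= 0)
  lr0 * decay_factor^(epoch %/% decay_every)
}

# Morphological gradient (dilation - erosion, 3x3 box) of a binary mask:
# the edge-branch supervision target.
#' Vessel-edge target from a binary vessel mask
#' @param mask binary (H, W) matrix.
#' @return binary (H, W) edge mask (dilation minus erosion, 3x3).
#' @export
edge_target <- function(mask) {
  k <- matrix(1, 3, 3)
  img <- EBImage::as.Image(t(mask))
  d <- EBImage::imageData(EBImage::dilate(img, k))
  e <- EBImage::imageData(EBImage::erode(img, k))
  out <- t(d - e)
  (out > 0.5) * 1
}

as_t3 <- function(m) { a <- as.numeric(m); dim(a) <- c(nrow(m), ncol(m), 1L); a }

#' Composite segmentation loss over one forward bundle
#'
#' `lambda_main L(S_s) + lambda_pre L(pre) + lambda_large sum L(S_li) +
#' lambda_edge L(edge)` with `L = BCE + Dice` (equal mix) per head.
#'
#' @param bundle forward bundle from [mfnet_forward()] (recorded on a tape
#'   when training).
#' @param targets list with `small_gt` (s x s), optional `large_gts` (list
#'   of five l x l masks) and `edge_gt` (s x s).
#' @param config a [train_config()] supplying the lambda weights.
#' @return scalar `ag_tensor` loss.
#' @export
build_loss <- function(bundle, targets, config = train_config()) {
  seg_loss <- function(p, t) ag_add(ag_bce(p, t), ag_dice_loss(p, t))
  check <- function(l, what) {
    if (!is.finite(ag_val(l))) stop("non-finite loss component: ", what)
    l
  }
  sg <- as_t3(targets$small_gt)
  L <- ag_scale(check(seg_loss(bundle$S_s, sg), "main head"), config$lambda_main)
  if (config$lambda_pre > 0) {
    Lp <- seg_loss(bundle$pre_prob, sg)
    if (!is.null(bundle$pre_prob_l) && !is.null(targets$large_gts)) {
      for (i in seq_along(bundle$pre_prob_l)) {
        Lp <- ag_add(Lp, ag_scale(seg_loss(bundle$pre_prob_l[[i]],
                                           as_t3(targets$large_gts[[i]])), 1 / 5))
      }
    }
    L <- ag_add(L, ag_scale(check(Lp, "pre-segmentation head"), config$lambda_pre))
  }
  if (config$lambda_large > 0 && !is.null(bundle$S_l) && !is.null(targets$large_gts)) {
    for (i in seq_along(bundle$S_l)) {
      L <- ag_add(L, ag_scale(check(seg_loss(bundle$S_l[[i]],
                                             as_t3(targets$large_gts[[i]])),
                                    paste0("large-patch head ", i)),
                              config$lambda_large))
    }
  }
  if (config$lambda_edge > 0 && !is.null(targets$edge_gt)) {
    L <- ag_add(L, ag_scale(check(seg_loss(bundle$edge_map,
                                           as_t3(targets$edge_gt)),
                                  "edge head"), config$lambda_edge))
  }
  L
}

# Build the (patch set, targets) pair for one origin of one record.
make_training_example <- function(record, origin, geometry, edge_gt = NULL) {
  ps <- extract_collaborative(record$image, origin, geometry)
  gt_ps <- extract_collaborative(record$vessel_gt, origin, geometry)
  if (is.null(edge_gt)) edge_gt <- edge_target(record$vessel_gt)
  ed_ps <- extract_collaborative(edge_gt, origin, geometry)
  list(patch_set = ps,
       targets = list(small_gt = gt_ps$small, large_gts = gt_ps$larges,
                      edge_gt = ed_ps$small))
}

#' Train the network
#'
#' Adam with the stepwise learning-rate schedule and L2 weight decay;
#' gradient accumulation over `batch_size` patch sets per step.  Each epoch
#' samples a fresh grid (+ random origins) per training image, with
#' augmentation.  The best checkpoint by validation F1 (held-out images) is
#' kept; per-epoch loss/metrics are returned and optionally written as CSV.
#'
#' @param model from [build_mfnet()].
#' @param records list of preprocessed `vs_record`s with vessel ground truth
#'   (see [preprocess_record()]).
#' @param config a [train_config()].
#' @param log_csv optional path for the per-epoch log.
#' @param checkpoint optional path (JSON) for the best parameters.
#' @param verbose print per-epoch progress.
#' @return list: `model` (with the best parameters restored), `log`
#'   (data.frame epoch/lr/loss/val_f1), `best_epoch`.
#' @export
train_mfnet <- function(model, records, config = train_config(),
                        log_csv = NULL, checkpoint = NULL, verbose = FALSE) {
  if (!length(records)) stop("empty training dataset")
  geometry <- model$config$geometry
  n_val <- min(config$val_images, length(records) - 1L)
  val_recs <- if (n_val > 0) records[seq_len(n_val)] else list()
  tr_recs <- if (n_val > 0) records[-seq_len(n_val)] else records
  params <- collect_params(model)
  opt <- adam_optimizer(params, lr = config$lr0,
                        weight_decay = config$weight_decay)
  pcfg <- preprocess_config()
  edge_gts <- lapply(tr_recs, function(r) edge_target(r$vessel_gt))

  log <- data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
                    val_f1 = numeric())
  best <- list(f1 = -Inf, params = NULL, epoch = NA_integer_)
  last_good <- params_to_list(params)

  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- lr_schedule(epoch, config$lr0, config$decay_factor, config$decay_every)
    examples <- list()
    for (ri in seq_along(tr_recs)) {
      rec <- tr_recs[[ri]]
      ex_seed <- config$seed + 1009L * epoch + 101L * ri
      if (config$augment) {
        aug <- augment(rec$image, rec$vessel_gt, rec$fov, pcfg, seed = ex_seed)
        rec <- list(image = aug$image, vessel_gt = aug$vessel_gt,
                    fov = aug$fov)
        edge_gt <- edge_target(rec$vessel_gt)
      } else {
        edge_gt <- edge_gts[[ri]]
      }
      s <- geometry$s
      origins <- sample_training_grid(dim(rec$image), s, s,
                                      n_random = config$n_random,
                                      fov = rec$fov, seed = ex_seed)
      # train on informative patches: the target region must lie mostly
      # inside the FOV, otherwise the out-of-FOV darkness (labelled
      # background) drowns out the vessel signal
      if (!is.null(rec$fov)) {
        keep <- vapply(seq_len(nrow(origins)), function(k) {
          o <- origins[k, ]
          mean(rec$fov[o[1] + 1:s, o[2] + 1:s]) >= 0.5
        }, logical(1))
        if (any(keep)) origins <- origins[keep, , drop = FALSE]
      }
      origins <- with_preserved_seed(ex_seed, {
        origins[sample.int(nrow(origins),
                           min(nrow(origins),
                               config$patches_per_image + config$n_random)), ,
                drop = FALSE]
      })
      for (k in seq_len(nrow(origins))) {
        examples[[length(examples) + 1L]] <-
          make_training_example(rec, origins[k, ], geometry, edge_gt)
      }
    }
    examples <- with_preserved_seed(config$seed + epoch,
                                    examples[sample.int(length(examples))])
    ep_loss <- 0
    nb <- 0L
    i <- 1L
    while (i <= length(examples)) {
      j <- min(i + config$batch_size - 1L, length(examples))
      zero_grads(params)
      bl <- 0
      for (k in i:j) {
        ex <- examples[[k]]
        ag_record()
        bundle <- mfnet_forward(model, ex$patch_set)
        L <- ag_scale(build_loss(bundle, ex$targets, config), 1 / (j - i + 1L))
        bl <- bl + ag_val(L) * (j - i + 1L)
        ag_backward(L)
      }
      if (!is.finite(bl)) {
        warning("training diverged (non-finite loss); restoring last checkpoint")
        params_from_list(params, last_good)
        return(list(model = model, log = log, best_epoch = best$epoch,
                    diverged = TRUE))
      }
      adam_step(opt, lr = lr)
      ep_loss <- ep_loss + bl / (j - i + 1L)
      nb <- nb + 1L
      i <- j + 1L
    }
    ep_loss <- ep_loss / max(1L, nb)
    last_good <- params_to_list(params)

    val_f1 <- NA_real_
    if (length(val_recs)) {
      f1s <- vapply(val_recs, function(r) {
        pm <- predict_image(model, r, stride = geometry$s)
        compute_metrics(pm, r$vessel_gt, r$fov)$F1
      }, numeric(1))
      val_f1 <- mean(f1s, na.rm = TRUE)
      if (!is.na(val_f1) && val_f1 > best$f1) {
        best <- list(f1 = val_f1, params = last_good, epoch = epoch)
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, lr = lr, loss = ep_loss,
                                 val_f1 = val_f1))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.5f  loss %.4f  val F1 %s",
                      epoch, lr, ep_loss,
                      ifelse(is.na(val_f1), "-", sprintf("%.4f", val_f1))))
    }
  }
  if (!is.null(best$params)) params_from_list(params, best$params)
  if (!is.null(log_csv)) utils::write.csv(log, log_csv, row.names = FALSE)
  if (!is.null(checkpoint)) save_checkpoint(model, checkpoint)
  list(model = model, log = log,
       best_epoch = if (is.null(best$params)) config$epochs - 1L else best$epoch,
       diverged = FALSE)
}

#' Save / load model parameters as JSON text
#'
#' The checkpoint holds every parameter tensor plus the configuration, in a
#' plain-text format.
#' @param model a `vs_mfnet`; @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  cfg <- model$config
  payload <- list(
    config = list(
      s = cfg$geometry$s, l = cfg$geometry$l,
      placements = as.vector(cfg$geometry$placements),
      context_scale = cfg$geometry$context_scale,
      main_channels = cfg$main_channels, pre_channels = cfg$pre_channels,
      context_channels = cfg$context_channels,
      fuse_channels = cfg$fuse_channels, fuse_out = cfg$fuse_out,
      corr_channels = cfg$corr_channels, edge_channels = cfg$edge_channels,
      aca_r = cfg$aca_r, gsa_M = cfg$gsa_M, gsa_heads = cfg$gsa_heads,
      use_edge_branch = cfg$use_edge_branch,
      use_collaborative = cfg$use_collaborative,
      use_aca = cfg$use_aca, use_gsa = cfg$use_gsa
    ),
    params = params_to_list(collect_params(model))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cj <- payload$config
  geo <- patch_geometry(cj$s, cj$l,
                        placements = matrix(as.integer(unlist(cj$placements)), ncol = 2),
                        context_scale = cj$context_scale)
  cfg <- mfnet_config(geometry = geo, main_channels = cj$main_channels,
                      pre_channels = cj$pre_channels,
                      context_channels = cj$context_channels,
                      fuse_channels = cj$fuse_channels, fuse_out = cj$fuse_out,
                      corr_channels = cj$corr_channels,
                      edge_channels = cj$edge_channels, aca_r = cj$aca_r,
                      gsa_M = cj$gsa_M, gsa_heads = cj$gsa_heads,
                      use_edge_branch = cj$use_edge_branch,
                      use_collaborative = cj$use_collaborative,
                      use_aca = cj$use_aca, use_gsa = cj$use_gsa)
  model <- build_mfnet(cfg)
  saved <- payload$params
  params_from_list(collect_params(model), saved)
  model
}

#' Tiled whole-image inference
#'
#' Extracts collaborative patch sets over a grid of target origins, runs the
#' network on each, and mean-stitches the small-patch probabilities into a
#' whole-image vessel probability map.
#'
#' @param model trained `vs_mfnet`.
#' @param record preprocessed `vs_record` (single-channel `$image`).
#' @param stride grid stride; the default `s/2` gives 50% overlap.
#' @param collaborative override of the collaborative flag.
#' @return (H, W) probability map.
#' @export
predict_image <- function(model, record, stride = NULL, collaborative = NULL) {
  geometry <- model$config$geometry
  s <- geometry$s
  if (is.null(stride)) stride <- max(1L, s %/% 2L)
  img <- record$image
  if (length(dim(img)) == 3) stop("record must be preprocessed (single channel)")
  origins <- sample_training_grid(dim(img), s, stride, n_random = 0L)
  preds <- vector("list", nrow(origins))
  for (k in seq_len(nrow(origins))) {
    ps <- extract_collaborative(img, origins[k, ], geometry)
    bundle <- mfnet_forward(model, ps, collaborative = collaborative)
    pm <- ag_val(bundle$S_s)
    dim(pm) <- dim(pm)[1:2]
    preds[[k]] <- list(origin = origins[k, ], patch = pm)
  }
  stitch_patches(preds, dim(img))
}

# ---- metrics ---------------------------------------------------------------

#' FOV-restricted confusion counts
#' @param prob_map (H,W) probabilities; @param vessel_gt,fov binary masks;
#' @param threshold binarization threshold.
#' @return list TP, FP, TN, FN (counts over `fov == 1` pixels only).
#' @export
confusion_counts <- function(prob_map, vessel_gt, fov, threshold = 0.5) {
  stopifnot(all(dim(prob_map) == dim(vessel_gt)),
            all(dim(prob_map) == dim(fov)))
  inside <- fov > 0.5
  if (!any(inside)) stop("FOV mask is empty")
  p <- prob_map[inside] >= threshold
  t <- vessel_gt[inside] > 0.5
  list(TP = sum(p & t), FP = sum(p & !t), TN = sum(!p & !t), FN = sum(!p & t))
}

#' Segmentation metrics inside the field of view
#'
#' ACC = (TP+TN)/(TP+TN+FP+FN); SE = TP/(TP+FN); SP = TN/(TN+FP);
#' F1 = 2TP/(2TP+FN+FP); AUC by the exact rank (Mann-Whitney) statistic over
#' FOV-pixel scores, with average ranks for ties.
#'
#' @inheritParams confusion_counts
#' @return list of class `vs_metrics`: ACC, SE, SP, F1, AUC and the counts.
#' @export
compute_metrics <- function(prob_map, vessel_gt, fov, threshold = 0.5) {
  cc <- confusion_counts(prob_map, vessel_gt, fov, threshold)
  total <- cc$TP + cc$TN + cc$FP + cc$FN
  inside <- fov > 0.5
  scores <- prob_map[inside]
  labels <- vessel_gt[inside] > 0.5
  P <- sum(labels); N <- sum(!labels)
  if (P == 0 || N == 0) {
    warning("ground truth has a single class inside the FOV; AUC undefined")
    auc <- NaN
  } else {
    r <- rank(scores)                     # average ranks on ties
    auc <- (sum(r[labels]) - P * (P + 1) / 2) / (P * N)
  }
  structure(list(
    ACC = (cc$TP + cc$TN) / total,
    SE = if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else NaN,
    SP = if (cc$TN + cc$FP > 0) cc$TN / (cc$TN + cc$FP) else NaN,
    F1 = 2 * cc$TP / (2 * cc$TP + cc$FN + cc$FP),
    AUC = auc, counts = cc
  ), class = "vs_metrics")
}

#' @export
print.vs_metrics <- function(x, ...) {
  cat(sprintf("ACC %.4f  SE %.4f  SP %.4f  F1 %.4f  AUC %.4f\n",
              x$ACC, x$SE, x$SP, x$F1, x$AUC))
  invisible(x)
}

#' Evaluate a model over a dataset
#' @param model trained model; @param records preprocessed records with GT.
#' @param stride inference stride; @param threshold binarization threshold.
#' @param collaborative override of the collaborative flag.
#' @return data.frame of per-image metrics plus a `"mean"` row.
#' @export
evaluate_dataset <- function(model, records, stride = NULL, threshold = 0.5,
                             collaborative = NULL) {
  rows <- lapply(records, function(r) {
    pm <- predict_image(model, r, stride = stride, collaborative = collaborative)
    mt <- compute_metrics(pm, r$vessel_gt, r$fov, threshold)
    data.frame(id = r$id, ACC = mt$ACC, SE = mt$SE, SP = mt$SP, F1 = mt$F1,
               AUC = mt$AUC)
  })
  df <- do.call(rbind, rows)
  mean_row <- data.frame(id = "mean", ACC = mean(df$ACC), SE = mean(df$SE),
                         SP = mean(df$SP), F1 = mean(df$F1),
                         AUC = mean(df$AUC))
  rbind(df, mean_row)
}

#' Train/evaluate ablation variants
#'
#' Each variant toggles module construction (coordinate attention, bottleneck
#' self-attention, collaborative path) and is trained with a shared seed and
#' data split; results come back as one table.
#'
#' @param train_records,test_records preprocessed records.
#' @param base_config a [mfnet_config()] used as the template.
#' @param tconfig a [train_config()].
#' @param variants named list; each entry a list with any of `use_aca`,
#'   `use_gsa`, `use_collaborative`.
#' @return data.frame: variant, params, F1, ACC, AUC (test means).
#' @export
run_ablation <- function(train_records, test_records, base_config,
                         tconfig = train_config(),
                         variants = list(
                           base = list(use_aca = FALSE, use_gsa = FALSE),
                           aca = list(use_aca = TRUE, use_gsa = FALSE),
                           gsa = list(use_aca = FALSE, use_gsa = TRUE),
                           aca_gsa = list(use_aca = TRUE, use_gsa = TRUE)
                         )) {
  rows <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    cfg <- base_config
    for (f in names(v)) cfg[[f]] <- v[[f]]
    cfg <- do.call(mfnet_config, c(list(geometry = cfg$geometry),
                                   cfg[setdiff(names(cfg), c("geometry"))]))
    set.seed(tconfig$seed)
    model <- build_mfnet(cfg)
    fit <- train_mfnet(model, train_records, tconfig)
    ev <- evaluate_dataset(fit$model, test_records,
                           stride = cfg$geometry$s)
    mn <- ev[ev$id == "mean", ]
    data.frame(variant = nm, params = n_params(model), F1 = mn$F1,
               ACC = mn$ACC, AUC = mn$AUC)
  })
  do.call(rbind, rows)
}
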