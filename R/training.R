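#' Training settings
#'
#' @param epochs_max Maximum number of epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param early_stop_patience Epochs without validation improvement before
#'   training halts (>= 1); the checkpoint with the best validation loss is
#'   kept.
#' @param min_delta Smallest validation improvement that resets patience.
#' @param seed Seed driving shuffling, augmentation and weight init.
#' @param distill A [distill_config()].
#' @param arm Ablation arm name (see [ablation_arm()]).
#' @param augment Apply random horizontal flips (p = 0.5) to training
#'   samples; never applied at validation or test time.
#' @param val_fraction Fraction held out for validation when the data carry
#'   no `split` column.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs_max = 30, batch_size = 4,
                         learning_rate = 1e-3, early_stop_patience = 10,
                         min_delta = 1e-4, seed = 1L,
                         distill = distill_config(), arm = "aaws",
                         augment = TRUE, val_fraction = 0.1) {
  if (!is.numeric(epochs_max) || epochs_max < 1) {
    stop_param("`epochs_max` must be >= 1")
  }
  if (early_stop_patience < 1) stop_param("`early_stop_patience` must be >= 1")
  if (!inherits(distill, "distill_config")) {
    distill <- do.call(distill_config, as.list(distill))
  }
  arm <- ablation_arm(arm)$name # validates the name
  structure(
    list(
      epochs_max = as.integer(epochs_max), batch_size = as.integer(batch_size),
      learning_rate = learning_rate,
      early_stop_patience = as.integer(early_stop_patience),
      min_delta = min_delta, seed = as.integer(seed), distill = distill,
      arm = arm, augment = isTRUE(augment), val_fraction = val_fraction
    ),
    class = "train_config"
  )
}

#' Ablation arm definitions
#'
#' The seven training arms of the ablation study: plain U-Net, U-Net
#' initialised from a reconstruction-pretrained copy, the skip-less
#' autoencoder architecture trained for segmentation (random and pretrained
#' init), and the distillation framework with the KD term removed, the KL
#' term removed, or complete.
#'
#' @param name One of `"unet"`, `"unet_pre"`, `"ae"`, `"ae_pre"`,
#'   `"without_kd"`, `"without_kl"`, `"aaws"`, or `NULL` to get the full
#'   seven-row table.
#' @return A one-row tibble (or seven-row if `name` is `NULL`) with columns
#'   `name`, `label` (display name), `architecture`
#'   (`"unet"`/`"skipless"`), `uses_pretrained_encoder`, `uses_kd`,
#'   `uses_kl`.
#' @export
#' @examples
#' ablation_arm() # all seven arms
ablation_arm <- function(name = NULL) {
  arms <- tibble(
    name = c("unet", "unet_pre", "ae", "ae_pre",
             "without_kd", "without_kl", "aaws"),
    label = c("U-Net", "Unet_Pre", "AE", "AE_Pre",
              "Without_KD", "Without_KL", "AAWS-Net"),
    architecture = c("unet", "unet", "skipless", "skipless",
                     "unet", "unet", "unet"),
    uses_pretrained_encoder = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    uses_kd = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    uses_kl = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE)
  )
  if (is.null(name)) return(arms)
  hit <- arms[arms$name == name, ]
  if (nrow(hit) != 1) {
    stop_param(sprintf("unknown ablation arm '%s'", name))
  }
  hit
}

# ---- internal helpers -------------------------------------------------------

records_from_tibble <- function(data) {
  purrr::map(seq_len(nrow(data)), function(i) {
    list(
      id = data$id[i], image = data$image[[i]],
      mask = if ("mask" %in% names(data)) data$mask[[i]] else NULL,
      label = data$label[i],
      split = if ("split" %in% names(data)) data$split[i] else NA_character_
    )
  })
}

train_val_records <- function(data, cfg) {
  has_split <- "split" %in% names(data) && !all(is.na(data$split))
  if (has_split) {
    data <- data[!is.na(data$split) & data$split != "test", ]
    tr_rows <- which(data$split == "train")
    va_rows <- which(data$split == "val")
  } else {
    tr_rows <- seq_len(nrow(data))
    va_rows <- integer(0)
  }
  if (length(va_rows) == 0) {
    # no validation rows supplied: carve them out of the training rows
    n_val <- max(1L, floor(length(tr_rows) * cfg$val_fraction))
    idx <- with_seed(derive_seed(cfg$seed, 97L), sample(tr_rows))
    va_rows <- idx[seq_len(n_val)]
    tr_rows <- idx[-seq_len(n_val)]
  }
  tr <- records_from_tibble(data[tr_rows, ])
  va <- records_from_tibble(data[va_rows, ])
  if (length(tr) == 0 || length(va) == 0) {
    stop_param("training and validation subsets must both be non-empty")
  }
  list(train = tr, val = va)
}

onehot <- function(k, n) {
  v <- numeric(n)
  v[k] <- 1
  v
}

# d(loss)/d(logits) of the Dice + mean-BCE compound. The Dice term is scored
# against `dice_target`, the BCE term against `bce_target` (they coincide for
# the ground-truth loss but differ for KD, whose BCE needs the binarised
# teacher prediction).
dice_bce_grad <- function(dice_target, probs, bce_target = dice_target,
                          eps_dice = 1e-6) {
  n <- length(dice_target)
  num <- 2 * sum(probs * dice_target) + eps_dice
  den <- sum(probs) + sum(dice_target) + eps_dice
  d_dice <- -(2 * dice_target * den - num) / den^2 * probs * (1 - probs)
  d_bce <- (probs - bce_target) / n
  d_dice + d_bce
}

# Early-stopping bookkeeping: returns updated state after seeing a new
# validation loss.
es_update <- function(state, val, params, min_delta) {
  if (val < state$best - min_delta) {
    list(best = val, best_params = params, stale = 0L)
  } else {
    state$stale <- state$stale + 1L
    state
  }
}

# ---- teacher phase ----------------------------------------------------------

#' Pretrain the teacher on weakly annotated tiles
#'
#' Phase one of the protocol: the autoencoder teacher minimises
#' `L_T = L_L1 + L_CE` -- mean absolute reconstruction error plus
#' cross-entropy of the pathology prediction -- on tiles that carry a label
#' but no mask. Validation `L_T` is tracked per epoch (including an
#' epoch-0 evaluation of the untrained network), early stopping applies, and
#' the returned model is the checkpoint with the best validation loss.
#'
#' @param data Dataset tibble; every record must have a label. Masks are
#'   ignored. If a `split` column is present its `train`/`val` rows are
#'   used; otherwise `val_fraction` of the records is held out.
#' @param net_cfg A [net_config()].
#' @param cfg A [train_config()].
#' @param architecture `"skipless"` (the teacher proper) or `"unet"` (used
#'   to reconstruction-pretrain the skip-connected architecture for the
#'   `unet_pre` ablation arm).
#' @return An object of class `teacher_fit`: list with `model`, `history`
#'   (tibble: epoch, train_lt, train_l1, train_ce, val_lt), `best_epoch`.
#' @export
pretrain_teacher <- function(data, net_cfg = net_config(),
                             cfg = train_config(),
                             architecture = c("skipless", "unet")) {
  architecture <- match.arg(architecture)
  if (any(is.na(data$label))) {
    stop_param("every record needs a pathology label for teacher pretraining")
  }
  sets <- train_val_records(data, cfg)
  net <- build_net(net_cfg, skips = architecture == "unet",
                   seed = derive_seed(cfg$seed, 11L))

  val_lt <- function(net) {
    mean(purrr::map_dbl(sets$val, function(r) {
      fw <- forward_infer(net, r$image)
      teacher_like_loss(fw, r)$lt
    }))
  }
  teacher_like_loss <- function(fw, r) {
    recon <- sigmoid(fw$out_logits)
    l1 <- l1_loss(recon, r$image)
    z <- as.numeric(r$label == "malignant")
    probs <- soft_targets(fw$class_logits, T = 1)
    ce <- ce_loss(probs[2], z)
    list(lt = l1 + ce, l1 = l1, ce = ce, recon = recon, probs = probs, z = z)
  }

  history <- list(tibble(epoch = 0L, train_lt = NA_real_, train_l1 = NA_real_,
                         train_ce = NA_real_, val_lt = val_lt(net)))
  es <- list(best = history[[1]]$val_lt, best_params = net$params, stale = 0L)
  opt <- adam_init(net$params)
  n_pix <- net_cfg$in_size^2

  with_seed(derive_seed(cfg$seed, 13L), {
    for (epoch in seq_len(cfg$epochs_max)) {
      order <- sample(seq_along(sets$train))
      ep <- c(lt = 0, l1 = 0, ce = 0)
      for (start in seq(1, length(order), by = cfg$batch_size)) {
        batch <- order[start:min(start + cfg$batch_size - 1, length(order))]
        acc <- NULL
        for (i in batch) {
          r <- sets$train[[i]]
          x <- r$image
          if (cfg$augment && runif(1) < 0.5) x <- flip_horizontal(x)
          fw <- forward_full(net, x)
          ls <- teacher_like_loss(fw, list(image = x, label = r$label))
          d_out <- sign(ls$recon - x) / n_pix * ls$recon * (1 - ls$recon)
          d_class <- ls$probs - c(1 - ls$z, ls$z)
          g <- backward_full(net, fw, d_out = d_out, d_class = d_class)
          acc <- if (is.null(acc)) g else tree_add(acc, g)
          ep <- ep + c(ls$lt, ls$l1, ls$ce)
        }
        acc <- tree_scale(acc, 1 / length(batch))
        upd <- adam_step(net$params, acc, opt, cfg$learning_rate)
        net$params <- upd$params
        opt <- upd$state
      }
      ep <- ep / length(order)
      vl <- val_lt(net)
      history[[epoch + 1L]] <- tibble(
        epoch = epoch, train_lt = ep[["lt"]], train_l1 = ep[["l1"]],
        train_ce = ep[["ce"]], val_lt = vl
      )
      es <- es_update(es, vl, net$params, cfg$min_delta)
      if (es$stale >= cfg$early_stop_patience) break
    }
  })
  history <- purrr::list_rbind(history)
  net$params <- es$best_params
  structure(
    list(
      model = net, history = history,
      best_epoch = history$epoch[which.min(history$val_lt)],
      architecture = architecture
    ),
    class = "teacher_fit"
  )
}

# ---- student phase ----------------------------------------------------------

as_net <- function(x) {
  if (inherits(x, "teacher_fit") || inherits(x, "student_fit")) x$model else x
}

#' Train the student with a frozen teacher
#'
#' Phase two: the student minimises
#' `L_S = alpha * L_KD + (1 - alpha) * L_GT + lam * L_KL` on fully annotated
#' tiles. The teacher is frozen -- only its encoder is evaluated, its weights
#' are never touched -- and supplies, per tile, the bottleneck reference
#' distribution for the KL term and the temperature-softened class targets
#' for the KD term. The ablation arm in `cfg$arm` decides the architecture,
#' the initialisation and which loss terms are active (an excluded term has
#' its weight forced to zero and contributes exactly nothing).
#'
#' @param teacher A `teacher_fit` (or bare net) for distillation and/or
#'   pretraining-based initialisation; `NULL` for arms that use neither
#'   (`unet`, `ae`).
#' @param data Fully annotated dataset tibble (mask and label per record).
#' @param net_cfg A [net_config()]; must match the teacher's.
#' @param cfg A [train_config()]; `cfg$arm` selects the ablation arm.
#' @return An object of class `student_fit`: list with `model`, `history`
#'   (per-epoch tibble of the active loss terms and validation `L_S`),
#'   `arm`, `best_epoch`.
#' @export
train_student <- function(teacher, data, net_cfg = net_config(),
                          cfg = train_config()) {
  arm <- ablation_arm(cfg$arm)
  teacher <- if (!is.null(teacher)) as_net(teacher)
  needs_distill <- arm$uses_kd || arm$uses_kl

  if (any(!data$has_mask)) {
    stop_param("every record needs a ground-truth mask for student training")
  }
  if (needs_distill || arm$uses_pretrained_encoder) {
    if (is.null(teacher)) {
      stop_param(sprintf("arm '%s' requires a pretrained network", arm$name))
    }
    if (!identical(teacher$cfg$bottleneck_length, net_cfg$bottleneck_length)) {
      stop_param("teacher and student bottleneck lengths differ")
    }
  }
  if (needs_distill && any(is.na(data$label))) {
    stop_param("distillation arms need pathology labels")
  }

  alpha <- if (arm$uses_kd) cfg$distill$alpha else 0
  lam <- if (arm$uses_kl) cfg$distill$lam else 0
  skips <- arm$architecture == "unet"

  net <- build_net(net_cfg, skips = skips, seed = derive_seed(cfg$seed, 29L))
  if (arm$uses_pretrained_encoder) {
    if (!identical(teacher$skips, skips)) {
      stop_param(sprintf(
        "arm '%s' needs a pretrained %s architecture to initialise from",
        arm$name, arm$architecture
      ))
    }
    net$params$enc <- teacher$params$enc
    net$params$bott <- teacher$params$bott
    net$params$dec <- teacher$params$dec
  }

  sets <- train_val_records(data, cfg)

  # the teacher is frozen, so its encoder outputs per tile (and per flip
  # orientation) are computed once and cached
  tcache <- NULL
  if (needs_distill) {
    make_entry <- function(img) {
      fw <- forward_encoder(teacher, img)
      rho <- soft_targets(fw$class_logits, T = cfg$distill$T)
      list(
        q = bottleneck_distribution(fw$bottleneck),
        rho = rho,
        rho_star = onehot(which.max(rho), length(rho))
      )
    }
    cache_for <- function(recs) {
      purrr::map(recs, function(r) {
        list(
          orig = make_entry(r$image),
          flip = if (cfg$augment) make_entry(flip_horizontal(r$image))
        )
      })
    }
    tcache <- list(train = cache_for(sets$train), val = cache_for(sets$val))
  }

  sample_loss <- function(net, r, tc, flipped, infer = FALSE) {
    x <- r$image
    m <- r$mask
    if (flipped) {
      x <- flip_horizontal(x)
      m <- flip_horizontal(m)
    }
    fw <- if (infer) forward_infer(net, x) else forward_full(net, x)
    probs <- sigmoid(fw$out_logits)
    gt <- gt_loss(m, probs)
    kd <- 0
    kl <- 0
    d_class <- NULL
    d_bott <- NULL
    if (!is.null(tc)) {
      te <- if (flipped) tc$flip else tc$orig
      if (arm$uses_kd) {
        cprob <- sigmoid(fw$class_logits)
        kd <- kd_loss(te$rho, te$rho_star, cprob)
        d_class <- alpha * dice_bce_grad(te$rho, cprob, te$rho_star)
      }
      if (arm$uses_kl) {
        p <- bottleneck_distribution(fw$bottleneck)
        kl <- kl_loss(p, te$q)
        d_bott <- lam * (p - te$q)
      }
    }
    ls <- alpha * kd + (1 - alpha) * gt + lam * kl
    d_out <- (1 - alpha) * dice_bce_grad(m, probs)
    list(gt = gt, kd = kd, kl = kl, ls = ls,
         fw = fw, d_out = d_out, d_class = d_class, d_bott = d_bott)
  }

  val_ls <- function(net) {
    vals <- purrr::map(seq_along(sets$val), function(i) {
      sl <- sample_loss(net, sets$val[[i]],
                        if (needs_distill) tcache$val[[i]], FALSE,
                        infer = TRUE)
      c(gt = sl$gt, kd = sl$kd, kl = sl$kl, ls = sl$ls)
    })
    colMeans(do.call(rbind, vals))
  }

  v0 <- val_ls(net)
  hist_row <- function(epoch, tr, va) {
    row <- tibble(epoch = epoch, train_gt = tr[["gt"]],
                  val_gt = va[["gt"]], train_ls = tr[["ls"]],
                  val_ls = va[["ls"]])
    if (arm$uses_kd) {
      row$train_kd <- tr[["kd"]]
      row$val_kd <- va[["kd"]]
    }
    if (arm$uses_kl) {
      row$train_kl <- tr[["kl"]]
      row$val_kl <- va[["kl"]]
    }
    row
  }
  na4 <- c(gt = NA_real_, kd = NA_real_, kl = NA_real_, ls = NA_real_)
  history <- list(hist_row(0L, na4, v0))
  es <- list(best = v0[["ls"]], best_params = net$params, stale = 0L)
  opt <- adam_init(net$params)

  with_seed(derive_seed(cfg$seed, 31L), {
    for (epoch in seq_len(cfg$epochs_max)) {
      order <- sample(seq_along(sets$train))
      ep <- c(gt = 0, kd = 0, kl = 0, ls = 0)
      for (start in seq(1, length(order), by = cfg$batch_size)) {
        batch <- order[start:min(start + cfg$batch_size - 1, length(order))]
        acc <- NULL
        for (i in batch) {
          flipped <- cfg$augment && runif(1) < 0.5
          sl <- sample_loss(net, sets$train[[i]],
                            if (needs_distill) tcache$train[[i]], flipped)
          g <- backward_full(net, sl$fw, d_out = sl$d_out,
                             d_class = sl$d_class, d_bott = sl$d_bott)
          acc <- if (is.null(acc)) g else tree_add(acc, g)
          ep <- ep + c(sl$gt, sl$kd, sl$kl, sl$ls)
        }
        acc <- tree_scale(acc, 1 / length(batch))
        upd <- adam_step(net$params, acc, opt, cfg$learning_rate)
        net$params <- upd$params
        opt <- upd$state
      }
      ep <- ep / length(order)
      va <- val_ls(net)
      history[[epoch + 1L]] <- hist_row(epoch, ep, va)
      es <- es_update(es, va[["ls"]], net$params, cfg$min_delta)
      if (es$stale >= cfg$early_stop_patience) break
    }
  })
  history <- purrr::list_rbind(history)
  net$params <- es$best_params
  structure(
    list(
      model = net, history = history, arm = arm$name,
      best_epoch = history$epoch[which.min(history$val_ls)]
    ),
    class = "student_fit"
  )
}

# ---- evaluation -------------------------------------------------------------

#' Evaluate a segmentation model on a dataset split
#'
#' Predicts a probability map per tile, binarises it at `threshold`, and
#' reports the five pixel metrics, both per image and aggregated.
#'
#' @param model A `student_fit`/`teacher_fit` or bare `masskd_net`.
#' @param data Dataset tibble with masks.
#' @param split Which `split` value to evaluate (`NULL` for all rows).
#' @param threshold Binarisation threshold for the probability map.
#' @param aggregation Passed to [metrics_table()].
#' @return A list with `summary` (one-row tibble), `per_image` (tibble with
#'   one metrics row per tile, carrying the record `id`) and `predictions`
#'   (list of binarised masks, in split order).
#' @export
evaluate_model <- function(model, data, split = "test", threshold = 0.5,
                           aggregation = "per_image_mean") {
  net <- as_net(model)
  if (!is.null(split) && "split" %in% names(data)) {
    data <- data[!is.na(data$split) & data$split == split, ]
  }
  if (nrow(data) == 0) stop_param("no records to evaluate")
  if (any(!data$has_mask)) stop_param("evaluation needs ground-truth masks")
  preds <- purrr::map(data$image, function(img) {
    (predict(net, img, type = "segmentation") >= threshold) + 0
  })
  per <- purrr::map2(preds, data$mask, function(p, m) {
    compute_metrics(confusion(p, m))
  }) |> purrr::list_rbind()
  per <- dplyr::mutate(per, id = data$id, .before = 1)
  list(
    summary = metrics_table(preds, data$mask, aggregation = aggregation),
    per_image = per,
    predictions = preds
  )
}

# ---- ablation harness -------------------------------------------------------

#' Run the seven-arm ablation study
#'
#' Trains all seven arms on a shared split of the fully annotated subset --
#' plain U-Net, reconstruction-pretrained U-Net, the skip-less architecture
#' (random and pretrained), and the distillation framework without KD,
#' without KL, and complete -- then evaluates each on the held-out test
#' split. Teacher pretraining on the weak subset is done once per required
#' architecture and shared across arms, so arms differ only in the factors
#' under study.
#'
#' @param data Dataset tibble containing both weak (`annotation == "weak"`)
#'   and full records, e.g. from [generate_dataset()].
#' @param net_cfg A [net_config()].
#' @param cfg A [train_config()]; its `arm` field is ignored.
#' @param arms Character vector of arm names to run (default: all seven).
#' @return A list of class `ablation_result`: `table` (one row per arm with
#'   IoU, RE, F1 plus AC and SP), `fits` (named list of `student_fit`s),
#'   `teacher` (the pretrained skip-less teacher fit or `NULL`), `split`
#'   (the shared split assignment).
#' @export
run_ablation <- function(data, net_cfg = net_config(), cfg = train_config(),
                         arms = ablation_arm()$name) {
  arm_tbl <- ablation_arm()
  arms <- match.arg(arms, arm_tbl$name, several.ok = TRUE)
  weak <- data[data$annotation == "weak", ]
  full <- data[data$annotation == "full", ]
  if (nrow(full) < 3) stop_param("need at least 3 fully annotated records")
  full <- split_dataset(full, seed = derive_seed(cfg$seed, 41L))

  need <- arm_tbl[arm_tbl$name %in% arms, ]
  teacher_fit <- NULL
  unet_ae_fit <- NULL
  if (any(need$uses_kd | need$uses_kl |
            (need$uses_pretrained_encoder & need$architecture == "skipless"))) {
    if (nrow(weak) == 0) stop_param("arms requiring a teacher need weak records")
    teacher_fit <- pretrain_teacher(weak, net_cfg, cfg,
                                    architecture = "skipless")
  }
  if (any(need$uses_pretrained_encoder & need$architecture == "unet")) {
    if (nrow(weak) == 0) stop_param("arms requiring pretraining need weak records")
    unet_ae_fit <- pretrain_teacher(weak, net_cfg, cfg, architecture = "unet")
  }

  fits <- list()
  rows <- list()
  for (a in arms) {
    arm <- ablation_arm(a)
    acfg <- cfg
    acfg$arm <- a
    pre <- if (arm$uses_kd || arm$uses_kl) {
      teacher_fit
    } else if (arm$uses_pretrained_encoder) {
      if (arm$architecture == "unet") unet_ae_fit else teacher_fit
    }
    fit <- train_student(pre, full, net_cfg, acfg)
    ev <- evaluate_model(fit, full, split = "test")
    fits[[a]] <- fit
    arm_label <- arm$label
    rows[[a]] <- tibble(
      arm = a, label = arm_label,
      iou = ev$summary$iou, re = ev$summary$re, f1 = ev$summary$f1,
      ac = ev$summary$ac, sp = ev$summary$sp
    )
  }
  structure(
    list(
      table = purrr::list_rbind(rows),
      fits = fits,
      teacher = teacher_fit,
      split = full[, c("id", "split")]
    ),
    class = "ablation_result"
  )
}
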