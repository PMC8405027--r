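test_that("training configuration is validated", {
  expect_error(train_config(epochs_max = 0), class = "masskd_parameter_error")
  expect_error(train_config(early_stop_patience = 0),
               class = "masskd_parameter_error")
  expect_error(train_config(arm = "nope"), class = "masskd_parameter_error")
  cfg <- train_config(distill = list(T = 3, alpha = 0.2, lam = 0.5))
  expect_s3_class(cfg$distill, "distill_config")
})

test_that("the seven ablation arms carry the stated flag combinations", {
  arms <- ablation_arm()
  expect_identical(arms$name, c("unet", "unet_pre", "ae", "ae_pre",
                                "without_kd", "without_kl", "aaws"))
  aaws <- ablation_arm("aaws")
  expect_true(aaws$uses_kd && aaws$uses_kl)
  wkd <- ablation_arm("without_kd")
  expect_true(!wkd$uses_kd && wkd$uses_kl)
  wkl <- ablation_arm("without_kl")
  expect_true(wkl$uses_kd && !wkl$uses_kl)
  expect_identical(arms$architecture[arms$name %in% c("ae", "ae_pre")],
                   c("skipless", "skipless"))
})

test_that("teacher pretraining requires labels and logs an epoch-0 baseline", {
  d <- tiny_dataset(seed = 1, n_weak = 10, n_full = 0)
  bad <- d
  bad$label[3] <- NA
  expect_error(pretrain_teacher(bad, tiny_cfg(), tiny_train_cfg()),
               class = "masskd_parameter_error")
  fit <- pretrain_teacher(d, tiny_cfg(), tiny_train_cfg(epochs = 2))
  expect_s3_class(fit, "teacher_fit")
  expect_identical(fit$history$epoch[1], 0L)
  expect_false(is.na(fit$history$val_lt[1]))
  expect_identical(nrow(fit$history), 3L)
  expect_true(all(c("train_lt", "train_l1", "train_ce", "val_lt") %in%
                    names(fit$history)))
})

test_that("teacher pretraining with a fixed seed is exactly reproducible", {
  d <- tiny_dataset(seed = 2, n_weak = 8, n_full = 0)
  f1 <- pretrain_teacher(d, tiny_cfg(), tiny_train_cfg(seed = 5))
  f2 <- pretrain_teacher(d, tiny_cfg(), tiny_train_cfg(seed = 5))
  expect_identical(net_fingerprint(f1$model), net_fingerprint(f2$model))
  expect_identical(f1$history, f2$history)
})

test_that("student training validates inputs per arm", {
  d <- tiny_dataset(seed = 3, n_full = 8)
  expect_error(train_student(NULL, d, tiny_cfg(), tiny_train_cfg("aaws")),
               class = "masskd_parameter_error") # aaws needs a teacher
  weakish <- d
  weakish$has_mask[2] <- FALSE
  expect_error(train_student(NULL, weakish, tiny_cfg(), tiny_train_cfg()),
               class = "masskd_parameter_error") # missing mask
  # bottleneck length mismatch
  big_teacher <- build_teacher(net_config(16, 4, 2), seed = 1)
  expect_error(train_student(big_teacher, d, tiny_cfg(),
                             tiny_train_cfg("aaws")),
               "bottleneck", class = "masskd_parameter_error")
  # pretrained-init arms need the matching architecture
  skipless_teacher <- pretrain_teacher(tiny_dataset(4, n_weak = 6),
                                       tiny_cfg(), tiny_train_cfg())
  expect_error(train_student(skipless_teacher, d, tiny_cfg(),
                             tiny_train_cfg("unet_pre")),
               class = "masskd_parameter_error")
})

test_that("the supervised U-Net arm reduces to the pure ground-truth loss", {
  d <- tiny_dataset(seed = 5, n_full = 10)
  fit <- train_student(NULL, d, tiny_cfg(), tiny_train_cfg("unet"))
  h <- fit$history
  expect_false(any(c("train_kd", "train_kl") %in% names(h)))
  expect_equal(h$train_ls, h$train_gt, tolerance = 1e-12)
  expect_equal(h$val_ls, h$val_gt, tolerance = 1e-12)
})

test_that("arm flags force excluded losses to contribute exactly zero", {
  d <- tiny_dataset(seed = 6, n_full = 10)
  teach <- pretrain_teacher(tiny_dataset(7, n_weak = 8), tiny_cfg(),
                            tiny_train_cfg())
  wkl <- train_student(teach, d, tiny_cfg(), tiny_train_cfg("without_kl"))
  h <- wkl$history
  expect_true("train_kd" %in% names(h))
  expect_false("train_kl" %in% names(h)) # lambda forced to 0, term dropped
  a <- 0.5 # default alpha
  expect_equal(h$val_ls, a * h$val_kd + (1 - a) * h$val_gt, tolerance = 1e-12)

  wkd <- train_student(teach, d, tiny_cfg(), tiny_train_cfg("without_kd"))
  h2 <- wkd$history
  expect_false("train_kd" %in% names(h2))
  expect_true("train_kl" %in% names(h2))
  expect_equal(h2$val_ls, h2$val_gt + 0.1 * h2$val_kl, tolerance = 1e-12)
})

test_that("the teacher is byte-identical across student training", {
  d <- tiny_dataset(seed = 8, n_full = 8)
  teach <- pretrain_teacher(tiny_dataset(9, n_weak = 8), tiny_cfg(),
                            tiny_train_cfg())
  fp_before <- net_fingerprint(teach$model)
  fit <- train_student(teach, d, tiny_cfg(), tiny_train_cfg("aaws"))
  expect_identical(net_fingerprint(teach$model), fp_before)
  expect_s3_class(fit, "student_fit")
})

test_that("student training with equal seeds is exactly reproducible", {
  d <- tiny_dataset(seed = 10, n_full = 8)
  f1 <- train_student(NULL, d, tiny_cfg(), tiny_train_cfg("unet", seed = 3))
  f2 <- train_student(NULL, d, tiny_cfg(), tiny_train_cfg("unet", seed = 3))
  expect_identical(net_fingerprint(f1$model), net_fingerprint(f2$model))
  expect_identical(f1$history, f2$history)
})

test_that("early stopping halts within patience epochs of the optimum", {
  d <- tiny_dataset(seed = 11, n_full = 10)
  # zero learning rate: validation loss can never improve, so training must
  # stop after exactly `patience` epochs
  cfg <- tiny_train_cfg("unet", epochs = 50)
  cfg$learning_rate <- 0
  cfg$early_stop_patience <- 3L
  fit <- train_student(NULL, d, tiny_cfg(), cfg)
  expect_identical(max(fit$history$epoch), 3L)
  expect_identical(fit$best_epoch, 0L)
})

test_that("evaluation reports per-image and aggregate metrics on a split", {
  d <- split_dataset(tiny_dataset(seed = 12, n_full = 10), seed = 1)
  fit <- train_student(NULL, d, tiny_cfg(), tiny_train_cfg("unet"))
  ev <- evaluate_model(fit, d, split = "test")
  expect_identical(nrow(ev$per_image), sum(d$split == "test"))
  expect_true(all(ev$summary[, c("ac", "re", "f1", "sp", "iou")] >= 0))
  expect_true(all(ev$summary[, c("ac", "re", "f1", "sp", "iou")] <= 1))
  expect_error(evaluate_model(fit, d, split = "nope"),
               class = "masskd_parameter_error")
})

test_that("the ablation harness runs all seven arms on a shared test split", {
  d <- tiny_dataset(seed = 13, n_weak = 10, n_full = 10)
  res <- run_ablation(d, tiny_cfg(), tiny_train_cfg(epochs = 1))
  expect_s3_class(res, "ablation_result")
  expect_identical(nrow(res$table), 7L)
  expect_identical(res$table$arm, ablation_arm()$name)
  expect_identical(res$table$label, ablation_arm()$label)
  expect_true(all(c("iou", "re", "f1") %in% names(res$table)))
  expect_length(res$fits, 7)
  # all arms saw the identical held-out membership
  expect_identical(nrow(res$split), 10L)
  test_ids <- res$split$id[res$split$split == "test"]
  expect_gt(length(test_ids), 0)
  # and the teacher used for distillation arms is the shared pretrained one
  expect_s3_class(res$teacher, "teacher_fit")
})

test_that("tidy, glance and autoplot summarise fits", {
  d <- tiny_dataset(seed = 14, n_full = 8)
  fit <- train_student(NULL, d, tiny_cfg(), tiny_train_cfg("unet"))
  td <- tidy(fit)
  expect_true(all(c("epoch", "loss", "value") %in% names(td)))
  gl <- glance(fit)
  expect_identical(gl$arm, "unet")
  expect_s3_class(autoplot(fit), "ggplot")
  teach <- pretrain_teacher(tiny_dataset(15, n_weak = 6), tiny_cfg(),
                            tiny_train_cfg())
  expect_s3_class(autoplot(teach), "ggplot")
  expect_gt(nrow(tidy(teach)), 0)
})
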