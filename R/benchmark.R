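#' Desk-scale distillation benchmark
#'
#' The package's reference experiment: one seeded phantom dataset with 200
#' weakly annotated tiles (teacher phase) and 100 fully annotated tiles
#' (student phase, split 80/10/10), a teacher pretrained once on the weak
#' subset, and then -- across several student training seeds -- the plain
#' supervised U-Net arm against the full distillation arm, both evaluated on
#' the shared held-out test split. This mirrors the controlled-comparison
#' design of the ablation study at a size a single CPU handles in minutes.
#'
#' @param seed Master seed; the dataset, the split, the teacher and every
#'   student run derive their seeds from it.
#' @param n_weak,n_full Subset sizes (defaults 200/100).
#' @param net_cfg A [net_config()]; default desk scale (64 px, 8 base
#'   channels, depth 4).
#' @param n_train_seeds Number of independent student training seeds
#'   (default 5).
#' @param arms Arms trained per seed (default the supervised U-Net and the
#'   full distillation arm).
#' @param teacher_epochs,student_epochs Epoch caps for the two phases.
#' @param batch_size,patience Shared optimiser settings.
#' @return A list of class `distill_benchmark`:
#'   `teacher` (the `teacher_fit`), `teacher_reduction_pct` (percentage drop
#'   of validation `L_T` from epoch 0 to its optimum), `results` (tibble:
#'   `train_seed`, `arm`, `iou`, `re`, `f1`, `ac`, `sp`), and `medians`
#'   (tibble of median test metrics per arm).
#' @export
benchmark_distillation <- function(seed = 1L, n_weak = 200, n_full = 100,
                                   net_cfg = net_config(64, 8),
                                   n_train_seeds = 5,
                                   arms = c("unet", "aaws"),
                                   teacher_epochs = 14, student_epochs = 12,
                                   batch_size = 4, patience = 6) {
  data <- generate_dataset(phantom_spec(seed = seed), n_weak, n_full)
  weak <- data[data$annotation == "weak", ]
  full <- split_dataset(data[data$annotation == "full", ],
                        seed = derive_seed(seed, 7L))

  teacher_fit <- NULL
  needs_teacher <- any(ablation_arm()$uses_kd[match(arms, ablation_arm()$name)] |
                         ablation_arm()$uses_kl[match(arms, ablation_arm()$name)])
  if (needs_teacher) {
    teacher_fit <- pretrain_teacher(
      weak, net_cfg,
      train_config(epochs_max = teacher_epochs, batch_size = batch_size,
                   early_stop_patience = patience,
                   seed = derive_seed(seed, 17L))
    )
  }
  reduction <- if (!is.null(teacher_fit)) {
    h <- teacher_fit$history
    100 * (h$val_lt[1] - min(h$val_lt)) / h$val_lt[1]
  }
  fp_before <- if (!is.null(teacher_fit)) net_fingerprint(teacher_fit$model)

  rows <- list()
  for (k in seq_len(n_train_seeds)) {
    for (arm in arms) {
      cfg <- train_config(
        epochs_max = student_epochs, batch_size = batch_size,
        early_stop_patience = patience,
        seed = derive_seed(seed, 1000L + k), arm = arm
      )
      needs <- ablation_arm(arm)
      pre <- if (needs$uses_kd || needs$uses_kl || needs$uses_pretrained_encoder) {
        teacher_fit
      }
      fit <- train_student(pre, full, net_cfg, cfg)
      ev <- evaluate_model(fit, full, split = "test")
      rows[[length(rows) + 1L]] <- tibble(
        train_seed = k, arm = arm,
        iou = ev$summary$iou, re = ev$summary$re, f1 = ev$summary$f1,
        ac = ev$summary$ac, sp = ev$summary$sp
      )
    }
  }
  results <- purrr::list_rbind(rows)
  medians <- results |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(dplyr::across(c("iou", "re", "f1", "ac", "sp"),
                                   stats::median), .groups = "drop")
  structure(
    list(
      teacher = teacher_fit,
      teacher_reduction_pct = reduction,
      teacher_fingerprint_before = fp_before,
      teacher_fingerprint_after =
        if (!is.null(teacher_fit)) net_fingerprint(teacher_fit$model),
      results = results,
      medians = medians,
      seed = seed
    ),
    class = "distill_benchmark"
  )
}

#' @export
print.distill_benchmark <- function(x, ...) {
  cat("Desk-scale distillation benchmark (seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$teacher_reduction_pct)) {
    cat(sprintf("teacher: validation L_T reduced %.1f%% from epoch 0\n",
                x$teacher_reduction_pct))
  }
  cat("median test metrics over", length(unique(x$results$train_seed)),
      "training seeds:\n")
  print(as.data.frame(x$medians), digits = 3)
  invisible(x)
}
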