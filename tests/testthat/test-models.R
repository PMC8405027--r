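test_that("teacher and student preserve spatial shape and share bottleneck length", {
  cfg <- net_config(in_size = 64, base_channels = 8, depth = 4)
  tea <- build_teacher(cfg, seed = 1)
  stu <- build_student(cfg, seed = 2)
  set.seed(3)
  x <- matrix(runif(64 * 64), 64, 64)
  to <- teacher_forward(tea, x)
  so <- student_forward(stu, x)
  expect_identical(dim(to$reconstruction), c(64L, 64L))
  expect_identical(dim(so$seg_logits), c(64L, 64L))
  expect_length(to$class_logits, 2)
  expect_length(so$class_logits, 2)
  # bottleneck spatial side 64 / 2^4 = 4, channels 8 * 2^4 = 128
  expect_length(to$bottleneck, 4 * 4 * 128)
  expect_identical(length(to$bottleneck), length(so$bottleneck))
  expect_identical(cfg$bottleneck_length, 2048L)
  expect_true(all(to$reconstruction > 0 & to$reconstruction < 1))
})

test_that("shape preservation holds across configurations", {
  for (cfg in list(net_config(16, 2, 2), net_config(32, 3, 3))) {
    tea <- build_teacher(cfg, seed = 1)
    stu <- build_student(cfg, seed = 1)
    x <- matrix(runif(cfg$in_size^2), cfg$in_size)
    expect_identical(dim(teacher_forward(tea, x)$reconstruction), dim(x))
    expect_identical(dim(student_forward(stu, x)$seg_logits), dim(x))
    expect_identical(length(teacher_forward(tea, x)$bottleneck),
                     as.integer(cfg$bottleneck_length))
  }
  expect_error(net_config(in_size = 60, depth = 4), "2\\^depth")
  expect_error(forward_full(build_teacher(net_config(16, 2, 2), seed = 1),
                            matrix(0, 32, 32)),
               class = "masskd_shape_error")
})

test_that("builds are deterministic under a seed and differ without one", {
  cfg <- tiny_cfg()
  a <- build_student(cfg, seed = 9)
  b <- build_student(cfg, seed = 9)
  expect_identical(a$params, b$params)
  expect_identical(net_fingerprint(a), net_fingerprint(b))
  c <- build_student(cfg, seed = 10)
  expect_false(identical(net_fingerprint(a), net_fingerprint(c)))
})

test_that("the teacher has no skip paths: its decoder blocks are half-width", {
  cfg <- tiny_cfg()
  tea <- build_teacher(cfg, seed = 1)
  stu <- build_student(cfg, seed = 1)
  ch <- masskd:::stage_channels(cfg)
  for (d in seq_len(cfg$depth)) {
    # conv1 of the decoder block consumes 9 * channels_in rows
    expect_identical(nrow(tea$params$dec[[d]]$block$W1), as.integer(9 * ch[d]))
    expect_identical(nrow(stu$params$dec[[d]]$block$W1),
                     as.integer(18 * ch[d]))
  }
  # removing the skip concatenation reduces the student to the teacher's
  # topology: every other parameter shape coincides
  shapes <- function(p) rapply(p, dim, how = "list")
  st <- shapes(tea$params); ss <- shapes(stu$params)
  for (d in seq_len(cfg$depth)) {
    ss$dec[[d]]$block$W1 <- st$dec[[d]]$block$W1
  }
  expect_identical(st, ss)
  expect_false(tea$skips)
  expect_true(stu$skips)
})

test_that("a zero-weight teacher reconstructs a constant", {
  cfg <- tiny_cfg()
  tea <- build_teacher(cfg, seed = 1)
  tea$params <- masskd:::tree_zero(tea$params)
  r1 <- teacher_forward(tea, matrix(runif(256), 16, 16))$reconstruction
  r2 <- teacher_forward(tea, matrix(runif(256), 16, 16))$reconstruction
  expect_equal(max(r1) - min(r1), 0)
  expect_identical(r1, r2)
})

test_that("backpropagation matches finite differences on every layer type", {
  cfg <- tiny_cfg()
  net <- build_student(cfg, seed = 5)
  set.seed(6)
  x <- matrix(runif(256), 16, 16)
  mask <- random_binary_mask(16, 16, 0.3)
  qref <- random_prob_vec(cfg$bottleneck_length)
  rho <- c(0.7, 0.3); rho_star <- c(1, 0)
  alpha <- 0.4; lam <- 0.2

  loss_of <- function(net) {
    fw <- masskd:::forward_full(net, x)
    probs <- masskd:::sigmoid(fw$out_logits)
    cprob <- masskd:::sigmoid(fw$class_logits)
    p <- bottleneck_distribution(fw$bottleneck)
    alpha * kd_loss(rho, rho_star, cprob) +
      (1 - alpha) * gt_loss(mask, probs) + lam * kl_loss(p, qref)
  }
  fw <- masskd:::forward_full(net, x)
  probs <- masskd:::sigmoid(fw$out_logits)
  cprob <- masskd:::sigmoid(fw$class_logits)
  p <- bottleneck_distribution(fw$bottleneck)
  g <- masskd:::backward_full(
    net, fw,
    d_out = (1 - alpha) * masskd:::dice_bce_grad(mask, probs),
    d_class = alpha * masskd:::dice_bce_grad(rho, cprob, rho_star),
    d_bott = lam * (p - qref)
  )
  h <- 1e-5
  bump <- function(params, path, idx, delta) {
    walk <- function(node, d) {
      if (length(d) == 1) {
        node[[d[[1]]]][idx] <- node[[d[[1]]]][idx] + delta
        node
      } else {
        node[[d[[1]]]] <- walk(node[[d[[1]]]], d[-1])
        node
      }
    }
    walk(params, path)
  }
  cases <- list(
    list(list("enc", 1L, "W1"), 3L), list(list("enc", 2L, "W2"), 11L),
    list(list("bott", "W1"), 20L), list(list("bott", "b2"), 1L),
    list(list("dec", 2L, "Wu"), 5L), list(list("dec", 1L, "block", "W1"), 9L),
    list(list("out_head", "W"), 1L), list(list("class_head", "W"), 2L),
    list(list("class_head", "b"), 1L)
  )
  for (cs in cases) {
    path <- cs[[1]]; idx <- cs[[2]]
    n1 <- net; n1$params <- bump(net$params, path, idx, h)
    n2 <- net; n2$params <- bump(net$params, path, idx, -h)
    num <- (loss_of(n1) - loss_of(n2)) / (2 * h)
    ana <- Reduce(function(a, b) a[[b]], path, g)[idx]
    expect_equal(ana, num, tolerance = 1e-4)
  }
})

test_that("a frozen teacher contributes activations but no weight updates", {
  cfg <- tiny_cfg()
  tea <- build_teacher(cfg, seed = 1)
  fp <- net_fingerprint(tea)
  x <- matrix(runif(256), 16, 16)
  # the distillation path only ever evaluates the teacher's encoder
  fe <- masskd:::forward_encoder(tea, x)
  expect_length(bottleneck_distribution(fe$bottleneck),
                cfg$bottleneck_length)
  expect_identical(net_fingerprint(tea), fp)
})

test_that("checkpoints round-trip through files", {
  cfg <- tiny_cfg()
  stu <- build_student(cfg, seed = 4)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(stu, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, stu$params)
  expect_identical(class(back), class(stu))
  x <- matrix(runif(256), 16, 16)
  expect_identical(predict(back, x), predict(stu, x))
  unlink(f)
})

test_that("predict exposes segmentation, class and bottleneck views", {
  cfg <- tiny_cfg()
  stu <- build_student(cfg, seed = 4)
  x <- matrix(runif(256), 16, 16)
  seg <- predict(stu, x, type = "segmentation")
  expect_identical(dim(seg), dim(x))
  expect_true(all(seg > 0 & seg < 1))
  cl <- predict(stu, x, type = "class")
  expect_equal(sum(cl), 1)
  expect_length(predict(stu, x, type = "bottleneck"), cfg$bottleneck_length)
  expect_gt(n_parameters(stu), n_parameters(build_teacher(cfg, seed = 1)))
})
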