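# Scalar-loop reference implementations, kept deliberately naive and separate
# from the vectorised package code they check.
loop_l1 <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s / length(a)
}
loop_kl <- function(p, q, eps = 1e-7) {
  s <- 0
  for (j in seq_along(p)) {
    s <- s + q[j] * (log(max(q[j], eps)) - log(max(p[j], eps)))
  }
  s
}
loop_dice <- function(a, b, eps = 1e-6) {
  num <- 0; da <- 0; db <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]; da <- da + a[i]; db <- db + b[i]
  }
  (2 * num + eps) / (da + db + eps)
}
loop_bce_mean <- function(target, prob, eps = 1e-7) {
  s <- 0
  for (i in seq_along(prob)) {
    p <- min(max(prob[i], eps), 1 - eps)
    s <- s - target[i] * log(p) - (1 - target[i]) * log(1 - p)
  }
  s / length(prob)
}

test_that("soft targets form a shift-invariant temperature softmax", {
  expect_equal(soft_targets(c(0, 0), T = 5), c(0.5, 0.5))
  # closed form exp(1)/(exp(1)+1) for logits (2,0) at T = 2
  expect_equal(soft_targets(c(2, 0), T = 2),
               c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(soft_targets(c(5, -5), T = 1e6), c(0.5, 0.5), tolerance = 1e-5)
  expect_equal(soft_targets(c(1, 2, 3), T = 1), exp(1:3) / sum(exp(1:3)))
  set.seed(1)
  for (i in 1:50) {
    l <- rnorm(4, sd = 3)
    Tt <- runif(1, 0.1, 10)
    st <- soft_targets(l, Tt)
    expect_true(all(st > 0))
    expect_equal(sum(st), 1, tolerance = 1e-12)
    expect_equal(soft_targets(l + rnorm(1, sd = 10), Tt), st,
                 tolerance = 1e-9) # adding a constant changes nothing
  }
  expect_error(soft_targets(c(1, 0), T = 0), class = "masskd_parameter_error")
})

test_that("reconstruction and classification losses match closed forms", {
  expect_identical(l1_loss(matrix(0.3, 4, 4), matrix(0.3, 4, 4)), 0)
  expect_equal(l1_loss(c(1, 1), c(0, 1)), 0.5)
  expect_equal(ce_loss(1, 1), 0, tolerance = 1e-6)
  expect_equal(ce_loss(0.5, 1), log(2))
  expect_equal(ce_loss(0.9, 0), -log(0.1))
  expect_error(l1_loss(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "masskd_shape_error")
  expect_error(ce_loss(0.5, 0.3), class = "masskd_parameter_error")
})

test_that("teacher loss is the exact unweighted sum of its two terms", {
  out <- list(reconstruction = matrix(0.25, 4, 4),
              class_logits = c(0, 0))
  y <- matrix(0.75, 4, 4) # l1 = 0.5; ce(0.5, 1) = log 2
  expect_equal(teacher_loss(out, y, 1), 0.5 + log(2), tolerance = 1e-9)
  set.seed(7)
  for (i in 1:20) {
    out <- list(reconstruction = matrix(runif(16), 4, 4),
                class_logits = rnorm(2))
    y <- matrix(runif(16), 4, 4)
    z <- rbinom(1, 1, 0.5)
    expect_equal(
      teacher_loss(out, y, z),
      l1_loss(out$reconstruction, y) +
        ce_loss(soft_targets(out$class_logits, 1)[2], z),
      tolerance = 1e-12
    )
  }
})

test_that("KL transfer loss matches a hand-evaluated oracle and its properties", {
  expect_equal(kl_loss(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_loss(c(0.25, 0.75), c(0.5, 0.5)),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:100) {
    n <- sample(2:20, 1)
    p <- random_prob_vec(n)
    q <- random_prob_vec(n)
    expect_equal(kl_loss(p, q), loop_kl(p, q), tolerance = 1e-10)
    expect_gte(kl_loss(p, q), 0) # Gibbs inequality
    expect_equal(kl_loss(p, p), 0, tolerance = 1e-12)
  }
  # asymmetry on a generic pair
  expect_false(isTRUE(all.equal(kl_loss(c(0.2, 0.8), c(0.6, 0.4)),
                                kl_loss(c(0.6, 0.4), c(0.2, 0.8)))))
  expect_error(kl_loss(c(0.5, 0.5), c(1, 0, 0)), class = "masskd_shape_error")
  expect_error(kl_loss(c(0.9, 0.3), c(0.5, 0.5)),
               class = "masskd_parameter_error")
})

test_that("soft Dice matches hand counts and brute force", {
  m <- matrix(0, 4, 4)
  a <- m; a[1:2, 1:2] <- 1          # 4-pixel square
  b <- m; b[1, 1:2] <- 1            # 2 of those pixels
  expect_equal(soft_dice(a, a), 1, tolerance = 1e-6)
  expect_equal(soft_dice(a, 1 - a), 0, tolerance = 1e-6)
  expect_equal(soft_dice(a, b), 2 * 2 / (4 + 2), tolerance = 1e-6)
  set.seed(13)
  for (i in 1:100) {
    x <- runif(12); y <- runif(12)
    expect_equal(soft_dice(x, y), loop_dice(x, y), tolerance = 1e-12)
  }
  expect_error(soft_dice(c(1.2, 0), c(0, 1)), class = "masskd_parameter_error")
})

test_that("KD loss applies Dice to soft targets and BCE to the binarised ones", {
  # perfect agreement: one-hot everywhere
  expect_equal(kd_loss(c(1, 0), c(1, 0), c(1, 0)), 0, tolerance = 1e-5)
  # worked composite: Dice((.5,.5),(.5,.5)) = .5, BCE((1,0),(.5,.5)) = log 2
  expect_equal(kd_loss(c(0.5, 0.5), c(1, 0), c(0.5, 0.5)),
               0.5 + log(2), tolerance = 1e-6)
  set.seed(17)
  for (i in 1:100) {
    rho <- random_prob_vec(2)
    rho_star <- as.numeric(seq_along(rho) == which.max(rho))
    sp <- runif(2)
    oracle <- (1 - loop_dice(rho, sp)) + loop_bce_mean(rho_star, sp)
    expect_equal(kd_loss(rho, rho_star, sp), oracle, tolerance = 1e-10)
    expect_gte(kd_loss(rho, rho_star, sp), 0)
  }
  expect_error(kd_loss(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5)),
               class = "masskd_parameter_error") # rho_star not one-hot
})

test_that("ground-truth loss is zero at the mask and matches brute force", {
  m <- random_binary_mask(4, 4)
  expect_equal(gt_loss(m, m), 0, tolerance = 1e-5)
  # all-ones prediction against a half-ones mask on 4 pixels
  gt4 <- matrix(c(1, 1, 0, 0), 2, 2)
  pred4 <- matrix(1, 2, 2)
  oracle <- (1 - loop_dice(gt4, pred4)) + loop_bce_mean(gt4, pred4)
  expect_equal(gt_loss(gt4, pred4), oracle, tolerance = 1e-10)
  expect_equal(1 - loop_dice(gt4, pred4), 1 - 2 * 2 / (2 + 4),
               tolerance = 1e-6)
  set.seed(19)
  for (i in 1:100) {
    mk <- random_binary_mask(5, 5)
    pr <- matrix(runif(25), 5, 5)
    expect_equal(gt_loss(mk, pr),
                 (1 - loop_dice(mk, pr)) + loop_bce_mean(mk, pr),
                 tolerance = 1e-10)
  }
  # moving probabilities elementwise toward the mask lowers the loss
  set.seed(23)
  for (i in 1:20) {
    mk <- random_binary_mask(4, 4)
    pr <- matrix(runif(16, 0.05, 0.95), 4, 4)
    closer <- pr + 0.05 * (mk - pr)
    expect_lt(gt_loss(mk, closer), gt_loss(mk, pr))
  }
})

test_that("student loss is the stated affine combination and linear in each term", {
  expect_identical(student_loss(5, 4, 3, distill_config(alpha = 0, lam = 0)), 4)
  expect_identical(student_loss(5, 4, 3, distill_config(alpha = 1, lam = 0)), 5)
  expect_equal(student_loss(2, 4, 1, distill_config(alpha = 0.25, lam = 0.1)),
               3.6, tolerance = 1e-12)
  set.seed(29)
  for (i in 1:50) {
    cfg <- distill_config(T = runif(1, 0.5, 5), alpha = runif(1),
                          lam = runif(1, 0, 2))
    kd <- runif(1, 0, 5); gt <- runif(1, 0, 5); kl <- runif(1, 0, 5)
    expect_equal(student_loss(kd, gt, kl, cfg),
                 cfg$alpha * kd + (1 - cfg$alpha) * gt + cfg$lam * kl,
                 tolerance = 1e-12)
    # linearity in each component
    expect_equal(student_loss(2 * kd, gt, kl, cfg) -
                   student_loss(kd, gt, kl, cfg),
                 cfg$alpha * kd, tolerance = 1e-10)
    expect_equal(student_loss(kd, gt, 2 * kl, cfg) -
                   student_loss(kd, gt, kl, cfg),
                 cfg$lam * kl, tolerance = 1e-10)
  }
  expect_error(distill_config(alpha = 1.2), class = "masskd_parameter_error")
  expect_error(distill_config(T = -1), class = "masskd_parameter_error")
})

test_that("per-sample loss variants return one value per sample", {
  set.seed(31)
  ys <- replicate(3, matrix(runif(9), 3, 3), simplify = FALSE)
  yh <- replicate(3, matrix(runif(9), 3, 3), simplify = FALSE)
  each <- l1_loss_each(yh, ys)
  expect_length(each, 3)
  expect_equal(each[2], l1_loss(yh[[2]], ys[[2]]))
  masks <- replicate(3, random_binary_mask(3, 3), simplify = FALSE)
  probs <- replicate(3, matrix(runif(9), 3, 3), simplify = FALSE)
  expect_equal(gt_loss_each(masks, probs)[1], gt_loss(masks[[1]], probs[[1]]))
  expect_equal(soft_dice_each(masks, probs)[3],
               soft_dice(masks[[3]], probs[[3]]))
})

test_that("bottleneck normalisation lands on the probability simplex", {
  set.seed(37)
  code <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  p <- bottleneck_distribution(code)
  expect_length(p, 18)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p > 0))
  expect_equal(kl_loss(p, p), 0, tolerance = 1e-12)
})
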