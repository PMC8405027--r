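#' Network architecture settings
#'
#' Shared configuration of the teacher and student networks: a symmetric
#' encoder-decoder with `depth` downsampling stages (channel count doubling
#' per stage), a transition block at the bottom, and `depth` upsampling
#' stages back to full resolution. The default `depth = 4` matches the
#' four-fold downsampling of the reference design; teacher and student built
#' from the same config have bottlenecks of identical length, a precondition
#' of the KL transfer loss.
#'
#' @param in_size Input pixels per side; must be divisible by `2^depth`.
#' @param base_channels Channels at the first stage. The desk-scale default
#'   is 8; the full-scale preset is `net_config(1024, 64)`.
#' @param depth Number of downsamplings (default 4).
#' @param num_classes Pathology classes (default 2: benign/malignant).
#' @return A list of class `net_config` with an extra field
#'   `bottleneck_length = base_channels * 2^depth * (in_size / 2^depth)^2`.
#' @export
#' @examples
#' net_config(64, 8)$bottleneck_length # 2048
net_config <- function(in_size = 64, base_channels = 8, depth = 4,
                       num_classes = 2) {
  if (!is.numeric(in_size) || in_size < 2^depth ||
      in_size %% 2^depth != 0) {
    stop_param(sprintf("`in_size` must be divisible by 2^depth = %d", 2^depth))
  }
  if (base_channels < 1 || depth < 1) {
    stop_param("`base_channels` and `depth` must be >= 1")
  }
  structure(
    list(
      in_size = as.integer(in_size),
      base_channels = as.integer(base_channels),
      depth = as.integer(depth),
      num_classes = as.integer(num_classes),
      bottleneck_length =
        as.integer(base_channels * 2^depth * (in_size / 2^depth)^2)
    ),
    class = "net_config"
  )
}

stage_channels <- function(cfg) cfg$base_channels * 2^(seq_len(cfg$depth) - 1)

build_net <- function(cfg, skips, seed = NULL) {
  stopifnot(inherits(cfg, "net_config"))
  builder <- function() {
    ch <- stage_channels(cfg)
    cb <- cfg$base_channels * 2^cfg$depth
    enc <- purrr::map(seq_len(cfg$depth), function(d) {
      init_block(if (d == 1) 1L else ch[d - 1], ch[d])
    })
    bott <- init_block(ch[cfg$depth], cb)
    dec <- purrr::map(seq_len(cfg$depth), function(d) {
      cin_up <- if (d == cfg$depth) cb else ch[d + 1]
      c(
        init_upconv(cin_up, ch[d]),
        list(block = init_block(if (skips) 2 * ch[d] else ch[d], ch[d]))
      )
    })
    out_head <- list(W = matrix(rnorm(ch[1], sd = sqrt(2 / ch[1])), ch[1], 1),
                     b = 0)
    # a deliberately generous init: the head must be able to recruit the
    # shared encoder away from the trivial equal-logits solution
    class_head <- list(
      W = matrix(rnorm(cb * cfg$num_classes, sd = 0.3), cb, cfg$num_classes),
      b = numeric(cfg$num_classes)
    )
    list(enc = enc, bott = bott, dec = dec,
         out_head = out_head, class_head = class_head)
  }
  params <- if (is.null(seed)) builder() else with_seed(seed, builder())
  structure(
    list(cfg = cfg, skips = skips, params = params),
    class = c(if (skips) "student_net" else "teacher_net", "masskd_net")
  )
}

#' Build the teacher network
#'
#' A symmetric encoder-decoder *without* skip connections (an autoencoder),
#' with a reconstruction head at full resolution and a classification head
#' (global average pool over the bottleneck, then a linear projection to the
#' pathology classes). Trained to reconstruct its input and classify the
#' mass, so that its bottleneck encodes breast anatomy.
#'
#' @param cfg A [net_config()].
#' @param seed Optional seed making the initial weights reproducible.
#' @return An object of class `c("teacher_net", "masskd_net")`.
#' @export
build_teacher <- function(cfg = net_config(), seed = NULL) {
  build_net(cfg, skips = FALSE, seed = seed)
}

#' Build the student network
#'
#' A U-Net: the same encoder-decoder as the teacher but *with* skip
#' concatenations at every stage, a single-logit segmentation head, and an
#' auxiliary classification head mirroring the teacher's (needed by the
#' class-level knowledge-distillation loss). Under a shared [net_config()]
#' its bottleneck length equals the teacher's.
#'
#' @inheritParams build_teacher
#' @return An object of class `c("student_net", "masskd_net")`.
#' @export
build_student <- function(cfg = net_config(), seed = NULL) {
  build_net(cfg, skips = TRUE, seed = seed)
}

# Full forward pass with caches for backprop. Returns out_logits (H x W
# matrix, pre-sigmoid), class_logits, bottleneck cube and cache.
forward_full <- function(net, x) {
  p <- net$params
  depth <- net$cfg$depth
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1L))
  if (dim(x)[1] != net$cfg$in_size || dim(x)[2] != net$cfg$in_size) {
    stop_shape(sprintf("input must be %dx%d", net$cfg$in_size, net$cfg$in_size))
  }
  enc_cache <- vector("list", depth)
  pool_idx <- vector("list", depth)
  cur <- x
  for (d in seq_len(depth)) {
    bf <- block_forward(cur, p$enc[[d]])
    mp <- nn_maxpool2_forward(bf$out)
    enc_cache[[d]] <- bf
    pool_idx[[d]] <- mp$idx
    cur <- mp$y
  }
  bott_cache <- block_forward(cur, p$bott)
  bott <- bott_cache$out

  g <- apply(bott, 3, mean)
  class_logits <- as.numeric(t(p$class_head$W) %*% g + p$class_head$b)

  dec_cache <- vector("list", depth)
  cur <- bott
  for (d in rev(seq_len(depth))) {
    up_in <- cur
    up <- nn_upconv2_forward(up_in, p$dec[[d]]$Wu, p$dec[[d]]$bu)
    blk_in <- if (net$skips) concat_channels(up, enc_cache[[d]]$out) else up
    bf <- block_forward(blk_in, p$dec[[d]]$block)
    dec_cache[[d]] <- list(up_in = up_in, blk = bf)
    cur <- bf$out
  }
  out_logits <- nn_conv1_forward(cur, p$out_head$W,
                                 as.numeric(p$out_head$b))[, , 1]
  list(
    out_logits = out_logits, class_logits = class_logits,
    bottleneck = bott, gap = g,
    cache = list(enc = enc_cache, pool = pool_idx, bott = bott_cache,
                 dec = dec_cache, head_in = cur)
  )
}

block_infer <- function(x, p) {
  nn_block_infer(x, p$W1, p$b1, p$W2, p$b2)
}

# Encoder + classification head only (all a frozen teacher must provide
# during distillation). No gradient bookkeeping.
forward_encoder <- function(net, x) {
  p <- net$params
  depth <- net$cfg$depth
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1L))
  cur <- x
  for (d in seq_len(depth)) {
    cur <- nn_maxpool2_forward(block_infer(cur, p$enc[[d]]))$y
  }
  bott <- block_infer(cur, p$bott)
  g <- apply(bott, 3, mean)
  list(
    bottleneck = bott,
    class_logits = as.numeric(t(p$class_head$W) %*% g + p$class_head$b)
  )
}

# Cache-free full forward used for validation losses and prediction.
forward_infer <- function(net, x) {
  p <- net$params
  depth <- net$cfg$depth
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1L))
  skip <- vector("list", depth)
  cur <- x
  for (d in seq_len(depth)) {
    skip[[d]] <- block_infer(cur, p$enc[[d]])
    cur <- nn_maxpool2_forward(skip[[d]])$y
  }
  bott <- block_infer(cur, p$bott)
  g <- apply(bott, 3, mean)
  cur <- bott
  for (d in rev(seq_len(depth))) {
    up <- nn_upconv2_forward(cur, p$dec[[d]]$Wu, p$dec[[d]]$bu)
    blk_in <- if (net$skips) concat_channels(up, skip[[d]]) else up
    cur <- block_infer(blk_in, p$dec[[d]]$block)
  }
  list(
    out_logits = nn_conv1_forward(cur, p$out_head$W,
                                  as.numeric(p$out_head$b))[, , 1],
    class_logits = as.numeric(t(p$class_head$W) %*% g + p$class_head$b),
    bottleneck = bott
  )
}

# Backward pass. d_out: grad wrt out_logits (H x W matrix or NULL);
# d_class: grad wrt class_logits (vector or NULL); d_bott: grad wrt the
# bottleneck activations (numeric of bottleneck length, or NULL).
# Returns a gradient tree mirroring net$params.
backward_full <- function(net, fw, d_out = NULL, d_class = NULL,
                          d_bott = NULL) {
  p <- net$params
  depth <- net$cfg$depth
  ch <- stage_channels(net$cfg)
  cache <- fw$cache
  grads <- list(
    enc = vector("list", depth), bott = NULL, dec = vector("list", depth),
    out_head = NULL, class_head = NULL
  )
  hin <- cache$head_in
  if (is.null(d_out)) {
    d_cur <- array(0, dim = dim(hin))
    grads$out_head <- list(W = p$out_head$W * 0, b = 0)
  } else {
    dy <- array(d_out, dim = c(dim(hin)[1], dim(hin)[2], 1L))
    gh <- nn_conv1_backward(hin, p$out_head$W, dy)
    grads$out_head <- list(W = gh$dW, b = as.numeric(gh$db))
    d_cur <- gh$dx
  }

  skip_grads <- vector("list", depth)
  for (d in seq_len(depth)) {
    bb <- block_backward(cache$dec[[d]]$blk, p$dec[[d]]$block, d_cur)
    d_blk_in <- bb$dx
    if (net$skips) {
      d_up <- d_blk_in[, , seq_len(ch[d]), drop = FALSE]
      skip_grads[[d]] <- d_blk_in[, , ch[d] + seq_len(ch[d]), drop = FALSE]
    } else {
      d_up <- d_blk_in
    }
    ub <- nn_upconv2_backward(cache$dec[[d]]$up_in, p$dec[[d]]$Wu, d_up)
    grads$dec[[d]] <- list(Wu = ub$dW, bu = as.numeric(ub$db), block = bb$grads)
    d_cur <- ub$dx
  }

  # bottleneck node: decoder grad + classification head + external (KL) grad
  d_bott_cube <- d_cur
  if (!is.null(d_class)) {
    g <- fw$gap
    grads$class_head <- list(
      W = outer(g, as.numeric(d_class)),
      b = as.numeric(d_class)
    )
    dg <- as.numeric(p$class_head$W %*% d_class)
    hw <- dim(d_bott_cube)[1] * dim(d_bott_cube)[2]
    d_bott_cube <- d_bott_cube +
      aperm(array(dg / hw, dim = c(dim(d_bott_cube)[3], dim(d_bott_cube)[1],
                                   dim(d_bott_cube)[2])), c(2, 3, 1))
  } else {
    grads$class_head <- list(W = p$class_head$W * 0,
                             b = numeric(net$cfg$num_classes))
  }
  if (!is.null(d_bott)) {
    d_bott_cube <- d_bott_cube + array(d_bott, dim = dim(d_bott_cube))
  }

  bb <- block_backward(cache$bott, p$bott, d_bott_cube)
  grads$bott <- bb$grads
  d_cur <- bb$dx

  for (d in rev(seq_len(depth))) {
    d_unpooled <- nn_maxpool2_backward(cache$pool[[d]], d_cur)
    if (net$skips && !is.null(skip_grads[[d]])) {
      d_unpooled <- d_unpooled + skip_grads[[d]]
    }
    eb <- block_backward(cache$enc[[d]], p$enc[[d]], d_unpooled)
    grads$enc[[d]] <- eb$grads
    d_cur <- eb$dx
  }
  grads
}

#' Forward pass through a teacher network
#'
#' @param net A `teacher_net` from [build_teacher()].
#' @param x Input tile (matrix, values in `[0, 1]`).
#' @return A list with `reconstruction` (matrix, same shape as `x`, sigmoid
#'   applied), `class_logits` (length `num_classes`) and `bottleneck`
#'   (flattened numeric vector of the deepest activations).
#' @export
teacher_forward <- function(net, x) {
  stopifnot(inherits(net, "teacher_net"))
  fw <- forward_full(net, x)
  list(
    reconstruction = sigmoid(fw$out_logits),
    class_logits = fw$class_logits,
    bottleneck = as.numeric(fw$bottleneck)
  )
}

#' Forward pass through a student network
#'
#' @param net A `student_net` from [build_student()].
#' @param x Input tile (matrix, values in `[0, 1]`).
#' @return A list with `seg_logits` (pre-sigmoid matrix, same shape as `x`),
#'   `class_logits` and `bottleneck` (flattened numeric vector).
#' @export
student_forward <- function(net, x) {
  stopifnot(inherits(net, "student_net"))
  fw <- forward_full(net, x)
  list(
    seg_logits = fw$out_logits,
    class_logits = fw$class_logits,
    bottleneck = as.numeric(fw$bottleneck)
  )
}

#' Predict from a trained network
#'
#' @param object A `masskd_net`.
#' @param image Input tile matrix.
#' @param type `"segmentation"` (sigmoid probability map),
#'   `"reconstruction"` (sigmoid output map), `"class"` (softmax
#'   probabilities) or `"bottleneck"` (flattened activations).
#' @param ... Unused.
#' @return Matrix or numeric vector according to `type`.
#' @export
predict.masskd_net <- function(object, image,
                               type = c("segmentation", "reconstruction",
                                        "class", "bottleneck"), ...) {
  type <- match.arg(type)
  if (type %in% c("class", "bottleneck")) {
    fw <- forward_encoder(object, image)
    if (type == "class") return(soft_targets(fw$class_logits, T = 1))
    return(as.numeric(fw$bottleneck))
  }
  fw <- forward_infer(object, image)
  sigmoid(fw$out_logits)
}

#' Count of trainable parameters
#' @param net A `masskd_net`.
#' @return Integer scalar.
#' @export
n_parameters <- function(net) {
  sum(rapply(net$params, length, how = "unlist"))
}

#' Save / load network checkpoints
#'
#' Checkpoints are self-contained: config, architecture flag and weights.
#'
#' @param net A `masskd_net`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the network.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(cfg = net$cfg, skips = net$skips, params = net$params,
               class = class(net)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  structure(list(cfg = x$cfg, skips = x$skips, params = x$params),
            class = x$class)
}

#' Fingerprint of a network's weights
#'
#' MD5 digest of the serialised parameter tree; byte-identical weights give
#' identical fingerprints. Used to assert that a frozen teacher is untouched
#' by student training.
#'
#' @param net A `masskd_net`.
#' @return Character MD5 string.
#' @export
net_fingerprint <- function(net) {
  f <- tempfile(fileext = ".bin")
  on.exit(unlink(f))
  writeBin(serialize(net$params, NULL, version = 2), f)
  unname(tools::md5sum(f))
}
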