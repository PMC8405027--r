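#' Phantom generator settings
#'
#' Parameters of the seeded mammogram-like phantom generator. Each phantom is
#' a square grayscale tile holding a single mass over a smooth parenchyma-like
#' background: benign masses are plain ellipses with softly blurred edges,
#' malignant masses are radially perturbed ellipses with triangular spicules.
#'
#' @param image_size Pixels per side of the square tile (>= 16).
#' @param mass_radius_range Length-2 numeric, min/max semi-axis as a fraction
#'   of `image_size`; must satisfy `0 < min <= max < 0.5`.
#' @param contrast Mass-vs-background intensity offset in `(0, 1]`. Masses are
#'   deliberately low-contrast relative to the surrounding texture.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise
#'   (intensity units), nonnegative.
#' @param spicule_count_range Length-2 integer, min/max number of spicules on
#'   a malignant mass.
#' @param boundary_roughness Amplitude of the random radial (Fourier)
#'   perturbation of malignant borders; 0 disables it.
#' @param background_smoothness Correlation length in pixels of the
#'   low-frequency background field.
#' @param seed Integer random seed; the same spec, label and seed always
#'   produce a bit-identical phantom.
#' @return A list of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(image_size = 64, seed = 7)
#' rec <- generate_phantom(spec, "malignant")
#' sum(rec$mask) # mass area in pixels
phantom_spec <- function(image_size = 64,
                         mass_radius_range = c(0.12, 0.22),
                         contrast = 0.25,
                         noise_sigma = 0.08,
                         spicule_count_range = c(3L, 7L),
                         boundary_roughness = 0.25,
                         background_smoothness = 8,
                         seed = 1L) {
  if (!is.numeric(image_size) || length(image_size) != 1 || image_size < 16) {
    stop_param("`image_size` must be a single number >= 16")
  }
  if (length(mass_radius_range) != 2 ||
      mass_radius_range[1] <= 0 ||
      mass_radius_range[1] > mass_radius_range[2] ||
      mass_radius_range[2] >= 0.5) {
    stop_param("`mass_radius_range` must satisfy 0 < min <= max < 0.5")
  }
  if (!is.numeric(contrast) || length(contrast) != 1 ||
      contrast <= 0 || contrast > 1) {
    stop_param("`contrast` must be in (0, 1]")
  }
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1 || noise_sigma < 0) {
    stop_param("`noise_sigma` must be nonnegative")
  }
  if (length(spicule_count_range) != 2 ||
      any(spicule_count_range < 0) ||
      spicule_count_range[1] > spicule_count_range[2]) {
    stop_param("`spicule_count_range` must be an increasing nonnegative pair")
  }
  if (!is.numeric(boundary_roughness) || boundary_roughness < 0) {
    stop_param("`boundary_roughness` must be nonnegative")
  }
  if (!is.numeric(background_smoothness) || background_smoothness <= 0) {
    stop_param("`background_smoothness` must be positive")
  }
  structure(
    list(
      image_size = as.integer(image_size),
      mass_radius_range = as.numeric(mass_radius_range),
      contrast = contrast,
      noise_sigma = noise_sigma,
      spicule_count_range = as.integer(spicule_count_range),
      boundary_roughness = boundary_roughness,
      background_smoothness = background_smoothness,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# Separable Gaussian smoothing of a square matrix (reflected borders are not
# needed for a random field; zero padding is normalised away).
gauss_smooth <- function(x, sigma) {
  half <- max(1L, min(ceiling(3 * sigma), nrow(x) - 1L))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  n <- nrow(x)
  # Toeplitz band matrix implementing 1-D convolution with renormalised edges
  K <- matrix(0, n, n)
  for (d in -half:half) {
    i <- seq_len(n - abs(d))
    if (d >= 0) K[cbind(i, i + d)] <- k[d + half + 1]
    else K[cbind(i - d, i)] <- k[d + half + 1]
  }
  K <- K / rowSums(K)
  K %*% x %*% t(K)
}

#' Generate a single mammogram-like phantom
#'
#' Draws a textured background field, inserts one mass whose morphology
#' follows the pathology label (benign: smooth blurred ellipse; malignant:
#' radially perturbed ellipse with spicules), adds pixel noise, and returns
#' the image together with the exact binary mask of the inserted mass.
#'
#' @param spec A [phantom_spec()].
#' @param label `"benign"` or `"malignant"`.
#' @return A list of class `sample_record` with fields `image` (matrix in
#'   `[0, 1]`), `mask` (0/1 integer matrix), `label` and `id`.
#' @export
generate_phantom <- function(spec, label = c("benign", "malignant")) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  label <- match.arg(label)
  S <- spec$image_size
  with_seed(spec$seed, {
    # parenchyma-like background: low-pass filtered white noise
    bg <- gauss_smooth(matrix(rnorm(S * S), S, S), spec$background_smoothness)
    bg <- 0.40 + 0.10 * (bg - mean(bg)) / stats::sd(bg)

    # mass geometry
    cx <- runif(1, 0.42, 0.58) * S
    cy <- runif(1, 0.42, 0.58) * S
    rr <- spec$mass_radius_range * S
    ax <- runif(1, rr[1], rr[2])
    # benign masses are round-to-oval; malignant ones are more elongated
    aspect <- if (label == "benign") runif(1, 0.85, 1) else runif(1, 0.55, 0.9)
    bx <- min(max(ax * aspect, rr[1]), rr[2])
    phi <- runif(1, 0, 2 * pi)

    xs <- matrix(rep(seq_len(S) - 0.5, each = S), S, S) # column coord
    ys <- matrix(rep(seq_len(S) - 0.5, times = S), S, S) # row coord
    u <- ((xs - cx) * cos(phi) + (ys - cy) * sin(phi)) / ax
    v <- (-(xs - cx) * sin(phi) + (ys - cy) * cos(phi)) / bx
    rho <- sqrt(u^2 + v^2)

    if (label == "benign") {
      rlim <- 1
    } else {
      theta <- atan2(v, u)
      # random Fourier perturbation of the radius, bounded by the roughness;
      # low harmonics dominate so the lobulation is visible at coarse scale
      amp <- runif(4, -1, 1) / (1:4)
      amp <- amp / max(sum(abs(amp)), 1e-9) * spec$boundary_roughness
      ph <- runif(4, 0, 2 * pi)
      rlim <- 1 + Reduce(`+`, lapply(1:4, function(k) {
        amp[k] * cos((k + 1) * theta + ph[k])
      }))
      ks <- spec$spicule_count_range
      n_spic <- if (ks[1] == ks[2]) ks[1] else sample(ks[1]:ks[2], 1)
      if (n_spic > 0) {
        for (s in seq_len(n_spic)) {
          psi <- runif(1, 0, 2 * pi)
          w <- runif(1, 0.12, 0.2)
          len <- runif(1, 1.35, 1.8)
          d <- abs((theta - psi + pi) %% (2 * pi) - pi)
          spike <- 1 + (len - 1) * pmax(0, 1 - d / w)
          rlim <- pmax(rlim, spike)
        }
      }
    }
    mask <- matrix(as.integer(rho <= rlim), S, S)
    if (label == "malignant") {
      # pixelation can detach the outermost pixels of a thin spicule tip;
      # keep the component holding the mass body so every mask is one mass
      lbl <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
      if (max(lbl) > 1) {
        counts <- tabulate(lbl[lbl > 0])
        mask <- matrix(as.integer(lbl == which.max(counts)), S, S)
      }
    }

    # soft-edged intensity bump: benign edges are blurred more strongly
    edge_sigma <- if (label == "benign") 2.2 else 0.25
    bump <- gauss_smooth(mask + 0, edge_sigma)
    if (label == "malignant") {
      # malignant masses show heterogeneous internal density; benign ones
      # are homogeneous
      tex <- gauss_smooth(matrix(rnorm(S * S), S, S), 1.5)
      bump <- bump * (1 + 0.35 * (tex / stats::sd(tex)) * mask)
    }
    img <- bg + spec$contrast * bump
    if (spec$noise_sigma > 0) img <- img + rnorm(S * S, sd = spec$noise_sigma)
    img <- pmin(pmax(img, 0), 1)

    structure(
      list(
        image = img, mask = mask, label = label,
        id = sprintf("phantom_%s_%d", label, spec$seed)
      ),
      class = "sample_record"
    )
  })
}

#' Generate a weakly + fully annotated phantom dataset
#'
#' Emulates the two-tier annotation structure used to train the framework:
#' `n_weak` tiles carry only a pathology label (teacher pretraining data, no
#' mask) and `n_full` tiles carry mask and label (student training data).
#' Benign/malignant labels are allocated to match `benign_fraction` within
#' one sample per subset, in seeded shuffled order.
#'
#' @param spec A [phantom_spec()]; its `seed` drives everything.
#' @param n_weak Number of weakly annotated records (mask absent).
#' @param n_full Number of fully annotated records (mask present).
#' @param benign_fraction Proportion of benign labels per subset, in `[0, 1]`.
#' @return A tibble with columns `id`, `label`, `annotation`
#'   (`"weak"`/`"full"`), `has_mask`, and list-columns `image`, `mask`
#'   (`NULL` where absent). Weak records come first.
#' @export
#' @examples
#' d <- generate_dataset(phantom_spec(seed = 1), n_weak = 4, n_full = 2)
#' table(d$annotation, d$has_mask)
generate_dataset <- function(spec, n_weak, n_full, benign_fraction = 0.5) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  if (n_weak < 0 || n_full < 0) stop_param("`n_weak` and `n_full` must be >= 0")
  if (benign_fraction < 0 || benign_fraction > 1) {
    stop_param("`benign_fraction` must be in [0, 1]")
  }
  subset_labels <- function(n, tag) {
    if (n == 0) return(character(0))
    n_ben <- round(benign_fraction * n)
    labs <- c(rep("benign", n_ben), rep("malignant", n - n_ben))
    with_seed(derive_seed(spec$seed, if (tag == "weak") 1L else 2L),
              sample(labs))
  }
  make_records <- function(labels, tag, offset) {
    purrr::imap(labels, function(lab, i) {
      rspec <- spec
      rspec$seed <- derive_seed(spec$seed, offset + i)
      rec <- generate_phantom(rspec, lab)
      rec$id <- sprintf("%s_%04d_%s", tag, offset + i, lab)
      rec$annotation <- tag
      if (tag == "weak") rec$mask <- NULL
      rec
    })
  }
  recs <- c(
    make_records(subset_labels(n_weak, "weak"), "weak", 0L),
    make_records(subset_labels(n_full, "full"), "full", n_weak)
  )
  tibble(
    id = purrr::map_chr(recs, "id"),
    label = purrr::map_chr(recs, "label"),
    annotation = purrr::map_chr(recs, "annotation"),
    has_mask = purrr::map_lgl(recs, ~ !is.null(.x$mask)),
    image = purrr::map(recs, "image"),
    mask = purrr::map(recs, "mask")
  )
}

#' Mask compactness
#'
#' The shape statistic `4 * pi * area / perimeter^2`, 1 for a perfect disk
#' under an exact perimeter; computed here with the pixel-count area and a
#' 4-neighbour boundary-pixel perimeter estimate. Spiculated borders inflate
#' the perimeter and push compactness down, separating malignant from benign
#' morphology.
#'
#' @param mask Binary 0/1 matrix with at least one foreground pixel.
#' @return A single positive number.
#' @export
mask_compactness <- function(mask) {
  m <- mask == 1
  area <- sum(m)
  if (area == 0) stop_param("`mask` has no foreground pixels")
  n <- nrow(m); p <- ncol(m)
  pad <- matrix(FALSE, n + 2, p + 2)
  pad[2:(n + 1), 2:(p + 1)] <- m
  core <- pad[2:(n + 1), 2:(p + 1)]
  nb <- pad[1:n, 2:(p + 1)] & pad[3:(n + 2), 2:(p + 1)] &
    pad[2:(n + 1), 1:p] & pad[2:(n + 1), 3:(p + 2)]
  perim <- sum(core & !nb)
  4 * pi * area / perim^2
}
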