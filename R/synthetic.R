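# ---- synthetic cohort generator -----------------------------------------
#
# Emulates a pair of imbalanced binary chest-film cohorts related by a global
# intensity/contrast shift: textured background images ("normal", majority)
# vs. images carrying a bright disc lesion (minority, the positive class).
# Source images are unshifted; target images are the same latent images passed
# through a brightness/contrast transform plus fresh pixel noise. Matching the
# pre-shift latents between domains isolates the domain shift as the only
# systematic source/target difference.

#' Configuration for a synthetic two-domain cohort
#'
#' @param image_size pixels per side of the square images (>= 8).
#' @param n_source_majority,n_source_minority,n_target_majority,n_target_minority
#'   per-domain per-class sample counts (>= 0). Defaults give the 0.25:1
#'   imbalance typical of pneumonia-screening cohorts.
#' @param shift_brightness additive intensity offset applied to the target
#'   domain, in \[-0.5, 0.5\].
#' @param shift_contrast multiplicative contrast factor (> 0) for the target
#'   domain.
#' @param noise_sd standard deviation of the Gaussian pixel noise (>= 0),
#'   added both at rendering time and again by the domain shift.
#' @param lesion_intensity additive amplitude of the lesion disc, in (0, 1].
#' @param lesion_radius_range integer (min, max) lesion radius in pixels; must
#'   fit inside the image.
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return an object of class `dttl_syn_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_source_majority = 40, n_source_minority = 10,
#'                         n_target_majority = 40, n_target_minority = 10)
#' cohort <- make_cohort(cfg)
#' cohort_summary(cohort)
synthetic_config <- function(image_size = 32L,
                             n_source_majority = 400L,
                             n_source_minority = 100L,
                             n_target_majority = 400L,
                             n_target_minority = 100L,
                             shift_brightness = 0.15,
                             shift_contrast = 1.4,
                             noise_sd = 0.05,
                             lesion_intensity = 0.4,
                             lesion_radius_range = c(3L, 5L),
                             seed = 1L) {
  image_size <- as.integer(image_size)
  counts <- c(n_source_majority, n_source_minority,
              n_target_majority, n_target_minority)
  if (any(counts < 0)) stop("sample counts must be >= 0")
  if (image_size < 8L) stop("image_size must be >= 8")
  if (!is.finite(shift_brightness) || abs(shift_brightness) > 0.5)
    stop("shift_brightness must be finite and in [-0.5, 0.5]")
  if (!is.finite(shift_contrast) || shift_contrast <= 0)
    stop("shift_contrast must be finite and > 0")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (lesion_intensity <= 0 || lesion_intensity > 1)
    stop("lesion_intensity must be in (0, 1]")
  lesion_radius_range <- as.integer(lesion_radius_range)
  if (length(lesion_radius_range) != 2L ||
      lesion_radius_range[1L] > lesion_radius_range[2L] ||
      lesion_radius_range[1L] < 1L ||
      2L * lesion_radius_range[2L] + 1L > image_size)
    stop("lesion_radius_range must be (min, max) radii fitting in the image")
  structure(list(
    image_size = image_size,
    n_source_majority = as.integer(n_source_majority),
    n_source_minority = as.integer(n_source_minority),
    n_target_majority = as.integer(n_target_majority),
    n_target_minority = as.integer(n_target_minority),
    shift_brightness = shift_brightness,
    shift_contrast = shift_contrast,
    noise_sd = noise_sd,
    lesion_intensity = lesion_intensity,
    lesion_radius_range = lesion_radius_range,
    seed = as.integer(seed)
  ), class = "dttl_syn_config")
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# circulant Gaussian smoothing matrix (wrap-around texture)
smoothing_matrix <- function(s, sigma = 2) {
  d <- outer(seq_len(s), seq_len(s), function(i, j) {
    dd <- abs(i - j)
    pmin(dd, s - dd)
  })
  K <- exp(-d^2 / (2 * sigma^2))
  K / rowSums(K)
}

# zero-mean smoothed Gaussian texture field, amplitude `amp` (sd units)
render_background <- function(s, amp = 0.08, base = 0.35) {
  Z <- matrix(stats::rnorm(s * s), s, s)
  S <- smoothing_matrix(s)
  sm <- S %*% Z %*% t(S)
  sm <- (sm - mean(sm)) / stats::sd(sm)
  base + amp * sm
}

#' Render a single synthetic image
#'
#' Draws a textured background (smoothed, zero-mean Gaussian field over a
#' constant base level); for the minority class a bright disc lesion of
#' amplitude `lesion_intensity` is superimposed at a random interior location.
#' Gaussian pixel noise of sd `noise_sd` is added and the result is clipped
#' to \[0, 1\]. Uses the current RNG state; seed externally for determinism.
#'
#' @param label `"maj"` (no lesion) or `"min"` (lesion present).
#' @param cfg a [synthetic_config()].
#' @return an `image_size` x `image_size` numeric matrix with values in
#'   \[0, 1\].
#' @export
render_image <- function(label, cfg) {
  if (!label %in% c("maj", "min")) stop("label must be 'maj' or 'min'")
  s <- cfg$image_size
  img <- render_background(s)
  if (label == "min") {
    rr <- cfg$lesion_radius_range
    r <- if (rr[1L] == rr[2L]) rr[1L] else
      sample(seq.int(rr[1L], rr[2L]), 1L)
    ci <- sample(seq.int(r + 1L, s - r), 1L)
    cj <- sample(seq.int(r + 1L, s - r), 1L)
    di <- outer(seq_len(s) - ci, rep(1, s))
    dj <- outer(rep(1, s), seq_len(s) - cj)
    disc <- (di^2 + dj^2) <= r^2
    img <- img + cfg$lesion_intensity * disc
  }
  if (cfg$noise_sd > 0)
    img <- img + matrix(stats::rnorm(s * s, sd = cfg$noise_sd), s, s)
  pmin(pmax(img, 0), 1)
}

#' Apply the global intensity/contrast domain shift
#'
#' Returns `clip(shift_contrast * img + shift_brightness + noise, 0, 1)`,
#' the target-domain transform of the cohort model. Noise (sd `noise_sd`)
#' is drawn from the current RNG state.
#'
#' @param img numeric matrix with values in \[0, 1\].
#' @param cfg a [synthetic_config()].
#' @return shifted image matrix in \[0, 1\].
#' @export
apply_domain_shift <- function(img, cfg) {
  if (!all(is.finite(c(cfg$shift_contrast, cfg$shift_brightness,
                       cfg$noise_sd))))
    stop("shift parameters must be finite")
  out <- cfg$shift_contrast * img + cfg$shift_brightness
  if (cfg$noise_sd > 0)
    out <- out + matrix(stats::rnorm(length(img), sd = cfg$noise_sd),
                        nrow(img), ncol(img))
  pmin(pmax(out, 0), 1)
}

# dataset container: images as an n x (size^2) matrix of row-flattened pixels
image_dataset <- function(X, labels = NULL, image_size) {
  stopifnot(is.matrix(X), ncol(X) == image_size^2)
  if (!is.null(labels)) {
    labels <- factor(as.character(labels), levels = c("maj", "min"))
    stopifnot(length(labels) == nrow(X), !anyNA(labels))
  }
  structure(list(X = X, labels = labels, image_size = as.integer(image_size)),
            class = "dttl_dataset")
}

#' @export
print.dttl_dataset <- function(x, ...) {
  cat(sprintf("<dttl_dataset> %d images, %dx%d, %s\n", nrow(x$X),
              x$image_size, x$image_size,
              if (is.null(x$labels)) "unlabelled" else
                paste(table(x$labels), collapse = " maj / ")))
  invisible(x)
}

# per-sample latent seed shared between domains for a given (class, index)
latent_seed <- function(seed, label, i) {
  cls <- if (label == "min") 2L else 1L
  ((seed %% 100000L) * 20011L + cls * 1000003L + i * 7919L) %% 2147483647L
}

render_class_block <- function(n, label, cfg) {
  s <- cfg$image_size
  X <- matrix(0, n, s * s)
  for (i in seq_len(n)) {
    img <- local_seed(latent_seed(cfg$seed, label, i), render_image(label, cfg))
    X[i, ] <- as.vector(img)
  }
  X
}

#' Generate a paired source/target cohort
#'
#' Source images are rendered unshifted with labels; target images reuse the
#' per-(class, index) latent images and are passed through
#' [apply_domain_shift()]. Target labels are retained only in a hidden
#' evaluation manifest (`target_hidden`) that training code never reads.
#'
#' @param cfg a [synthetic_config()].
#' @return an object of class `dttl_cohort` with elements `source` (labelled
#'   `dttl_dataset`), `target` (unlabelled `dttl_dataset`), `target_hidden`
#'   (factor of hidden evaluation labels) and `cfg`.
#' @export
make_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "dttl_syn_config"))
  if (cfg$n_source_majority + cfg$n_source_minority == 0L ||
      cfg$n_target_majority + cfg$n_target_minority == 0L)
    stop("each domain needs at least one sample")
  Xs <- rbind(render_class_block(cfg$n_source_majority, "maj", cfg),
              render_class_block(cfg$n_source_minority, "min", cfg))
  ys <- rep(c("maj", "min"),
            c(cfg$n_source_majority, cfg$n_source_minority))
  Xt <- rbind(render_class_block(cfg$n_target_majority, "maj", cfg),
              render_class_block(cfg$n_target_minority, "min", cfg))
  yt <- rep(c("maj", "min"),
            c(cfg$n_target_majority, cfg$n_target_minority))
  s <- cfg$image_size
  Xt <- local_seed(derive_seed(cfg$seed, "cohort"), {
    t(apply(Xt, 1L, function(row)
      as.vector(apply_domain_shift(matrix(row, s, s), cfg))))
  })
  if (!is.matrix(Xt)) Xt <- matrix(Xt, nrow = length(yt))
  structure(list(
    source = image_dataset(Xs, ys, s),
    target = image_dataset(Xt, NULL, s),
    target_hidden = factor(yt, levels = c("maj", "min")),
    cfg = cfg
  ), class = "dttl_cohort")
}

#' Summarise a cohort's class distribution
#'
#' Per-domain, per-class counts with the imbalance ratio minority/majority
#' (0 when the minority is empty). Target counts come from the hidden
#' evaluation manifest and are for reporting only.
#'
#' @param cohort a `dttl_cohort`.
#' @return a data frame with columns `domain`, `n_majority`, `n_minority`,
#'   `imbalance_ratio`.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "dttl_cohort"))
  row_for <- function(domain, labels) {
    n_maj <- sum(labels == "maj")
    n_min <- sum(labels == "min")
    ratio <- if (n_min == 0L) 0 else if (n_maj == 0L) NA_real_ else
      n_min / n_maj
    data.frame(domain = domain, n_majority = n_maj, n_minority = n_min,
               imbalance_ratio = ratio)
  }
  rbind(row_for("source", cohort$source$labels),
        row_for("target", cohort$target_hidden))
}

# ---- template-matching oracle -------------------------------------------

#' Lesion template response
#'
#' Maximum correlation of each image with a zero-mean disc kernel, swept over
#' all interior positions. A fixed, training-free detector used as an
#' independent separability oracle for the synthetic cohorts.
#'
#' @param X n x (s^2) pixel matrix (row-flattened images).
#' @param image_size s, pixels per side.
#' @param radius disc kernel radius in pixels.
#' @return numeric vector of per-image maximum template responses.
#' @export
template_response <- function(X, image_size, radius = 4L) {
  s <- as.integer(image_size)
  r <- as.integer(radius)
  k <- 2L * r + 1L
  di <- outer(seq_len(k) - r - 1L, rep(1, k))
  dj <- outer(rep(1, k), seq_len(k) - r - 1L)
  kern <- (di^2 + dj^2) <= r^2
  kern <- kern - mean(kern)
  n_pos <- (s - k + 1L)^2
  K <- matrix(0, s * s, n_pos)
  pos <- 1L
  for (cj in seq_len(s - k + 1L)) {
    for (ci in seq_len(s - k + 1L)) {
      idx <- as.vector(outer(ci:(ci + k - 1L),
                             (cj:(cj + k - 1L) - 1L) * s, "+"))
      K[idx, pos] <- as.vector(kern)
      pos <- pos + 1L
    }
  }
  resp <- X %*% K
  apply(resp, 1L, max)
}
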