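test_that("config validation rejects impossible cohorts", {
  expect_error(synthetic_config(image_size = 4), "image_size")
  expect_error(synthetic_config(n_source_majority = -1), "counts")
  expect_error(synthetic_config(shift_contrast = 0), "shift_contrast")
  expect_error(synthetic_config(lesion_radius_range = c(10, 20)),
               "lesion_radius_range")
  expect_error(synthetic_config(shift_brightness = 0.9), "shift_brightness")
})

test_that("rendering puts a lesion only in minority images", {
  cfg <- synthetic_config(noise_sd = 0, lesion_intensity = 1.0,
                          lesion_radius_range = c(4L, 4L))
  set.seed(5)
  img_min <- dttl:::local_seed(42L, render_image("min", cfg))
  img_maj <- dttl:::local_seed(42L, render_image("maj", cfg))
  # same latent background, so the difference isolates the disc
  diff <- img_min - img_maj
  expect_gt(sum(diff > 0), 40)            # pi * 4^2 ~ 50 pixels
  expect_true(all(diff >= 0))
  # majority carries no region matching the disc amplitude
  expect_lt(max(img_maj), 0.8)
  expect_error(render_image("lesional", cfg), "label")
})

test_that("minority peak equals background plus lesion amplitude (no noise)", {
  cfg <- synthetic_config(noise_sd = 0, lesion_intensity = 0.3,
                          lesion_radius_range = c(3L, 3L))
  img_min <- dttl:::local_seed(7L, render_image("min", cfg))
  img_maj <- dttl:::local_seed(7L, render_image("maj", cfg))
  disc <- img_min - img_maj > 0
  expected <- min(max(img_maj[disc]) + 0.3, 1)
  expect_equal(max(img_min), expected, tolerance = 1e-12)
})

test_that("rendering is bit-identical under a fixed seed", {
  cfg <- synthetic_config()
  a <- dttl:::local_seed(11L, render_image("min", cfg))
  b <- dttl:::local_seed(11L, render_image("min", cfg))
  expect_identical(a, b)
})

test_that("domain shift is the documented affine clip transform", {
  idcfg <- synthetic_config(shift_contrast = 1, shift_brightness = 0,
                            noise_sd = 0)
  img <- matrix(runif(64), 8, 8)
  expect_equal(apply_domain_shift(img, idcfg), img)
  cfg <- synthetic_config(shift_contrast = 1.5, shift_brightness = 0.1,
                          noise_sd = 0)
  expect_equal(apply_domain_shift(matrix(0.4, 8, 8), cfg),
               matrix(0.7, 8, 8), tolerance = 1e-12)
  cfg2 <- synthetic_config(shift_contrast = 2, shift_brightness = 0,
                           noise_sd = 0)
  expect_equal(apply_domain_shift(matrix(0.9, 8, 8), cfg2),
               matrix(1, 8, 8))
  bad <- synthetic_config()
  bad$shift_contrast <- NaN
  expect_error(apply_domain_shift(img, bad), "finite")
})

test_that("cohorts honour configured counts and imbalance ratio", {
  cfg <- tiny_syn_config()
  cfg$n_source_majority <- 40L
  cfg$n_source_minority <- 10L
  co <- make_cohort(cfg)
  sm <- cohort_summary(co)
  expect_equal(sm$n_majority, c(40L, 48L))
  expect_equal(sm$n_minority, c(10L, 12L))
  expect_equal(sm$imbalance_ratio[1], 0.25)
})

test_that("imbalance ratio matches published-style cohort counts", {
  co <- make_cohort(tiny_syn_config())
  sm <- cohort_summary(co)
  expect_equal(sm$imbalance_ratio, c(0.25, 0.25))
  # screening-archive-scale counts: 20672 majority vs 6011 minority
  big <- structure(list(
    source = list(labels = factor(rep(c("maj", "min"), c(20672, 6011)),
                                  levels = c("maj", "min"))),
    target_hidden = factor(rep(c("maj", "min"), c(1349, 300)),
                           levels = c("maj", "min"))),
    class = "dttl_cohort")
  sm_big <- cohort_summary(big)
  expect_equal(sm_big$imbalance_ratio[1], 0.2908, tolerance = 1e-4)
  co0 <- make_cohort(tiny_syn_config(n_target_minority = 0L))
  expect_equal(cohort_summary(co0)$imbalance_ratio[2], 0)
  co1 <- make_cohort(tiny_syn_config(n_source_minority = 48L))
  expect_equal(cohort_summary(co1)$imbalance_ratio[1], 1)
})

test_that("identity shift leaves no domain gap in class means", {
  cfg <- tiny_syn_config(shift_brightness = 0, shift_contrast = 1,
                         noise_sd = 0)
  co <- make_cohort(cfg)
  for (cls in c("maj", "min")) {
    ms <- mean(co$source$X[co$source$labels == cls, ])
    mt <- mean(co$target$X[co$target_hidden == cls, ])
    expect_lt(abs(ms - mt), 1e-6)
  }
})

test_that("cohorts are deterministic given the config", {
  a <- make_cohort(tiny_syn_config(seed = 9L))
  b <- make_cohort(tiny_syn_config(seed = 9L))
  expect_identical(a$source$X, b$source$X)
  expect_identical(a$target$X, b$target$X)
  expect_identical(a$target_hidden, b$target_hidden)
  c2 <- make_cohort(tiny_syn_config(seed = 10L))
  expect_false(identical(a$source$X, c2$source$X))
})

test_that("template matching separates classes perfectly without noise", {
  cfg <- tiny_syn_config(shift_brightness = 0, shift_contrast = 1,
                         noise_sd = 0)
  co <- make_cohort(cfg)
  r_s <- template_response(co$source$X, cfg$image_size, radius = 2L)
  r_t <- template_response(co$target$X, cfg$image_size, radius = 2L)
  expect_equal(auc(r_s, co$source$labels), 1.0)
  expect_equal(auc(r_t, co$target_hidden), 1.0)
})

test_that("domain gap grows with the brightness shift", {
  gaps <- vapply(c(0, 0.1, 0.25), function(b) {
    cfg <- tiny_syn_config(shift_brightness = b, shift_contrast = 1,
                           noise_sd = 0)
    co <- make_cohort(cfg)
    gap <- 0
    for (cls in c("maj", "min")) {
      ms <- colMeans(co$source$X[co$source$labels == cls, , drop = FALSE])
      mt <- colMeans(co$target$X[co$target_hidden == cls, , drop = FALSE])
      gap <- gap + mean(abs(ms - mt))
    }
    gap / 2
  }, numeric(1))
  expect_true(all(diff(gaps) >= 0))
})
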