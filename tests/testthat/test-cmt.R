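identity_gen <- function(X) X

test_that("direct-translation loss measures pixel deviation from input", {
  X <- matrix(0.5, 3, 16)
  expect_equal(dt_loss(identity_gen, X), 0)
  expect_equal(dt_loss(function(x) x + 0.2, X), 0.2, tolerance = 1e-12)
  set.seed(2)
  Xr <- random_images(5)
  shift <- function(x) x + 0.07
  expect_equal(dt_loss(shift, Xr), dt_loss(shift, Xr[sample(5), ]),
               tolerance = 1e-12)
  expect_error(dt_loss(identity_gen, Xr[0, , drop = FALSE]), "empty")
})

test_that("cycle-consistency loss vanishes for exact inverses", {
  Xs <- matrix(0.4, 2, 9)
  Xt <- matrix(0.6, 2, 9)
  expect_equal(mcc_loss(identity_gen, identity_gen, Xs, Xt), 0)
  plus <- function(x) x + 0.1
  minus <- function(x) x - 0.1
  expect_equal(mcc_loss(plus, minus, Xs, Xt), 0, tolerance = 1e-12)
  expect_equal(mcc_loss(plus, identity_gen, Xs, Xt), 0.2,
               tolerance = 1e-12)
  expect_equal(mcc_loss(plus, identity_gen, Xs, NULL), 0.1,
               tolerance = 1e-12)
  expect_error(mcc_loss(plus, minus, NULL, NULL), "empty")
})

test_that("identity loss penalises generators that move in-domain samples", {
  Xs <- matrix(0.3, 2, 4)
  Xt <- matrix(0.3, 2, 4)
  expect_equal(identity_loss(identity_gen, identity_gen, Xs, Xt), 0)
  zero_gen <- function(x) x * 0
  expect_equal(identity_loss(identity_gen, zero_gen, Xs, NULL), 0.3,
               tolerance = 1e-12)
  set.seed(8)
  g1 <- function(x) pmin(pmax(x + rnorm(1), 0), 1)
  expect_gte(identity_loss(g1, g1, random_images(3), random_images(3)), 0)
})

test_that("pixel losses agree with scalar-loop oracles on random images", {
  set.seed(77)
  for (rep in 1:5) {
    X <- random_images(4)
    g <- function(x) pmin(pmax(1.1 * x - 0.03, 0), 1)
    gp <- function(x) pmin(pmax(0.9 * x + 0.05, 0), 1)
    expect_equal(dt_loss(g, X), l1_mean_oracle(g(X), X), tolerance = 1e-6)
    Y <- random_images(3)
    expect_equal(mcc_loss(g, gp, X, Y),
                 l1_mean_oracle(gp(g(X)), X) + l1_mean_oracle(g(gp(Y)), Y),
                 tolerance = 1e-6)
    expect_equal(identity_loss(g, gp, X, Y),
                 l1_mean_oracle(gp(X), X) + l1_mean_oracle(g(Y), Y),
                 tolerance = 1e-6)
  }
})

test_that("adversarial losses match closed forms and the scalar oracle", {
  const_disc <- function(v) function(X) rep(v, nrow(X))
  state_half <- list(G = identity_gen, G_prime = identity_gen,
                     D_s = const_disc(0.5), D_t = const_disc(0.5))
  B <- random_images(2)
  gl <- gan_losses(state_half, B, B, B, B)
  expect_equal(gl$discriminator, 4 * log(0.5), tolerance = 1e-9)
  # single-sample arithmetic case: D_t(x)=0.8, D_t(G(x))=0.3,
  # D_s(x)=0.9, D_s(G'(x))=0.4
  mk_disc <- function(real, fake, fake_X) function(X) {
    if (isTRUE(all.equal(X, fake_X))) rep(fake, nrow(X))
    else rep(real, nrow(X))
  }
  x1 <- random_images(1)
  state <- list(G = function(x) x + 1e-3, G_prime = function(x) x - 1e-3,
                D_t = mk_disc(0.8, 0.3, x1 + 1e-3),
                D_s = mk_disc(0.9, 0.4, x1 - 1e-3))
  gl2 <- gan_losses(state, x1, x1, x1, x1)
  expect_equal(gl2$discriminator,
               log(0.8) + log(0.7) + log(0.9) + log(0.6),
               tolerance = 1e-9)
  expect_equal(gl2$discriminator,
               gan_disc_oracle(0.8, 0.3, 0.9, 0.4), tolerance = 1e-9)
  # perfect discriminators (real -> 1, fake -> 0) approach the supremum 0
  shift_g <- function(x) x + 1e-3
  fake_B <- B + 1e-3
  perfect <- function(X) {
    if (isTRUE(all.equal(X, fake_B))) rep(1e-9, nrow(X)) else
      rep(1 - 1e-9, nrow(X))
  }
  state_sup <- list(G = shift_g, G_prime = shift_g,
                    D_s = perfect, D_t = perfect)
  expect_gt(gan_losses(state_sup, B, B, B, B)$discriminator, -1e-4)
  expect_error(gan_losses(state_half, B[0, , drop = FALSE], B, B, B),
               "empty")
})

test_that("combined objective is the stated weighted sum and linear", {
  expect_equal(cmt_objective(-1, 0.2, 0.4, 0.1,
                             cmt_weights(1, 10, 5)), 3.7)
  expect_equal(cmt_objective(-2, 1, 1, 1, cmt_weights(0, 0, 0)), -2)
  w <- cmt_weights(2, 3, 4)
  a <- cmt_objective(1, 1, 1, 1, w)
  expect_equal(cmt_objective(1, 2, 1, 1, w) - a, 2)
  expect_equal(cmt_objective(1, 1, 2, 1, w) - a, 3)
  expect_equal(cmt_objective(1, 1, 1, 2, w) - a, 4)
})

test_that("synthesis is one-to-one with identity provenance", {
  co <- make_cohort(tiny_syn_config())
  part <- list(maj = 1:48, min = 49:60,
               pseudo_labels = factor(rep(c("maj", "min"), c(48, 12)),
                                      levels = c("maj", "min")))
  class(part) <- "dttl_partition"
  state <- train_cmt(co$source, part, co$target,
                     cmt_config(max_epochs = 0L, seed = 4L))
  maj_X <- co$source$X[co$source$labels == "maj", ]
  pool <- synthesize_minority(state, maj_X)
  expect_equal(nrow(pool$X), nrow(maj_X))
  expect_equal(pool$provenance, seq_len(nrow(maj_X)))
  # untrained generators are identity-initialised
  expect_equal(pool$X, maj_X)
  empty <- synthesize_minority(state, maj_X[0, , drop = FALSE])
  expect_equal(nrow(empty$X), 0)
})

test_that("translation training logs all components deterministically", {
  co <- make_cohort(tiny_syn_config())
  part <- list(maj = 1:48, min = 49:60,
               pseudo_labels = factor(rep(c("maj", "min"), c(48, 12)),
                                      levels = c("maj", "min")))
  class(part) <- "dttl_partition"
  cfg <- cmt_config(max_epochs = 2L, learning_rate = 1e-3, seed = 5L)
  a <- train_cmt(co$source, part, co$target, cfg)
  b <- train_cmt(co$source, part, co$target, cfg)
  expect_identical(a$training_log, b$training_log)
  expect_named(a$training_log,
               c("epoch", "l_gan", "l_dt", "l_mcc", "l_ide", "l_cmt"))
  expect_true(all(is.finite(as.matrix(a$training_log))))
  expect_true(all(a$training_log[, c("l_dt", "l_mcc", "l_ide")] >= 0))
  # outputs stay valid images
  pool <- synthesize_minority(a, co$source$X[co$source$labels == "maj", ])
  expect_true(all(pool$X >= 0 & pool$X <= 1))
  expect_equal(ncol(pool$X), ncol(co$source$X))
})

test_that("empty required subsets are named in errors", {
  co <- make_cohort(tiny_syn_config())
  part_bad <- list(maj = seq_len(nrow(co$target$X)), min = integer(0),
                   pseudo_labels = factor(rep("maj", nrow(co$target$X)),
                                          levels = c("maj", "min")))
  class(part_bad) <- "dttl_partition"
  expect_error(train_cmt(co$source, part_bad, co$target, cmt_config()),
               "pseudo-minority")
})

test_that("translated majority images acquire minority structure", {
  # ground-truth partition stands in for pseudo-labels: this block tests
  # the translation stage in isolation on the default cohort
  co <- make_cohort(synthetic_config(seed = 21L))
  n <- nrow(co$target$X)
  min_idx <- which(co$target_hidden == "min")
  part <- structure(list(maj = setdiff(seq_len(n), min_idx), min = min_idx,
                         pseudo_labels = co$target_hidden),
                    class = "dttl_partition")
  cm <- train_cmt(co$source, part, co$target,
                  cmt_config(learning_rate = 2e-3, max_epochs = 40L,
                             seed = 21L))
  maj_X <- co$source$X[co$source$labels == "maj", ]
  pool <- synthesize_minority(cm, maj_X)
  r_before <- mean(template_response(maj_X, 32L))
  r_after <- mean(template_response(pool$X, 32L))
  expect_gt(r_after, r_before)
})
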