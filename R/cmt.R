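# ---- cross-domain minority translation -----------------------------------
#
# A cycle-consistency GAN with two residual generators, G (source-majority ->
# target-minority) and G' (target-majority -> source-minority), and two
# discriminators: D_t scores target-side realism against the full target
# domain, D_s scores source-side realism against the full source domain.
# The objective combines the adversarial loss with direct-translation (DT),
# minority-cycle-consistency (MCC) and identity (IDE) pixel losses.

#' Loss weights for the minority-translation objective
#'
#' Total objective: `gan + lambda_dt * dt + lambda_mcc * mcc +
#' lambda_ide * ide`. Defaults follow the usual cycle-translation convention
#' (cycle consistency weighted far above the identity and direct terms).
#'
#' @param lambda_dt,lambda_mcc,lambda_ide non-negative weights.
#' @return an object of class `dttl_cmt_weights`.
#' @export
cmt_weights <- function(lambda_dt = 1, lambda_mcc = 10, lambda_ide = 5) {
  stopifnot(lambda_dt >= 0, lambda_mcc >= 0, lambda_ide >= 0)
  structure(list(lambda_dt = lambda_dt, lambda_mcc = lambda_mcc,
                 lambda_ide = lambda_ide), class = "dttl_cmt_weights")
}

#' Training configuration for minority translation
#'
#' @param weights a [cmt_weights()].
#' @param learning_rate,weight_decay,batch_size,max_epochs,loss_tolerance
#'   Adam and stopping settings (see [cda_config()]).
#' @param gen_hidden,disc_hidden hidden widths of the residual generators and
#'   the discriminators.
#' @param gen_grid block size of the generators' coarse residual grid
#'   (1 = per-pixel residuals); the default matches the lesion scale.
#' @param disc_pool optional average-pooling factor in front of the
#'   discriminators (fixed linear map; default 1 = raw pixels, which keeps
#'   the discriminators sensitive to the fine lesion structure the
#'   translation should acquire).
#' @param dt_on_source_majority if `TRUE`, the direct-translation loss is
#'   evaluated on source-majority rather than target-majority images (an
#'   alternative reading of the objective; default `FALSE`).
#' @param seed integer seed.
#' @return an object of class `dttl_cmt_config`.
#' @export
cmt_config <- function(weights = cmt_weights(), learning_rate = 2e-4,
                       weight_decay = 5e-4, batch_size = 16L,
                       max_epochs = 200L, loss_tolerance = 5e-4,
                       gen_hidden = 32L, disc_hidden = 32L,
                       gen_grid = 4L, disc_pool = 1L,
                       dt_on_source_majority = FALSE, seed = 1L) {
  stopifnot(inherits(weights, "dttl_cmt_weights"), learning_rate > 0,
            batch_size >= 1, max_epochs >= 0, loss_tolerance >= 0)
  structure(list(weights = weights, learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 loss_tolerance = loss_tolerance,
                 gen_hidden = as.integer(gen_hidden),
                 disc_hidden = as.integer(disc_hidden),
                 gen_grid = as.integer(gen_grid),
                 disc_pool = as.integer(disc_pool),
                 dt_on_source_majority = isTRUE(dt_on_source_majority),
                 seed = as.integer(seed)),
            class = "dttl_cmt_config")
}

# apply a generator given either a dttl_generator net or a plain function
apply_gen <- function(G, X) {
  if (is.function(G)) G(X) else gen_forward(G, X)$out
}

disc_prob <- function(D, X) {
  if (is.function(D)) D(X) else sigmoid(mlp_forward(D, X)$out[, 1L])
}

#' Direct translation (DT) loss
#'
#' Mean absolute pixel deviation between a generator's output and its input,
#' `mean |G(x) - x|`, averaged over all pixels of the batch.
#'
#' @param G a generator (`dttl_generator` or a function on pixel matrices).
#' @param batch n x p pixel matrix (non-empty).
#' @return scalar loss (>= 0).
#' @export
dt_loss <- function(G, batch) {
  if (is.null(batch) || nrow(batch) == 0L) stop("dt_loss: empty batch")
  mean(abs(apply_gen(G, batch) - batch))
}

#' Minority cycle-consistency (MCC) loss
#'
#' `mean |G'(G(x_s)) - x_s| + mean |G(G'(x_t)) - x_t|`: round-trip
#' translation must reconstruct the input minority samples. An empty side
#' contributes 0; both sides empty is an error.
#'
#' @param G,G_prime generators.
#' @param batch_s source-minority pixel matrix (or `NULL`).
#' @param batch_t target-minority pixel matrix (or `NULL`).
#' @return scalar loss (>= 0).
#' @export
mcc_loss <- function(G, G_prime, batch_s, batch_t) {
  ns <- if (is.null(batch_s)) 0L else nrow(batch_s)
  nt <- if (is.null(batch_t)) 0L else nrow(batch_t)
  if (ns == 0L && nt == 0L) stop("mcc_loss: both batches empty")
  out <- 0
  if (ns > 0L)
    out <- out + mean(abs(apply_gen(G_prime, apply_gen(G, batch_s)) - batch_s))
  if (nt > 0L)
    out <- out + mean(abs(apply_gen(G, apply_gen(G_prime, batch_t)) - batch_t))
  out
}

#' Identity (IDE) loss
#'
#' `mean |G'(x_s) - x_s| + mean |G(x_t) - x_t|`: each generator should act as
#' the identity on samples already drawn from its output-side minority
#' distribution.
#'
#' @inheritParams mcc_loss
#' @return scalar loss (>= 0).
#' @export
identity_loss <- function(G, G_prime, batch_s, batch_t) {
  ns <- if (is.null(batch_s)) 0L else nrow(batch_s)
  nt <- if (is.null(batch_t)) 0L else nrow(batch_t)
  if (ns == 0L && nt == 0L) stop("identity_loss: both batches empty")
  out <- 0
  if (ns > 0L)
    out <- out + mean(abs(apply_gen(G_prime, batch_s) - batch_s))
  if (nt > 0L)
    out <- out + mean(abs(apply_gen(G, batch_t) - batch_t))
  out
}

#' Adversarial losses of the translation GAN
#'
#' The discriminator objective is
#' `mean log D_t(x_t) + mean log(1 - D_t(G(x_s_maj))) + mean log D_s(x_s) +
#' mean log(1 - D_s(G'(x_t_maj)))`, maximised by the discriminators
#' (real = the full target/source domains, fake = the translated majority
#' batches). The generators oppose them; the returned generator loss is the
#' non-saturating form `-mean log D_t(G(x_s_maj)) - mean log D_s(G'(x_t_maj))`.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param state list with generators `G`, `G_prime` and discriminators
#'   `D_s`, `D_t` (networks or plain functions).
#' @param batch_s_maj,batch_t_maj majority pixel batches to translate.
#' @param batch_s_all,batch_t_all real source/target pixel batches.
#' @return list with elements `generator` and `discriminator` (scalars).
#' @export
gan_losses <- function(state, batch_s_maj, batch_t_maj, batch_s_all,
                       batch_t_all) {
  for (b in list(batch_s_maj, batch_t_maj, batch_s_all, batch_t_all))
    if (is.null(b) || nrow(b) == 0L) stop("gan_losses: empty batch")
  fake_t <- apply_gen(state$G, batch_s_maj)
  fake_s <- apply_gen(state$G_prime, batch_t_maj)
  pool_in <- function(X) {
    if (is.null(state$P)) X else X %*% state$P
  }
  d_real_t <- clamp01_eps(disc_prob(state$D_t, pool_in(batch_t_all)))
  d_fake_t <- clamp01_eps(disc_prob(state$D_t, pool_in(fake_t)))
  d_real_s <- clamp01_eps(disc_prob(state$D_s, pool_in(batch_s_all)))
  d_fake_s <- clamp01_eps(disc_prob(state$D_s, pool_in(fake_s)))
  disc <- mean(log(d_real_t)) + mean(log(1 - d_fake_t)) +
    mean(log(d_real_s)) + mean(log(1 - d_fake_s))
  gen <- -mean(log(d_fake_t)) - mean(log(d_fake_s))
  if (!is.finite(disc) || !is.finite(gen))
    stop("gan_losses: non-finite adversarial loss")
  list(generator = gen, discriminator = disc)
}

#' Combined minority-translation objective
#'
#' `gan + lambda_dt * dt + lambda_mcc * mcc + lambda_ide * ide`.
#'
#' @param gan,dt,mcc,ide scalar loss components.
#' @param w a [cmt_weights()].
#' @return scalar.
#' @export
cmt_objective <- function(gan, dt, mcc, ide, w = cmt_weights()) {
  stopifnot(inherits(w, "dttl_cmt_weights"))
  gan + w$lambda_dt * dt + w$lambda_mcc * mcc + w$lambda_ide * ide
}

add_grads <- function(a, b, scale = 1) {
  if (is.null(a)) return(list(W = lapply(b$W, `*`, scale),
                              b = lapply(b$b, `*`, scale)))
  list(W = Map(function(x, y) x + scale * y, a$W, b$W),
       b = Map(function(x, y) x + scale * y, a$b, b$b))
}

sample_batch <- function(n, bs) sample.int(n, bs, replace = bs > n)

#' Train the minority-translation GAN
#'
#' Alternating 1:1 generator/discriminator Adam updates on the combined
#' objective. Real pools for the discriminators are the full source and
#' target domains; fakes are the translated majority batches. Stops when the
#' smoothed variation of the pixel-loss part (DT/MCC/IDE, which is monotone
#' near convergence, unlike the adversarial part) falls below
#' `loss_tolerance`, or at `max_epochs`.
#'
#' @param source labelled `dttl_dataset` with both classes.
#' @param partition `dttl_partition` of the target domain (both sides
#'   non-empty).
#' @param target unlabelled `dttl_dataset`.
#' @param cfg a [cmt_config()].
#' @return object of class `dttl_cmt_state` with `G`, `G_prime`, `D_s`,
#'   `D_t`, `weights` and a per-epoch `training_log` of all loss components.
#' @export
train_cmt <- function(source, partition, target, cfg = cmt_config()) {
  stopifnot(inherits(source, "dttl_dataset"),
            inherits(partition, "dttl_partition"),
            inherits(target, "dttl_dataset"))
  Xs_maj <- source$X[source$labels == "maj", , drop = FALSE]
  Xs_min <- source$X[source$labels == "min", , drop = FALSE]
  Xt_maj <- target$X[partition$maj, , drop = FALSE]
  Xt_min <- target$X[partition$min, , drop = FALSE]
  pools <- list(`source majority` = Xs_maj, `source minority` = Xs_min,
                `target pseudo-majority` = Xt_maj,
                `target pseudo-minority` = Xt_min)
  for (nm in names(pools))
    if (nrow(pools[[nm]]) == 0L)
      stop(sprintf("train_cmt: empty %s set", nm))
  p <- ncol(source$X)
  P <- pool_matrix(as.integer(sqrt(p)), cfg$disc_pool)
  p_d <- if (is.null(P)) p else ncol(P)
  local_seed(derive_seed(cfg$seed, "cmt"), {
    state <- list(
      G = gen_init(p, cfg$gen_hidden, cfg$gen_grid),
      G_prime = gen_init(p, cfg$gen_hidden, cfg$gen_grid),
      P = P,
      D_s = mlp_init(c(p_d, cfg$disc_hidden, 1L)),
      D_t = mlp_init(c(p_d, cfg$disc_hidden, 1L)),
      weights = cfg$weights, cfg = cfg,
      training_log = data.frame(epoch = integer(), l_gan = numeric(),
                                l_dt = numeric(), l_mcc = numeric(),
                                l_ide = numeric(), l_cmt = numeric())
    )
    class(state) <- "dttl_cmt_state"
    if (cfg$max_epochs > 0L)
      state <- run_cmt_epochs(state, Xs_maj, Xs_min, Xt_maj, Xt_min,
                              source$X, target$X, cfg)
    state
  })
}

run_cmt_epochs <- function(state, Xs_maj, Xs_min, Xt_maj, Xt_min,
                           Xs_all, Xt_all, cfg) {
  bs <- cfg$batch_size
  w <- cfg$weights
  optG <- adam_new(state$G)
  optGp <- adam_new(state$G_prime)
  optDs <- adam_new(state$D_s)
  optDt <- adam_new(state$D_t)
  steps <- max(1L, ceiling(nrow(Xs_maj) / bs))
  monitored <- numeric(0)
  npix <- function(X) length(X)
  for (epoch in seq_len(cfg$max_epochs)) {
    ep <- c(l_gan = 0, l_dt = 0, l_mcc = 0, l_ide = 0)
    for (st in seq_len(steps)) {
      b_s_maj <- Xs_maj[sample_batch(nrow(Xs_maj), bs), , drop = FALSE]
      b_t_maj <- Xt_maj[sample_batch(nrow(Xt_maj), bs), , drop = FALSE]
      b_s_min <- Xs_min[sample_batch(nrow(Xs_min), bs), , drop = FALSE]
      b_t_min <- Xt_min[sample_batch(nrow(Xt_min), bs), , drop = FALSE]
      b_s_all <- Xs_all[sample_batch(nrow(Xs_all), bs), , drop = FALSE]
      b_t_all <- Xt_all[sample_batch(nrow(Xt_all), bs), , drop = FALSE]

      # ---- generator step ----
      gG <- NULL
      gGp <- NULL
      # adversarial (non-saturating): push translated batches to "real"
      pool_in <- function(X) if (is.null(state$P)) X else X %*% state$P
      unpool_grad <- function(dXp) if (is.null(state$P)) dXp else
        dXp %*% t(state$P)
      fG <- gen_forward(state$G, b_s_maj)
      dft <- mlp_forward(state$D_t, pool_in(fG$out))
      d_ft <- clamp01_eps(sigmoid(dft$out[, 1L]))
      dZ <- matrix(-(1 - d_ft) / length(d_ft), ncol = 1L)
      dY <- unpool_grad(mlp_backward(dft$cache, dZ)$dX)
      gG <- add_grads(gG, gen_backward(fG$cache, dY))

      fGp <- gen_forward(state$G_prime, b_t_maj)
      dfs <- mlp_forward(state$D_s, pool_in(fGp$out))
      d_fs <- clamp01_eps(sigmoid(dfs$out[, 1L]))
      dZ <- matrix(-(1 - d_fs) / length(d_fs), ncol = 1L)
      dY <- unpool_grad(mlp_backward(dfs$cache, dZ)$dX)
      gGp <- add_grads(gGp, gen_backward(fGp$cache, dY))

      l_gan_gen <- -mean(log(d_ft)) - mean(log(d_fs))
      if (!is.finite(l_gan_gen)) stop("train_cmt: adversarial loss diverged")

      # direct translation
      b_dt <- if (cfg$dt_on_source_majority) b_s_maj else b_t_maj
      fdt <- gen_forward(state$G, b_dt)
      l_dt <- mean(abs(fdt$out - b_dt))
      dY <- sign(fdt$out - b_dt) / npix(b_dt)
      gG <- add_grads(gG, gen_backward(fdt$cache, dY), w$lambda_dt)

      # minority cycle consistency
      f1 <- gen_forward(state$G, b_s_min)
      f2 <- gen_forward(state$G_prime, f1$out)
      l_mcc <- mean(abs(f2$out - b_s_min))
      dY2 <- sign(f2$out - b_s_min) / npix(b_s_min)
      back2 <- gen_backward(f2$cache, dY2)
      gGp <- add_grads(gGp, back2, w$lambda_mcc)
      gG <- add_grads(gG, gen_backward(f1$cache, back2$dX), w$lambda_mcc)

      f3 <- gen_forward(state$G_prime, b_t_min)
      f4 <- gen_forward(state$G, f3$out)
      l_mcc <- l_mcc + mean(abs(f4$out - b_t_min))
      dY4 <- sign(f4$out - b_t_min) / npix(b_t_min)
      back4 <- gen_backward(f4$cache, dY4)
      gG <- add_grads(gG, back4, w$lambda_mcc)
      gGp <- add_grads(gGp, gen_backward(f3$cache, back4$dX), w$lambda_mcc)

      # identity
      f5 <- gen_forward(state$G_prime, b_s_min)
      l_ide <- mean(abs(f5$out - b_s_min))
      dY5 <- sign(f5$out - b_s_min) / npix(b_s_min)
      gGp <- add_grads(gGp, gen_backward(f5$cache, dY5), w$lambda_ide)

      f6 <- gen_forward(state$G, b_t_min)
      l_ide <- l_ide + mean(abs(f6$out - b_t_min))
      dY6 <- sign(f6$out - b_t_min) / npix(b_t_min)
      gG <- add_grads(gG, gen_backward(f6$cache, dY6), w$lambda_ide)

      upd <- adam_step(state$G, gG, optG, cfg$learning_rate,
                       weight_decay = cfg$weight_decay)
      state$G <- upd$net; optG <- upd$opt
      upd <- adam_step(state$G_prime, gGp, optGp, cfg$learning_rate,
                       weight_decay = cfg$weight_decay)
      state$G_prime <- upd$net; optGp <- upd$opt

      # ---- discriminator step (fakes from the updated generators) ----
      fake_t <- gen_forward(state$G, b_s_maj)$out
      fake_s <- gen_forward(state$G_prime, b_t_maj)$out

      Xt_batch <- pool_in(rbind(b_t_all, fake_t))
      dfwd <- mlp_forward(state$D_t, Xt_batch)
      d <- clamp01_eps(sigmoid(dfwd$out[, 1L]))
      nr <- nrow(b_t_all)
      dZ <- matrix(c(-(1 - d[seq_len(nr)]) / nr,
                     d[nr + seq_len(nrow(fake_t))] / nrow(fake_t)),
                   ncol = 1L)
      gDt <- mlp_backward(dfwd$cache, dZ)
      upd <- adam_step(state$D_t, gDt, optDt, cfg$learning_rate,
                       weight_decay = cfg$weight_decay)
      state$D_t <- upd$net; optDt <- upd$opt
      l_gan_t <- mean(log(d[seq_len(nr)])) +
        mean(log(1 - d[nr + seq_len(nrow(fake_t))]))

      Xs_batch <- pool_in(rbind(b_s_all, fake_s))
      dfwd <- mlp_forward(state$D_s, Xs_batch)
      d <- clamp01_eps(sigmoid(dfwd$out[, 1L]))
      nr <- nrow(b_s_all)
      dZ <- matrix(c(-(1 - d[seq_len(nr)]) / nr,
                     d[nr + seq_len(nrow(fake_s))] / nrow(fake_s)),
                   ncol = 1L)
      gDs <- mlp_backward(dfwd$cache, dZ)
      upd <- adam_step(state$D_s, gDs, optDs, cfg$learning_rate,
                       weight_decay = cfg$weight_decay)
      state$D_s <- upd$net; optDs <- upd$opt
      l_gan_s <- mean(log(d[seq_len(nr)])) +
        mean(log(1 - d[nr + seq_len(nrow(fake_s))]))

      ep <- ep + c(l_gan_t + l_gan_s, l_dt, l_mcc, l_ide)
    }
    ep <- ep / steps
    l_cmt <- cmt_objective(ep[1L], ep[2L], ep[3L], ep[4L], w)
    state$training_log <- rbind(state$training_log,
                                data.frame(epoch = epoch, l_gan = ep[1L],
                                           l_dt = ep[2L], l_mcc = ep[3L],
                                           l_ide = ep[4L], l_cmt = l_cmt))
    monitored <- c(monitored,
                   w$lambda_dt * ep[2L] + w$lambda_mcc * ep[3L] +
                     w$lambda_ide * ep[4L])
    if (smoothed_variation(monitored) < cfg$loss_tolerance) break
  }
  state
}

#' Translate source-majority images into synthetic target-minority images
#'
#' Applies the trained generator `G` to each majority image; provenance
#' records which input produced each output. Outputs stay in \[0, 1\].
#'
#' @param state a `dttl_cmt_state`.
#' @param majority n x p pixel matrix of source-majority images (possibly
#'   with zero rows, giving an empty pool).
#' @return object of class `dttl_generated_pool` with `X` (pixel matrix) and
#'   integer `provenance`.
#' @export
synthesize_minority <- function(state, majority) {
  stopifnot(inherits(state, "dttl_cmt_state"), is.matrix(majority))
  if (nrow(majority) == 0L) {
    return(structure(list(X = majority, provenance = integer()),
                     class = "dttl_generated_pool"))
  }
  Y <- gen_forward(state$G, majority)$out
  structure(list(X = Y, provenance = seq_len(nrow(majority))),
            class = "dttl_generated_pool")
}
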