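# ---- cross-domain discriminability adaptation ----------------------------
#
# Adversarial alignment of source and target features (domain-invariant
# feature learning, DFL) combined with a synthetic discriminability (SD)
# loss: source cross-entropy plus lambda times the target prediction
# entropy. After training, the unlabelled target domain is pseudo-labelled
# and partitioned into pseudo-majority / pseudo-minority sets.

#' Configuration for cross-domain discriminability adaptation
#'
#' @param lambda balance parameter (>= 0) weighting the target
#'   prediction-entropy term of the SD loss.
#' @param learning_rate Adam step size (> 0).
#' @param weight_decay L2 weight decay applied by Adam.
#' @param batch_size samples per domain per step (>= 1).
#' @param max_epochs epoch cap; 0 returns the initialised state untrained.
#' @param loss_tolerance stop when the smoothed epoch-loss variation falls
#'   below this value.
#' @param arch integer vector of hidden widths for the feature generator;
#'   the last entry is the feature dimension.
#' @param dropout dropout rate on the domain discriminator's hidden layer.
#' @param adv_weight scale of the adversarial gradient flowing into the
#'   feature generator. It is ramped in smoothly from 0 over training (the
#'   usual warm-up of adversarial adaptation), so the classifier settles
#'   before alignment pressure peaks.
#' @param d_lr_mult learning-rate multiplier for the domain discriminator.
#' @param d_steps discriminator updates per feature-generator update.
#' @param ema_decay exponential-moving-average decay for epoch-level Polyak
#'   averaging of the feature generator and classifier; the averaged weights
#'   form the returned model. 0 disables averaging.
#' @param pool average-pooling factor applied to the input pixels before the
#'   feature generator (a fixed, parameter-free linear map; 1 disables it).
#'   Pooling denoises and stabilises the desk-scale adversarial game.
#' @param seed integer seed for initialisation and batch sampling.
#' @return an object of class `dttl_cda_config`.
#' @export
cda_config <- function(lambda = 0.1, learning_rate = 2e-4,
                       weight_decay = 5e-4, batch_size = 16L,
                       max_epochs = 200L, loss_tolerance = 5e-4,
                       arch = c(64L, 32L), dropout = 0.5,
                       adv_weight = 1, d_lr_mult = 1, d_steps = 1L,
                       pool = 4L, ema_decay = 0.9, seed = 1L) {
  stopifnot(lambda >= 0, learning_rate > 0, batch_size >= 1,
            max_epochs >= 0, loss_tolerance >= 0, length(arch) >= 1,
            dropout >= 0, dropout < 1, adv_weight >= 0, d_lr_mult > 0,
            d_steps >= 1, pool >= 1, ema_decay >= 0, ema_decay < 1)
  structure(list(lambda = lambda, learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 loss_tolerance = loss_tolerance, arch = as.integer(arch),
                 dropout = dropout, adv_weight = adv_weight,
                 d_lr_mult = d_lr_mult, d_steps = as.integer(d_steps),
                 pool = as.integer(pool), ema_decay = ema_decay,
                 seed = as.integer(seed)),
            class = "dttl_cda_config")
}

#' Domain-invariant feature learning (DFL) loss
#'
#' `mean(log d_source) + mean(log(1 - d_target))`, the adversarial
#' domain-classification objective: the discriminator ascends on it, the
#' feature generator descends. Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]` before the logarithm; the value is always <= 0 and
#' approaches 0 only under perfect discrimination.
#'
#' @param d_source,d_target discriminator outputs (probability of "source")
#'   for source- and target-domain features.
#' @return scalar loss value.
#' @export
dfl_loss <- function(d_source, d_target) {
  if (length(d_source) == 0L || length(d_target) == 0L)
    stop("dfl_loss: empty batch")
  mean(log(clamp01_eps(d_source))) + mean(log(clamp01_eps(1 - d_target)))
}

#' Synthetic discriminability (SD) loss
#'
#' Source cross-entropy plus `lambda` times the mean target prediction
#' entropy: `-mean_s log p(true class) - lambda * mean_t sum_k p_k log p_k`.
#' The target term equals `+lambda *` mean entropy, so minimising it
#' sharpens target predictions.
#'
#' @param p_source n_s x 2 matrix of source class probabilities
#'   (columns: maj, min).
#' @param y_source source labels (`"maj"`/`"min"`).
#' @param p_target n_t x 2 matrix of target class probabilities.
#' @param lambda entropy weight (>= 0).
#' @return scalar loss value.
#' @export
sd_loss <- function(p_source, y_source, p_target, lambda) {
  y <- factor(as.character(y_source), levels = c("maj", "min"))
  if (anyNA(y)) stop("sd_loss: labels must be 'maj' or 'min'")
  ps <- clamp01_eps(as.matrix(p_source))
  pt <- clamp01_eps(as.matrix(p_target))
  p_true <- ifelse(y == "min", ps[, 2L], ps[, 1L])
  ce <- -mean(log(p_true))
  ent <- -mean(rowSums(pt * log(pt)))
  ce + lambda * ent
}

init_cda_state <- function(p, cfg) {
  s <- as.integer(sqrt(p))
  P <- pool_matrix(s, cfg$pool)
  p_in <- if (is.null(P)) p else ncol(P)
  local_seed(derive_seed(cfg$seed, "init"), {
    feat_dim <- cfg$arch[length(cfg$arch)]
    list(
      P = P,
      input_size = p,
      F = mlp_init(c(p_in, cfg$arch)),
      C = mlp_init(c(feat_dim, 16L, 2L)),
      D = mlp_init(c(feat_dim, 16L, 1L)),
      opt = NULL, cfg = cfg,
      training_log = data.frame(epoch = integer(), l_dfl = numeric(),
                                l_sd = numeric(), l_ce = numeric(),
                                l_ent = numeric())
    )
  })
}

# gradient of mean target prediction entropy w.r.t. softmax pre-activations
entropy_grad <- function(p) {
  lp <- log(clamp01_eps(p))
  s <- rowSums(p * lp)
  -(p * (lp - s)) / nrow(p)
}

smoothed_variation <- function(losses, window = 10L, min_epochs = 40L) {
  n <- length(losses)
  if (n < max(2L * window, min_epochs)) return(Inf)
  abs(mean(losses[(n - window + 1L):n]) -
        mean(losses[(n - 2L * window + 1L):(n - window)]))
}

#' Train the CDA model
#'
#' Alternating optimisation per mini-batch: (i) the domain discriminator
#' ascends on the DFL loss; (ii) the feature generator descends on it while
#' the generator and classifier jointly descend on the SD loss. Adam with
#' weight decay throughout; training stops when the smoothed epoch-loss
#' variation drops below `loss_tolerance` or after `max_epochs`.
#'
#' With `mode = "source_only"` the adversarial and entropy terms are
#' skipped and F, C are fitted by source cross-entropy alone (the baseline
#' and the CDA-ablated variant).
#'
#' @param source labelled `dttl_dataset` containing both classes.
#' @param target unlabelled `dttl_dataset` (same image size).
#' @param cfg a [cda_config()].
#' @param mode `"cda"` (default) or `"source_only"`.
#' @return an object of class `dttl_cda_state` holding the networks `F`,
#'   `C`, `D` and a per-epoch `training_log`.
#' @export
train_cda <- function(source, target, cfg = cda_config(), mode = "cda") {
  stopifnot(inherits(source, "dttl_dataset"), inherits(target, "dttl_dataset"))
  mode <- match.arg(mode, c("cda", "source_only"))
  if (nrow(source$X) == 0L || nrow(target$X) == 0L)
    stop("source and target must be non-empty")
  if (length(unique(source$labels)) < 2L)
    stop("source must contain both classes")
  p <- ncol(source$X)
  state <- init_cda_state(p, cfg)
  state$mode <- mode
  class(state) <- "dttl_cda_state"
  if (cfg$max_epochs == 0L) return(state)
  state <- local_seed(derive_seed(cfg$seed, "cda"),
                      run_cda_epochs(state, source, target, cfg, mode))
  state
}

run_cda_epochs <- function(state, source, target, cfg, mode) {
  Xs <- if (is.null(state$P)) source$X else source$X %*% state$P
  Xt <- if (is.null(state$P)) target$X else target$X %*% state$P
  ys <- source$labels
  ns <- nrow(Xs)
  nt <- nrow(Xt)
  bs <- cfg$batch_size
  onehot <- cbind(as.numeric(ys == "maj"), as.numeric(ys == "min"))
  optF <- adam_new(state$F)
  optC <- adam_new(state$C)
  optD <- adam_new(state$D)
  steps <- max(1L, ceiling(max(ns, nt) / bs))
  monitored <- numeric(0)
  ema <- NULL
  blend <- function(old, new, d) {
    for (l in seq_along(new$W)) {
      new$W[[l]] <- d * old$W[[l]] + (1 - d) * new$W[[l]]
      new$b[[l]] <- d * old$b[[l]] + (1 - d) * new$b[[l]]
    }
    new
  }
  for (epoch in seq_len(cfg$max_epochs)) {
    ord_s <- sample.int(ns)
    ord_t <- sample.int(nt)
    # smooth 0 -> adv_weight ramp of the adversarial pressure on F
    adv_w <- cfg$adv_weight *
      (2 / (1 + exp(-10 * epoch / cfg$max_epochs)) - 1)
    ep <- c(l_dfl = 0, l_sd = 0, l_ce = 0, l_ent = 0)
    for (st in seq_len(steps)) {
      is <- ord_s[(((st - 1L) * bs + seq_len(bs) - 1L) %% ns) + 1L]
      it <- ord_t[(((st - 1L) * bs + seq_len(bs) - 1L) %% nt) + 1L]
      xb_s <- Xs[is, , drop = FALSE]
      xb_t <- Xt[it, , drop = FALSE]
      fwd_s <- mlp_forward(state$F, xb_s)
      fs <- tanh(fwd_s$out)
      l_dfl <- NA_real_
      if (mode == "cda") {
        fwd_t <- mlp_forward(state$F, xb_t)
        ft <- tanh(fwd_t$out)
        # --- discriminator ascent on DFL ---
        feats <- rbind(fs, ft)
        for (ds in seq_len(cfg$d_steps)) {
          dfwd <- mlp_forward(state$D, feats, dropout = cfg$dropout,
                              train = TRUE)
          d <- sigmoid(dfwd$out[, 1L])
          d_s <- d[seq_len(bs)]
          d_t <- d[bs + seq_len(bs)]
          if (ds == 1L) {
            l_dfl <- dfl_loss(d_s, d_t)
            if (!is.finite(l_dfl)) stop("train_cda: DFL loss diverged")
          }
          # minimise -L_dfl in theta_d
          dZ <- matrix(c(-(1 - d_s) / bs, d_t / bs), ncol = 1L)
          gD <- mlp_backward(dfwd$cache, dZ)
          upd <- adam_step(state$D, gD, optD,
                           cfg$learning_rate * cfg$d_lr_mult,
                           weight_decay = cfg$weight_decay)
          state$D <- upd$net
          optD <- upd$opt
        }
        # --- feature/classifier descent ---
        dfwd2 <- mlp_forward(state$D, feats)
        d2 <- sigmoid(dfwd2$out[, 1L])
        d2s <- d2[seq_len(bs)]
        d2t <- d2[bs + seq_len(bs)]
        # minimise +L_dfl in theta_f (warm-up scaled)
        dZf <- adv_w * matrix(c((1 - d2s) / bs, -d2t / bs), ncol = 1L)
        dFeat_adv <- mlp_backward(dfwd2$cache, dZf)$dX
        cf_s <- mlp_forward(state$C, fs)
        p_s <- softmax_rows(cf_s$out)
        cf_t <- mlp_forward(state$C, ft)
        p_t <- softmax_rows(cf_t$out)
        l_ce <- -mean(log(clamp01_eps(
          ifelse(ys[is] == "min", p_s[, 2L], p_s[, 1L]))))
        l_ent <- -mean(rowSums(clamp01_eps(p_t) * log(clamp01_eps(p_t))))
        l_sd <- l_ce + cfg$lambda * l_ent
        if (!is.finite(l_sd)) stop("train_cda: SD loss diverged")
        dZc_s <- (p_s - onehot[is, , drop = FALSE]) / bs
        dZc_t <- cfg$lambda * entropy_grad(p_t)
        gC_s <- mlp_backward(cf_s$cache, dZc_s)
        gC_t <- mlp_backward(cf_t$cache, dZc_t)
        gC <- list(W = Map(`+`, gC_s$W, gC_t$W),
                   b = Map(`+`, gC_s$b, gC_t$b))
        dFs <- (gC_s$dX + dFeat_adv[seq_len(bs), , drop = FALSE]) *
          (1 - fs^2)
        dFt <- (gC_t$dX + dFeat_adv[bs + seq_len(bs), , drop = FALSE]) *
          (1 - ft^2)
        gF_s <- mlp_backward(fwd_s$cache, dFs)
        gF_t <- mlp_backward(fwd_t$cache, dFt)
        gF <- list(W = Map(`+`, gF_s$W, gF_t$W),
                   b = Map(`+`, gF_s$b, gF_t$b))
      } else {
        cf_s <- mlp_forward(state$C, fs)
        p_s <- softmax_rows(cf_s$out)
        l_ce <- -mean(log(clamp01_eps(
          ifelse(ys[is] == "min", p_s[, 2L], p_s[, 1L]))))
        if (!is.finite(l_ce)) stop("train_cda: source CE diverged")
        l_ent <- 0
        l_sd <- l_ce
        dZc_s <- (p_s - onehot[is, , drop = FALSE]) / bs
        gC <- mlp_backward(cf_s$cache, dZc_s)
        gF <- mlp_backward(fwd_s$cache, gC$dX * (1 - fs^2))
      }
      updC <- adam_step(state$C, gC, optC, cfg$learning_rate,
                        weight_decay = cfg$weight_decay)
      state$C <- updC$net
      optC <- updC$opt
      updF <- adam_step(state$F, gF, optF, cfg$learning_rate,
                        weight_decay = cfg$weight_decay)
      state$F <- updF$net
      optF <- updF$opt
      ep <- ep + c(if (is.na(l_dfl)) 0 else l_dfl, l_sd, l_ce, l_ent)
    }
    ep <- ep / steps
    state$training_log <- rbind(state$training_log,
                                data.frame(epoch = epoch, l_dfl = ep[1L],
                                           l_sd = ep[2L], l_ce = ep[3L],
                                           l_ent = ep[4L]))
    monitored <- c(monitored, ep[2L])
    if (cfg$ema_decay > 0) {
      ema <- if (is.null(ema)) list(F = state$F, C = state$C) else
        list(F = blend(ema$F, state$F, cfg$ema_decay),
             C = blend(ema$C, state$C, cfg$ema_decay))
    }
    if (smoothed_variation(monitored) < cfg$loss_tolerance) break
  }
  if (!is.null(ema)) {
    state$F <- ema$F
    state$C <- ema$C
  }
  state
}

#' Class probabilities of the current model
#'
#' @param state a `dttl_cda_state`.
#' @param X n x p pixel matrix matching the trained input width.
#' @return n x 2 matrix of probabilities (columns `maj`, `min`), rows
#'   summing to 1.
#' @export
predict_proba <- function(state, X) {
  stopifnot(inherits(state, "dttl_cda_state"))
  if (ncol(X) != state$input_size)
    stop("predict_proba: input width does not match the trained model")
  if (!is.null(state$P)) X <- X %*% state$P
  feats <- tanh(mlp_forward(state$F, X)$out)
  p <- softmax_rows(mlp_forward(state$C, feats)$out)
  colnames(p) <- c("maj", "min")
  p
}

#' Pseudo-label and partition the target domain
#'
#' Each target sample receives the argmax class of `C(F(x))`; exact ties go
#' to the majority class. The returned partition is disjoint and covers the
#' whole target set.
#'
#' @param state a `dttl_cda_state`.
#' @param target unlabelled `dttl_dataset`.
#' @return object of class `dttl_partition` with integer index vectors
#'   `maj`, `min` and the factor `pseudo_labels`.
#' @export
pseudo_label <- function(state, target) {
  stopifnot(inherits(target, "dttl_dataset"))
  if (nrow(target$X) == 0L) stop("pseudo_label: empty target set")
  p <- predict_proba(state, target$X)
  lab <- ifelse(p[, 2L] > p[, 1L], "min", "maj")
  pseudo <- factor(lab, levels = c("maj", "min"))
  structure(list(maj = which(pseudo == "maj"),
                 min = which(pseudo == "min"),
                 pseudo_labels = pseudo),
            class = "dttl_partition")
}
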