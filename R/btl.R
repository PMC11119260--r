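# ---- balanced target learning ---------------------------------------------
#
# Confidence-based selection of synthesised minority samples, assembly of the
# balanced pseudo-labelled target set T', and final supervised fine-tuning of
# the feature generator and classifier on T'.

#' Selection hyperparameters
#'
#' @param p_max probability threshold in (0, 1]; synthesised samples whose
#'   predicted minority probability exceeds it are discarded as too far from
#'   the class boundary.
#' @param s retention multiple (> 0) of the target pseudo-minority count.
#' @return object of class `dttl_selection_config`.
#' @export
selection_config <- function(p_max = 0.95, s = 1.0) {
  stopifnot(p_max > 0, p_max <= 1, s > 0)
  structure(list(p_max = p_max, s = s), class = "dttl_selection_config")
}

#' Minority-class probability of synthesised samples
#'
#' Scores each sample of a generated pool with `C(F(x))` restricted to the
#' minority class, using the trained adaptation model.
#'
#' @param state a `dttl_cda_state`.
#' @param pool a `dttl_generated_pool` (non-empty).
#' @return numeric vector of scores in \[0, 1\], one per pool sample.
#' @export
score_minority_prob <- function(state, pool) {
  stopifnot(inherits(pool, "dttl_generated_pool"))
  if (nrow(pool$X) == 0L) stop("score_minority_prob: empty pool")
  predict_proba(state, pool$X)[, 2L]
}

#' Confidence-based selection of synthesised samples
#'
#' Keeps samples with score `<= p_max`, sorts them by descending score (ties
#' broken by pool index, ascending) and returns the first
#' `floor(s * n_min)`, or all eligible samples if fewer are available.
#'
#' @param pool a `dttl_generated_pool`.
#' @param scores numeric vector aligned with the pool.
#' @param cfg a [selection_config()].
#' @param n_min target pseudo-minority count (>= 0).
#' @return list with `indices` (into the pool, in selection order), `X`
#'   (their pixel rows) and `scores`.
#' @export
select_samples <- function(pool, scores, cfg, n_min) {
  stopifnot(inherits(pool, "dttl_generated_pool"),
            inherits(cfg, "dttl_selection_config"),
            length(scores) == nrow(pool$X))
  if (n_min < 0) stop("select_samples: n_min must be >= 0")
  eligible <- which(scores <= cfg$p_max)
  ord <- eligible[order(-scores[eligible], eligible)]
  k <- min(floor(cfg$s * n_min), length(ord))
  idx <- if (k > 0) ord[seq_len(k)] else integer(0)
  list(indices = idx, X = pool$X[idx, , drop = FALSE],
       scores = scores[idx])
}

#' Assemble the balanced target training set
#'
#' Union of the pseudo-majority (label maj), pseudo-minority (label min) and
#' the selected synthesised samples (label min), with per-sample origin
#' recorded.
#'
#' @param part a `dttl_partition` of the target domain.
#' @param target the unlabelled target `dttl_dataset` the partition indexes.
#' @param selected result of [select_samples()] (may be empty).
#' @return object of class `dttl_balanced_set` with `X`, factor `labels`
#'   and factor `origin` in
#'   `{target-pseudo-maj, target-pseudo-min, synthesized-min}`.
#' @export
assemble_balanced_target <- function(part, target, selected) {
  stopifnot(inherits(part, "dttl_partition"),
            inherits(target, "dttl_dataset"))
  X_maj <- target$X[part$maj, , drop = FALSE]
  X_min <- target$X[part$min, , drop = FALSE]
  X_sel <- selected$X
  X <- rbind(X_maj, X_min, X_sel)
  labels <- factor(rep(c("maj", "min", "min"),
                       c(nrow(X_maj), nrow(X_min), nrow(X_sel))),
                   levels = c("maj", "min"))
  origin <- factor(rep(c("target-pseudo-maj", "target-pseudo-min",
                         "synthesized-min"),
                       c(nrow(X_maj), nrow(X_min), nrow(X_sel))),
                   levels = c("target-pseudo-maj", "target-pseudo-min",
                              "synthesized-min"))
  structure(list(X = X, labels = labels, origin = origin),
            class = "dttl_balanced_set")
}

#' Cross-entropy on the balanced target set
#'
#' `-mean log p(true class)` with the usual probability clamping.
#'
#' @param p n x 2 matrix of class probabilities (columns maj, min).
#' @param y labels (`"maj"`/`"min"`).
#' @return scalar loss (>= 0).
#' @export
balanced_ce_loss <- function(p, y) {
  y <- factor(as.character(y), levels = c("maj", "min"))
  if (anyNA(y)) stop("balanced_ce_loss: labels must be 'maj' or 'min'")
  p <- clamp01_eps(as.matrix(p))
  -mean(log(ifelse(y == "min", p[, 2L], p[, 1L])))
}

#' Final supervised training on the balanced target set
#'
#' Continues training the feature generator and classifier (the domain
#' discriminator is frozen and unused) on the balanced set by cross-entropy
#' with Adam, using the same stopping rule as the earlier stages. The
#' networks are reused, not reinitialised.
#'
#' @param state a trained `dttl_cda_state`.
#' @param t_prime a `dttl_balanced_set` containing both labels.
#' @param cfg a [cda_config()] supplying optimiser and stopping settings
#'   (`lambda` is ignored here).
#' @return the fine-tuned `dttl_cda_state`; `training_log` gains the BTL
#'   epochs (column `l_ent`, the balanced cross-entropy, is reused as
#'   `l_sd`/`l_ce` for these rows).
#' @export
train_btl <- function(state, t_prime, cfg = cda_config()) {
  stopifnot(inherits(state, "dttl_cda_state"),
            inherits(t_prime, "dttl_balanced_set"))
  if (length(unique(t_prime$labels)) < 2L)
    stop("train_btl: balanced set contains a single class")
  if (cfg$max_epochs == 0L) return(state)
  local_seed(derive_seed(cfg$seed, "btl"), {
    X <- if (is.null(state$P)) t_prime$X else t_prime$X %*% state$P
    y <- t_prime$labels
    n <- nrow(X)
    bs <- cfg$batch_size
    onehot <- cbind(as.numeric(y == "maj"), as.numeric(y == "min"))
    optF <- adam_new(state$F)
    optC <- adam_new(state$C)
    steps <- max(1L, ceiling(n / bs))
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
      ord <- sample.int(n)
      ep_loss <- 0
      for (st in seq_len(steps)) {
        ib <- ord[(((st - 1L) * bs + seq_len(bs) - 1L) %% n) + 1L]
        xb <- X[ib, , drop = FALSE]
        fwd <- mlp_forward(state$F, xb)
        fb <- tanh(fwd$out)
        cf <- mlp_forward(state$C, fb)
        pb <- softmax_rows(cf$out)
        loss <- balanced_ce_loss(pb, y[ib])
        if (!is.finite(loss)) stop("train_btl: cross-entropy diverged")
        dZ <- (pb - onehot[ib, , drop = FALSE]) / length(ib)
        gC <- mlp_backward(cf$cache, dZ)
        gF <- mlp_backward(fwd$cache, gC$dX * (1 - fb^2))
        upd <- adam_step(state$C, gC, optC, cfg$learning_rate,
                         weight_decay = cfg$weight_decay)
        state$C <- upd$net; optC <- upd$opt
        upd <- adam_step(state$F, gF, optF, cfg$learning_rate,
                         weight_decay = cfg$weight_decay)
        state$F <- upd$net; optF <- upd$opt
        ep_loss <- ep_loss + loss
      }
      ep_loss <- ep_loss / steps
      state$training_log <- rbind(state$training_log,
                                  data.frame(epoch = epoch, l_dfl = NA_real_,
                                             l_sd = ep_loss, l_ce = ep_loss,
                                             l_ent = 0))
      monitored <- c(monitored, ep_loss)
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
  })
}
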