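# shared fixtures and independent scalar-loop oracles

tiny_syn_config <- function(seed = 1L, ...) {
  args <- list(image_size = 16L,
               n_source_majority = 48L, n_source_minority = 12L,
               n_target_majority = 48L, n_target_minority = 12L,
               lesion_radius_range = c(2L, 3L), seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}

tiny_run_config <- function(seed = 1L, ...) {
  run_config(synthetic = tiny_syn_config(seed = seed),
             cda = cda_config(max_epochs = 12L, learning_rate = 1e-3,
                              pool = 4L),
             cmt = cmt_config(max_epochs = 4L, learning_rate = 1e-3),
             btl = cda_config(max_epochs = 8L),
             seed = seed, ...)
}

random_images <- function(n, s = 4L) {
  matrix(runif(n * s * s), n, s * s)
}

# scalar-loop oracles, deliberately naive ---------------------------------

clamp_oracle <- function(p) min(max(p, 1e-7), 1 - 1e-7)

dfl_loss_oracle <- function(d_s, d_t) {
  acc_s <- 0
  for (d in d_s) acc_s <- acc_s + log(clamp_oracle(d))
  acc_t <- 0
  for (d in d_t) acc_t <- acc_t + log(clamp_oracle(1 - d))
  acc_s / length(d_s) + acc_t / length(d_t)
}

sd_loss_oracle <- function(p_s, y_s, p_t, lambda) {
  ce <- 0
  for (i in seq_len(nrow(p_s))) {
    p_true <- if (y_s[i] == "min") p_s[i, 2] else p_s[i, 1]
    ce <- ce - log(clamp_oracle(p_true))
  }
  ce <- ce / nrow(p_s)
  ent <- 0
  for (j in seq_len(nrow(p_t))) {
    for (k in 1:2) {
      pk <- clamp_oracle(p_t[j, k])
      ent <- ent - pk * log(pk)
    }
  }
  ce + lambda * ent / nrow(p_t)
}

l1_mean_oracle <- function(A, B) {
  acc <- 0
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(A)))
      acc <- acc + abs(A[i, j] - B[i, j])
  acc / (nrow(A) * ncol(A))
}

gan_disc_oracle <- function(d_real_t, d_fake_t, d_real_s, d_fake_s) {
  term <- function(v, real) {
    acc <- 0
    for (d in v) acc <- acc + log(clamp_oracle(if (real) d else 1 - d))
    acc / length(v)
  }
  term(d_real_t, TRUE) + term(d_fake_t, FALSE) +
    term(d_real_s, TRUE) + term(d_fake_s, FALSE)
}

# exhaustive filter-sort-truncate selection oracle
select_oracle <- function(scores, p_max, s, n_min) {
  eligible <- which(scores <= p_max)
  if (length(eligible) > 1L) {
    for (a in seq_len(length(eligible) - 1L)) {
      for (b in seq.int(a + 1L, length(eligible))) {
        swap <- scores[eligible[b]] > scores[eligible[a]] ||
          (scores[eligible[b]] == scores[eligible[a]] &&
             eligible[b] < eligible[a])
        if (swap) {
          tmp <- eligible[a]; eligible[a] <- eligible[b]; eligible[b] <- tmp
        }
      }
    }
  }
  k <- min(floor(s * n_min), length(eligible))
  if (k > 0) eligible[seq_len(k)] else integer(0)
}

# O(n^2) pairwise concordance AUC
auc_oracle <- function(scores, labels) {
  pos <- which(labels == "min")
  neg <- which(labels == "maj")
  acc <- 0
  for (i in pos) {
    for (j in neg) {
      if (scores[i] > scores[j]) acc <- acc + 1
      else if (scores[i] == scores[j]) acc <- acc + 0.5
    }
  }
  acc / (length(pos) * length(neg))
}
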