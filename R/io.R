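# ---- dataset and artifact I/O ---------------------------------------------
#
# Directory layout (shared by the synthetic generator and user datasets):
#   source/maj/*.png, source/min/*.png, target/unlabeled/*.png
#   target_manifest.csv (filename, hidden_label)  -- evaluation only
# Images are 8-bit grayscale PNG; pixel values are decoded to [0, 1].

matrix_from_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3L])),
                                         drop = FALSE], c(1L, 2L), mean)
  a
}

# nearest-neighbour resize to s x s
resize_nn <- function(img, s) {
  if (nrow(img) == s && ncol(img) == s) return(img)
  ri <- pmin(nrow(img), pmax(1L, round(seq(1, nrow(img), length.out = s))))
  ci <- pmin(ncol(img), pmax(1L, round(seq(1, ncol(img), length.out = s))))
  img[ri, ci, drop = FALSE]
}

#' Load an image dataset from a directory tree
#'
#' A directory with `maj/` and `min/` subdirectories yields a labelled
#' dataset; a directory of loose images yields an unlabelled one. Images are
#' decoded to \[0, 1\] grayscale and resized (nearest neighbour) to
#' `image_size`. Unreadable files are skipped with a warning; an empty class
#' directory is an error.
#'
#' @param path dataset directory.
#' @param image_size pixels per side; defaults to the first image's size.
#' @return a `dttl_dataset`.
#' @export
load_image_dataset <- function(path, image_size = NULL) {
  if (!dir.exists(path)) stop("load_image_dataset: no such directory: ", path)
  sub <- c("maj", "min")
  labelled <- all(dir.exists(file.path(path, sub)))
  read_dir <- function(d) {
    files <- sort(list.files(d, pattern = "\\.png$", ignore.case = TRUE,
                             full.names = TRUE))
    imgs <- list()
    for (f in files) {
      img <- tryCatch(matrix_from_png(f), error = function(e) {
        warning("skipping unreadable image: ", f, call. = FALSE)
        NULL
      })
      if (!is.null(img)) imgs[[length(imgs) + 1L]] <- img
    }
    imgs
  }
  if (labelled) {
    blocks <- lapply(file.path(path, sub), read_dir)
    for (k in seq_along(sub))
      if (length(blocks[[k]]) == 0L)
        stop("load_image_dataset: empty class directory: ",
             file.path(path, sub[k]))
    imgs <- c(blocks[[1L]], blocks[[2L]])
    labels <- rep(sub, vapply(blocks, length, integer(1)))
  } else {
    imgs <- read_dir(path)
    if (length(imgs) == 0L)
      stop("load_image_dataset: no readable images in ", path)
    labels <- NULL
  }
  if (is.null(image_size)) image_size <- nrow(imgs[[1L]])
  X <- t(vapply(imgs, function(im) as.vector(resize_nn(im, image_size)),
                numeric(image_size^2)))
  image_dataset(X, labels, image_size)
}

#' Write a synthetic cohort as a directory tree
#'
#' Writes 8-bit grayscale PNGs under `source/maj`, `source/min`,
#' `target/unlabeled` and the evaluation-only `target_manifest.csv`
#' (filename, hidden_label).
#'
#' @param cohort a `dttl_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dttl_cohort"))
  s <- cohort$cfg$image_size
  write_block <- function(X, d, prefix) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    names <- sprintf("%s_%04d.png", prefix, seq_len(nrow(X)))
    for (i in seq_len(nrow(X)))
      png::writePNG(matrix(X[i, ], s, s), file.path(d, names[i]))
    names
  }
  src <- cohort$source
  write_block(src$X[src$labels == "maj", , drop = FALSE],
              file.path(dir, "source", "maj"), "maj")
  write_block(src$X[src$labels == "min", , drop = FALSE],
              file.path(dir, "source", "min"), "min")
  tnames <- write_block(cohort$target$X,
                        file.path(dir, "target", "unlabeled"), "tgt")
  utils::write.csv(data.frame(filename = tnames,
                              hidden_label = as.character(cohort$target_hidden)),
                   file.path(dir, "target_manifest.csv"), row.names = FALSE)
  invisible(dir)
}

# polynomial rolling hash of a configuration's JSON serialisation (hex)
config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(unclass_rec(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else unclass(x)
}

#' Save / load model checkpoints
#'
#' Checkpoints are plain-text JSON dumps of all network parameters plus the
#' configuration hash, so they survive version control and diffing.
#'
#' @param state a `dttl_cda_state` or `dttl_cmt_state`.
#' @param path file to write.
#' @return `path` invisibly (`save_checkpoint`); the restored state
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(state, path) {
  nets <- Filter(function(x) inherits(x, "dttl_mlp"), state)
  payload <- list(
    class = class(state)[1L],
    mode = state$mode,
    input_size = state$input_size,
    pool = state$cfg$pool,
    config_hash = config_hash(state$cfg),
    nets = lapply(nets, function(net) list(
      sizes = net$sizes, classes = class(net),
      W = lapply(net$W, identity), b = net$b))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  nets <- lapply(payload$nets, function(n) {
    net <- list(W = lapply(n$W, as.matrix), b = lapply(n$b, as.numeric),
                sizes = as.integer(n$sizes))
    class(net) <- n$classes
    net
  })
  state <- c(nets, list(mode = payload$mode,
                        config_hash = payload$config_hash,
                        training_log = NULL))
  if (!is.null(payload$input_size)) {
    state$input_size <- as.integer(payload$input_size)
    if (!is.null(payload$pool))
      state$P <- pool_matrix(as.integer(sqrt(state$input_size)),
                             as.integer(payload$pool))
  }
  class(state) <- payload$class
  state
}
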