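# Lightweight trainable encoder backend.
#
# Both the token classifier (NER) and the pair classifier (RE) are served by
# the same core: a sparse-categorical-feature embedding layer averaged into
# a tanh hidden state, followed by a softmax output layer, trained with
# minibatch Adam, decoupled weight decay, global-norm gradient clipping,
# hidden-layer dropout and patience-based early stopping on validation loss.
# Any backend that maps feature bags to class scores and supports gradient
# fitting can stand in; this one is written so the whole pipeline trains on
# one CPU in seconds-to-minutes. A full pretrained transformer is a drop-in
# at scale via the same fit/predict surface.

#' Optimization settings for the encoder backend
#'
#' @param dim Embedding/hidden dimension.
#' @param batch_size Minibatch size (examples per optimization step).
#' @param learning_rate Adam step size.
#' @param epochs Maximum passes over the training data.
#' @param patience_steps Early stopping: training halts once this many
#'   optimization steps pass without a new best validation loss.
#' @param eval_every Steps between validation-loss evaluations; defaults to
#'   once per epoch.
#' @param dropout Dropout probability on the hidden layer during training.
#' @param weight_decay Decoupled L2 weight decay on embedding and output
#'   weights.
#' @param grad_clip Global gradient-norm clipping threshold.
#' @param gradient_accumulation Number of minibatches whose gradients are
#'   accumulated before each optimizer step.
#' @param seed Seed for initialization and batch shuffling.
#' @return List of class `encoder_opts`.
#' @export
encoder_opts <- function(dim = 24L, batch_size = 128L, learning_rate = 5e-5,
                         epochs = 10L, patience_steps = 1600L,
                         eval_every = NULL, dropout = 0.1,
                         weight_decay = 0.01, grad_clip = 1.0,
                         gradient_accumulation = 1L, seed = 1L) {
  stopifnot(dim >= 2L, batch_size >= 1L, learning_rate > 0, epochs >= 1L,
            patience_steps >= 1L, dropout >= 0, dropout < 1,
            weight_decay >= 0, grad_clip > 0, gradient_accumulation >= 1L)
  structure(list(dim = as.integer(dim), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 patience_steps = as.integer(patience_steps),
                 eval_every = eval_every, dropout = dropout,
                 weight_decay = weight_decay, grad_clip = grad_clip,
                 gradient_accumulation = as.integer(gradient_accumulation),
                 seed = as.integer(seed)),
            class = "encoder_opts")
}

# featurized dataset: feats = list of character vectors, y = factor levels idx
index_features <- function(feats, vocab) {
  lapply(feats, function(f) {
    ix <- match(f, vocab)
    ix <- ix[!is.na(ix)]
    if (!length(ix)) 0L else ix  # 0 = sentinel "no known features"
  })
}

net_forward <- function(params, feat_ids, drop_mask = NULL) {
  n <- length(feat_ids)
  d <- ncol(params$E)
  lens <- lengths(feat_ids)
  idx <- unlist(feat_ids, use.names = FALSE)
  keep <- idx > 0L
  rows <- rep.int(seq_len(n), lens)[keep]
  idx <- idx[keep]
  Hpre <- matrix(0, n, d)
  if (length(idx)) {
    sums <- rowsum(params$E[idx, , drop = FALSE], rows)
    r <- as.integer(rownames(sums))
    cnt <- tabulate(rows, nbins = n)[r]
    Hpre[r, ] <- sums / cnt
  }
  Hpre <- sweep(Hpre, 2L, params$b1, `+`)
  H <- tanh(Hpre)
  Hd <- if (is.null(drop_mask)) H else H * drop_mask
  logits <- Hd %*% params$W2
  logits <- sweep(logits, 2L, params$b2, `+`)
  list(H = H, Hd = Hd, logits = logits, rows = rows, idx = idx,
       cnt = pmax(tabulate(rows, nbins = n), 1L))
}

softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

xent_loss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

net_loss <- function(params, feat_ids, y, batch = 4096L) {
  n <- length(y); tot <- 0
  for (s in seq(1L, n, by = batch)) {
    ix <- s:min(n, s + batch - 1L)
    p <- softmax_rows(net_forward(params, feat_ids[ix])$logits)
    tot <- tot + xent_loss(p, y[ix]) * length(ix)
  }
  tot / n
}

net_backward <- function(params, fw, y, drop_mask) {
  n <- nrow(fw$logits)
  P <- softmax_rows(fw$logits)
  P[cbind(seq_len(n), y)] <- P[cbind(seq_len(n), y)] - 1
  dlogits <- P / n
  g <- list()
  g$W2 <- crossprod(fw$Hd, dlogits)
  g$b2 <- colSums(dlogits)
  dH <- dlogits %*% t(params$W2)
  if (!is.null(drop_mask)) dH <- dH * drop_mask
  dHpre <- dH * (1 - fw$H^2)
  g$b1 <- colSums(dHpre)
  g$E <- matrix(0, nrow(params$E), ncol(params$E))
  if (length(fw$idx)) {
    contrib <- dHpre[fw$rows, , drop = FALSE] / fw$cnt[fw$rows]
    acc <- rowsum(contrib, fw$idx)
    g$E[as.integer(rownames(acc)), ] <- acc
  }
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, opts) {
  # global-norm clipping, then AdamW update (decay on weight matrices only)
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (gn > opts$grad_clip) grads <- lapply(grads, function(g) g * opts$grad_clip / gn)
  state$t <- state$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(params)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mh <- state$m[[nm]] / (1 - b1^state$t)
    vh <- state$v[[nm]] / (1 - b2^state$t)
    upd <- opts$learning_rate * mh / (sqrt(vh) + eps)
    if (nm %in% c("E", "W2"))
      upd <- upd + opts$learning_rate * opts$weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

#' Fit the sparse-feature softmax network
#'
#' @param feats List of character vectors, one feature bag per example.
#' @param y Character vector of class labels.
#' @param val_feats,val_y Validation examples for early stopping.
#' @param classes Character vector fixing the class order.
#' @param opts [encoder_opts()].
#' @return List of class `softmax_net` with the fitted parameters, feature
#'   vocabulary, class labels and a training log (`step`, `train_loss`,
#'   `val_loss`).
#' @keywords internal
train_softmax_net <- function(feats, y, val_feats, val_y, classes, opts) {
  stopifnot(length(feats) == length(y), length(val_feats) == length(val_y))
  if (!length(feats)) stop("empty training set")
  bad <- setdiff(unique(c(y, val_y)), classes)
  if (length(bad)) stop("label outside class set: ", paste(bad, collapse = ", "))
  vocab <- unique(unlist(feats, use.names = FALSE))
  Xtr <- index_features(feats, vocab)
  Xva <- index_features(val_feats, vocab)
  ytr <- match(y, classes); yva <- match(val_y, classes)
  K <- length(classes); d <- opts$dim
  with_seed(opts$seed, {
    params <- list(
      E = matrix(stats::rnorm(length(vocab) * d, sd = 0.3), length(vocab), d),
      b1 = numeric(d),
      W2 = matrix(stats::rnorm(d * K, sd = 0.1), d, K),
      b2 = numeric(K))
    state <- adam_init(params)
    n <- length(ytr)
    steps_per_epoch <- max(1L, ceiling(n / opts$batch_size / opts$gradient_accumulation))
    eval_every <- if (is.null(opts$eval_every)) steps_per_epoch
                  else as.integer(opts$eval_every)
    best <- list(loss = Inf, params = params, step = 0L)
    log <- list()
    step <- 0L; stopped <- FALSE
    for (epoch in seq_len(opts$epochs)) {
      perm <- sample.int(n)
      b_start <- 1L
      while (b_start <= n && !stopped) {
        acc_grads <- NULL; acc_loss <- 0; nb <- 0L
        for (a in seq_len(opts$gradient_accumulation)) {
          if (b_start > n) break
          ix <- perm[b_start:min(n, b_start + opts$batch_size - 1L)]
          b_start <- b_start + opts$batch_size
          mask <- if (opts$dropout > 0)
            matrix(stats::rbinom(length(ix) * d, 1L, 1 - opts$dropout),
                   length(ix), d) / (1 - opts$dropout) else NULL
          fw <- net_forward(params, Xtr[ix], mask)
          acc_loss <- acc_loss + xent_loss(softmax_rows(fw$logits), ytr[ix])
          g <- net_backward(params, fw, ytr[ix], mask)
          acc_grads <- if (is.null(acc_grads)) g
                       else Map(`+`, acc_grads, g)
          nb <- nb + 1L
        }
        if (nb == 0L) break
        acc_grads <- lapply(acc_grads, function(g) g / nb)
        res <- adam_step(params, acc_grads, state, opts)
        params <- res$params; state <- res$state
        step <- step + 1L
        if (step %% eval_every == 0L) {
          vloss <- net_loss(params, Xva, yva)
          log[[length(log) + 1L]] <- c(step = step,
                                       train_loss = acc_loss / nb,
                                       val_loss = vloss)
          if (vloss < best$loss - 1e-6) {
            best <- list(loss = vloss, params = params, step = step)
          } else if (step - best$step >= opts$patience_steps) {
            stopped <- TRUE
          }
        }
      }
      if (stopped) break
    }
    structure(list(params = best$params, vocab = vocab, classes = classes,
                   best_val_loss = best$loss,
                   log = as.data.frame(do.call(rbind, log)), opts = opts),
              class = "softmax_net")
  })
}

#' Predict class probabilities from a fitted softmax network
#'
#' @param net A `softmax_net`.
#' @param feats List of feature bags.
#' @return Matrix of normalized class probabilities, one row per example,
#'   columns named by class.
#' @keywords internal
predict_softmax_net <- function(net, feats) {
  X <- index_features(feats, net$vocab)
  out <- matrix(0, length(feats), length(net$classes),
                dimnames = list(NULL, net$classes))
  n <- length(feats)
  for (s in seq(1L, n, by = 4096L)) {
    ix <- s:min(n, s + 4095L)
    out[ix, ] <- softmax_rows(net_forward(net$params, X[ix])$logits)
  }
  out
}

# plain-text (JSON) checkpointing so run directories stay portable
save_softmax_net <- function(net, path) {
  obj <- list(params = lapply(net$params, function(p) {
                if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
                else list(data = as.vector(p))
              }),
              vocab = net$vocab, classes = net$classes,
              best_val_loss = net$best_val_loss, opts = unclass(net$opts))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

load_softmax_net <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1L], p$dim[2L]) else p$data
  })
  structure(list(params = params, vocab = obj$vocab, classes = obj$classes,
                 best_val_loss = obj$best_val_loss,
                 log = NULL, opts = do.call(encoder_opts, as.list(obj$opts))),
            class = "softmax_net")
}
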