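#' Training configuration
#'
#' Optimization recipe for the nodule classifier: AdamW, batch size 2, base
#' learning rate 2e-4, 200 epochs with the rate held constant for the first
#' 130 and then decayed ("W" schedule; the default decay is linear to zero,
#' pluggable), 2-class cross-entropy, and top-3 validation-accuracy
#' checkpointing. The default moment pair (0.999, 0.99) for first/second
#' order is deliberately unusual; `conventional_moments = TRUE` swaps in the
#' customary (0.9, 0.999).
#'
#' @param batch_size minibatch size (default 2).
#' @param lr0 initial learning rate (default 2e-4).
#' @param epochs total epochs (default 200).
#' @param constant_epochs epochs at constant `lr0` under the `"W"` schedule
#'   (default 130).
#' @param optimizer `"adamw"`, `"adam"`, or `"sgd"`.
#' @param moment1,moment2 first/second-moment coefficients.
#' @param conventional_moments use (0.9, 0.999) instead of the defaults.
#' @param weight_decay decoupled weight decay on conv/linear weights
#'   (default 0.01; norm gains/biases are not decayed).
#' @param schedule `"W"` (constant then decay) or `"cosine"`.
#' @param seed RNG seed governing shuffling (and any augmentation drawn from
#'   the training loop).
#' @return object of class `train_control`.
#' @export
train_control <- function(batch_size = 2L, lr0 = 2e-4, epochs = 200L,
                          constant_epochs = min(130L, epochs),
                          optimizer = c("adamw", "adam", "sgd"),
                          moment1 = 0.999, moment2 = 0.99,
                          conventional_moments = FALSE,
                          weight_decay = 0.01,
                          schedule = c("W", "cosine"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  schedule <- match.arg(schedule)
  if (constant_epochs > epochs)
    stop("constant_epochs must be <= epochs", call. = FALSE)
  if (lr0 <= 0) stop("lr0 must be positive", call. = FALSE)
  if (conventional_moments) { moment1 <- 0.9; moment2 <- 0.999 }
  structure(list(batch_size = as.integer(batch_size), lr0 = lr0,
                 epochs = as.integer(epochs),
                 constant_epochs = as.integer(constant_epochs),
                 optimizer = optimizer, moment1 = moment1, moment2 = moment2,
                 weight_decay = weight_decay, schedule = schedule,
                 seed = as.integer(seed)),
            class = "train_control")
}

#' Learning rate at a given epoch
#'
#' `"W"` schedule: constant `lr0` through `constant_epochs`, then the
#' pluggable decay (default: linear to zero over the remaining epochs).
#' `"cosine"`: half-cosine from `lr0` to 0 over all epochs.
#'
#' @param control a [train_control()].
#' @param epoch epoch in `1..epochs`.
#' @return learning rate.
#' @export
lr_at_epoch <- function(control, epoch) {
  if (epoch < 1 || epoch > control$epochs)
    stop("epoch out of range 1..", control$epochs, call. = FALSE)
  if (control$schedule == "cosine")
    return(control$lr0 * (1 + cos(pi * epoch / control$epochs)) / 2)
  if (epoch <= control$constant_epochs) return(control$lr0)
  rem <- control$epochs - control$constant_epochs
  control$lr0 * (1 - (epoch - control$constant_epochs) / rem)
}

.label_index <- function(y) {
  if (is.numeric(y) || is.logical(y)) return(as.integer(y) + 1L)  # 0/1 -> 1/2
  v <- match(as.character(y), c("benign", "malignant"))
  if (any(is.na(v))) stop("labels must be benign/malignant (or 0/1)", call. = FALSE)
  v
}

softmax_ce <- function(logits, yidx) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), yidx)], 1e-12)))
  g <- p
  g[cbind(seq_len(n), yidx)] <- g[cbind(seq_len(n), yidx)] - 1
  list(loss = loss, glogits = g / n)
}

.decayable <- function(name) grepl("\\.(W|v)$", name)

optimizer_step <- function(params, grads, state, control, lr) {
  eps <- 1e-8
  state$t <- state$t + 1L
  if (control$optimizer == "sgd") {
    for (nm in names(params)) {
      g <- grads[[nm]]
      if (is.null(g)) next
      if (control$weight_decay > 0 && .decayable(nm))
        g <- g + control$weight_decay * params[[nm]]
      if (is.null(state$mom[[nm]])) state$mom[[nm]] <- 0 * params[[nm]]
      state$mom[[nm]] <- 0.9 * state$mom[[nm]] + g
      params[[nm]] <- params[[nm]] - lr * state$mom[[nm]]
    }
    return(list(params = params, state = state))
  }
  b1 <- control$moment1; b2 <- control$moment2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (control$optimizer == "adam" && control$weight_decay > 0 && .decayable(nm))
      g <- g + control$weight_decay * params[[nm]]   # coupled (plain Adam)
    if (is.null(state$m[[nm]])) { state$m[[nm]] <- 0 * params[[nm]]
                                  state$v[[nm]] <- 0 * params[[nm]] }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (control$optimizer == "adamw" && control$weight_decay > 0 && .decayable(nm))
      upd <- upd + control$weight_decay * params[[nm]]  # decoupled decay
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

.eval_accuracy <- function(net, x, yidx, batch = 8L) {
  n <- dim(x)[5L]
  correct <- 0L
  for (i0 in seq(1L, n, by = batch)) {
    idx <- i0:min(i0 + batch - 1L, n)
    lg <- net_forward(net, x[, , , , idx, drop = FALSE], train = FALSE)$logits
    correct <- correct + sum(max.col(lg, ties.method = "first") == yidx[idx])
  }
  correct / n
}

#' Train a network on labelled patches
#'
#' Minibatch AdamW (or Adam/SGD) with per-epoch logging and online top-3
#' validation-accuracy checkpointing (ties broken in favour of the later
#' epoch). Deterministic for a fixed [train_control()] seed. Aborts with the
#' epoch context if the loss goes non-finite.
#'
#' @param net a built `ghost_resnet3d`.
#' @param x training patches (4D `(n, D, H, W)` array, list of cubes, or 5D
#'   tensor).
#' @param y training labels (`"benign"`/`"malignant"` or 0/1).
#' @param val_x,val_y validation set (may be NULL; checkpoints then track
#'   training accuracy).
#' @param control a [train_control()].
#' @param verbose print per-epoch lines (default FALSE).
#' @return list with `net` (final-epoch weights), `checkpoints` (a
#'   `checkpoint_set`), and `log` (data.frame epoch, lr, train_loss,
#'   val_acc).
#' @export
train_network <- function(net, x, y, val_x = NULL, val_y = NULL,
                          control = train_control(), verbose = FALSE) {
  xb <- as_batch(x)
  yidx <- .label_index(y)
  n <- dim(xb)[5L]
  if (n < 1L) stop("empty training set", call. = FALSE)
  if (length(yidx) != n) stop("x and y lengths differ", call. = FALSE)
  vb <- if (!is.null(val_x)) as_batch(val_x) else NULL
  vidx <- if (!is.null(val_y)) .label_index(val_y) else NULL
  state <- list(t = 0L, m = list(), v = list(), mom = list())
  checkpoints <- list()
  log <- data.frame(epoch = integer(), lr = numeric(),
                    train_loss = numeric(), val_acc = numeric())
  with_seed(control$seed, {
    for (epoch in seq_len(control$epochs)) {
      lr <- lr_at_epoch(control, epoch)
      ord <- sample(n)
      losses <- numeric()
      for (i0 in seq(1L, n, by = control$batch_size)) {
        idx <- ord[i0:min(i0 + control$batch_size - 1L, n)]
        fw <- net_forward(net, xb[, , , , idx, drop = FALSE], train = TRUE)
        net <- fw$net
        ce <- softmax_ce(fw$logits, yidx[idx])
        if (!is.finite(ce$loss))
          stop("non-finite loss at epoch ", epoch, call. = FALSE)
        losses <- c(losses, ce$loss)
        bw <- net_backward(net, fw$caches, ce$glogits)
        params <- net_params(net)
        st <- optimizer_step(params, bw$grads, state, control, lr)
        state <- st$state
        net <- net_set_params(net, st$params)
      }
      val_acc <- if (!is.null(vb)) .eval_accuracy(net, vb, vidx)
                 else .eval_accuracy(net, xb, yidx)
      log[nrow(log) + 1L, ] <- list(epoch, lr, mean(losses), val_acc)
      checkpoints <- .update_checkpoints(checkpoints, net_params(net),
                                         epoch, val_acc)
      if (verbose)
        cat(sprintf("epoch %3d  lr %.2e  loss %.4f  val acc %.3f\n",
                    epoch, lr, mean(losses), val_acc))
    }
  })
  list(net = net,
       checkpoints = structure(checkpoints, class = "checkpoint_set"),
       log = log)
}

# Keep the top 3 (val_acc, epoch) snapshots, sorted by val_acc descending,
# ties to the later epoch.
.update_checkpoints <- function(cps, params, epoch, val_acc) {
  cps[[length(cps) + 1L]] <- list(params = params, epoch = epoch,
                                  val_acc = val_acc)
  accs <- vapply(cps, `[[`, numeric(1), "val_acc")
  eps <- vapply(cps, `[[`, numeric(1), "epoch")
  ord <- order(-accs, -eps)
  cps[ord[seq_len(min(3L, length(cps)))]]
}

#' @export
print.checkpoint_set <- function(x, ...) {
  for (cp in x)
    cat(sprintf("epoch %d: val acc %.4f\n", cp$epoch, cp$val_acc))
  invisible(x)
}

#' Evaluate checkpoints on a test set
#'
#' Each checkpoint is scored individually (confusion matrix, the full metric
#' suite, and the mean softmax confidence of its correct predictions) and
#' the softmax-averaged ensemble of all checkpoints is reported alongside.
#'
#' @param net the trained `ghost_resnet3d` (architecture holder).
#' @param checkpoints a `checkpoint_set` from [train_network()].
#' @param x,y test patches and labels.
#' @return list with `per_checkpoint` (list of `list(epoch, val_acc, cm,
#'   metrics, mean_confidence)`) and `ensemble` of the same shape.
#' @export
evaluate_checkpoints <- function(net, checkpoints, x, y) {
  if (!length(checkpoints)) stop("empty checkpoint set", call. = FALSE)
  xb <- as_batch(x)
  if (dim(xb)[5L] < 1L) stop("empty test set", call. = FALSE)
  yidx <- .label_index(y)
  score <- function(p) {
    pred <- max.col(p, ties.method = "first")
    cm <- confusion_from_predictions(yidx == 2L, pred == 2L)
    conf <- p[cbind(seq_len(nrow(p)), pred)]
    list(cm = cm, metrics = compute_metrics(cm),
         mean_confidence = mean(conf[pred == yidx]))
  }
  probs <- list()
  per <- vector("list", length(checkpoints))
  for (i in seq_along(checkpoints)) {
    cp <- checkpoints[[i]]
    neti <- net_set_params(net, cp$params)
    p <- predict(neti, xb, type = "prob")
    probs[[i]] <- p
    per[[i]] <- c(list(epoch = cp$epoch, val_acc = cp$val_acc), score(p))
  }
  ens <- Reduce(`+`, probs) / length(probs)
  list(per_checkpoint = per, ensemble = score(ens))
}
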