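#' Fit a 3D nodule malignancy classifier
#'
#' The package's central fitting function: builds the configured ghost
#' residual network, trains it with the given optimization recipe, and
#' returns a classed fit with the usual modelling methods ([predict()],
#' [summary()], [plot()], [coef()], [residuals()], [simulate()]).
#' The weights of the best-validation checkpoint are installed in the
#' returned network; all top-3 checkpoints remain available for ensembling
#' via [evaluate_checkpoints()].
#'
#' @param x training patches: 4D `(n, 32, 32, 32)` array, list of 32^3
#'   cubes, or list of `labeled_patch`es.
#' @param y labels, `"benign"`/`"malignant"` (or 0/1). May be omitted when
#'   `x` is a list of `labeled_patch`es carrying labels.
#' @param config a [network_config()] (default: flagship 50-layer ghost
#'   network; reduce `widths` for desk-scale experiments).
#' @param control a [train_control()].
#' @param validation NULL, a fraction in (0, 1) (stratified holdout carved
#'   from `x`), or `list(x =, y =)`.
#' @param verbose print per-epoch progress.
#' @return object of class `nodule_cnn`.
#' @export
nodule_cnn <- function(x, y = NULL, config = network_config(),
                       control = train_control(), validation = NULL,
                       verbose = FALSE) {
  if (is.null(y)) {
    if (!is.list(x) || is.null(x[[1L]]$label))
      stop("y is required unless x is a list of labelled patches", call. = FALSE)
    y <- vapply(x, `[[`, character(1), "label")
  }
  xb <- as_batch(x)
  y <- as.character(.label_levels()[.label_index(y)])
  val <- NULL
  if (is.numeric(validation) && length(validation) == 1L) {
    sp <- split_dataset(y, fractions = c(1 - validation, validation, 0),
                        seed = control$seed)
    val <- list(x = xb[, , , , sp$validation, drop = FALSE],
                y = y[sp$validation])
    xb <- xb[, , , , sp$train, drop = FALSE]
    y <- y[sp$train]
  } else if (is.list(validation)) {
    val <- list(x = as_batch(validation$x), y = validation$y)
  }
  net <- build_network(config, seed = control$seed)
  tr <- train_network(net, xb, y, val$x, val$y, control, verbose = verbose)
  best <- tr$checkpoints[[1L]]
  structure(list(net = net_set_params(tr$net, best$params),
                 final_net = tr$net,
                 checkpoints = tr$checkpoints, log = tr$log,
                 config = config, control = control,
                 best_epoch = best$epoch, best_val_acc = best$val_acc,
                 n_train = length(y),
                 call = match.call()),
            class = "nodule_cnn")
}

.label_levels <- function() c("benign", "malignant")

#' @export
print.nodule_cnn <- function(x, ...) {
  cat("3D nodule malignancy classifier\n")
  print(x$config)
  cat(sprintf("trained %d epochs on %d patches; best val acc %.4f (epoch %d)\n",
              nrow(x$log), x$n_train, x$best_val_acc, x$best_epoch))
  invisible(x)
}

#' @export
summary.nodule_cnn <- function(object, ...) {
  out <- list(config = object$config,
              complexity = complexity_report(object$net),
              log = object$log,
              checkpoints = object$checkpoints,
              best_epoch = object$best_epoch,
              best_val_acc = object$best_val_acc)
  class(out) <- "summary.nodule_cnn"
  out
}

#' @export
print.summary.nodule_cnn <- function(x, ...) {
  print(x$config)
  print(x$complexity)
  cat("top checkpoints:\n"); print(x$checkpoints)
  tail_n <- min(5L, nrow(x$log))
  cat("last epochs:\n")
  print(utils::tail(x$log, tail_n), row.names = FALSE)
  invisible(x)
}

#' @export
predict.nodule_cnn <- function(object, newdata,
                               type = c("prob", "class", "logits"), ...) {
  type <- match.arg(type)
  predict(object$net, newdata, type = type)
}

#' @export
coef.nodule_cnn <- function(object, ...) net_params(object$net)

#' Response residuals of the fitted classifier
#'
#' `y - p(malignant)` with y coded 0 (benign) / 1 (malignant), on the data
#' supplied.
#'
#' @param object a `nodule_cnn`.
#' @param x patches.
#' @param y labels.
#' @param ... unused.
#' @return numeric vector of residuals.
#' @export
residuals.nodule_cnn <- function(object, x, y, ...) {
  p <- predict(object, x, type = "prob")[, "malignant"]
  (.label_index(y) - 1L) - p
}

#' Simulate labels from the fitted class probabilities
#'
#' @param object a `nodule_cnn`.
#' @param nsim number of simulated label vectors.
#' @param seed RNG seed.
#' @param x patches to simulate labels for.
#' @param ... unused.
#' @return data.frame with `nsim` columns of simulated labels.
#' @export
simulate.nodule_cnn <- function(object, nsim = 1, seed = NULL, x, ...) {
  p <- predict(object, x, type = "prob")[, "malignant"]
  draw <- function() .label_levels()[1L + stats::rbinom(length(p), 1L, p)]
  sims <- if (is.null(seed)) replicate(nsim, draw(), simplify = FALSE)
          else with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)),
                       stringsAsFactors = FALSE)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Training curves of a fitted classifier
#'
#' Two-panel base-graphics plot: training loss and validation accuracy per
#' epoch, with the learning-rate schedule overlaid.
#'
#' @param x a `nodule_cnn`.
#' @param ... passed to [plot.default()].
#' @return `x`, invisibly.
#' @export
plot.nodule_cnn <- function(x, ...) {
  log <- x$log
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(log$epoch, log$train_loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "loss", ...)
  plot(log$epoch, log$val_acc, type = "l", xlab = "epoch",
       ylab = "validation accuracy", ylim = c(0, 1), main = "accuracy", ...)
  graphics::abline(h = max(log$val_acc), lty = 3)
  invisible(x)
}
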