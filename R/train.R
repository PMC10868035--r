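#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param lambda L1 penalty strength on the code-weight parameter.
#' @param max_steps Maximum full-batch gradient steps.
#' @param seed Seed controlling initialization and any internal splits.
#' @param patience Early stopping: number of evaluations (every `eval_every`
#'   steps) without improvement of the monitored loss before halting.
#' @param eval_every Steps between early-stopping evaluations.
#' @param val_fraction Patient-wise fraction held out inside [fit()] to
#'   monitor validation loss (0 monitors the training objective).
#' @param lr_grid,lambda_grid Grids searched by [grid_search()].
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-2, lambda = 0, max_steps = 5000, seed = 1,
                         patience = 20, eval_every = 25, val_fraction = 0,
                         lr_grid = c(1e-3, 1e-2),
                         lambda_grid = c(0, 1e-3, 1e-2, 1e-1)) {
  if (lr <= 0) stop_invalid("`lr` must be positive")
  if (lambda < 0) stop_invalid("`lambda` must be non-negative")
  max_steps <- check_count(max_steps, "max_steps")
  if (length(lr_grid) == 0 || length(lambda_grid) == 0) {
    stop_invalid("hyperparameter grids must be non-empty")
  }
  check_fraction(val_fraction, "val_fraction")
  structure(
    list(lr = lr, lambda = lambda, max_steps = max_steps, seed = seed,
         patience = patience, eval_every = eval_every,
         val_fraction = val_fraction, lr_grid = sort(lr_grid),
         lambda_grid = sort(lambda_grid)),
    class = "train_config"
  )
}

# Stack a tensor list into flat arrays for vectorized full-batch gradients.
# Xmat is (N*M) x D with sample-major row blocks.
stack_tensors <- function(tensors) {
  N <- length(tensors)
  M <- nrow(tensors[[1]]$X)
  D <- ncol(tensors[[1]]$X)
  d <- length(tensors[[1]]$x)
  Xmat <- do.call(rbind, lapply(tensors, `[[`, "X"))
  labs <- do.call(rbind, lapply(tensors, `[[`, "x"))
  y01 <- vapply(tensors, function(s) as.numeric(s$y), numeric(1))
  list(Xmat = Xmat, labs = labs, y = labels_pm1(y01), y01 = y01,
       N = N, M = M, D = D, d = d,
       patient = vapply(tensors, function(s) s$patient_id %||% NA_character_,
                        character(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# logits for the whole stack given a flat parameter list
stack_logits <- function(kind, st, cw, v, b) {
  v1 <- v[seq_len(st$D)]
  v2 <- v[st$D + seq_len(st$d)]
  if (kind == "standard") {
    P <- matrix(st$Xmat %*% v1, st$M, st$N)  # column i = X_i v1
    drop(crossprod(P, cw)) + drop(st$labs %*% v2) + b
  } else {
    A <- matrix(st$Xmat %*% cw, st$M, st$N)  # column i = X_i w
    P <- matrix(st$Xmat %*% v1, st$M, st$N)
    colSums(A * P) + drop(st$labs %*% v2) + b
  }
}

stack_loss_grad <- function(kind, st, cw, v, b) {
  v1 <- v[seq_len(st$D)]
  v2 <- v[st$D + seq_len(st$d)]
  P <- matrix(st$Xmat %*% v1, st$M, st$N)
  if (kind == "standard") {
    logits <- drop(crossprod(P, cw)) + drop(st$labs %*% v2) + b
  } else {
    A <- matrix(st$Xmat %*% cw, st$M, st$N)
    logits <- colSums(A * P) + drop(st$labs %*% v2) + b
  }
  z <- -st$y * logits
  loss <- mean(softplus(z))
  g <- -st$y * plogis(z) / st$N

  if (kind == "standard") {
    grad_cw <- drop(P %*% g)
    grad_v1 <- drop(crossprod(st$Xmat, as.vector(outer(cw, g))))
  } else {
    grad_cw <- drop(crossprod(st$Xmat, as.vector(sweep(P, 2, g, "*"))))
    grad_v1 <- drop(crossprod(st$Xmat, as.vector(sweep(A, 2, g, "*"))))
  }
  grad_v2 <- drop(crossprod(st$labs, g))
  list(loss = loss, logits = logits,
       grad_cw = grad_cw, grad_v = c(grad_v1, grad_v2), grad_b = sum(g))
}

kaiming_uniform <- function(n, fan_in) {
  bound <- sqrt(6 / fan_in)
  runif(n, -bound, bound)
}

#' Fit an LTR model with proximal Adam
#'
#' Full-batch Adam on the cross-entropy objective, with the L1 penalty on
#' the code-weight parameter handled by a proximal soft-threshold step after
#' each update (so sparsity produces exact zeros rather than oscillation
#' around zero). Weights are initialized Kaiming-uniform
#' (`U(-sqrt(6/fan_in), sqrt(6/fan_in))`, `fan_in` = the parameter's input
#' dimension), the intercept at zero. Training halts at `max_steps` or when
#' the monitored loss (patient-wise validation loss when
#' `val_fraction > 0`, otherwise the training objective) fails to improve
#' for `patience` consecutive evaluations; the best-seen parameters are
#' restored. Deterministic given `cfg$seed`.
#'
#' @param model_kind `"standard"` or `"personalized"`.
#' @param tensors List of `sample_tensor`s (at least two samples per class).
#' @param cfg A [train_config()].
#' @return An `ltr_fit`: `params`, per-step objective `history`,
#'   `chosen_hparams`, `steps_run`.
#' @export
fit_ltr <- function(model_kind = c("standard", "personalized"), tensors,
                    cfg = train_config()) {
  model_kind <- match.arg(model_kind)
  y01 <- vapply(tensors, function(s) as.numeric(s$y), numeric(1))
  if (min(table(factor(y01, levels = c(0, 1)))) < 2) {
    stop_degenerate("need at least 2 samples in each class")
  }

  val_tensors <- NULL
  if (cfg$val_fraction > 0) {
    split <- split_patients(tensors, cfg$val_fraction, cfg$seed + 7919L)
    val_tensors <- tensors[split$held]
    tensors <- tensors[split$kept]
  }
  st <- stack_tensors(tensors)
  stv <- if (!is.null(val_tensors) && length(val_tensors)) {
    stack_tensors(val_tensors)
  }

  n_cw <- if (model_kind == "standard") st$M else st$D
  fan_cw <- n_cw
  with_seed(cfg$seed, {
    cw <- kaiming_uniform(n_cw, fan_cw)
    v <- kaiming_uniform(st$D + st$d, st$D + st$d)
  })
  b <- 0

  theta <- c(cw, v, b)
  i_cw <- seq_len(n_cw)
  i_v <- n_cw + seq_len(st$D + st$d)
  i_b <- n_cw + st$D + st$d + 1L
  m <- numeric(length(theta)); v2m <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  history <- numeric(cfg$max_steps)
  best <- list(loss = Inf, theta = theta, step = 0L)
  stall <- 0L
  steps_run <- 0L

  for (step in seq_len(cfg$max_steps)) {
    sg <- stack_loss_grad(model_kind, st, theta[i_cw], theta[i_v], theta[i_b])
    grad <- c(sg$grad_cw, sg$grad_v, sg$grad_b)
    m <- beta1 * m + (1 - beta1) * grad
    v2m <- beta2 * v2m + (1 - beta2) * grad^2
    mh <- m / (1 - beta1^step)
    vh <- v2m / (1 - beta2^step)
    theta <- theta - cfg$lr * mh / (sqrt(vh) + eps)
    if (cfg$lambda > 0) {
      # proximal step under Adam's diagonal preconditioner: the soft
      # threshold is the penalty times the coordinate-wise effective step
      thr <- cfg$lr * cfg$lambda / (sqrt(vh[i_cw]) + eps)
      cwv <- theta[i_cw]
      theta[i_cw] <- sign(cwv) * pmax(abs(cwv) - thr, 0)
    }
    history[step] <- sg$loss + cfg$lambda * sum(abs(theta[i_cw]))
    steps_run <- step

    if (step %% cfg$eval_every == 0) {
      monitor <- if (!is.null(stv)) {
        lg <- stack_logits(model_kind, stv, theta[i_cw], theta[i_v], theta[i_b])
        mean(softplus(-stv$y * lg))
      } else {
        history[step]
      }
      if (monitor < best$loss - 1e-7) {
        best <- list(loss = monitor, theta = theta, step = step)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
  }

  # keep the best parameters seen by the monitor (fall back to final)
  if (best$step > 0L) theta <- best$theta
  params <- if (model_kind == "standard") {
    p <- standard_ltr(theta[i_cw], theta[i_v], theta[i_b])
    attr(p, "D") <- st$D
    p
  } else {
    personalized_ltr(theta[i_cw], theta[i_v], theta[i_b])
  }

  structure(
    list(kind = model_kind, params = params,
         history = history[seq_len(steps_run)],
         chosen_hparams = list(lr = cfg$lr, lambda = cfg$lambda),
         steps_run = steps_run, cfg = cfg),
    class = "ltr_fit"
  )
}

#' @export
print.ltr_fit <- function(x, ...) {
  cat(sprintf(
    "<ltr_fit> %s LTR, %d steps, final objective %.4f (lr=%g, lambda=%g)\n",
    x$kind, x$steps_run, x$history[x$steps_run],
    x$chosen_hparams$lr, x$chosen_hparams$lambda
  ))
  invisible(x)
}

#' Predicted probabilities from a fitted LTR model
#'
#' @param object An `ltr_fit`.
#' @param tensors List of `sample_tensor`s.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.ltr_fit <- function(object, tensors, ...) {
  st <- stack_tensors(tensors)
  cw <- code_weight_param(object$params)
  logits <- stack_logits(object$kind, st, cw, object$params$v,
                         object$params$b)
  plogis(pmin(pmax(logits, -30), 30))
}

# Patient-wise random split; returns indices kept/held.
split_patients <- function(tensors, fraction, seed) {
  pid <- vapply(tensors, function(s) s$patient_id %||% NA_character_,
                character(1))
  pid[is.na(pid)] <- sprintf("anon%d", which(is.na(pid)))
  patients <- unique(pid)
  n_hold <- max(1L, round(fraction * length(patients)))
  held_p <- with_seed(seed, sample(patients, n_hold))
  list(kept = which(!(pid %in% held_p)), held = which(pid %in% held_p))
}

#' Exhaustive grid search over (learning rate, lambda)
#'
#' Fits every cell of `cfg$lr_grid` x `cfg$lambda_grid` on a patient-wise
#' internal training split and scores it by validation AUC; the winning cell
#' (ties broken toward smaller `lambda`, then smaller `lr`) is refit on the
#' full data. The per-cell log is attached as attribute `"search_log"`.
#'
#' @inheritParams fit_ltr
#' @param val_fraction Patient-wise fraction held out to score cells
#'   (defaults to `cfg$val_fraction`, or 0.2 when that is 0).
#' @return An `ltr_fit` for the winning cell, refit on all of `tensors`.
#' @export
grid_search <- function(model_kind = c("standard", "personalized"), tensors,
                        cfg = train_config(), val_fraction = NULL) {
  model_kind <- match.arg(model_kind)
  if (is.null(val_fraction)) {
    val_fraction <- if (cfg$val_fraction > 0) cfg$val_fraction else 0.2
  }
  split <- split_patients(tensors, val_fraction, cfg$seed + 104729L)
  train <- tensors[split$kept]
  val <- tensors[split$held]
  yv <- vapply(val, function(s) as.numeric(s$y), numeric(1))
  if (length(unique(yv)) < 2) {
    stop_degenerate("validation split has a single class; change seed or fraction")
  }

  log <- expand.grid(lambda = cfg$lambda_grid, lr = cfg$lr_grid,
                     KEEP.OUT.ATTRS = FALSE)
  log <- log[order(log$lambda, log$lr), , drop = FALSE]
  log$val_auc <- NA_real_
  best <- NULL
  for (r in seq_len(nrow(log))) {
    cell <- modify_config(cfg, lr = log$lr[r], lambda = log$lambda[r],
                          val_fraction = 0)
    f <- fit_ltr(model_kind, train, cell)
    auc <- auc_midrank(yv, predict(f, val))
    log$val_auc[r] <- auc
    if (is.null(best) || auc > best$auc) {
      best <- list(auc = auc, lr = log$lr[r], lambda = log$lambda[r])
    }
  }

  final_cfg <- modify_config(cfg, lr = best$lr, lambda = best$lambda,
                             val_fraction = 0)
  out <- fit_ltr(model_kind, tensors, final_cfg)
  attr(out, "search_log") <- log
  out$chosen_hparams <- list(lr = best$lr, lambda = best$lambda)
  out
}

modify_config <- function(cfg, ...) {
  repl <- list(...)
  for (nm in names(repl)) cfg[[nm]] <- repl[[nm]]
  cfg
}
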