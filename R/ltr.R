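#' Logistic tensor regression parameter objects
#'
#' `standard_ltr()` holds the population-level model: one weight per medical
#' code (`u`, length `M`), regression coefficients `v` (length `D + d`, the
#' first `D` entries act on the code block, the rest on the labs) and an
#' intercept `b`. Its linear predictor for a sample `(X, x)` is
#' `[u' X | x'] v + b`.
#'
#' `personalized_ltr()` replaces `u` by an embedding-space weight `w`
#' (length `D`) acting through the sample-wise Gram matrix `S = X' X`, with
#' linear predictor `[w' S | x'] v + b`. Because `w' S = (X w)' X`, each
#' sample induces its own code-weight vector `u_i = X_i w`, which is what
#' makes per-patient interpretation possible.
#'
#' @param u,w,v Numeric parameter vectors (finite).
#' @param b Scalar intercept.
#' @return An object of class `standard_ltr` / `personalized_ltr` (both also
#'   `ltr_params`).
#' @export
standard_ltr <- function(u, v, b = 0) {
  u <- as.numeric(u); v <- as.numeric(v); b <- as.numeric(b)
  if (!all(is.finite(u)) || !all(is.finite(v)) || !is.finite(b)) {
    stop_invalid("LTR parameters must be finite")
  }
  structure(list(u = u, v = v, b = b),
            class = c("standard_ltr", "ltr_params"))
}

#' @rdname standard_ltr
#' @export
personalized_ltr <- function(w, v, b = 0) {
  w <- as.numeric(w); v <- as.numeric(v); b <- as.numeric(b)
  if (!all(is.finite(w)) || !all(is.finite(v)) || !is.finite(b)) {
    stop_invalid("LTR parameters must be finite")
  }
  if (length(v) <= length(w)) {
    stop_invalid("`v` must have length D + d with d >= 1")
  }
  structure(list(w = w, v = v, b = b),
            class = c("personalized_ltr", "ltr_params"))
}

#' Loss configuration
#'
#' @param lambda Non-negative L1 penalty strength on the code-weight
#'   parameter (`u` for the standard model, `w` for the personalized model).
#' @param clamp Probabilities are computed from logits clamped at
#'   `+- clamp`, keeping outputs strictly inside (0, 1).
#' @return A `loss_config` list.
#' @export
loss_config <- function(lambda = 0, clamp = 30) {
  if (length(lambda) != 1 || !is.finite(lambda) || lambda < 0) {
    stop_invalid("`lambda` must be a single non-negative number")
  }
  structure(list(lambda = lambda, clamp = clamp), class = "loss_config")
}

check_dims_standard <- function(params, sample) {
  D <- ncol(sample$X)
  d <- length(sample$x)
  if (length(params$u) != nrow(sample$X)) {
    stop_invalid(sprintf("length(u) = %d but X has %d rows",
                         length(params$u), nrow(sample$X)))
  }
  if (length(params$v) != D + d) {
    stop_invalid(sprintf("length(v) = %d but D + d = %d",
                         length(params$v), D + d))
  }
  invisible(TRUE)
}

check_dims_personalized <- function(params, sample) {
  D <- ncol(sample$X)
  d <- length(sample$x)
  if (length(params$w) != D) {
    stop_invalid(sprintf("length(w) = %d but X has %d columns",
                         length(params$w), D))
  }
  if (length(params$v) != D + d) {
    stop_invalid(sprintf("length(v) = %d but D + d = %d",
                         length(params$v), D + d))
  }
  invisible(TRUE)
}

#' Forward pass of the standard LTR model
#'
#' Computes `sigmoid([u' X | x'] v + b)` for one sample. The returned
#' probability carries the unclamped linear predictor as attribute
#' `"logit"`; the probability itself is computed from the logit clamped at
#' `+- clamp` so it is strictly inside (0, 1).
#'
#' @param params A [standard_ltr()].
#' @param sample A `sample_tensor` (positional encoding, if wanted, must
#'   already be applied).
#' @param clamp Logit clamp for the probability.
#' @return Probability in (0, 1) with attribute `logit`.
#' @export
forward_standard <- function(params, sample, clamp = 30) {
  check_dims_standard(params, sample)
  D <- ncol(sample$X)
  d <- length(sample$x)
  logit <- sum(drop(crossprod(params$u, sample$X)) * params$v[seq_len(D)]) +
    sum(sample$x * params$v[D + seq_len(d)]) + params$b
  prob <- plogis(pmin(pmax(logit, -clamp), clamp))
  attr(prob, "logit") <- logit
  prob
}

#' Forward pass of the personalized LTR model
#'
#' Computes `sigmoid([w' S | x'] v + b)` with `S = X' X` (`form = "gram"`),
#' or equivalently derives the per-sample code weights `u_i = X w` and
#' evaluates `[u_i' X | x'] v + b` (`form = "attention"`). The two routes are
#' algebraically identical; both are provided so the identity can be
#' exercised. `weight_tanh = TRUE` squashes `u_i` through `tanh` before
#' aggregation (attention-style bounded weights; only available in attention
#' form). `output = "tanh"` replaces the sigmoid by an affinely rescaled
#' `tanh`, `(tanh(logit) + 1) / 2`.
#'
#' @param params A [personalized_ltr()].
#' @param sample A `sample_tensor`.
#' @param form `"gram"` or `"attention"`.
#' @param output `"sigmoid"` (default) or `"tanh"`.
#' @param weight_tanh Squash the derived code weights through `tanh`.
#' @param clamp Logit clamp for the probability.
#' @return Probability in (0, 1) with attribute `logit`.
#' @export
forward_personalized <- function(params, sample,
                                 form = c("gram", "attention"),
                                 output = c("sigmoid", "tanh"),
                                 weight_tanh = FALSE, clamp = 30) {
  form <- match.arg(form)
  output <- match.arg(output)
  check_dims_personalized(params, sample)
  D <- ncol(sample$X)
  d <- length(sample$x)
  v1 <- params$v[seq_len(D)]
  if (weight_tanh && form == "gram") {
    stop_invalid("weight_tanh requires form = \"attention\"")
  }
  core <- if (form == "gram") {
    S <- crossprod(sample$X)
    sum(drop(crossprod(params$w, S)) * v1)
  } else {
    u_i <- drop(sample$X %*% params$w)
    if (weight_tanh) u_i <- tanh(u_i)
    sum(drop(crossprod(u_i, sample$X)) * v1)
  }
  logit <- core + sum(sample$x * params$v[D + seq_len(d)]) + params$b
  cl <- pmin(pmax(logit, -clamp), clamp)
  prob <- if (output == "sigmoid") plogis(cl) else (tanh(cl) + 1) / 2
  attr(prob, "logit") <- logit
  prob
}

#' Per-sample code weights of the personalized model
#'
#' Returns `u_i = X_i w`, the sample-specific weight of every medical code
#' (zero for absent codes). These are the quantities plotted in a personal
#' risk profile.
#'
#' @inheritParams forward_personalized
#' @return Named numeric vector of length `M`.
#' @export
personal_code_weights <- function(params, sample, weight_tanh = FALSE) {
  check_dims_personalized(params, sample)
  u_i <- drop(sample$X %*% params$w)
  if (weight_tanh) u_i <- tanh(u_i)
  names(u_i) <- rownames(sample$emb$vectors)
  u_i
}

ltr_logits <- function(params, batch) {
  vapply(batch, function(s) {
    if (inherits(params, "standard_ltr")) {
      attr(forward_standard(params, s), "logit")
    } else {
      attr(forward_personalized(params, s), "logit")
    }
  }, numeric(1))
}

code_weight_param <- function(params) {
  if (inherits(params, "standard_ltr")) params$u else params$w
}

#' Penalized cross-entropy loss
#'
#' Mean binary cross-entropy over a batch plus `lambda` times the L1 norm of
#' the code-weight parameter (`u` or `w`). With labels mapped to
#' `{-1, +1}`, the cross-entropy of one sample equals the logistic loss
#' `log(1 + exp(-y * logit))`, which is how it is computed (via a stable
#' softplus, so extreme logits cannot overflow).
#'
#' @param params A [standard_ltr()] or [personalized_ltr()].
#' @param batch Non-empty list of `sample_tensor`s.
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
ltr_loss <- function(params, batch, cfg = loss_config()) {
  if (length(batch) == 0) stop_invalid("`batch` must be non-empty")
  logits <- ltr_logits(params, batch)
  y <- labels_pm1(vapply(batch, function(s) as.numeric(s$y), numeric(1)))
  mean(softplus(-y * logits)) + cfg$lambda * sum(abs(code_weight_param(params)))
}

#' Analytic gradient of the penalized loss
#'
#' Gradients of [ltr_loss()] with respect to every parameter. The smooth
#' part is exact; the L1 term contributes the subgradient
#' `lambda * sign(.)`, taken as 0 at exact zeros.
#'
#' @inheritParams ltr_loss
#' @return Named list of gradients with the same shapes as the parameters
#'   (`u` or `w`, `v`, `b`).
#' @export
ltr_gradient <- function(params, batch, cfg = loss_config()) {
  if (length(batch) == 0) stop_invalid("`batch` must be non-empty")
  N <- length(batch)
  logits <- ltr_logits(params, batch)
  y <- labels_pm1(vapply(batch, function(s) as.numeric(s$y), numeric(1)))
  # d/dlogit of mean softplus(-y*logit)
  g <- -y * plogis(-y * logits) / N

  D <- ncol(batch[[1]]$X)
  d <- length(batch[[1]]$x)
  v1 <- params$v[seq_len(D)]
  grad_v <- numeric(D + d)
  grad_b <- sum(g)

  if (inherits(params, "standard_ltr")) {
    grad_u <- numeric(length(params$u))
    for (i in seq_len(N)) {
      X <- batch[[i]]$X
      grad_u <- grad_u + g[i] * drop(X %*% v1)
      grad_v[seq_len(D)] <- grad_v[seq_len(D)] +
        g[i] * drop(crossprod(X, params$u))
      grad_v[D + seq_len(d)] <- grad_v[D + seq_len(d)] + g[i] * batch[[i]]$x
    }
    grad_u <- grad_u + cfg$lambda * sign(params$u)
    list(u = grad_u, v = grad_v, b = grad_b)
  } else {
    grad_w <- numeric(length(params$w))
    for (i in seq_len(N)) {
      X <- batch[[i]]$X
      a <- drop(X %*% params$w)
      bb <- drop(X %*% v1)
      grad_w <- grad_w + g[i] * drop(crossprod(X, bb))
      grad_v[seq_len(D)] <- grad_v[seq_len(D)] + g[i] * drop(crossprod(X, a))
      grad_v[D + seq_len(d)] <- grad_v[D + seq_len(d)] + g[i] * batch[[i]]$x
    }
    grad_w <- grad_w + cfg$lambda * sign(params$w)
    list(w = grad_w, v = grad_v, b = grad_b)
  }
}

#' Effective (identifiable) per-code weights
#'
#' In the bilinear form `u' X v1` the factor `u` is identified only jointly
#' with `v1`: rescaling `u_c` and the projection `e_c . v1` in opposite
#' directions leaves every prediction unchanged. The invariant quantity is
#' the *effective* weight `alpha_c = u_c * (e_c . v1)` — exactly the logit
#' shift caused by code `c` being present at a visit (before positional
#' encoding). All population-level interpretation and recovery comparisons
#' in this package use effective weights.
#'
#' @param params A [standard_ltr()] (with attribute `"D"`, as produced by
#'   [fit_ltr()]) or explicit `D` via `v1` length inference.
#' @param emb A `code_embedding` (or a codes-by-`D` matrix).
#' @return Named numeric vector of length `M`.
#' @export
effective_code_weights <- function(params, emb) {
  if (!inherits(params, "standard_ltr")) {
    stop_invalid("`params` must be a standard_ltr")
  }
  E <- if (inherits(emb, "code_embedding")) emb$vectors else as.matrix(emb)
  D <- ncol(E)
  if (length(params$v) < D) stop_invalid("`v` shorter than the embedding dimension")
  if (length(params$u) != nrow(E)) {
    stop_invalid("length(u) must equal the number of codes")
  }
  out <- params$u * drop(E %*% params$v[seq_len(D)])
  names(out) <- rownames(E)
  out
}

#' Flip the sign orientation of a bilinear fit
#'
#' The bilinear form `u' X v1` is invariant under jointly negating the code
#' weights and the code block of `v`; a fitted model is therefore only
#' identified up to this global sign. `flip_ltr_sign()` returns the
#' equivalent parameters with the opposite orientation, which is useful when
#' aligning a fit with a reference weight vector.
#'
#' @param params A [standard_ltr()] or [personalized_ltr()].
#' @return Parameters of the same class describing the identical model.
#' @export
flip_ltr_sign <- function(params) {
  if (inherits(params, "standard_ltr")) {
    # the code block of v is everything but the lab tail; its length D is
    # carried as an attribute by fitted standard models
    D <- attr(params, "D")
    if (is.null(D)) stop_invalid("standard_ltr needs attr(params, \"D\") to flip sign")
    v <- params$v
    v[seq_len(D)] <- -v[seq_len(D)]
    out <- standard_ltr(-params$u, v, params$b)
    attr(out, "D") <- D
    out
  } else {
    D <- length(params$w)
    v <- params$v
    v[seq_len(D)] <- -v[seq_len(D)]
    personalized_ltr(-params$w, v, params$b)
  }
}

#' Save and load LTR parameters as JSON
#'
#' Full-precision (17 significant digits) JSON persistence; reading back
#' reproduces the parameters exactly.
#'
#' @param params An `ltr_params` object.
#' @param path File path.
#' @return `write_ltr_params()` returns `path` invisibly; `read_ltr_params()`
#'   the parameter object.
#' @export
write_ltr_params <- function(params, path) {
  kind <- if (inherits(params, "standard_ltr")) "standard" else "personalized"
  obj <- list(
    kind = kind,
    code_weights = code_weight_param(params),
    v = params$v,
    b = params$b,
    D = attr(params, "D")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_ltr_params
#' @export
read_ltr_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$kind == "standard") {
    out <- standard_ltr(obj$code_weights, obj$v, obj$b)
    if (!is.null(obj$D)) attr(out, "D") <- as.integer(obj$D)
    out
  } else {
    personalized_ltr(obj$code_weights, obj$v, obj$b)
  }
}
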