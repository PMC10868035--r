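random_instance <- function(seed, M = 7, D = 4, d = 2, n_codes = 3,
                            scale = 0.5) {
  set.seed(seed)
  v <- tiny_vocab(n_codes = M, n_groups = 2, seed = seed)
  emb <- rand_embedding(v, D = D, seed = seed + 1)
  ten <- make_tensor(sample(v$code, n_codes), emb,
                     labs = rnorm(d), t = runif(1, 1, 200),
                     y = sample(0:1, 1))
  list(
    ten = ten,
    std = standard_ltr(rnorm(M, sd = scale), rnorm(D + d, sd = scale),
                       rnorm(1, sd = scale)),
    per = personalized_ltr(rnorm(D, sd = scale), rnorm(D + d, sd = scale),
                           rnorm(1, sd = scale))
  )
}

test_that("zero parameters predict probability one half", {
  inst <- random_instance(1)
  zten <- inst$ten; zten$x <- numeric(2)
  p_s <- forward_standard(standard_ltr(numeric(7), rnorm(6), 0), zten)
  expect_equal(as.numeric(p_s), 0.5)
  p_p <- forward_personalized(personalized_ltr(numeric(4), rnorm(6), 0), zten)
  expect_equal(as.numeric(p_p), 0.5)
})

test_that("standard forward matches a scalar loop oracle and is scale invariant", {
  for (seed in 1:12) {
    inst <- random_instance(seed)
    p <- forward_standard(inst$std, inst$ten)
    expected <- loop_logit_standard(inst$std$u, inst$std$v, inst$std$b,
                                    inst$ten$X, inst$ten$x)
    expect_equal(attr(p, "logit"), expected, tolerance = 1e-12)
    expect_equal(as.numeric(p), plogis(expected), tolerance = 1e-12)

    # u -> 2u with the code block of v halved leaves the prediction fixed
    v2 <- inst$std$v
    v2[1:4] <- v2[1:4] / 2
    p2 <- forward_standard(standard_ltr(2 * inst$std$u, v2, inst$std$b),
                           inst$ten)
    expect_equal(as.numeric(p2), as.numeric(p), tolerance = 1e-12)
  }
})

test_that("gram and attention forms of the personalized model agree", {
  for (seed in 1:25) {
    inst <- random_instance(seed)
    g <- forward_personalized(inst$per, inst$ten, form = "gram")
    a <- forward_personalized(inst$per, inst$ten, form = "attention")
    expect_lt(abs(attr(g, "logit") - attr(a, "logit")), 1e-10)
  }
})

test_that("a single-code visit exposes its one personal weight", {
  v <- tiny_vocab(n_codes = 6, n_groups = 2, seed = 3)
  emb <- rand_embedding(v, D = 4, seed = 4)
  ten <- apply_pe(make_tensor(v$code[2], emb, t = 15))
  par <- personalized_ltr(rnorm(4), rnorm(6), 0.1)
  u_i <- personal_code_weights(par, ten)
  expect_equal(sum(u_i != 0), 1)
  pe <- as.numeric(positional_encoding(15, 4, 2))
  expect_equal(unname(u_i[v$code[2]]),
               sum(emb$vectors[v$code[2], ] * pe[1:4] * par$w),
               tolerance = 1e-12)
})

test_that("tanh modes stay in (0,1) and weight_tanh requires attention form", {
  inst <- random_instance(5)
  p <- forward_personalized(inst$per, inst$ten, output = "tanh")
  expect_gt(as.numeric(p), 0); expect_lt(as.numeric(p), 1)
  pt <- forward_personalized(inst$per, inst$ten, form = "attention",
                             weight_tanh = TRUE)
  expect_gt(as.numeric(pt), 0); expect_lt(as.numeric(pt), 1)
  expect_invalid(
    forward_personalized(inst$per, inst$ten, form = "gram", weight_tanh = TRUE)
  )
})

test_that("probabilities are strictly inside (0,1) even for huge logits", {
  inst <- random_instance(6)
  big <- standard_ltr(1e6 * (inst$std$u + 1), inst$std$v + 1, 1e8)
  p <- as.numeric(forward_standard(big, inst$ten))
  expect_gt(p, 0); expect_lt(p, 1)
  neg <- standard_ltr(big$u, big$v, -1e12)
  pn <- as.numeric(forward_standard(neg, inst$ten))
  expect_gt(pn, 0); expect_lt(pn, 1)
})

test_that("loss reduces to ln 2 at zero parameters and vanishes when confident", {
  insts <- lapply(1:5, random_instance)
  batch <- lapply(insts, function(i) { t <- i$ten; t$x <- numeric(2); t })
  zero <- standard_ltr(numeric(7), numeric(6), 0)
  expect_equal(ltr_loss(zero, batch), log(2), tolerance = 1e-12)

  # perfectly confident: scale a separating direction until |logit| > 10
  conf <- lapply(batch, function(t) { t$y <- 1L; t })
  strong <- standard_ltr(numeric(7), c(numeric(4), 0, 0), 20)
  expect_lt(ltr_loss(strong, conf), 1e-3)
})

test_that("loss equals a scalar re-summation including the L1 term", {
  insts <- lapply(11:16, random_instance)
  batch <- lapply(insts, `[[`, "ten")
  par <- insts[[1]]$std
  lo <- ltr_loss(par, batch, loss_config(lambda = 0.1))
  probs <- vapply(batch, function(s) as.numeric(forward_standard(par, s)),
                  numeric(1))
  y <- vapply(batch, function(s) s$y, integer(1))
  byhand <- -mean(y * log(probs) + (1 - y) * log(1 - probs)) +
    0.1 * sum(abs(par$u))
  expect_equal(lo, byhand, tolerance = 1e-10)
})

test_that("loss is invariant under the compensating bilinear rescaling", {
  insts <- lapply(21:26, random_instance)
  batch <- lapply(insts, `[[`, "ten")
  par <- insts[[3]]$std
  v2 <- par$v; v2[1:4] <- v2[1:4] / 7
  par2 <- standard_ltr(7 * par$u, v2, par$b)
  expect_equal(ltr_loss(par, batch), ltr_loss(par2, batch),
               tolerance = 1e-12)
})

fd_check <- function(params, batch, cfg, get, set, n_par) {
  g <- ltr_gradient(params, batch, cfg)
  eps <- 1e-6
  max_rel <- 0
  for (i in seq_len(n_par)) {
    up <- set(params, i, get(params, i) + eps)
    dn <- set(params, i, get(params, i) - eps)
    fd <- (ltr_loss(up, batch, cfg) - ltr_loss(dn, batch, cfg)) / (2 * eps)
    an <- get(g, i)
    denom <- max(abs(fd), abs(an), 1e-4)
    max_rel <- max(max_rel, abs(fd - an) / denom)
  }
  max_rel
}

test_that("analytic gradients match central finite differences", {
  set.seed(99)
  v <- tiny_vocab(n_codes = 6, n_groups = 2, seed = 99)
  emb <- rand_embedding(v, D = 4, seed = 100)
  batch <- lapply(1:5, function(i) {
    make_tensor(sample(v$code, 2), emb, labs = rnorm(2),
                t = runif(1, 1, 60), y = (i %% 2))
  })
  std <- standard_ltr(rnorm(6, sd = 0.4), rnorm(6, sd = 0.4), 0.2)
  per <- personalized_ltr(rnorm(4, sd = 0.4), rnorm(6, sd = 0.4), -0.1)

  for (lam in c(0, 0.05)) {
    cfg <- loss_config(lambda = lam)
    # standard: u block, v block, b
    r_u <- fd_check(std, batch, cfg,
                    function(p, i) if (is.list(p)) p$u[i] else NULL,
                    function(p, i, val) { p$u[i] <- val; p }, 6)
    expect_lt(r_u, 1e-5)
    r_v <- fd_check(std, batch, cfg,
                    function(p, i) p$v[i],
                    function(p, i, val) { p$v[i] <- val; p }, 6)
    expect_lt(r_v, 1e-5)
    r_w <- fd_check(per, batch, cfg,
                    function(p, i) p$w[i],
                    function(p, i, val) { p$w[i] <- val; p }, 4)
    expect_lt(r_w, 1e-5)
  }
})

test_that("gradient conventions: symmetric batches and zeros under L1", {
  v <- tiny_vocab(n_codes = 4, n_groups = 2, seed = 7)
  emb <- rand_embedding(v, D = 4, seed = 8)
  # two samples with identical features and opposite labels: at zero logit
  # the intercept gradient cancels
  t1 <- make_tensor(v$code[1:2], emb, labs = c(0.5, -0.5), y = 1)
  t2 <- make_tensor(v$code[1:2], emb, labs = c(0.5, -0.5), y = 0)
  zero <- standard_ltr(numeric(4), numeric(6), 0)
  g <- ltr_gradient(zero, list(t1, t2))
  expect_equal(g$b, 0, tolerance = 1e-15)

  # L1 subgradient is zero at exactly-zero coordinates
  par <- standard_ltr(c(0, 1, 0, -1), rnorm(6), 0)
  g0 <- ltr_gradient(par, list(t1, t2), loss_config(lambda = 0))
  g1 <- ltr_gradient(par, list(t1, t2), loss_config(lambda = 5))
  delta <- g1$u - g0$u
  expect_equal(delta, c(0, 5, 0, -5), tolerance = 1e-12)
})

test_that("effective code weights are the identifiable per-code logit shifts", {
  v <- tiny_vocab(n_codes = 6, n_groups = 2, seed = 31)
  emb <- rand_embedding(v, D = 4, seed = 32)
  par <- standard_ltr(rnorm(6), rnorm(6), 0.3)
  eff <- effective_code_weights(par, emb)
  # adding code c to an empty visit (no PE) shifts the logit by eff[c]
  for (c in v$code[1:3]) {
    t0 <- make_tensor(character(), emb, labs = c(0, 0))
    t1 <- make_tensor(c, emb, labs = c(0, 0))
    shift <- attr(forward_standard(par, t1), "logit") -
      attr(forward_standard(par, t0), "logit")
    expect_equal(unname(eff[c]), shift, tolerance = 1e-12)
  }
  # invariant under the compensating rescaling
  v2 <- par$v; v2[1:4] <- v2[1:4] / 3
  eff2 <- effective_code_weights(standard_ltr(3 * par$u, v2, par$b), emb)
  expect_equal(eff, eff2, tolerance = 1e-12)
})

test_that("parameter JSON persistence round-trips exactly", {
  par <- standard_ltr(rnorm(5), rnorm(7), rnorm(1))
  attr(par, "D") <- 5L
  f <- tempfile(fileext = ".json")
  write_ltr_params(par, f)
  back <- read_ltr_params(f)
  expect_identical(back$u, par$u)
  expect_identical(back$v, par$v)
  expect_identical(back$b, par$b)

  per <- personalized_ltr(rnorm(4), rnorm(6), 0.25)
  write_ltr_params(per, f)
  backp <- read_ltr_params(f)
  expect_identical(backp$w, per$w)
  expect_identical(backp$v, per$v)
})

test_that("dimension mismatches raise invalid-argument errors", {
  inst <- random_instance(41)
  bad <- standard_ltr(rnorm(3), rnorm(6), 0)
  expect_invalid(forward_standard(bad, inst$ten))
  badv <- personalized_ltr(rnorm(4), rnorm(9), 0)
  expect_invalid(forward_personalized(badv, inst$ten))
  expect_invalid(ltr_loss(inst$std, list()))
})
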