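#' Positional encoding of elapsed time
#'
#' Encodes an elapsed time `t` (days) as a length `D + d` vector of sines and
#' cosines at geometrically spaced frequencies, the fixed encoding used to
#' inject irregular inter-visit gaps into the feature tensor. With positions
#' numbered from 1 and `j = 1, ..., (D + d) / 2`:
#' \deqn{PE(t, 2j-1) = \sin(t / 10000^{2j/(D+d)}), \quad
#'       PE(t, 2j)   = \cos(t / 10000^{2j/(D+d)})}
#' so odd positions are sines and even positions cosines. `D + d` must be
#' even. At `t = 0` the vector is the exact alternating `0, 1, 0, 1, ...`
#' pattern; every entry lies in `[-1, 1]` for any `t`.
#'
#' @param t Non-negative elapsed time in days (used raw; no rescaling).
#' @param D Embedding dimension (first `D` positions scale the columns of
#'   `X`).
#' @param d Lab dimension (last `d` positions scale the lab entries).
#' @return Numeric vector of length `D + d` with attribute `t`, class
#'   `pe_vector`.
#' @examples
#' positional_encoding(0, D = 4, d = 2)       # 0 1 0 1 0 1
#' positional_encoding(30, D = 100, d = 4)[1] # sin(30 / 10000^(2/104))
#' @export
positional_encoding <- function(t, D, d) {
  D <- check_count(D, "D")
  d <- check_count(d, "d")
  if ((D + d) %% 2 != 0) stop_invalid("`D + d` must be even")
  if (length(t) != 1 || !is.finite(t) || t < 0) {
    stop_invalid("`t` must be a single non-negative number")
  }
  half <- (D + d) %/% 2
  j <- seq_len(half)
  angle <- t / 10000^(2 * j / (D + d))
  values <- numeric(D + d)
  values[2 * j - 1] <- sin(angle)
  values[2 * j] <- cos(angle)
  structure(values, t = t, class = "pe_vector")
}

#' Apply positional encoding to a sample tensor
#'
#' Scales the `D` columns of the embedding matrix `X` and the `d` lab entries
#' by the corresponding entries of [positional_encoding()] evaluated at the
#' sample's elapsed time (multiplicative application, the package default).
#' An additive mode (`mode = "additive"`, the transformer convention: the
#' encoding is added to nonzero rows of `X` and to the labs) is available for
#' ablation. Zero rows of `X` — absent codes — remain exactly zero in both
#' modes; `t` and `y` are unchanged. Applying the encoding twice is not
#' idempotent and the `pe_applied` flag guards accidental reapplication
#' (warning).
#'
#' @param sample A `sample_tensor`.
#' @param mode `"multiplicative"` or `"additive"`.
#' @return The encoded `sample_tensor` (`pe_applied = TRUE`).
#' @export
apply_pe <- function(sample, mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  if (!inherits(sample, "sample_tensor")) {
    stop_invalid("`sample` must be a sample_tensor")
  }
  D <- ncol(sample$X)
  d <- length(sample$x)
  pe <- as.numeric(positional_encoding(sample$t, D, d))
  if (isTRUE(sample$pe_applied)) {
    warning("positional encoding already applied; applying again")
  }
  if (mode == "multiplicative") {
    sample$X <- sweep(sample$X, 2, pe[seq_len(D)], "*")
    sample$x <- sample$x * pe[D + seq_len(d)]
  } else {
    if (length(sample$code_idx)) {
      sample$X[sample$code_idx, ] <-
        sweep(sample$X[sample$code_idx, , drop = FALSE], 2,
              pe[seq_len(D)], "+")
    }
    sample$x <- sample$x + pe[D + seq_len(d)]
  }
  sample$pe_applied <- TRUE
  sample$pe_mode <- mode
  sample
}
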