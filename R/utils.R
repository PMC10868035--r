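# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
        x != round(x)) {
    stop_invalid(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name, max = 1) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x >= max) {
    stop_invalid(sprintf("`%s` must be a single number in [0, %g)", name, max))
  }
  as.numeric(x)
}

#' Cosine similarity between two vectors
#'
#' Returns `NA` when either vector has zero norm (cosine undefined).
#'
#' @param a,b Numeric vectors of equal length.
#' @return A single number in `[-1, 1]`, or `NA` for a zero vector.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("vectors differ in length")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

# Stable softplus: log(1 + exp(z)) without overflow.
softplus <- function(z) {
  out <- z
  small <- z <= 30
  out[small] <- log1p(exp(z[small]))
  # for z > 30, log1p(exp(z)) == z to double precision
  out
}

# Map labels in {0,1} (or already {-1,1}) to {-1,+1}.
labels_pm1 <- function(y) {
  if (all(y %in% c(0, 1))) return(ifelse(y > 0, 1, -1))
  if (all(y %in% c(-1, 1))) return(as.numeric(y))
  stop_invalid("labels must be coded {0,1} or {-1,+1}")
}

fmt_num <- function(x) sprintf("%.12g", x)
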