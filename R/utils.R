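# Internal numerical helpers shared across modules.

#' Row-wise softmax
#'
#' Numerically stable softmax applied to each row of a matrix (or to a single
#' vector, returned as a vector). Every output row sums to one.
#'
#' @param z Numeric matrix of logits (rows = samples) or a numeric vector.
#' @return Matrix (or vector) of probabilities with the shape of `z`.
#' @export
#' @examples
#' softmax_rows(c(1, 0))
#' softmax_rows(matrix(c(2, 0, 0, 2), 2, 2))
softmax_rows <- function(z) {
  if (is.null(dim(z))) {
    zs <- z - max(z)
    e <- exp(zs)
    return(e / sum(e))
  }
  zs <- z - apply(z, 1L, max)
  e <- exp(zs)
  e / rowSums(e)
}

# log(sum(exp(z))) per row, stable
logsumexp_rows <- function(z) {
  m <- apply(z, 1L, max)
  m + log(rowSums(exp(z - m)))
}

# Deterministic sub-stream seed derivation: every stochastic sub-step draws
# from its own named stream so sub-steps are independently reproducible.
# Small multiplicative string hash folded into [0, 2^31 - 2].
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 31 + cc) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 131 + h) %% 2147483629 + 1)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; restores the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# argmax with ties broken toward the lowest class index
argmax_first <- function(x) which.max(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mm <- function(...) stop(..., call. = FALSE)

check_prob_vector <- function(p, name, tol = 1e-9) {
  if (any(p < 0)) stop_mm(name, " has negative entries")
  if (abs(sum(p) - 1) > tol) stop_mm(name, " must sum to 1 (got ", sum(p), ")")
  invisible(p)
}

check_row_stochastic <- function(m, name = "eta", tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_mm(name, " must be a square matrix")
  }
  if (any(m < 0)) stop_mm(name, " has negative entries")
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol)) {
    stop_mm(name, " rows must each sum to 1 (row sums: ",
            paste(signif(rs, 6), collapse = ", "), ")")
  }
  invisible(m)
}
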