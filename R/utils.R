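`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centered moving average
#'
#' O(n) cumulative-sum moving average with shrinking windows at the edges,
#' used for the iskNA envelope and the QRS integration window.
#'
#' @param x numeric vector.
#' @param k window length in samples (coerced to odd).
#' @return numeric vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, k) {
  n <- length(x)
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= n) return(rep(mean(x), n))
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Deterministic per-stage seed derivation: all randomness flows from one
# global seed; stage/unit offsets keep streams independent and < 2^31.
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed) %% 2147483629
  for (i in ix) s <- (s * 69069 + as.double(i) + 1) %% 2147483629
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

clip01 <- function(x) pmin(1, pmax(0, x))

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}
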