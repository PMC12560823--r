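#' @import methods
#' @importFrom stats rnorm runif dist na.omit
#' @importFrom utils read.csv head tail
NULL

## 32-bit FNV-1a over a character string; returns a non-negative integer
## < 2^31. Used for vocabulary fingerprints and per-molecule RNG streams so
## that augmentation does not depend on batch order.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    ## 32-bit multiply by 16777619 in double arithmetic, then reduce
    h <- (h * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

## Mix several integer seed components into one seed < 2^31.
mixSeed <- function(...) {
  parts <- unlist(list(...))
  fnv1a32(paste(format(parts, scientific = FALSE, trim = TRUE),
                collapse = ":"))
}

## Evaluate expr with a private RNG state: the caller's .Random.seed is
## saved and restored, so library code never perturbs user randomness.
withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
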