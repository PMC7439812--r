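# Internal helpers shared across modules.

# Circular difference of angles in degrees, wrapped to [-180, 180).
circDiff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d >= 180, d - 360, d)
}

# Wrap angles (degrees) to [0, 360).
wrapAngle <- function(a) a %% 360

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

assertMask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0L, 1L)))
    stop("mask must be a matrix of {0, 1}", call. = FALSE)
  invisible(mask)
}

# Deterministic argmax with smallest-index tie-break at relative tolerance.
argmaxTol <- function(x, rtol = 1e-9) {
  m <- max(x)
  which(x >= m - abs(m) * rtol)[1L]
}
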