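# Deterministic seeding utilities. Every stochastic stage consumes an
# explicit seed derived from the top-level seed and a stage label, so stages
# can be rerun independently and full runs are byte-reproducible.

#' Derive a stage seed from a top-level seed
#'
#' SplitMix-style integer mixing of the top-level seed with a stage label
#' hash; the result is a positive 31-bit integer suitable for `set.seed()`.
#'
#' @param seed Integer top-level seed.
#' @param stage Character stage label.
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 131 + ch) %% 2147483647
  x <- (as.numeric(seed) %% 2147483647) * 48271 %% 2147483647
  as.integer((x + h * 69621 + 1) %% 2147483647 + 1)
}

# evaluate expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# squared distances from one point to a set of points (n x 2 matrix)
.dist2 <- function(pts, p) (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2

# hexagonal grid covering [lo, hi]^2 at the given spacing
.hex_grid <- function(lo, hi, spacing) {
  if (hi <= lo) return(matrix(numeric(0), ncol = 2))
  gy <- seq(lo, hi, by = spacing * sqrt(3) / 2)
  do.call(rbind, lapply(seq_along(gy), function(i) {
    xs <- seq(lo + (i %% 2) * spacing / 2, hi, by = spacing)
    if (!length(xs)) return(NULL)
    cbind(xs, gy[i])
  }))
}
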