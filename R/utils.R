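# shared internal helpers

# evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_invalid <- function(...) {
  stop(structure(class = c("ropecoil_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid(name, " must be a single positive finite number")
  x
}

# bilinear interpolation of a matrix sampled at pixel centers
# value[i, j] sits at x = (i - 0.5) * px, y = (j - 0.5) * px; queries
# outside the grid replicate the nearest edge pixel
bilinear_px <- function(m, x, y, px) {
  nx <- nrow(m); ny <- ncol(m)
  u <- pmin(pmax(x / px - 0.5, 0), nx - 1)
  v <- pmin(pmax(y / px - 0.5, 0), ny - 1)
  i0 <- pmin(floor(u), nx - 2); j0 <- pmin(floor(v), ny - 2)
  if (nx == 1) i0 <- rep(0, length(u))
  if (ny == 1) j0 <- rep(0, length(v))
  fu <- u - i0; fv <- v - j0
  i1 <- pmin(i0 + 1, nx - 1); j1 <- pmin(j0 + 1, ny - 1)
  m[cbind(i0 + 1, j0 + 1)] * (1 - fu) * (1 - fv) +
    m[cbind(i1 + 1, j0 + 1)] * fu * (1 - fv) +
    m[cbind(i0 + 1, j1 + 1)] * (1 - fu) * fv +
    m[cbind(i1 + 1, j1 + 1)] * fu * fv
}

# quantile summary used throughout the morphometry reports
quantile_summary <- function(x) {
  list(quartiles = quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
       deciles   = quantile(x, seq(0.1, 0.9, by = 0.1), names = FALSE),
       ventiles  = quantile(x, seq(0.05, 0.95, by = 0.05), names = FALSE))
}
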