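## Internal helpers.

#' @importFrom stats sd
.zscore <- function(x) {
  s <- sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

## Centered moving average, reflected at the edges. n odd is enforced.
.movavg <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n <- n + 1L
  if (n == 1L) return(x)
  h <- (n - 1L) %/% 2L
  xp <- c(rev(x[seq_len(h) + 1L]), x, rev(x[length(x) - seq_len(h)]))
  cs <- cumsum(xp)
  (cs[(n):(length(xp))] - c(0, cs[seq_len(length(xp) - n)])) / n
}

.sampleIndex <- function(times, rate, t0 = 0) {
  as.integer(round((times - t0) * rate)) + 1L
}

## Wrap angle to (-pi, pi].
.wrapAngle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

## Linear interpolation of the first upward crossing of `level` by y
## (regular grid, spacing dt, origin t[1] = 0). Returns NA when absent.
.firstCrossingUp <- function(y, level, dt) {
  above <- y >= level
  i <- which(!above[-length(y)] & above[-1])
  if (!length(i)) return(NA_real_)
  i <- i[1]
  frac <- (level - y[i]) / (y[i + 1] - y[i])
  (i - 1 + frac) * dt
}

.firstCrossingDown <- function(y, level, dt) {
  below <- y <= level
  i <- which(!below[-length(y)] & below[-1])
  if (!length(i)) return(NA_real_)
  i <- i[1]
  frac <- (y[i] - level) / (y[i] - y[i + 1])
  (i - 1 + frac) * dt
}

.assertScalar <- function(x, name) {
  if (length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
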