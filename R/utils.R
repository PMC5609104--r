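# internal helpers shared across modules

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded package
#' functions never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with sprintf formatting, never showing the call
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# checks a scalar is a single finite number
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# arclength parameterization of a polyline given as data.frame(x, y)
polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
}

# points at given arclength positions s along polyline p (data.frame x,y)
polyline_point <- function(p, s) {
  seg <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg))
  frac <- (s - cum[idx]) / seg[idx]
  frac[!is.finite(frac)] <- 0
  data.frame(x = p$x[idx] + frac * (p$x[idx + 1L] - p$x[idx]),
             y = p$y[idx] + frac * (p$y[idx + 1L] - p$y[idx]))
}

# closest point on polyline p to point q = c(x, y); returns list(point, s, dist)
polyline_project <- function(p, q) {
  best <- list(dist = Inf)
  cum <- 0
  for (i in seq_len(nrow(p) - 1L)) {
    a <- c(p$x[i], p$y[i]); b <- c(p$x[i + 1L], p$y[i + 1L])
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 > 0) sum((q - a) * ab) / len2 else 0
    t <- min(max(t, 0), 1)
    pt <- a + t * ab
    d <- sqrt(sum((q - pt)^2))
    if (d < best$dist) {
      best <- list(point = pt, s = cum + t * sqrt(len2), dist = d)
    }
    cum <- cum + sqrt(len2)
  }
  best
}

# do segments (p1,p2) and (q1,q2) properly intersect?
segments_intersect <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

# bilinear interpolation of matrix img at continuous (x = col, y = row)
# coordinates; pixel centers sit at integer coordinates (1-based).
# NA pixels propagate to any sample that touches them.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  c0 <- pmin(floor(x), nc - 1L); r0 <- pmin(floor(y), nr - 1L)
  fx <- x - c0; fy <- y - r0
  v00 <- img[cbind(r0, c0)]
  v01 <- img[cbind(r0, c0 + 1L)]
  v10 <- img[cbind(r0 + 1L, c0)]
  v11 <- img[cbind(r0 + 1L, c0 + 1L)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# trapezoidal integral of y over x (both sorted by x)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
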