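# Banded dynamic-programming maximal-path engine.
#
# A path assigns one y-column to every row z in [z_sup, z_inf] and may move
# by at most one column between consecutive rows.  The engine maximises the
# cumulative fitness q, with q forced to zero outside the per-row band
# [y_ant(z), y_post(z)].  Callers must supply fitness fields that are
# non-negative inside the band so that the zero sentinel can never beat an
# in-band path.

#' Construct a fitness field
#'
#' @param values numeric matrix `[y, z]` of per-pixel fitness values.
#' @param name tag identifying which fitness function produced the field.
#' @return An object of class `fitness_field`.
#' @export
fitness_field <- function(values, name = "f") {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (any(!is.finite(values))) stop("fitness values must be finite")
  structure(list(values = values, name = name), class = "fitness_field")
}

#' Construct band bounds for a DP run
#'
#' Column limits may be scalars or per-row vectors (one entry per row of the
#' `[z_sup, z_inf]` range); they are clamped to the image width when tables
#' are accumulated.
#'
#' @param z_sup,z_inf inclusive row range.
#' @param y_ant,y_post anterior and posterior column limits (inclusive).
#' @return An object of class `band_bounds`.
#' @export
band_bounds <- function(z_sup, z_inf, y_ant, y_post) {
  z_sup <- as.integer(z_sup); z_inf <- as.integer(z_inf)
  if (z_sup > z_inf) stop("z_sup must not exceed z_inf")
  n <- z_inf - z_sup + 1L
  expand <- function(v) {
    v <- as.integer(round(v))
    if (length(v) == 1L) rep(v, n)
    else if (length(v) == n) v
    else stop("per-row bounds must have one entry per row")
  }
  structure(list(z_sup = z_sup, z_inf = z_inf,
                 y_ant = expand(y_ant), y_post = expand(y_post)),
            class = "band_bounds")
}

# Clamp band limits to the image width; error on empty bands.
clamp_band <- function(b, W) {
  ya <- clamp(b$y_ant, 1L, W)
  yp <- clamp(b$y_post, 1L, W)
  if (any(ya > yp)) stop("empty band: y_ant > y_post after clamping")
  list(z_sup = b$z_sup, z_inf = b$z_inf, y_ant = ya, y_post = yp)
}

#' Accumulate cumulative-fitness and predecessor tables
#'
#' Builds the cumulative table `q` row by row: the first row copies the
#' fitness, later rows add the fitness to the best of the three allowed
#' predecessors (y-1, y, y+1 in the previous row).  Out-of-band cells are
#' zeroed.  The predecessor table `p` stores offsets in `{-1, 0, +1}` with
#' the tie precedence: straight (0) whenever the middle predecessor ties for
#' the maximum, otherwise -1 when the anterior predecessor ties or wins,
#' otherwise +1.
#'
#' @param f a [fitness_field()]; values must be non-negative inside the band.
#' @param b a [band_bounds()].
#' @return A list of class `dp_tables` with matrices `q` and `p`
#'   (`W` columns wide, one column per row of the band's z-range) and the
#'   clamped band.
#' @export
accumulate <- function(f, b) {
  W <- nrow(f$values)
  H <- ncol(f$values)
  if (b$z_sup < 1 || b$z_inf > H) stop("band rows outside the image")
  cb <- clamp_band(b, W)
  nz <- cb$z_inf - cb$z_sup + 1L
  q <- matrix(0, W, nz)
  p <- matrix(0L, W, nz)
  ys <- seq_len(W)
  for (t in seq_len(nz)) {
    z <- cb$z_sup + t - 1L
    fv <- f$values[, z]
    in_band <- ys >= cb$y_ant[t] & ys <= cb$y_post[t]
    if (any(fv[in_band] < 0))
      stop("fitness field `", f$name, "` is negative inside the band; ",
           "add an offset before running DP")
    if (t == 1L) {
      q[, t] <- ifelse(in_band, fv, 0)
    } else {
      prev <- q[, t - 1L]
      up <- c(0, prev[-W])      # q[y-1, t-1]
      dn <- c(prev[-1], 0)      # q[y+1, t-1]
      best <- pmax(up, prev, dn)
      q[, t] <- ifelse(in_band, best + fv, 0)
      p[, t] <- ifelse(prev == best, 0L, ifelse(up == best, -1L, 1L))
    }
  }
  structure(list(q = q, p = p, band = cb), class = "dp_tables")
}

#' Backtrack the best path through accumulated tables
#'
#' Starts from the in-band column with the largest cumulative fitness in the
#' lowermost row (ties broken toward the smallest y) and follows the
#' predecessor offsets upward.
#'
#' @param t a `dp_tables` object from [accumulate()].
#' @return A [path_curve()].
#' @export
backtrack <- function(t) {
  cb <- t$band
  nz <- ncol(t$q)
  in_band <- seq_len(nrow(t$q)) >= cb$y_ant[nz] &
    seq_len(nrow(t$q)) <= cb$y_post[nz]
  qlast <- ifelse(in_band, t$q[, nz], -Inf)
  b <- integer(nz)
  b[nz] <- which.max(qlast)   # first maximum = smallest y
  if (nz > 1) {
    for (i in seq(nz - 1L, 1L)) {
      b[i] <- b[i + 1L] + t$p[b[i + 1L], i + 1L]
    }
  }
  path_curve(cb$z_sup, cb$z_inf, b)
}

#' Find the best continuous path through a fitness field
#'
#' Composition of [accumulate()] and [backtrack()].
#'
#' @inheritParams accumulate
#' @return A [path_curve()].
#' @export
find_best_path <- function(f, b) backtrack(accumulate(f, b))

#' Total fitness collected along a path
#' @param f a [fitness_field()].
#' @param curve a [path_curve()].
#' @return numeric scalar.
#' @export
path_total <- function(f, curve) {
  zs <- curve$z_sup:curve$z_inf
  sum(f$values[cbind(curve$values, zs)])
}
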