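#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one user seed. Each stage of each
#' scene draws from its own sub-stream, keyed by a label path, so stages can
#' be regenerated independently and in any order.
#'
#' @param seed Integer base seed.
#' @param ... Character/numeric labels identifying the sub-stream
#'   (e.g. root id, tile id, stage name).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  label <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                        character(1)), collapse = "/")
  m <- 2147480009  # large prime < 2^31
  h <- 0
  for (cp in utf8ToInt(label)) h <- (h * 131 + cp) %% m
  as.integer(((abs(seed) %% m) * 48271 + h) %% m) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# pixel-center coordinates (um) of a grid axis with n pixels
px_centers <- function(n, pixel_size_um) (seq_len(n) - 0.5) * pixel_size_um

# map um coordinates to 1-based pixel indices; error when outside the grid
point_to_index <- function(x_um, n, pixel_size_um) {
  i <- floor(x_um / pixel_size_um) + 1L
  # points exactly on the far edge belong to the last pixel
  i[x_um == n * pixel_size_um] <- n
  if (any(i < 1L | i > n | !is.finite(x_um)))
    abort("point outside the pixel grid")
  as.integer(i)
}

# cumulative polyline arc length from the first vertex
arc_length <- function(xy) {
  if (nrow(xy) < 2) return(rep(0, nrow(xy)))
  c(0, cumsum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)))
}

# n-dimensional unit ball volume (V_1 = 2, V_2 = pi, V_3 = 4*pi/3)
unit_ball_volume <- function(n) pi^(n / 2) / gamma(n / 2 + 1)

# polynomial rolling hash of a string, hex; used for config fingerprints
string_hash <- function(x) {
  m <- 2147480009
  h <- 0
  for (cp in utf8ToInt(x)) h <- (h * 131 + cp) %% m
  sprintf("%08x", as.integer(h))
}
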