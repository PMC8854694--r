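# Internal geometry, sampling and file helpers shared across modules.
#
# Image convention (documented in README): matrices are indexed [row, col]
# with the pixel at matrix position [i, j] centred on the 0-based image
# coordinate (x = j - 1, y = i - 1); origin top-left, y increases downward.

stop_bad_arg <- function(msg, class = "epiquant_error") {
  abort(msg, class = class)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)) || x < lower || x > upper) {
    stop_bad_arg(sprintf(
      "`%s` must be a single %snumber in [%s, %s], got %s",
      name, if (finite) "finite " else "", format(lower), format(upper),
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

check_prob <- function(x, name) check_number(x, name, 0, 1)

# Quantize to a dyadic grid (multiples of 2^-bits). Sums and differences of
# grid values of moderate magnitude are exact in double precision, so a rigid
# per-frame offset added to both coordinates and centres cancels bit-exactly
# on subtraction.
quantize_coord <- function(x, bits = 16L) {
  round(x * 2^bits) / 2^bits
}

deg <- function(rad) rad * 180 / pi

# Angle in degrees in [0, 180] between 2D vectors given as length-2 numerics.
angle_between <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  cosang <- sum(v1 * v2) / (n1 * n2)
  deg(acos(pmin(1, pmax(-1, cosang))))
}

# Points strictly or boundary-inside a simple polygon. `px`, `py` numeric
# vectors; polygon as data.frame with x, y. pracma::inpolygon marks boundary
# points as inside.
points_in_polygon <- function(px, py, polygon) {
  stopifnot(is.data.frame(polygon), nrow(polygon) >= 3)
  pracma::inpolygon(px, py, polygon$x, polygon$y, boundary = TRUE)
}

# Logical mask (ny x nx) of pixels whose centres fall inside the polygon
# (image coordinates, 0-based).
polygon_mask <- function(polygon, ny, nx) {
  g <- expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1)
  inside <- points_in_polygon(g$x, g$y, polygon)
  matrix(inside[order(g$y, g$x)], nrow = ny, ncol = nx, byrow = TRUE)
}

# Bilinear interpolation of image values at 0-based coordinates (x, y).
# Coordinates must satisfy 0 <= x <= nx-1, 0 <= y <= ny-1.
bilinear <- function(image, x, y) {
  ny <- nrow(image); nx <- ncol(image)
  if (any(x < 0 | x > nx - 1 | y < 0 | y > ny - 1)) {
    bad <- which(x < 0 | x > nx - 1 | y < 0 | y > ny - 1)[1]
    stop_bad_arg(sprintf(
      "sample point %d at (x = %.3f, y = %.3f) lies outside the image",
      bad, x[bad], y[bad]
    ))
  }
  x0 <- pmin(floor(x), nx - 2); x1 <- x0 + 1
  y0 <- pmin(floor(y), ny - 2); y1 <- y0 + 1
  fx <- x - x0; fy <- y - y0
  idx <- function(yy, xx) image[cbind(yy + 1, xx + 1)]
  (1 - fx) * (1 - fy) * idx(y0, x0) +
    fx * (1 - fy) * idx(y0, x1) +
    (1 - fx) * fy * idx(y1, x0) +
    fx * fy * idx(y1, x1)
}

# Resample an ordered polyline (data.frame x, y) at equal arc-length steps.
# Returns data.frame x, y, s (cumulative arc length) including both endpoints.
resample_polyline <- function(path, step = 1) {
  stopifnot(is.data.frame(path), nrow(path) >= 2)
  seg <- sqrt(diff(path$x)^2 + diff(path$y)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) stop_bad_arg("path has zero length")
  out_s <- unique(c(seq(0, total, by = step), total))
  data.frame(
    x = approx(s, path$x, xout = out_s, ties = "ordered")$y,
    y = approx(s, path$y, xout = out_s, ties = "ordered")$y,
    s = out_s
  )
}

# Shortest distance from point p = c(x, y) to a polyline (data.frame x, y).
dist_to_polyline <- function(p, path) {
  ax <- path$x[-nrow(path)]; ay <- path$y[-nrow(path)]
  bx <- path$x[-1]; by <- path$y[-1]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 == 0, 0, ((p[1] - ax) * dx + (p[2] - ay) * dy) / len2)
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx; qy <- ay + t * dy
  min(sqrt((p[1] - qx)^2 + (p[2] - qy)^2))
}

# Sample from the von Mises distribution (mean 0, concentration kappa) with
# the Best-Fisher rejection algorithm. kappa = Inf gives exactly 0.
rvonmises <- function(n, kappa) {
  if (!is.finite(kappa)) return(rep(0, n))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  out
}

# Atomic file writes: write to a sibling temp file, then rename.
atomic_write <- function(path, write_fun) {
  tmp <- paste0(path, ".tmp-", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fun(tmp)
  if (!file.rename(tmp, path)) {
    stop_bad_arg(sprintf("failed to move temporary file onto '%s'", path))
  }
  invisible(path)
}

write_json_atomic <- function(x, path) {
  atomic_write(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
  })
}

write_csv_atomic <- function(x, path) {
  atomic_write(path, function(tmp) readr::write_csv(x, tmp, progress = FALSE))
}
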