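# Small numeric helpers shared across modules. All user-facing geometry is in
# mm; FEM and oracle internals convert to SI (m, S/m, A*m, V, T) at entry.

MM_PER_M <- 1e3
MU0_OVER_4PI <- 1e-7  # T*m/A

#' @noRd
.asMatrix3 <- function(x, what = "points") {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(what, " must have 3 columns")
  storage.mode(x) <- "double"
  x
}

#' @noRd
.rowNorms <- function(x) sqrt(rowSums(x * x))

#' @noRd
.normalizeRows <- function(x, zeroError = TRUE) {
  n <- .rowNorms(x)
  if (zeroError && any(n < .Machine$double.eps)) stop("zero-length vector cannot be normalized")
  x / pmax(n, .Machine$double.eps)
}

#' @noRd
.rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @noRd
.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Quasi-uniform directions on the unit sphere (Fibonacci lattice)
#' @noRd
.fibonacciSphere <- function(n, phase = 0) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1) + phase
  cbind(r * cos(th), r * sin(th), z)
}

#' Deterministic rotation matrix from a seed (uniform over SO(3))
#' @noRd
.seedRotation <- function(seed) {
  # save/restore global RNG state manually (no withr dependency at run time)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Run code with a temporary RNG seed, restoring global state afterwards
#' @noRd
.withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from one global seed
#'
#' Hashing the stage name together with the global seed means adding a stage
#' never perturbs the randomness of earlier stages. Result is < 2^28 so it is
#' always a valid R integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
deriveSeed <- function(seed, stage) {
  h <- rlang::hash(paste0(stage, "/", as.integer(seed)))
  strtoi(substr(h, 1, 7), base = 16L)
}

#' Nearest-vertex lookup (brute force, chunked)
#'
#' @param points n x 3 matrix of query points.
#' @param vertices m x 3 matrix of reference vertices.
#' @return list with integer `index` and numeric `distance` per query point.
#' @noRd
.nearestVertex <- function(points, vertices, chunk = 256L) {
  points <- .asMatrix3(points)
  vertices <- .asMatrix3(vertices)
  n <- nrow(points)
  idx <- integer(n)
  dst <- numeric(n)
  v2 <- rowSums(vertices^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    p <- points[s:e, , drop = FALSE]
    # squared distances via (p - v)^2 = p^2 - 2 p.v + v^2
    d2 <- outer(rowSums(p^2), v2, "+") - 2 * p %*% t(vertices)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dst[s:e] <- sqrt(pmax(0, d2[cbind(seq_len(nrow(p)), j)]))
  }
  list(index = idx, distance = dst)
}

#' Relative difference measure and magnitude ratio between forward solutions
#'
#' RDM is the norm of the difference of the two unit-normalized topographies
#' (range 0..2); MAG is the ratio of the norms.
#'
#' @param b numeric vector, test solution.
#' @param ref numeric vector, reference solution.
#' @return named numeric vector with elements `rdm` and `mag`.
#' @export
rdmMag <- function(b, ref) {
  stopifnot(length(b) == length(ref))
  nb <- sqrt(sum(b^2)); nr <- sqrt(sum(ref^2))
  if (nb == 0 || nr == 0) stop("rdmMag: zero-norm topography")
  c(rdm = sqrt(sum((b / nb - ref / nr)^2)), mag = nb / nr)
}
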