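# Icosahedron-based triangulations of the unit sphere. These are the angular
# building block of the layered-sphere volume meshes and of all synthetic
# surfaces (cortex, inner skull, subcortical balls).

#' Subdivided icosahedron projected onto the unit sphere
#'
#' @param subdiv non-negative integer; each level quadruples the face count
#'   (20 * 4^subdiv faces, 10 * 4^subdiv + 2 vertices).
#' @return list with `vertices` (V x 3, unit norm) and `faces` (F x 3 integer,
#'   consistently outward-oriented).
#' @export
icosphere <- function(subdiv = 0L) {
  stopifnot(subdiv >= 0L)
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  storage.mode(f) <- "integer"
  for (lev in seq_len(subdiv)) {
    nv <- nrow(v)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    ue <- !duplicated(ekey)
    mid.id <- match(ekey, ekey[ue])            # 1..n_unique per edge occurrence
    mids <- (v[e[ue, 1], , drop = FALSE] + v[e[ue, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- nv + mid.id[seq_len(nf)]
    m23 <- nv + mid.id[nf + seq_len(nf)]
    m13 <- nv + mid.id[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m13),
               cbind(m12, f[, 2], m23),
               cbind(m13, m23, f[, 3]),
               cbind(m12, m23, m13))
    storage.mode(f) <- "integer"
  }
  dimnames(v) <- NULL
  dimnames(f) <- NULL
  list(vertices = v, faces = f)
}

#' Signed volume enclosed by a triangulated surface
#' @noRd
.surfaceVolume <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c3 <- vertices[faces[, 3], , drop = FALSE]
  sum(rowSums(a * .rowCross(b, c3))) / 6
}

#' Area-weighted outward vertex normals of a triangulated surface
#' @noRd
.vertexNormals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c3 <- vertices[faces[, 3], , drop = FALSE]
  fn <- .rowCross(b - a, c3 - a)  # |fn| = 2 * area, direction by face ordering
  nrm <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], faces[, k])
      i <- as.integer(rownames(acc))
      nrm[i, d] <- nrm[i, d] + acc[, 1]
    }
  }
  .normalizeRows(nrm)
}
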