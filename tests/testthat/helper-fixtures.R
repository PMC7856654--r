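# Shared fixtures, built programmatically and cached per test file.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixtureCache)) assign(name, build(), .fixtureCache)
  get(name, .fixtureCache)
}

# one-shell ball, 560 tets - fast FEM playground
tinyMesh <- function() fixture("tinyMesh", function()
  buildLayeredSphereMesh(92, 30, seed = 1, labelNames = "brain"))

tinyCond <- function() fixture("tinyCond", function()
  assignConductivities(tinyMesh(), "3CI"))

tinySystem <- function() fixture("tinySystem", function()
  assembleStiffness(tinyMesh(), tinyCond()))

tinySensors <- function() fixture("tinySensors", function()
  placeSensors(tinyMesh(), 10, 6, 60, seed = 1))

# small 4-shell mesh for conductivity/label logic
smallFourShell <- function() fixture("smallFourShell", function()
  buildLayeredSphereMesh(c(78, 80, 86, 92), 16, seed = 1))

# one-element mesh: the reference tetrahedron (mm coordinates)
refTetMesh <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  new("LabeledTetMesh", nodes = nodes,
      elements = matrix(1:4, 1), labels = 1L, labelNames = "brain")
}

isotropicField <- function(mesh, sigma, variant = "3CI") {
  m <- nrow(meshElements(mesh))
  new("ConductivityField",
      tensors = cbind(matrix(sigma, m, 3), matrix(0, m, 3)),
      variant = variant)
}

# angle between rows of two matrices of unit vectors, degrees
rowAngles <- function(a, b) {
  d <- pmin(1, pmax(-1, rowSums(a * b)))
  acos(d) * 180 / pi
}

randomRotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
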