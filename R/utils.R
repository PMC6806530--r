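# Internal helpers: units, small linear algebra, validation.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
mm2m <- function(x) x / 1000
m2mm <- function(x) x * 1000

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

#' Rotation matrices about the coordinate axes
#'
#' Right-handed rotations, angles in degrees.
#'
#' @param deg angle in degrees
#' @return a 3 x 3 rotation matrix
#' @keywords internal
#' @name rotations
NULL

rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

rot_x <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

# Fix the sign of a unit vector so its first component of magnitude > tol is
# positive. Used to make eigenvector directions deterministic.
canonical_sign <- function(v, tol = 1e-12) {
  for (x in v) {
    if (abs(x) > tol) return(if (x < 0) -v else v)
  }
  v
}

stopifnot_matrix3 <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || ncol(x) != 3 || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix with 3 columns", name))
  if (anyNA(x)) stop(sprintf("'%s' contains missing values", name))
  invisible(x)
}

as_points <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  storage.mode(x) <- "double"
  stopifnot_matrix3(x, "points")
  x
}

# Seeded evaluation that never leaks into the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from (seed, index) while staying below 2^31.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(index) * 12289L) %% 2147483629)
}
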