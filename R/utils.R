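# Classed error helpers: "user" errors map to CLI exit 1, "data" errors to 2.

pc_stop_user <- function(msg, class = NULL) {
  stop(structure(class = c(class, "pcalign_user_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

pc_stop_data <- function(msg, class = NULL) {
  stop(structure(class = c(class, "pcalign_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation plus a translation, applied as
#' `x -> R x + t` to column 3-vectors (rows of an n x 3 coordinate matrix).
#' `rigid_transform()` validates and builds one, `apply_transform()` applies
#' it to an n x 3 matrix, `compose_transforms()` returns the transform
#' equivalent to applying `b` first and then `a`, `invert_transform()` the
#' inverse, and `rotation_angle()` the rotation angle in radians.
#'
#' @param rotation 3 x 3 proper rotation matrix (orthonormal, det +1).
#' @param translation numeric 3-vector, Angstrom.
#' @return `rigid_transform()` returns an object of class `pc_transform`
#'   with elements `rotation` and `translation`.
#' @examples
#' t1 <- rigid_transform(diag(3), c(1, 0, 0))
#' apply_transform(t1, matrix(0, 1, 3))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    pc_stop_data("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "pc_transform")
}

#' @export
identity_transform <- function() rigid_transform(diag(3), c(0, 0, 0))

#' @rdname rigid_transform
#' @param transform,a,b `pc_transform` objects.
#' @param xyz n x 3 coordinate matrix.
#' @export
apply_transform <- function(transform, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  sweep(xyz %*% t(transform$rotation), 2L, transform$translation, `+`)
}

#' @rdname rigid_transform
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, as.numeric(-rt %*% transform$translation))
}

#' @rdname rigid_transform
#' @param r 3 x 3 rotation matrix.
#' @export
rotation_angle <- function(r) {
  if (inherits(r, "pc_transform")) r <- r$rotation
  acos(max(-1, min(1, (sum(diag(r)) - 1) / 2)))
}

#' @export
print.pc_transform <- function(x, ...) {
  cat("Rigid transform: rotation angle",
      sprintf("%.3f", rotation_angle(x) * 180 / pi), "deg, translation",
      sprintf("(%.3f, %.3f, %.3f) A\n", x$translation[1], x$translation[2],
              x$translation[3]))
  invisible(x)
}

# Distance matrix between two n x 3 / m x 3 coordinate sets (n x m result).
cross_dist <- function(a, b) {
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
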