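#' Rigid 3D transform
#'
#' A 6-degree-of-freedom rigid map of physical points,
#' `T(p) = R (p - center) + center + translation`, with
#' `R = Rz(gamma) Ry(beta) Rx(alpha)` (intrinsic rotations applied in x, y, z
#' order; angles in radians).
#'
#' @param rotation numeric length-3, angles `(alpha, beta, gamma)` in radians.
#' @param translation numeric length-3, mm.
#' @param center rotation center, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.numeric(rotation)
  translation <- as.numeric(translation)
  center <- as.numeric(center)
  if (length(rotation) != 3L || any(!is.finite(rotation)))
    stop("`rotation` must be three finite angles (radians)", call. = FALSE)
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("`translation` must be three finite lengths (mm)", call. = FALSE)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("`center` must be three finite coordinates (mm)", call. = FALSE)
  structure(list(rotation = rotation, translation = translation, center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angles (deg): %s; translation (mm): %s; center: %s\n",
              paste(signif(x$rotation * 180 / pi, 4), collapse = ", "),
              paste(signif(x$translation, 4), collapse = ", "),
              paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

rotation_matrix <- function(angles) {
  a <- angles[1]; b <- angles[2]; g <- angles[3]
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Homogeneous 3x4 matrix of a rigid transform
#' @param t a [rigid_transform()].
#' @return 3x4 numeric matrix `[R | t0]` with `T(p) = R p + t0`.
#' @export
transform_matrix <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  R <- rotation_matrix(t$rotation)
  t0 <- as.numeric(t$center + t$translation - R %*% t$center)
  cbind(R, t0)
}

#' Apply a rigid transform to physical points
#' @param t a [rigid_transform()].
#' @param pts N x 3 matrix of physical coordinates (mm).
#' @return N x 3 matrix of mapped coordinates.
#' @export
transform_points <- function(t, pts) {
  M <- transform_matrix(t)
  pts <- matrix(as.numeric(pts), ncol = 3L)
  sweep(pts %*% t(M[, 1:3]), 2L, M[, 4], "+")
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @return the inverse as a `rigid_transform` (center 0; the matrices compose
#'   to the identity even though the parameterization differs).
#' @export
invert_transform <- function(t) {
  M <- transform_matrix(t)
  Ri <- t(M[, 1:3])
  ti <- -as.numeric(Ri %*% M[, 4])
  matrix_to_transform(cbind(Ri, ti))
}

#' Compose two rigid transforms
#' @param t1,t2 [rigid_transform()] objects; the result applies `t2` first,
#'   then `t1` (i.e. `T(p) = t1(t2(p))`).
#' @return a `rigid_transform`.
#' @export
compose_transforms <- function(t1, t2) {
  M1 <- transform_matrix(t1)
  M2 <- transform_matrix(t2)
  R <- M1[, 1:3] %*% M2[, 1:3]
  t0 <- as.numeric(M1[, 1:3] %*% M2[, 4] + M1[, 4])
  matrix_to_transform(cbind(R, t0))
}

# Recover (alpha, beta, gamma) ZYX-composed Euler angles from a 3x4 matrix.
matrix_to_transform <- function(M) {
  R <- M[, 1:3]
  beta <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(beta)) > 1e-9) {
    alpha <- atan2(R[3, 2], R[3, 3])
    gamma <- atan2(R[2, 1], R[1, 1])
  } else {
    alpha <- atan2(-R[2, 3], R[2, 2])
    gamma <- 0
  }
  rigid_transform(rotation = c(alpha, beta, gamma), translation = as.numeric(M[, 4]),
                  center = c(0, 0, 0))
}

#' Serialize a rigid transform to JSON
#' @param t a [rigid_transform()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  jsonlite::write_json(list(rotation = t$rotation, translation = t$translation,
                            center = t$center, axis_order = "zyx-intrinsic-xyz"),
                       path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path file written by [write_transform()].
#' @return a [rigid_transform()].
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(rotation = x$rotation, translation = x$translation,
                  center = x$center)
}
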