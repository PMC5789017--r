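#' 2D affine transforms between camera frames
#'
#' A 6-parameter map `p' = A p + t` from a secondary camera's pixel frame
#' to the reference camera's frame. Stored direction is always
#' secondary -> reference so every localization table carries coordinates
#' in one canonical frame.
#'
#' @param A 2x2 linear part.
#' @param t Length-2 translation (pixels).
#' @param direction Free-text direction tag.
#'
#' @return An `affine2d` object.
#' @examples
#' tr <- affine2d(matrix(c(1, 0, 0, 1), 2), c(3.2, -1.7))
#' apply_affine(tr, c(0, 0))
#' @export
affine2d <- function(A = diag(2), t = c(0, 0),
                     direction = "secondary_to_reference") {
  A <- matrix(as.numeric(A), 2, 2)
  t <- as.numeric(t)
  stopifnot(length(t) == 2L)
  if (abs(det(A)) <= 1e-12) {
    stop("registration error: linear part is singular", call. = FALSE)
  }
  structure(list(A = A, t = t, direction = direction, rms = NA_real_),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d>", x$direction, "\n")
  cat(sprintf("  A = [%.6g %.6g; %.6g %.6g], t = (%.6g, %.6g)",
              x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$t[1], x$t[2]))
  if (is.finite(x$rms)) cat(sprintf(", fit RMS %.4g px", x$rms))
  cat("\n")
  invisible(x)
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  points
}

#' Apply, invert and compose affine transforms
#'
#' `apply_affine()` maps points (an `n x 2` matrix, a data frame with
#' `x`/`y`, or a length-2 vector); `invert_affine()` and `compose_affine()`
#' are the group operations, with `compose_affine(t1, t2)` meaning
#' "apply `t2`, then `t1`".
#'
#' @param transform,t1,t2 `affine2d` objects.
#' @param points Points to map.
#' @return Mapped points (`n x 2` matrix), or an `affine2d`.
#' @export
apply_affine <- function(transform, points) {
  p <- as_point_matrix(points)
  sweep(p %*% t(transform$A), 2, transform$t, `+`)
}

#' @rdname apply_affine
#' @export
invert_affine <- function(transform) {
  Ai <- solve(transform$A)
  affine2d(Ai, -Ai %*% transform$t,
           direction = paste0("inverse(", transform$direction, ")"))
}

#' @rdname apply_affine
#' @export
compose_affine <- function(t1, t2) {
  affine2d(t1$A %*% t2$A, t1$A %*% t2$t + t1$t,
           direction = paste(t2$direction, "then", t1$direction))
}

#' Pair points between two cameras by mutual nearest neighbours
#'
#' @param points_a,points_b Point sets (`n x 2` matrices or data frames
#'   with `x`, `y`), in pixel units.
#' @param max_dist Maximum pairing distance (pixels).
#'
#' @return A tibble with columns `index_a`, `index_b`, `dist`; each point
#'   appears at most once.
#' @export
match_points <- function(points_a, points_b, max_dist) {
  stopifnot(max_dist > 0)
  a <- as_point_matrix(points_a)
  b <- as_point_matrix(points_b)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  nn_ab <- max.col(-d2, ties.method = "first")
  nn_ba <- max.col(-t(d2), ties.method = "first")
  ia <- seq_len(nrow(a))
  mutual <- nn_ba[nn_ab] == ia
  dist <- sqrt(d2[cbind(ia, nn_ab)])
  ok <- mutual & dist <= max_dist
  pairs <- tibble::tibble(index_a = ia[ok], index_b = nn_ab[ok],
                          dist = dist[ok])
  if (nrow(pairs) < 3L) {
    stop("registration error: fewer than 3 point pairs (affine underdetermined)",
         call. = FALSE)
  }
  pairs
}

#' Least-squares affine estimation from point correspondences
#'
#' Finds the affine transform minimizing the summed squared residuals
#' `|A p_src + t - p_dst|^2` over all pairs (unweighted). The residual RMS
#' is stored on the returned transform.
#'
#' @param src,dst Corresponding points in the secondary (`src`) and
#'   reference (`dst`) frames; `n x 2` matrices or data frames with
#'   `x`, `y`. At least 3 non-collinear pairs.
#'
#' @return An `affine2d` (secondary -> reference) with an `rms` field.
#' @export
estimate_affine <- function(src, dst) {
  s <- as_point_matrix(src)
  d <- as_point_matrix(dst)
  stopifnot(nrow(s) == nrow(d))
  if (nrow(s) < 3L) {
    stop("registration error: need at least 3 pairs", call. = FALSE)
  }
  X <- cbind(s, 1)
  if (qr(X)$rank < 3L) {
    stop("registration error: source points are collinear", call. = FALSE)
  }
  beta <- qr.solve(X, d)                  # 3 x 2: rows (a_x, a_y, t)
  tr <- affine2d(t(beta[1:2, ]), beta[3, ])
  res <- X %*% beta - d
  tr$rms <- sqrt(mean(rowSums(res^2)))
  tr
}
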