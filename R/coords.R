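# Coordinate matching: estimate and apply a 2-D affine transform that
# roughly superposes the second slice onto the first before candidate
# selection. Transforms follow the row-vector convention S' = [S 1] %*% M,
# so translation occupies the third row and the third column is (0,0,1)'.

new_affine <- function(Mt, source) {
  Mt <- as.matrix(Mt)
  stopifnot(all(dim(Mt) == c(3, 3)))
  if (max(abs(Mt[, 3] - c(0, 0, 1))) > 1e-12)
    stop("invalid affine matrix: third column must be (0, 0, 1)")
  structure(list(Mt = Mt, source = source), class = "affine_transform")
}

#' @exportS3Method base::print
print.affine_transform <- function(x, ...) {
  A <- x$Mt[1:2, 1:2]
  cat(sprintf("affine_transform (%s): rotation %.2f deg, scale %.4f, translation (%.3g, %.3g)\n",
              x$source, atan2(A[1, 2], A[1, 1]) * 180 / pi,
              sqrt(abs(det(A))), x$Mt[3, 1], x$Mt[3, 2]))
  invisible(x)
}

#' Identity transform
#' @return an `affine_transform` equal to the identity.
#' @export
identity_transform <- function() new_affine(diag(3), "manual")

#' Apply an affine transform to coordinates
#'
#' @param S numeric matrix, N x 2.
#' @param t an `affine_transform`.
#' @return transformed N x 2 coordinates.
#' @export
apply_transform <- function(S, t) {
  S <- as.matrix(S)
  cbind(S, 1) %*% t$Mt[, 1:2]
}

#' Invert an affine transform
#' @param t an `affine_transform`.
#' @return the inverse `affine_transform`.
#' @export
invert_transform <- function(t) {
  if (abs(det(t$Mt)) < 1e-15) stop("singular transform cannot be inverted")
  new_affine(solve(t$Mt), t$source)
}

#' Manual transform from scale, rotation and translation
#'
#' Composed in the order scale, then rotation (counter-clockwise, about
#' `center`), then translation.
#'
#' @param rotate_deg rotation angle in degrees.
#' @param scale isotropic scale factor, `> 0`.
#' @param translate length-2 translation vector.
#' @param center rotation/scaling center (default origin; pass the slice
#'   centroid to transform about it).
#' @return an `affine_transform`.
#' @export
manual_transform <- function(rotate_deg = 0, scale = 1, translate = c(0, 0),
                             center = c(0, 0)) {
  stopifnot(scale > 0, length(translate) == 2)
  A <- scale * t(rot2(rotate_deg))  # row-vector convention: S %*% A
  shift <- center - center %*% A + translate
  Mt <- rbind(cbind(A, c(0, 0)), c(shift, 1))
  new_affine(Mt, "manual")
}

#' Load an externally estimated transform
#'
#' Reads a whitespace-delimited 3x3 matrix (row-vector convention), e.g. one
#' exported by an image-registration tool.
#'
#' @param path text file with 3 rows of 3 numbers.
#' @return an `affine_transform` with `source = "external"`.
#' @export
read_transform <- function(path) {
  new_affine(unname(as.matrix(utils::read.table(path))), "external")
}

#' Write a transform as a 3x3 text matrix
#' @param t an `affine_transform`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transform <- function(t, path) {
  utils::write.table(format(t$Mt, digits = 17), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Closed-form least-squares similarity fit (orthogonal Procrustes / Umeyama)
# mapping rows of B onto rows of A under fixed correspondence:
# A ~ s * B %*% t(R) + t. Reflections are excluded (det(R) = +1).
procrustes_fit <- function(A, B, with_scale = TRUE) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(B0, A0)
  sv <- svd(H)
  D <- diag(c(1, sign(det(tcrossprod(sv$v, sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (with_scale) {
    sum(diag(D) * sv$d) / sum(B0^2)
  } else 1
  tr <- as.numeric(ca - s * cb %*% t(R))
  fitted <- sweep(s * B %*% t(R), 2, tr, "+")
  list(R = R, s = s, t = tr,
       residual = mean(sqrt(rowSums((fitted - A)^2))))
}

# Build the homogeneous row-vector matrix for p' = s * p %*% t(R) + t.
similarity_to_affine <- function(R, s, tr, source) {
  A <- s * t(R)
  new_affine(rbind(cbind(A, c(0, 0)), c(tr, 1)), source)
}

#' Iterative-closest-point registration
#'
#' Registers the second point set onto the first by alternating
#' nearest-neighbor correspondence with a closed-form rigid(+isotropic
#' scale) Procrustes fit, run from 12 coarse initial rotations (30-degree
#' grid) to escape local optima; the best final residual wins. Large point
#' sets are subsampled to `max_points` for the correspondence search and
#' the winning transform is refit on all points.
#'
#' @param S1 reference coordinates, N1 x 2 (>= 3 points).
#' @param S2 moving coordinates, N2 x 2 (>= 3 points).
#' @param max_iter iterations per start (default 50).
#' @param tol stop when the mean nearest-neighbor residual changes by less
#'   than this (default 1e-6).
#' @param with_scale fit isotropic scale in addition to rotation and
#'   translation (default TRUE).
#' @param max_points subsample bound for correspondence search (default 5000).
#' @return an `affine_transform` with `source = "icp"` and attributes
#'   `residual` (mean final nearest-neighbor distance) and `converged`.
#' @export
icp_register <- function(S1, S2, max_iter = 50, tol = 1e-6,
                         with_scale = TRUE, max_points = 5000) {
  S1 <- as.matrix(S1); S2 <- as.matrix(S2)
  stopifnot(nrow(S1) >= 3, nrow(S2) >= 3)
  sub <- function(S) {
    if (nrow(S) <= max_points) S
    else S[round(seq(1, nrow(S), length.out = max_points)), , drop = FALSE]
  }
  S1s <- sub(S1); S2s <- sub(S2)
  c2 <- colMeans(S2s)

  run_icp <- function(init_deg) {
    tcur <- manual_transform(rotate_deg = init_deg, center = c2)
    prev <- Inf; res <- Inf; converged <- FALSE
    for (it in seq_len(max_iter)) {
      P2 <- apply_transform(S2s, tcur)
      nn <- knn_indices(P2, S1s, 1)
      res <- mean(sqrt(rowSums((P2 - S1s[nn[, 1], , drop = FALSE])^2)))
      if (abs(prev - res) < tol) { converged <- TRUE; break }
      prev <- res
      fit <- procrustes_fit(S1s[nn[, 1], , drop = FALSE], S2s,
                            with_scale = with_scale)
      tcur <- similarity_to_affine(fit$R, fit$s, fit$t, "icp")
    }
    list(t = tcur, residual = res, converged = converged)
  }

  best <- NULL
  for (ang in seq(0, 330, by = 30)) {
    cand <- run_icp(ang)
    if (is.null(best) || cand$residual < best$residual) best <- cand
  }
  if (!best$converged)
    warning("ICP did not converge within max_iter; returning best iterate")
  # refit on all points with the winning correspondence
  P2 <- apply_transform(S2, best$t)
  nn <- knn_indices(P2, S1, 1)
  fit <- procrustes_fit(S1[nn[, 1], , drop = FALSE], S2, with_scale = with_scale)
  out <- similarity_to_affine(fit$R, fit$s, fit$t, "icp")
  attr(out, "residual") <- best$residual
  attr(out, "converged") <- best$converged
  out
}
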