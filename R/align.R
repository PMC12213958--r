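#' Rigidly align a measured montage into head coordinates
#'
#' Least-squares rigid (optionally uniformly scaled) registration of
#' measured fiducial landmarks onto the head-model landmarks (Umeyama /
#' Kabsch solution via SVD), applied to all electrode positions. At least
#' three non-collinear landmarks shared by name are required.
#'
#' @param montage_points n x 3 matrix of measured electrode positions.
#' @param measured_fiducials Named list of measured landmark 3-vectors.
#' @param head_fiducials Named list of head-model landmark 3-vectors
#'   (e.g. `make_head()$fiducials`).
#' @param allow_scale Estimate an isotropic scale factor (default FALSE).
#' @return List with `rotation` (3 x 3, det +1), `translation`, `scale`,
#'   `aligned` (transformed electrode matrix), `residual_rms` (m) over the
#'   shared fiducials.
#' @export
align_montage <- function(montage_points, measured_fiducials, head_fiducials,
                          allow_scale = FALSE) {
  shared <- intersect(names(measured_fiducials), names(head_fiducials))
  if (length(shared) < 3L)
    stopf("need at least 3 shared fiducials, got %d", length(shared))
  A <- t(vapply(shared, function(n) as.numeric(measured_fiducials[[n]]),
                numeric(3)))
  B <- t(vapply(shared, function(n) as.numeric(head_fiducials[[n]]),
                numeric(3)))
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (qr(A0)$rank < 2L) stopf("fiducials are collinear; alignment is degenerate")
  S <- crossprod(A0, B0)               # 3x3 covariance
  sv <- svd(S)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  Rot <- sv$v %*% D %*% t(sv$u)
  scale <- if (allow_scale) {
    sum(sv$d * c(1, 1, d)) / sum(A0^2)
  } else 1
  tr <- cb - scale * drop(Rot %*% ca)
  apply_tf <- function(X) sweep(scale * t(Rot %*% t(X)), 2, tr, `+`)
  resid <- apply_tf(A) - B
  montage_points <- as.matrix(montage_points)
  aligned <- apply_tf(montage_points)
  dimnames(aligned) <- dimnames(montage_points)
  list(rotation = Rot, translation = tr, scale = scale,
       aligned = aligned,
       residual_rms = sqrt(mean(rowSums(resid^2))))
}
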