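# eLORETA inverse operator: the weighted minimum-norm solution whose
# per-source 3x3 weight blocks W_j satisfy the fixed point
#   W_j = ( K_j' M K_j )^(1/2),  M = pinv( K W^-1 K' + alpha c H ),
# with K the average-referenced lead field, K_j its 3-column block for grid
# point j, H the average-reference centering matrix and c a trace-based
# scale. This weighting gives exact (zero-error) localization of single
# point sources in the noiseless, unregularized case.

# Symmetric square root / inverse helpers for small SPD matrices.
sym_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

sym_inv <- function(S, floor_rel = 1e-12) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  keep <- e$values > floor_rel * max(e$values)
  iv <- ifelse(keep, 1 / e$values, 0)
  e$vectors %*% (iv * t(e$vectors))
}

# Moore-Penrose pseudo-inverse via eigendecomposition (symmetric input),
# relative eigenvalue floor 1e-12.
sym_pinv <- function(S, floor_rel = 1e-12) sym_inv(S, floor_rel)

#' Compute eLORETA weight blocks
#'
#' Iterates the eLORETA fixed point for the per-source 3 x 3 weight
#' matrices until the largest relative Frobenius change of any block falls
#' below `tol`.
#'
#' @param leadfield A [compute_leadfield()] object (average-referenced).
#' @param alpha Regularization as a fraction of the mean sensor-space
#'   eigenvalue (default 0.05; use 0 for noiseless data).
#' @param tol Convergence tolerance on the blocks (default 1e-6).
#' @param max_iter Iteration cap (default 100); on non-convergence the best
#'   iterate is returned with `converged = FALSE` and a warning.
#' @return `smeloc_eloreta_weights`: list `W` of 3 x 3 blocks, `alpha`,
#'   `iterations`, `converged`.
#' @export
eloreta_weights <- function(leadfield, alpha = 0.05, tol = 1e-6,
                            max_iter = 100L) {
  stopifnot(inherits(leadfield, "smeloc_leadfield"))
  K <- leadfield$gain
  if (!all(is.finite(K))) stopf("lead field contains non-finite entries")
  if (alpha < 0) stopf("alpha must be >= 0")
  if (tol <= 0) stopf("tol must be positive")
  ne <- nrow(K)
  M <- ncol(K) / 3L
  H <- centering_matrix(ne)
  Kb <- lapply(seq_len(M), function(j) K[, (3L * j - 2L):(3L * j), drop = FALSE])
  W <- rep(list(diag(3)), M)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # C = K W^-1 K'
    C <- matrix(0, ne, ne)
    Winv <- lapply(W, sym_inv)
    for (j in seq_len(M)) C <- C + Kb[[j]] %*% Winv[[j]] %*% t(Kb[[j]])
    if (alpha > 0) {
      cc <- sum(diag(C)) / ne
      C <- C + alpha * cc * H
    }
    Mmat <- sym_pinv(C)
    delta <- 0
    Wn <- vector("list", M)
    for (j in seq_len(M)) {
      Wj <- sym_sqrt(t(Kb[[j]]) %*% Mmat %*% Kb[[j]])
      delta <- max(delta, norm(Wj - W[[j]], "F") / max(norm(W[[j]], "F"), 1e-300))
      Wn[[j]] <- Wj
    }
    W <- Wn
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("eLORETA weights did not converge in %d iterations (last change %.3g)",
          max_iter, delta)
  structure(list(W = W, alpha = alpha, iterations = it, converged = converged),
            class = "smeloc_eloreta_weights")
}

#' Assemble the eLORETA inverse operator
#'
#' Builds the linear operator `T = W^-1 K' M` mapping average-referenced
#' channel potentials (μV) to stacked per-grid dipole moment components
#' (nA·m), using converged [eloreta_weights()].
#'
#' @param leadfield The lead field the weights were computed from.
#' @param weights An [eloreta_weights()] object.
#' @param alpha Regularization fraction; defaults to the value stored in
#'   `weights`.
#' @return `smeloc_inverse_operator`: `operator` (3M x channels), `alpha`,
#'   `n_sources`, `converged`.
#' @export
make_inverse_operator <- function(leadfield, weights, alpha = weights$alpha) {
  stopifnot(inherits(leadfield, "smeloc_leadfield"),
            inherits(weights, "smeloc_eloreta_weights"))
  K <- leadfield$gain
  M <- ncol(K) / 3L
  if (length(weights$W) != M)
    stopf("weights were computed for %d sources, lead field has %d",
          length(weights$W), M)
  ne <- nrow(K)
  C <- matrix(0, ne, ne)
  Winv <- lapply(weights$W, sym_inv)
  for (j in seq_len(M)) {
    Kj <- K[, (3L * j - 2L):(3L * j), drop = FALSE]
    C <- C + Kj %*% Winv[[j]] %*% t(Kj)
  }
  if (alpha > 0) C <- C + alpha * (sum(diag(C)) / ne) * centering_matrix(ne)
  Mmat <- sym_pinv(C)
  Tmat <- matrix(0, 3L * M, ne)
  for (j in seq_len(M)) {
    Kj <- K[, (3L * j - 2L):(3L * j), drop = FALSE]
    Tmat[(3L * j - 2L):(3L * j), ] <- Winv[[j]] %*% t(Kj) %*% Mmat
  }
  structure(list(operator = Tmat, alpha = alpha, n_sources = M,
                 converged = weights$converged,
                 channel = leadfield$channel),
            class = "smeloc_inverse_operator")
}

#' @export
print.smeloc_inverse_operator <- function(x, ...) {
  cat(sprintf("<smeloc_inverse_operator> %d sources x %d channels (alpha = %g%s)\n",
              x$n_sources, ncol(x$operator), x$alpha,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Project a component-window ERP into source space
#'
#' Averages the trials of one condition, restricts the average to the
#' component window and applies the inverse operator sample by sample.
#'
#' @param operator A [make_inverse_operator()] object.
#' @param epochs An [epochs_set()] (preprocessed and re-baselined).
#' @param component_window A component window (see [locate_p2_window()]).
#' @param condition Condition label to average; must be present.
#' @return `smeloc_moments`: array M x 3 x n_window_samples of dipole
#'   moments (nA·m), plus `window` metadata.
#' @export
apply_inverse_window <- function(operator, epochs, component_window, condition) {
  stopifnot(inherits(operator, "smeloc_inverse_operator"))
  sel <- epochs$condition == condition
  if (!any(sel)) stopf("condition '%s' not present in epochs", condition)
  idx <- window_samples(component_window, epochs$fs_hz, epochs$t0_ms,
                        dim(epochs$data)[3])
  erp <- apply(epochs$data[sel, , idx, drop = FALSE], c(2, 3), mean)
  mom <- operator$operator %*% erp          # 3M x nwin
  M <- operator$n_sources
  out <- array(0, c(M, 3L, length(idx)))
  for (a in 1:3) out[, a, ] <- mom[seq(a, 3L * M, by = 3L), , drop = FALSE]
  structure(list(moments = out, window = component_window,
                 condition = condition, n_trials = sum(sel)),
            class = "smeloc_moments")
}

#' Current-density (CDR) scores from dipole moment series
#'
#' For each grid point, takes the Euclidean norm of the 3-component moment
#' vector at every window sample and averages the norms over the window
#' (norm-then-average).
#'
#' @param moment_series A [apply_inverse_window()] result, or a plain
#'   M x 3 x S array.
#' @return Numeric vector of non-negative CDR scores, one per grid point.
#' @export
cdr_scores <- function(moment_series) {
  arr <- if (inherits(moment_series, "smeloc_moments")) moment_series$moments
         else moment_series
  if (length(dim(arr)) != 3L || dim(arr)[2] != 3L)
    stopf("moment series must be an M x 3 x S array")
  norms <- matrix(sqrt(arr[, 1, ]^2 + arr[, 2, ]^2 + arr[, 3, ]^2),
                  nrow = dim(arr)[1])
  rowMeans(norms)
}

#' Aggregate CDR scores over ROI masks
#'
#' @param cdr Numeric vector of per-grid CDR scores.
#' @param masks A [make_roi_masks()] mask set.
#' @return data.frame with one row per mask: `mask`, `roi`, `hemisphere`,
#'   `family`, `n_grid`, `mean_cdr`.
#' @export
roi_aggregate <- function(cdr, masks) {
  stopifnot(inherits(masks, "smeloc_roi_masks"))
  rows <- lapply(names(masks$masks), function(key) {
    m <- masks$masks[[key]]
    if (!length(m$indices)) stopf("mask '%s' is empty", key)
    if (any(m$indices > length(cdr)))
      stopf("mask '%s' indexes beyond the CDR map", key)
    data.frame(mask = key, roi = m$roi, hemisphere = m$hemisphere,
               family = m$family, n_grid = length(m$indices),
               mean_cdr = mean(cdr[m$indices]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
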