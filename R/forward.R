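# Analytic EEG forward model for a current dipole inside nested homogeneous
# spherical shells. Per spherical-harmonic degree n the potential in shell k
# is A_k r^n + B_k r^-(n+1); matching potential and radial current density at
# every interface (and zero current at the scalp-air boundary) yields a
# per-degree scalar transfer factor t_n relative to the infinite-medium
# primary expansion of the dipole. Units: positions m, conductivity S/m,
# moments nA*m, potentials uV.

# Legendre polynomials P_n(u) and derivatives P'_n(u) for n = 1..L,
# vectorised over u. Returns L x length(u) matrices.
legendre_table <- function(L, u) {
  nu <- length(u)
  P <- matrix(0, L, nu)
  dP <- matrix(0, L, nu)
  Pm2 <- rep(1, nu)           # P_0
  Pm1 <- u                    # P_1
  dPm2 <- rep(0, nu)
  dPm1 <- rep(1, nu)
  P[1, ] <- Pm1
  dP[1, ] <- dPm1
  if (L >= 2) {
    for (n in 2:L) {
      Pn <- ((2 * n - 1) * u * Pm1 - (n - 1) * Pm2) / n
      dPn <- dPm2 + (2 * n - 1) * Pm1    # P'_n = P'_{n-2} + (2n-1) P_{n-1}
      P[n, ] <- Pn
      dP[n, ] <- dPn
      Pm2 <- Pm1; Pm1 <- Pn
      dPm2 <- dPm1; dPm1 <- dPn
    }
  }
  list(P = P, dP = dP)
}

# Per-degree transfer factors t_n, n = 1..L, for a head geometry. In shell k
# the radial basis is normalised to that shell's outer radius,
# (r/rho_k)^n and (rho_k/r)^(n+1), so the interface equations only involve
# ratios of adjacent radii and stay well conditioned at large n. The source
# enters shell 1 with coefficient 1 on (rho_1/r)^(n+1); t_n rescales the
# outer-surface solution back to the (r/r_outer) primary convention used by
# dipole_series. For a single homogeneous sphere t_n = (2n+1)/n exactly.
shell_transfer <- function(head, L) {
  radii <- head$radii
  sig <- head$conductivities
  N <- length(radii)
  if (N == 1L) {
    n <- seq_len(L)
    return((2 * n + 1) / n)
  }
  x1 <- radii[1] / radii[N]
  t_n <- numeric(L)
  nun <- 2L * N - 1L
  iA <- function(k) k                         # A_k index
  iB <- function(k) N + k - 1L                # B_k index, k >= 2
  for (n in seq_len(L)) {
    M <- matrix(0, nun, nun)
    rhs <- numeric(nun)
    row <- 0L
    for (k in seq_len(N - 1L)) {
      g <- radii[k] / radii[k + 1L]
      gp <- g^n                               # shell k+1 growing term at rho_k
      gm <- g^(-(n + 1))                      # shell k+1 decaying term at rho_k
      # potential continuity at interface k (shell-k basis is 1 there)
      row <- row + 1L
      M[row, iA(k)] <- 1
      if (k >= 2L) M[row, iB(k)] <- 1
      M[row, iA(k + 1L)] <- -gp
      M[row, iB(k + 1L)] <- -gm
      if (k == 1L) rhs[row] <- -1             # from source coefficient B_1 = 1
      # radial current continuity, multiplied through by r
      row <- row + 1L
      M[row, iA(k)] <- sig[k] * n
      if (k >= 2L) M[row, iB(k)] <- -sig[k] * (n + 1)
      M[row, iA(k + 1L)] <- -sig[k + 1L] * n * gp
      M[row, iB(k + 1L)] <- sig[k + 1L] * (n + 1) * gm
      if (k == 1L) rhs[row] <- sig[1L] * (n + 1)
    }
    # outer boundary: dV/dr = 0 at r = r_outer
    row <- row + 1L
    M[row, iA(N)] <- n
    M[row, iB(N)] <- -(n + 1)
    sol <- solve(M, rhs)
    t_n[n] <- (sol[iA(N)] + sol[iB(N)]) / x1^(n + 1)
  }
  t_n
}

#' Scalp potential of a current dipole in a concentric-shell head
#'
#' Evaluates the truncated Legendre-series solution for the electric
#' potential generated on the outer surface of a multi-shell spherical head
#' by a single current dipole. The result is raw (un-referenced).
#'
#' @param head A [make_head()] object.
#' @param dipole_position 3-vector, meters, strictly inside the innermost
#'   shell.
#' @param dipole_moment 3-vector, nA·m.
#' @param electrode_positions n x 3 matrix of sensor positions; they are
#'   projected radially onto the outer shell before evaluation.
#' @param truncation_L Series truncation degree (default 60).
#' @return Numeric vector of potentials in μV, one per electrode.
#' @export
dipole_potential <- function(head, dipole_position, dipole_moment,
                             electrode_positions, truncation_L = 60L) {
  stopifnot(inherits(head, "smeloc_head"))
  if (truncation_L < 1L) stopf("truncation_L must be >= 1")
  pos <- as.numeric(dipole_position)
  q <- as.numeric(dipole_moment)
  b <- vec_norm(pos)
  if (b >= head$r_inner)
    stopf("dipole at radius %.4f m is not strictly inside the innermost shell (%.4f m)",
          b, head$r_inner)
  E <- project_electrodes(electrode_positions, head$r_outer)
  t_n <- shell_transfer(head, truncation_L)
  dipole_series(pos, q, E$unit, b, head$r_outer, head$conductivities[1], t_n)
}

# Shared series evaluation. re_unit: E x 3 unit electrode directions.
# Returns uV for q in nA*m.
dipole_series <- function(pos, q, re_unit, b, rN, sigma1, t_n) {
  L <- length(t_n)
  if (b == 0) {
    r0 <- c(0, 0, 1)                     # direction immaterial at the center
  } else {
    r0 <- pos / b
  }
  u <- pmin(1, pmax(-1, drop(re_unit %*% r0)))
  leg <- legendre_table(L, u)
  f <- b / rN
  n <- seq_len(L)
  fpow <- if (f == 0) c(1, numeric(L - 1L)) else f^(n - 1)
  w <- t_n * fpow
  qr <- sum(q * r0)
  qe <- drop(re_unit %*% q)
  # sum_n w_n [ n * qr * P_n(u) + (q.re - u qr) * P'_n(u) ]
  s1 <- drop(crossprod(leg$P, w * n))    # per-electrode radial series
  s2 <- drop(crossprod(leg$dP, w))       # per-electrode tangential series
  v_si <- (qr * s1 + (qe - u * qr) * s2) / (4 * pi * sigma1 * rN^2)
  unname(v_si) * 1e-3                    # (1e-9 A*m) * (1e6 uV/V)
}

#' Closed-form dipole potential for a homogeneous sphere
#'
#' Exact surface potential of a current dipole inside a single homogeneous
#' conducting sphere, via the summed Legendre generating functions. Serves
#' as an independent reference for the series solution.
#'
#' @param radius Sphere radius (m); @param sigma conductivity (S/m).
#' @param dipole_position,dipole_moment Dipole location (m) and moment
#'   (nA·m); @param electrode_positions sensors, projected onto the sphere.
#' @return Potentials in μV.
#' @export
homogeneous_dipole_potential <- function(radius, sigma, dipole_position,
                                         dipole_moment, electrode_positions) {
  pos <- as.numeric(dipole_position)
  q <- as.numeric(dipole_moment)
  b <- vec_norm(pos)
  if (b >= radius) stopf("dipole must be strictly inside the sphere")
  re <- unit_rows(project_electrodes(electrode_positions, radius)$on_shell)
  r0 <- if (b == 0) c(0, 0, 1) else pos / b
  u <- pmin(1, pmax(-1, drop(re %*% r0)))
  f <- b / radius
  rho <- sqrt(1 - 2 * f * u + f^2)
  # S1 = sum (2n+1) f^(n-1) P_n ; S2 = sum (2n+1)/n f^(n-1) P'_n
  if (f == 0) {
    S1 <- 3 * u          # n = 1 term only
    S2 <- rep(3, length(u))
  } else {
    S1 <- (2 * f * (u - f) / rho^3 + 1 / rho - 1) / f
    S2 <- 2 / rho^3 + (rho + 1) / (rho * (1 - f * u + rho))
  }
  qr <- sum(q * r0)
  qe <- drop(re %*% q)
  v_si <- (qr * S1 + (qe - u * qr) * S2) / (4 * pi * sigma * radius^2)
  unname(v_si) * 1e-3
}

# Radially project sensors onto the outer shell; report displacement as QC.
project_electrodes <- function(pos, R) {
  pos <- as.matrix(pos)
  if (ncol(pos) != 3L) stopf("electrode positions must be an n x 3 matrix")
  nr <- sqrt(rowSums(pos^2))
  if (any(nr == 0)) stopf("electrode at the origin cannot be projected")
  on_shell <- pos * (R / nr)
  list(on_shell = on_shell, unit = on_shell / R,
       projection_dist = abs(nr - R))
}

#' Compute the average-referenced lead field
#'
#' Builds the gain matrix mapping 3-component dipole moments at every source
#' grid point to average-referenced electrode potentials. Columns are
#' ordered grid-major with x, y, z moment axes within each grid point, in
#' μV per nA·m.
#'
#' @param head A [make_head()] head geometry.
#' @param source_space A [make_source_space()] grid.
#' @param montage A [make_montage()] montage (positions are projected onto
#'   the outer shell; the projection distance is kept as a QC field).
#' @param truncation_L Series truncation degree, default 60.
#' @return `smeloc_leadfield`: list with `gain` (channels x 3M), `channel`
#'   names, `reference = "average"`, `truncation_L`, `qc_projection_m`.
#' @export
compute_leadfield <- function(head, source_space, montage, truncation_L = 60L) {
  stopifnot(inherits(head, "smeloc_head"),
            inherits(source_space, "smeloc_source_space"),
            inherits(montage, "smeloc_montage"))
  pos <- source_space$grid_positions
  rad <- sqrt(rowSums(pos^2))
  out <- which(rad >= head$r_inner)
  if (length(out))
    stopf("source grid point %d lies outside the innermost shell", out[1])
  E <- project_electrodes(montage$positions, head$r_outer)
  t_n <- shell_transfer(head, truncation_L)
  M <- nrow(pos)
  ne <- nrow(E$unit)
  gain <- matrix(0, ne, 3L * M)
  ax <- diag(3)
  for (j in seq_len(M)) {
    for (a in 1:3) {
      gain[, 3L * (j - 1L) + a] <-
        dipole_series(pos[j, ], ax[a, ], E$unit, rad[j], head$r_outer,
                      head$conductivities[1], t_n)
    }
  }
  H <- centering_matrix(ne)
  gain <- H %*% gain
  structure(list(
    gain = gain,
    channel = montage$labels,
    reference = "average",
    truncation_L = as.integer(truncation_L),
    n_sources = M,
    qc_projection_m = E$projection_dist,
    head_radii = head$radii,
    head_conductivities = head$conductivities
  ), class = "smeloc_leadfield")
}

#' @export
print.smeloc_leadfield <- function(x, ...) {
  cat(sprintf("<smeloc_leadfield> %d channels x %d sources (avg ref, L = %d)\n",
              nrow(x$gain), x$n_sources, x$truncation_L))
  invisible(x)
}
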