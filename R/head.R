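#' Build a concentric-shell head geometry
#'
#' Constructs an analytic head model made of nested homogeneous spherical
#' shells (innermost shell is brain tissue, outermost is scalp), together
#' with a deterministic set of anatomical fiducial landmarks on the outer
#' surface. The shell model admits a closed-form (Legendre-series) solution
#' for the potential of a current dipole, which the forward module exploits.
#'
#' Coordinates are RAS-oriented head coordinates in meters: +x right,
#' +y anterior, +z superior, origin at the sphere center.
#'
#' @param radii Numeric vector of shell outer radii in meters, strictly
#'   increasing, innermost first. Default is a four-shell child-sized head:
#'   brain 0.08, CSF 0.082, skull 0.087, scalp 0.092 m.
#' @param conductivities Shell conductivities in S/m, one per shell.
#'   Defaults: brain 0.33, CSF 1.79, skull 0.01, scalp 0.43.
#' @param fiducials Optional named list of 3-vectors overriding the default
#'   landmark set (nasion, inion, left/right pre-auricular, left/right
#'   mastoid, vertex). Landmarks are placed on the outer shell.
#' @return An object of class `smeloc_head` with elements `radii`,
#'   `conductivities`, `fiducials` (named list of 3-vectors) and
#'   `r_outer`/`r_inner` convenience fields.
#' @examples
#' head <- make_head()
#' head$r_outer
#' @export
make_head <- function(radii = c(0.08, 0.082, 0.087, 0.092),
                      conductivities = c(0.33, 1.79, 0.01, 0.43),
                      fiducials = NULL) {
  if (length(radii) < 1L) stopf("at least one shell is required")
  if (length(radii) != length(conductivities))
    stopf("radii and conductivities must have the same length")
  if (any(diff(radii) <= 0))
    stopf("shell radii must be strictly increasing (shell %d)",
          which(diff(radii) <= 0)[1] + 1L)
  bad <- which(conductivities <= 0)
  if (length(bad))
    stopf("conductivity of shell %d must be positive", bad[1])

  R <- radii[length(radii)]
  if (is.null(fiducials)) fiducials <- default_fiducials(R)
  if (is.null(names(fiducials)) || anyDuplicated(names(fiducials)))
    stopf("fiducial names must be unique and non-empty")

  structure(list(
    radii = as.numeric(radii),
    conductivities = as.numeric(conductivities),
    fiducials = lapply(fiducials, as.numeric),
    r_inner = radii[1],
    r_outer = R
  ), class = "smeloc_head")
}

# Seven standard scalp landmarks on the outer shell (radius R).
# Mastoids sit 30 degrees below the pre-auricular axis, slightly posterior.
default_fiducials <- function(R) {
  lower <- c(cos(pi / 6), 0, -sin(pi / 6))
  list(
    nasion = c(0, R, 0),
    inion = c(0, -R, 0),
    lpa = c(-R, 0, 0),
    rpa = c(R, 0, 0),
    left_mastoid = R * unit_rows(matrix(c(-lower[1], -0.15, lower[3]), 1))[1, ],
    right_mastoid = R * unit_rows(matrix(c(lower[1], -0.15, lower[3]), 1))[1, ],
    vertex = c(0, 0, R)
  )
}

#' @export
print.smeloc_head <- function(x, ...) {
  cat(sprintf("<smeloc_head> %d shell(s), outer radius %.3f m\n",
              length(x$radii), x$r_outer))
  cat(sprintf("  radii (m):          %s\n", paste(x$radii, collapse = ", ")))
  cat(sprintf("  conductivity (S/m): %s\n",
              paste(x$conductivities, collapse = ", ")))
  cat(sprintf("  fiducials: %s\n", paste(names(x$fiducials), collapse = ", ")))
  invisible(x)
}
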