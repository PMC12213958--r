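#' Build a volumetric source grid inside the innermost shell
#'
#' Lays a regular cubic lattice over the head and keeps points inside a
#' spherical grey-matter band, expressed as fractions of the innermost
#' shell radius. Each grid point receives a hemisphere label from the sign
#' of its left-right (x) coordinate, with a declared midline band of half a
#' grid step.
#'
#' @param head A [make_head()] geometry.
#' @param spacing Grid pitch in meters (default 0.003, i.e. 3 mm).
#' @param band Inner/outer band fractions of the innermost radius kept as
#'   sources; default `c(0.55, 0.85)`.
#' @return `smeloc_source_space`: `grid_positions` (M x 3), `spacing`,
#'   `hemisphere` (factor left/midline/right), `band`.
#' @export
make_source_space <- function(head, spacing = 0.003, band = c(0.55, 0.85)) {
  stopifnot(inherits(head, "smeloc_head"))
  if (spacing <= 0) stopf("spacing must be positive")
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] || band[2] > 1)
    stopf("band must be increasing fractions in (0, 1]")
  r1 <- head$r_inner
  lim <- band[2] * r1
  ax <- seq(-floor(lim / spacing), floor(lim / spacing)) * spacing
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  rad <- sqrt(rowSums(g^2))
  keep <- rad >= band[1] * r1 & rad <= band[2] * r1
  if (!any(keep)) stopf("empty source space: spacing %.4g m leaves no grid point in the band", spacing)
  g <- g[keep, , drop = FALSE]
  hemi <- cut(g[, 1], c(-Inf, -spacing / 2, spacing / 2, Inf),
              labels = c("left", "midline", "right"), right = FALSE)
  structure(list(
    grid_positions = unname(g),
    spacing = spacing,
    hemisphere = hemi,
    band = band,
    r_inner = r1
  ), class = "smeloc_source_space")
}

#' @export
print.smeloc_source_space <- function(x, ...) {
  cat(sprintf("<smeloc_source_space> %d grid points, %.1f mm pitch, band [%.2f, %.2f] x %.3f m\n",
              nrow(x$grid_positions), 1000 * x$spacing, x$band[1], x$band[2],
              x$r_inner))
  print(table(x$hemisphere))
  invisible(x)
}
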