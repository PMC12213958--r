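#' Build a deterministic scalp montage on the outer shell
#'
#' Places `n_electrodes` quasi-uniformly over the upper portion of the outer
#' shell using a deterministic spherical (Fibonacci) spiral, assigns
#' 10-10-style labels (the standard 64-channel set when `n_electrodes` is
#' 64, generic `E<k>` labels otherwise) and a 3 x 3 (coronal x sagittal)
#' cluster for every electrode. Cluster rows/columns are rank tertiles of
#' the anterior-posterior (y) and left-right (x) coordinates, so all nine
#' cells partition the montage.
#'
#' Note the labels are nominal: electrode geometry comes from the spiral,
#' not from measured 10-10 positions.
#'
#' @param head A [make_head()] geometry; electrodes sit at its outer radius.
#' @param n_electrodes Number of electrodes, at least 4. Default 64.
#' @param theta_max Polar angle (radians from vertex) of the lowest
#'   electrode ring; default 2.0 (just below the equator, sparing the face).
#' @return `smeloc_montage`: `labels`, `positions` (n x 3, m), `coronal`
#'   and `sagittal` factors (frontal/central/posterior, left/middle/right),
#'   and `fiducials` copied from the head.
#' @export
make_montage <- function(head, n_electrodes = 64L, theta_max = 2.0) {
  stopifnot(inherits(head, "smeloc_head"))
  n <- as.integer(n_electrodes)
  if (n < 4L) stopf("at least 4 electrodes are required")
  R <- head$r_outer
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(n)
  z <- 1 - (k - 0.5) / n * (1 - cos(theta_max))   # cos(theta), vertex-down
  phi <- k * golden + pi / 2                      # start near the midline
  s <- sqrt(pmax(0, 1 - z^2))
  pos <- R * cbind(x = s * cos(phi), y = s * sin(phi), z = z)
  labels <- if (n == 64L) biosemi64_labels() else sprintf("E%02d", k)
  rownames(pos) <- labels

  tertile <- function(v, lv) {
    rk <- rank(v, ties.method = "first")
    cut(rk, breaks = quantile(rk, c(0, 1 / 3, 2 / 3, 1)),
        labels = lv, include.lowest = TRUE)
  }
  # y decreasing: frontal first; x increasing: left first
  coronal <- tertile(-pos[, "y"], c("frontal", "central", "posterior"))
  sagittal <- tertile(pos[, "x"], c("left", "middle", "right"))

  structure(list(
    labels = labels,
    positions = pos,
    coronal = coronal,
    sagittal = sagittal,
    fiducials = head$fiducials,
    r_shell = R
  ), class = "smeloc_montage")
}

# Standard 64-channel (BioSemi/10-10 style) label set.
biosemi64_labels <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz", "Fpz",
    "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6",
    "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4",
    "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2")
}

#' Channel indices of one coronal x sagittal cluster
#'
#' @param montage A [make_montage()] montage.
#' @param coronal One of "frontal", "central", "posterior" or NULL for all.
#' @param sagittal One of "left", "middle", "right" or NULL for all.
#' @return Integer channel indices.
#' @export
cluster_channels <- function(montage, coronal = NULL, sagittal = NULL) {
  keep <- rep(TRUE, length(montage$labels))
  if (!is.null(coronal)) keep <- keep & montage$coronal == coronal
  if (!is.null(sagittal)) keep <- keep & montage$sagittal == sagittal
  idx <- which(keep)
  if (!length(idx)) stopf("empty channel cluster (%s, %s)",
                          coronal %||% "*", sagittal %||% "*")
  idx
}

#' Write / read a montage as .sfp-style text
#'
#' One line per point: `label x y z` in meters. Fiducial lines carry a
#' `fid_` prefix (with the conventional `FidNz`/`FidT9`/`FidT10` aliases
#' for nasion and pre-auricular points).
#'
#' @param montage A montage; @param path output text file.
#' @return `write_sfp` returns `path` invisibly; `read_sfp` returns a list
#'   with `labels`, `positions`, `fiducials`.
#' @export
write_sfp <- function(montage, path) {
  alias <- c(nasion = "FidNz", lpa = "FidT9", rpa = "FidT10")
  fl <- vapply(names(montage$fiducials), function(nm) {
    lab <- if (nm %in% names(alias)) alias[[nm]] else paste0("fid_", nm)
    p <- montage$fiducials[[nm]]
    sprintf("%s\t%.9g\t%.9g\t%.9g", lab, p[1], p[2], p[3])
  }, character(1))
  el <- sprintf("%s\t%.9g\t%.9g\t%.9g", montage$labels,
                montage$positions[, 1], montage$positions[, 2],
                montage$positions[, 3])
  writeLines(c(fl, el), path)
  invisible(path)
}

#' @rdname write_sfp
#' @param path Path of an .sfp-style file.
#' @export
read_sfp <- function(path) {
  tab <- utils::read.table(path, col.names = c("label", "x", "y", "z"),
                           colClasses = c("character", rep("numeric", 3)))
  alias <- c(FidNz = "nasion", FidT9 = "lpa", FidT10 = "rpa")
  is_fid <- tab$label %in% names(alias) | startsWith(tab$label, "fid_")
  fid <- list()
  for (i in which(is_fid)) {
    nm <- if (tab$label[i] %in% names(alias)) alias[[tab$label[i]]] else
      sub("^fid_", "", tab$label[i])
    fid[[nm]] <- c(tab$x[i], tab$y[i], tab$z[i])
  }
  pos <- as.matrix(tab[!is_fid, c("x", "y", "z")])
  rownames(pos) <- tab$label[!is_fid]
  list(labels = tab$label[!is_fid], positions = pos, fiducials = fid)
}

#' @export
print.smeloc_montage <- function(x, ...) {
  cat(sprintf("<smeloc_montage> %d electrodes on shell r = %.3f m\n",
              length(x$labels), x$r_shell))
  print(table(coronal = x$coronal, sagittal = x$sagittal))
  invisible(x)
}
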