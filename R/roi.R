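# Synthetic ROI mask families over the source grid. Two families mirror the
# study's ROI sets: a bilateral medial-temporal ("MTL_atlas") family of six
# subregions per hemisphere, seeded in the inferior-medial band of the grid,
# and an "fMRI_constrained" family of six task-defined cortical regions.
# Patches grow by nearest-neighbour accretion from deterministic seed
# directions and are disjoint within a family.

mtl_roi_names <- function() {
  c("rostral PhG", "caudal PhG", "lateral PPHC", "medial PPHC", "EC", "TI")
}

fmri_roi_names <- function() {
  c("left IPL/SPL", "IOG", "left ITG", "left IFG", "FuG", "OFG")
}

# Unit seed directions. MTL subregions sit inferior-medial, ordered roughly
# rostral -> caudal; fMRI regions sit at frontal/parietal/occipital/temporal
# loci. Left-hemisphere mirror is the x sign flip.
roi_seed_directions <- function() {
  mtl <- rbind(
    "rostral PhG"  = c(-0.35, 0.45, -0.82),
    "caudal PhG"   = c(-0.35, -0.10, -0.93),
    "lateral PPHC" = c(-0.55, -0.35, -0.76),
    "medial PPHC"  = c(-0.22, -0.35, -0.91),
    "EC"           = c(-0.40, 0.20, -0.89),
    "TI"           = c(-0.60, 0.35, -0.71))
  fmri <- rbind(
    "left IPL/SPL" = c(-0.45, -0.35, 0.82),
    "IOG"          = c(0.30, -0.85, -0.43),
    "left ITG"     = c(-0.85, -0.15, -0.50),
    "left IFG"     = c(-0.70, 0.60, 0.20),
    "FuG"          = c(0.25, -0.45, -0.86),
    "OFG"          = c(0.00, 0.85, -0.53))
  list(mtl = unit_rows(mtl), fmri = unit_rows(fmri))
}

#' Generate the two ROI mask families on a source grid
#'
#' Builds the bilateral six-subregion medial-temporal family (tag
#' `MTL_atlas`; twelve masks, left and right) and the six-region
#' fMRI-informed family (tag `fMRI_constrained`). Each mask is a contiguous
#' patch grown by nearest-neighbour accretion from a fixed seed direction;
#' hemisphere-specific masks only recruit grid points of their hemisphere.
#' The construction is fully deterministic; `seed` is recorded in the
#' output for provenance.
#'
#' @param source_space A [make_source_space()] grid.
#' @param patch_size Grid points per mask (default 6).
#' @param seed Integer recorded with the mask set.
#' @return `smeloc_roi_masks`: named list `masks` of entries with `indices`,
#'   `roi`, `hemisphere`, `family`; plus `patch_size`, `seed`.
#' @export
make_roi_masks <- function(source_space, patch_size = 6L, seed = 1L) {
  stopifnot(inherits(source_space, "smeloc_source_space"))
  g <- source_space$grid_positions
  M <- nrow(g)
  hemi <- as.character(source_space$hemisphere)
  r_mid <- mean(source_space$band) * source_space$r_inner
  dirs <- roi_seed_directions()

  specs <- list()
  for (nm in mtl_roi_names()) {
    d <- dirs$mtl[nm, ]
    specs[[paste("left", nm)]] <- list(roi = nm, hemisphere = "left",
                                       family = "MTL_atlas", dir = d)
    specs[[paste("right", nm)]] <- list(roi = nm, hemisphere = "right",
                                        family = "MTL_atlas",
                                        dir = d * c(-1, 1, 1))
  }
  for (nm in fmri_roi_names()) {
    h <- if (startsWith(nm, "left")) "left" else "any"
    specs[[nm]] <- list(roi = nm, hemisphere = h, family = "fMRI_constrained",
                        dir = dirs$fmri[nm, ])
  }

  claimed <- list(MTL_atlas = logical(M), fMRI_constrained = logical(M))
  masks <- list()
  for (key in names(specs)) {
    sp <- specs[[key]]
    elig <- !claimed[[sp$family]]
    if (sp$hemisphere %in% c("left", "right")) elig <- elig & hemi == sp$hemisphere
    if (sum(elig) < patch_size)
      stopf("mask '%s': requested patch size %d exceeds the %d eligible grid points",
            key, patch_size, sum(elig))
    idx <- grow_patch(g, which(elig), sp$dir * r_mid, patch_size)
    claimed[[sp$family]][idx] <- TRUE
    cx <- mean(g[idx, 1])
    hemi_tag <- if (sp$hemisphere != "any") sp$hemisphere else
      if (abs(cx) < source_space$spacing / 2) "midline" else
        if (cx < 0) "left" else "right"
    masks[[key]] <- list(indices = idx, roi = sp$roi,
                         hemisphere = hemi_tag, family = sp$family)
  }
  structure(list(masks = masks, patch_size = as.integer(patch_size),
                 seed = as.integer(seed), n_grid = M),
            class = "smeloc_roi_masks")
}

# Nearest-neighbour accretion: start from the eligible point closest to the
# seed location, then repeatedly add the eligible point closest to any
# current member. Deterministic (ties resolved by grid index order).
grow_patch <- function(g, eligible, seed_pos, size) {
  d_seed <- sqrt(colSums((t(g[eligible, , drop = FALSE]) - seed_pos)^2))
  members <- eligible[which.min(d_seed)]
  free <- setdiff(eligible, members)
  while (length(members) < size) {
    dmat <- as.matrix(stats::dist(g[c(members, free), , drop = FALSE]))
    nm <- length(members)
    d_to_patch <- apply(dmat[seq_len(nm), -seq_len(nm), drop = FALSE], 2, min)
    pick <- free[which.min(d_to_patch)]
    members <- c(members, pick)
    free <- setdiff(free, pick)
  }
  sort(members)
}

#' Validate a mask set against a source space
#'
#' Checks index validity, non-emptiness and within-family disjointness;
#' errors on the first violation.
#' @param masks A [make_roi_masks()] object; @param source_space its grid.
#' @return Invisibly TRUE.
#' @export
validate_roi_masks <- function(masks, source_space) {
  M <- nrow(source_space$grid_positions)
  for (fam in unique(vapply(masks$masks, `[[`, "", "family"))) {
    seen <- integer(0)
    for (key in names(masks$masks)) {
      m <- masks$masks[[key]]
      if (m$family != fam) next
      if (!length(m$indices)) stopf("mask '%s' is empty", key)
      if (any(m$indices < 1 | m$indices > M))
        stopf("mask '%s' has out-of-range grid indices", key)
      if (any(m$indices %in% seen))
        stopf("mask '%s' overlaps another mask of family %s", key, fam)
      seen <- c(seen, m$indices)
    }
  }
  invisible(TRUE)
}

#' @export
print.smeloc_roi_masks <- function(x, ...) {
  fam <- vapply(x$masks, `[[`, "", "family")
  cat(sprintf("<smeloc_roi_masks> %d masks (%s), %d points each\n",
              length(x$masks),
              paste(sprintf("%s: %d", names(table(fam)), table(fam)),
                    collapse = ", "),
              x$patch_size))
  invisible(x)
}

# JSON round trip for mask sets (indices stored 1-based).
#' Write / read ROI masks as JSON
#' @param masks Mask set; @param path JSON file path.
#' @return `write_roi_masks` returns `path` invisibly; `read_roi_masks`
#'   the mask set.
#' @export
write_roi_masks <- function(masks, path) {
  jsonlite::write_json(
    list(patch_size = masks$patch_size, seed = masks$seed,
         n_grid = masks$n_grid,
         masks = lapply(masks$masks, function(m)
           list(indices = m$indices, roi = m$roi,
                hemisphere = m$hemisphere, family = m$family))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_masks
#' @export
read_roi_masks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  masks <- lapply(x$masks, function(m) {
    m$indices <- as.integer(m$indices)
    m
  })
  structure(list(masks = masks, patch_size = as.integer(x$patch_size),
                 seed = as.integer(x$seed), n_grid = as.integer(x$n_grid)),
            class = "smeloc_roi_masks")
}
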