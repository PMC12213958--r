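# On-disk artifact formats: lead field (float64 binary + JSON metadata with
# invariant checks on load), TSV tables, atomic writes, file hashing.

# Atomic write: produce the file under a temporary name in the same
# directory, then rename, so interrupted runs never leave truncated files.
atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writer(tmp)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stopf("could not move temporary file into place for %s", path)
  }
  invisible(path)
}

hash_files <- function(paths, rel_to = NULL) {
  h <- tools::md5sum(paths)
  nm <- if (is.null(rel_to)) basename(paths) else
    sub(paste0("^", rel_to, "/?"), "", paths)
  stats::setNames(as.vector(h), nm)
}

write_tsv <- function(df, path) {
  atomic_write(path, function(p)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write / read a lead field (binary matrix + JSON metadata)
#'
#' The gain matrix is stored as little-endian float64 (column-major) with a
#' JSON sidecar carrying the shape, column ordering, units, truncation
#' degree and head parameters. The reader verifies the shape and the
#' average-reference column-sum invariant.
#'
#' @param leadfield A [compute_leadfield()] object; @param stem path
#'   without extension.
#' @return `write_leadfield` returns the paths invisibly; `read_leadfield`
#'   the lead field.
#' @export
write_leadfield <- function(leadfield, stem) {
  bin <- paste0(stem, ".bin"); side <- paste0(stem, ".json")
  atomic_write(bin, function(p) {
    con <- file(p, "wb"); on.exit(close(con))
    writeBin(as.numeric(leadfield$gain), con, size = 8L, endian = "little")
  })
  atomic_write(side, function(p) jsonlite::write_json(list(
    shape = dim(leadfield$gain), ordering = "grid-major, xyz within grid",
    units = "uV per nA*m", reference = leadfield$reference,
    truncation_L = leadfield$truncation_L, n_sources = leadfield$n_sources,
    channel = leadfield$channel,
    head_radii = leadfield$head_radii,
    head_conductivities = leadfield$head_conductivities,
    qc_projection_m = leadfield$qc_projection_m
  ), p, auto_unbox = TRUE, digits = NA))
  invisible(c(bin = bin, json = side))
}

#' @rdname write_leadfield
#' @param stem Path stem previously passed to `write_leadfield`.
#' @export
read_leadfield <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  shp <- as.integer(side$shape)
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  g <- matrix(readBin(con, "numeric", prod(shp), size = 8L,
                      endian = "little"), shp[1], shp[2])
  if (max(abs(colSums(g))) > 1e-9 * max(abs(g)))
    stopf("lead field failed the average-reference column-sum check on read")
  structure(list(gain = g, channel = side$channel, reference = side$reference,
                 truncation_L = as.integer(side$truncation_L),
                 n_sources = as.integer(side$n_sources),
                 qc_projection_m = side$qc_projection_m,
                 head_radii = side$head_radii,
                 head_conductivities = side$head_conductivities),
            class = "smeloc_leadfield")
}
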