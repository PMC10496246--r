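# Plain-text node bundle persistence.
#
# A bundle is <id>.json (node_id, label, dim, spacing) plus
# <id>_volume.csv and <id>_mask.csv holding the integer voxel values in
# column-major order, one slice block per line. Text-only by design so
# cohorts can be cached and diffed anywhere; a NIfTI/DICOM reader is
# deliberately not part of this package (see the vignette).

#' Write / read a node bundle (text format)
#' @param node a [node_image()].
#' @param dir output directory.
#' @return the bundle basename, invisibly / the [node_image()].
#' @export
write_node_bundle <- function(node, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, node$node_id)
  jsonlite::write_json(
    list(node_id = node$node_id, label = node$label,
         dim = dim(node$volume), spacing = node$spacing),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  write_slices <- function(arr, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (s in seq_len(dim(arr)[3]))
      writeLines(paste(as.integer(arr[, , s]), collapse = ","), con)
  }
  write_slices(node$volume, paste0(base, "_volume.csv"))
  write_slices(node$mask, paste0(base, "_mask.csv"))
  invisible(node$node_id)
}

#' @rdname write_node_bundle
#' @param node_id bundle basename inside `dir`.
#' @export
read_node_bundle <- function(dir, node_id) {
  base <- file.path(dir, node_id)
  hdr <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  read_slices <- function(path, d) {
    lines <- readLines(path)
    vals <- unlist(lapply(lines, function(l)
      as.numeric(strsplit(l, ",", fixed = TRUE)[[1]])), use.names = FALSE)
    array(vals, d)
  }
  d <- as.integer(hdr$dim)
  node_image(read_slices(paste0(base, "_volume.csv"), d),
             read_slices(paste0(base, "_mask.csv"), d) > 0,
             hdr$spacing, node_id = hdr$node_id,
             label = if (is.null(hdr$label)) NULL else hdr$label)
}
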