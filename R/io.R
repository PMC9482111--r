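# TIFF I/O. Intensities are kept on [0, 1] in memory; bit depth only affects
# the on-disk quantisation.

#' Read and write micrograph TIFFs
#'
#' Single-plane images round-trip as matrices; multi-page TIFFs are returned
#' as `rows x cols x slices` arrays suitable for [project_max()].
#'
#' @param img Matrix or 3D array with values in `[0, 1]`.
#' @param path File path.
#' @param bits Bits per sample (8 or 16).
#' @return `read_micrograph`: a matrix or 3D array; `read_mask`: a logical
#'   matrix.
#' @export
write_micrograph <- function(img, path, bits = 16) {
  stopifnot(bits %in% c(8, 16))
  if (length(dim(img)) == 3L) {
    pages <- lapply(seq_len(dim(img)[3]), function(k) img[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = bits)
  }
  invisible(path)
}

#' @rdname write_micrograph
#' @export
read_micrograph <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1] else p  # drop extra channels
  })
  if (length(pages) == 1L) {
    pages[[1]]
  } else {
    array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  }
}

#' @rdname write_micrograph
#' @export
read_mask <- function(path) {
  m <- read_micrograph(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}
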