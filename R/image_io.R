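## Raster I/O. Images are held in memory as numeric matrices (grey) or
## H x W x C arrays (C = 3 RGB or 4 RGBA) on the 0..255 scale.
## Supported on disk: PNG and JPEG (via the png/jpeg packages) and plain
## ASCII netpbm (P2 PGM grey / P3 PPM colour) so fixtures can be stored as
## text. TIFF is not supported in this environment.

#' Read a raster image
#'
#' @param path file path ending in `.png`, `.jpg`/`.jpeg`, `.pgm` or
#'   `.ppm`.
#' @return a numeric matrix (greyscale) or `H x W x C` array on the
#'   0--255 scale; an alpha channel, when present in a PNG, is kept as the
#'   last plane.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path),
                                "crumblab_io_error")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path) * 255,
    jpg  = ,
    jpeg = jpeg::readJPEG(path) * 255,
    pgm  = ,
    ppm  = read_pnm(path),
    abort(paste0("unsupported image format: .", ext), "crumblab_io_error")
  )
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1L]
  img
}

#' Write a raster image
#'
#' @param img numeric matrix or `H x W x C` array, values 0--255.
#' @param path destination; format chosen from the extension (`.png`,
#'   `.pgm`, `.ppm`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(img, 0), 255)
  switch(ext,
    png = png::writePNG(img / 255, path),
    pgm = ,
    ppm = write_pnm(img, path),
    abort(paste0("unsupported output format: .", ext), "crumblab_io_error")
  )
  invisible(path)
}

## plain (ASCII) netpbm: P2 = grey, P3 = RGB; maxval 255 or 65535
read_pnm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  magic <- toks[1L]
  if (!magic %in% c("P2", "P3")) {
    abort("only plain (ASCII) P2/P3 netpbm files are supported",
          "crumblab_io_error")
  }
  head <- as.numeric(toks[2:4])
  w <- head[1L]; h <- head[2L]; maxval <- head[3L]
  vals <- as.numeric(toks[-(1:4)]) * (255 / maxval)
  if (magic == "P2") {
    if (length(vals) != w * h) abort("corrupt PGM payload", "crumblab_io_error")
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    if (length(vals) != 3 * w * h) abort("corrupt PPM payload", "crumblab_io_error")
    px <- matrix(vals, ncol = 3L, byrow = TRUE)
    array(c(matrix(px[, 1L], h, w, byrow = TRUE),
            matrix(px[, 2L], h, w, byrow = TRUE),
            matrix(px[, 3L], h, w, byrow = TRUE)), dim = c(h, w, 3L))
  }
}

write_pnm <- function(img, path) {
  img <- round(img)
  con <- file(path, "w")
  on.exit(close(con))
  if (is.matrix(img)) {
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
    write.table(img, con, row.names = FALSE, col.names = FALSE)
  } else {
    if (dim(img)[3] == 4L) img <- img[, , 1:3]  # drop alpha for PPM
    h <- dim(img)[1L]; w <- dim(img)[2L]
    ## interleave channels row-major: r g b per pixel
    flat <- matrix(aperm(img, c(3L, 2L, 1L)), nrow = 3L)
    writeLines(c("P3", paste(w, h), "255"), con)
    writeLines(paste(flat[1L, ], flat[2L, ], flat[3L, ]), con)
  }
  invisible(path)
}

#' Write / read a region label mask
#'
#' Label masks (integer region ids, 0 = background) are stored as 16-bit
#' ASCII PGM (maxval 65535). The available PNG writer quantizes to 8
#' bits, which would corrupt label ids above 255, so label masks are
#' text-only on disk.
#'
#' @param labels integer matrix of region labels.
#' @param path `.pgm` file path.
#' @return `path` (write) or the label matrix (read).
#' @export
write_label_mask <- function(labels, path) {
  if (max(labels) > 65535) abort("more than 65535 labels", "crumblab_io_error")
  if (tolower(tools::file_ext(path)) != "pgm") {
    abort("label masks are written as 16-bit ASCII PGM (.pgm)",
          "crumblab_io_error")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(labels), nrow(labels)), "65535"), con)
  write.table(labels, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  head <- as.numeric(toks[2:4])
  matrix(as.numeric(toks[-(1:4)]), nrow = head[2L], ncol = head[1L],
         byrow = TRUE)
}
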