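#' Construct a raw mammogram object
#'
#' A `raw_mammogram` wraps a 2-D non-negative integer intensity grid from a raw
#' ("for processing") full-field digital mammogram together with its pixel
#' spacing and acquisition metadata. Raw FFDM polarity is assumed: dense tissue
#' attenuates and is *low* intensity, air background is high intensity. Use
#' `inverted = TRUE` for sources with the opposite polarity; the pixel grid is
#' flipped about its maximum at construction so downstream code sees raw
#' polarity throughout.
#'
#' @param pixels integer-valued matrix of intensities, at least 2x2.
#' @param pixel_spacing mm per pixel (isotropic, positive scalar).
#' @param side `"left"` or `"right"`.
#' @param view `"CC"` or `"MLO"`.
#' @param subject_id opaque subject identifier.
#' @param inverted logical; if `TRUE` the input uses display polarity
#'   (dense = high) and is flipped to raw polarity.
#' @return An object of class `raw_mammogram`.
#' @export
raw_mammogram <- function(pixels, pixel_spacing, side = "left", view = "CC",
                          subject_id = "anonymous", inverted = FALSE) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("mammogram must be at least 2x2 pixels")
  if (!is.numeric(pixels) || any(!is.finite(pixels)) || any(pixels < 0))
    stop("pixel intensities must be finite and non-negative")
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      !is.finite(pixel_spacing) || pixel_spacing <= 0)
    stop("pixel_spacing must be a positive scalar (mm per pixel)")
  side <- match.arg(side, c("left", "right"))
  view <- match.arg(view, c("CC", "MLO"))
  if (isTRUE(inverted)) pixels <- max(pixels) - pixels
  structure(
    list(pixels = pixels, pixel_spacing = pixel_spacing, side = side,
         view = view, subject_id = as.character(subject_id)),
    class = "raw_mammogram"
  )
}

#' @export
print.raw_mammogram <- function(x, ...) {
  cat(sprintf("<raw_mammogram> %s %s/%s  %d x %d px @ %.4f mm/px\n",
              x$subject_id, x$side, x$view, nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing))
  invisible(x)
}

#' Read a raw mammogram from disk
#'
#' Reads portable greymap (PGM, plain `P2` or binary `P5`, up to 16-bit)
#' images. Pixel spacing is not stored in PGM and must be supplied. DICOM and
#' TIFF containers are recognised by extension but no offline reader is
#' available in this toolchain; convert such images to 16-bit PGM (e.g. with
#' ImageMagick `convert in.dcm out.pgm`) and pass the spacing explicitly. No
#' photometric inversion is applied at read time: windowing handles polarity.
#'
#' @param path path to the image file.
#' @param pixel_spacing mm per pixel; required for PGM input.
#' @param ... further arguments passed to [raw_mammogram()].
#' @return A [raw_mammogram()].
#' @export
read_mammogram <- function(path, pixel_spacing = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom", "tif", "tiff", "png"))
    stop("no offline reader for '.", ext, "' images is available; ",
         "convert to 16-bit PGM and supply pixel_spacing")
  if (is.null(pixel_spacing))
    stop("PGM stores no pixel spacing; supply `pixel_spacing` (mm per pixel)")
  raw_mammogram(read_pgm(path), pixel_spacing = pixel_spacing, ...)
}

#' Read / write portable greymap (PGM) images
#'
#' Minimal PGM codec used for text-friendly fixtures: plain (`P2`) and binary
#' (`P5`) variants, maxval up to 65535 (16-bit, big-endian as per the format).
#'
#' @param path file path.
#' @return `read_pgm` returns an integer matrix (rows = image rows).
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() { # whitespace/comment-delimited token
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("unexpected end of PGM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
      } else if (!grepl("[ \t\r\n]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[ \t\r\n]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (magic ", magic, ")")
  nc <- as.integer(tok()); nr <- as.integer(tok()); maxval <- as.integer(tok())
  if (anyNA(c(nc, nr, maxval)) || nc < 1L || nr < 1L)
    stop("malformed PGM header")
  npix <- nr * nc
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = npix, quiet = TRUE)
  } else {
    if (maxval > 255L) {
      raw2 <- readBin(con, "raw", n = 2L * npix)
      vals <- as.integer(raw2[c(TRUE, FALSE)]) * 256L + as.integer(raw2[c(FALSE, TRUE)])
    } else {
      vals <- as.integer(readBin(con, "raw", n = npix))
    }
  }
  if (length(vals) != npix) stop("truncated PGM pixel data")
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}

#' @rdname read_pgm
#' @param pixels integer matrix to write.
#' @param maxval maximum grey value declared in the header.
#' @param binary write binary `P5` (default) or plain-text `P2`.
#' @export
write_pgm <- function(pixels, path, maxval = max(pixels), binary = TRUE) {
  pixels <- round(as.matrix(pixels))
  if (any(pixels < 0) || any(pixels > maxval)) stop("pixels outside [0, maxval]")
  hdr <- sprintf("%s\n%d %d\n%d\n", if (binary) "P5" else "P2",
                 ncol(pixels), nrow(pixels), as.integer(maxval))
  v <- as.integer(t(pixels)) # row-major
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeChar(hdr, con, eos = NULL)
    if (maxval > 255) {
      b <- integer(2L * length(v))
      b[c(TRUE, FALSE)] <- v %/% 256L
      b[c(FALSE, TRUE)] <- v %% 256L
      writeBin(as.raw(b), con)
    } else {
      writeBin(as.raw(v), con)
    }
  } else {
    writeLines(c(sub("\n$", "", hdr),
                 paste(v, collapse = " ")), path)
  }
  invisible(path)
}

#' Read a breast mask image
#'
#' Masks are 8-bit PGM images where values >= 128 mark in-breast pixels.
#' @param path mask image path.
#' @param img optional [raw_mammogram()] the mask must be congruent with.
#' @return A logical matrix usable wherever a breast mask is expected.
#' @export
read_mask <- function(path, img = NULL) {
  m <- read_pgm(path) >= 128L
  if (!is.null(img)) check_mask(m, img$pixels)
  m
}

check_mask <- function(mask, pixels) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!identical(dim(mask), dim(pixels)))
    stop("mask dimensions do not match the image")
  if (sum(mask) < 64L)
    stop("breast mask has fewer than 64 pixels")
  invisible(mask)
}
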