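#' Multi-channel section image
#'
#' Container for a fluorescence section image: a named list of equal-sized
#' intensity matrices (values in \[0, 1\]) plus the physical pixel size.
#' Conventional channel names are `"hypoxia"` (e.g. EF5/Cy3, red),
#' `"proliferation"` (e.g. Ki-67/AF488, green) and optionally `"nuclear"`
#' (e.g. Hoechst, blue). Pixel centres sit at integer coordinates, origin at
#' the top-left, y increasing downwards.
#'
#' @param channels Named list of numeric matrices with identical dimensions.
#' @param scale Physical scale, micrometres per pixel (> 0).
#' @return An object of class `section_image`.
#' @export
section_image <- function(channels, scale) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop_invalid("'channels' must be a non-empty named list of matrices")
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), logical(1))))
    stop_invalid("all channels must be numeric matrices")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop_invalid("all channels must have identical dimensions")
  if (any(vapply(channels, function(m) any(!is.finite(m)) || any(m < 0), logical(1))))
    stop_invalid("channel intensities must be finite and non-negative")
  assert_scalar_pos(scale, "scale")
  structure(list(channels = channels, scale = scale), class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Section image: %d x %d px, %.3g um/px, channels: %s\n",
              d[1], d[2], x$scale, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

stain_channels <- function(image) {
  nm <- setdiff(names(image$channels), "nuclear")
  if (length(nm) == 0L) stop_invalid("image has no stain channels")
  nm
}

# Union (pixelwise max) of the stain channels.
stain_union <- function(image) {
  nm <- stain_channels(image)
  Reduce(pmax, image$channels[nm])
}

#' Read a section image from disk
#'
#' Supports PNG (RGB or greyscale, via the `png` package), ASCII NetPBM
#' (`.ppm` P3 colour / `.pgm` P2 greyscale) and single-channel CSV matrices.
#' RGB images are split into channels according to `channel_map`.
#'
#' @param path Path to the image file.
#' @param scale Micrometres per pixel (mandatory; section images carry no
#'   physical scale themselves).
#' @param channel_map Named character vector mapping colour planes to channel
#'   names, default `c(red = "hypoxia", green = "proliferation",
#'   blue = "nuclear")`.
#' @return A [section_image()].
#' @export
read_section <- function(path, scale,
                         channel_map = c(red = "hypoxia",
                                         green = "proliferation",
                                         blue = "nuclear")) {
  if (!file.exists(path)) stop_invalid(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop_invalid(
                     sprintf("failed to read PNG '%s': %s", path, conditionMessage(e)))),
    ppm = ,
    pgm = ,
    pnm = read_pnm(path),
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop_invalid(sprintf("unsupported image format '.%s' (use png/ppm/pgm/csv)", ext))
  )
  if (is.matrix(arr)) {
    chans <- list(hypoxia = arr)
  } else {
    planes <- c("red", "green", "blue")[seq_len(min(3L, dim(arr)[3]))]
    chans <- list()
    for (i in seq_along(planes)) {
      nm <- channel_map[[planes[i]]]
      if (!is.null(nm) && !is.na(nm)) chans[[nm]] <- arr[, , i]
    }
  }
  section_image(chans, scale)
}

#' Write a section image to disk
#'
#' Writes PNG (RGB; channels mapped to colour planes by `channel_map`) or
#' ASCII NetPBM (`.ppm`/`.pgm`, plain-text, suitable for fixtures).
#'
#' @param image A [section_image()].
#' @param path Output path; format chosen by extension.
#' @param channel_map As in [read_section()].
#' @param maxval Integer quantisation maximum for NetPBM output.
#' @return `path`, invisibly.
#' @export
write_section <- function(image, path,
                          channel_map = c(red = "hypoxia",
                                          green = "proliferation",
                                          blue = "nuclear"),
                          maxval = 255L) {
  if (!inherits(image, "section_image")) stop_invalid("not a section_image")
  d <- dim(image$channels[[1]])
  plane <- function(colour) {
    nm <- channel_map[[colour]]
    if (!is.null(nm) && nm %in% names(image$channels))
      pmin(pmax(image$channels[[nm]], 0), 1)
    else matrix(0, d[1], d[2])
  }
  arr <- array(0, c(d[1], d[2], 3L))
  arr[, , 1] <- plane("red"); arr[, , 2] <- plane("green"); arr[, , 3] <- plane("blue")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, path)
  } else if (ext %in% c("ppm", "pnm")) {
    write_pnm(arr, path, maxval = maxval)
  } else if (ext == "pgm") {
    write_pnm(pmax(arr[, , 1], arr[, , 2], arr[, , 3]), path, maxval = maxval)
  } else {
    stop_invalid(sprintf("unsupported output format '.%s'", ext))
  }
  invisible(path)
}

#' Read a plain (ASCII) NetPBM image
#'
#' Parses P2 (greyscale) and P3 (colour) plain NetPBM files. Returns a
#' matrix (P2) or an array with a third colour dimension (P3), intensities
#' rescaled to \[0, 1\].
#'
#' @param path Path to a `.pgm`/`.ppm` file.
#' @return Numeric matrix or 3-d array.
#' @export
read_pnm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = "\n"), what = character(),
              quiet = TRUE)
  magic <- tok[1]
  if (!magic %in% c("P2", "P3"))
    stop_invalid(sprintf("unsupported NetPBM magic '%s' (only plain P2/P3)", magic))
  nums <- as.numeric(tok[-1])
  w <- nums[1]; h <- nums[2]; maxval <- nums[3]
  px <- nums[-(1:3)]
  if (magic == "P2") {
    if (length(px) != w * h) stop_invalid("corrupt PGM: pixel count mismatch")
    matrix(px / maxval, nrow = h, ncol = w, byrow = TRUE)
  } else {
    if (length(px) != 3 * w * h) stop_invalid("corrupt PPM: pixel count mismatch")
    arr <- array(0, c(h, w, 3L))
    for (k in 1:3) {
      arr[, , k] <- matrix(px[seq(k, length(px), by = 3)] / maxval,
                           nrow = h, ncol = w, byrow = TRUE)
    }
    arr
  }
}

#' Write a plain (ASCII) NetPBM image
#'
#' @param x Numeric matrix (written as P2) or 3-d array (P3), values in
#'   \[0, 1\].
#' @param path Output path.
#' @param maxval Quantisation maximum (default 255).
#' @return `path`, invisibly.
#' @export
write_pnm <- function(x, path, maxval = 255L) {
  q <- function(v) as.integer(round(pmin(pmax(v, 0), 1) * maxval))
  con <- file(path, "w")
  on.exit(close(con))
  if (is.matrix(x)) {
    writeLines(c("P2", paste(ncol(x), nrow(x)), as.character(maxval)), con)
    utils::write.table(matrix(q(t(x)), nrow = nrow(x), byrow = TRUE), con,
                       row.names = FALSE, col.names = FALSE)
  } else if (length(dim(x)) == 3L && dim(x)[3] == 3L) {
    h <- dim(x)[1]; w <- dim(x)[2]
    writeLines(c("P3", paste(w, h), as.character(maxval)), con)
    flat <- matrix(0L, nrow = h, ncol = 3L * w)
    for (k in 1:3) flat[, seq(k, 3L * w, by = 3L)] <- matrix(q(x[, , k]), h, w)
    utils::write.table(flat, con, row.names = FALSE, col.names = FALSE)
  } else {
    stop_invalid("x must be a matrix or an h x w x 3 array")
  }
  invisible(path)
}

#' Export a radial profile to CSV
#'
#' Writes the two-column CSV interchange format (`radius_um`, `pO2_mmHg`).
#'
#' @param profile A data frame from [oxygen_profile()] or [solve_mm_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  if (!all(c("radius_um", "pO2_mmHg") %in% names(profile)))
    stop_invalid("profile must have columns radius_um and pO2_mmHg")
  utils::write.csv(profile[, c("radius_um", "pO2_mmHg")], path,
                   row.names = FALSE)
  invisible(path)
}
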