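#' ENVI-style cube input/output
#'
#' Cubes are stored in the ENVI convention used by most hyperspectral
#' toolchains: a flat binary file plus an ASCII header (`<path>.hdr`)
#' recording `samples` (cross-track pixels), `lines`, `bands`, `data
#' type`, `interleave` and the wavelength list.  BIL interleave is the
#' default, matching line-scan acquisition order.  Reflectance cubes are
#' stored as 32-bit floats (ENVI data type 4); raw-count cubes as 16-bit
#' integers (data type 2), wide enough for a 12-bit sensor.  The cube
#' `kind` is preserved in the header so a round trip restores it.
#'
#' Internally cubes are indexed (line, pixel, band); the header writer
#' maps this onto ENVI's `lines`/`samples`/`bands`.
#'
#' @param cube a [hypercube()].
#' @param path path of the binary file; the header is written beside it
#'   with `.hdr` appended.
#' @param interleave one of `"bil"`, `"bip"`, `"bsq"`.
#' @return `write_envi()` returns `path` invisibly; `read_envi()` returns
#'   the [hypercube()].
#' @name envi_io
NULL

# 16-bit integers for integral raw counts (12-bit sensor convention),
# 32-bit floats otherwise
.envi_dtype <- function(cube) {
  v <- cube$values
  if (cube$kind == "raw" && all(v == round(v)) && all(abs(v) < 2^15)) {
    2L
  } else {
    4L
  }
}

#' @rdname envi_io
#' @export
write_envi <- function(cube, path, interleave = c("bil", "bip", "bsq")) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$values)
  dtype <- .envi_dtype(cube)
  perm <- switch(interleave,
    bsq = c(2, 1, 3), # sample fastest, then line, then band
    bil = c(2, 3, 1), # sample, band, line
    bip = c(3, 2, 1)  # band, sample, line
  )
  vec <- as.vector(aperm(cube$values, perm))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  if (dtype == 2L) {
    writeBin(as.integer(round(vec)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(vec), con, size = 4, endian = "little")
  }
  hdr <- c(
    "ENVI",
    "description = {carspls hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", dtype),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("cube kind = %s", cube$kind),
    "wavelength units = Nanometers",
    paste0(
      "wavelength = {",
      paste(format(cube$grid$centers, trim = TRUE), collapse = ", "),
      "}"
    )
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

.parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  # multi-line {...} values are joined before parsing
  txt <- paste(lines, collapse = " \n ")
  get_scalar <- function(key) {
    hit <- grep(paste0("^\\s*", key, "\\s*="), lines, value = TRUE)
    if (length(hit) == 0) {
      return(NA_character_)
    }
    trimws(sub("^[^=]*=", "", hit[1]))
  }
  get_list <- function(key) {
    m <- regmatches(txt, regexec(paste0(key, "\\s*=\\s*\\{([^}]*)\\}"),
                                 txt))[[1]]
    if (length(m) < 2) {
      return(NULL)
    }
    as.numeric(trimws(strsplit(m[2], ",")[[1]]))
  }
  list(
    samples = as.integer(get_scalar("samples")),
    lines = as.integer(get_scalar("lines")),
    bands = as.integer(get_scalar("bands")),
    dtype = as.integer(get_scalar("data type")),
    interleave = tolower(get_scalar("interleave")),
    kind = get_scalar("cube kind"),
    wavelength = get_list("wavelength")
  )
}

#' @rdname envi_io
#' @export
read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) {
    stop(sprintf("missing ENVI header %s", hdr_path))
  }
  h <- .parse_envi_header(hdr_path)
  if (anyNA(c(h$samples, h$lines, h$bands))) {
    stop("ENVI header missing samples/lines/bands")
  }
  if (!h$interleave %in% c("bil", "bip", "bsq")) {
    stop(sprintf("unknown interleave '%s'", h$interleave))
  }
  bytes <- switch(as.character(h$dtype), "2" = 2L, "4" = 4L, "5" = 8L,
                  stop(sprintf("unsupported ENVI data type %d", h$dtype)))
  n <- h$samples * h$lines * h$bands
  if (file.info(path)$size != as.numeric(n) * bytes) {
    stop(sprintf(
      "binary size %d does not match header dimensions (%d x %d x %d, %d bytes/value)",
      file.info(path)$size, h$lines, h$samples, h$bands, bytes
    ))
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  vec <- if (h$dtype == 2L) {
    as.numeric(readBin(con, "integer", n = n, size = 2, endian = "little"))
  } else {
    readBin(con, "numeric", n = n, size = bytes, endian = "little")
  }
  dims <- switch(h$interleave,
    bsq = c(h$samples, h$lines, h$bands),
    bil = c(h$samples, h$bands, h$lines),
    bip = c(h$bands, h$samples, h$lines)
  )
  perm <- switch(h$interleave,
    bsq = c(2, 1, 3),
    bil = c(3, 1, 2),
    bip = c(3, 2, 1)
  )
  values <- aperm(array(vec, dim = dims), perm)
  wl <- h$wavelength
  if (is.null(wl) || length(wl) != h$bands) {
    stop("ENVI header wavelength list missing or wrong length")
  }
  steps <- diff(wl)
  if (length(wl) > 1 && max(abs(steps - steps[1])) > 1e-6) {
    stop("non-uniform wavelength list not supported")
  }
  step <- if (length(wl) > 1) steps[1] else 2
  grid <- wavelength_grid(wl[1], wl[length(wl)] + step, step)
  kind <- if (!is.na(h$kind) && h$kind == "reflectance") "reflectance" else "raw"
  hypercube(values, grid, kind)
}
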