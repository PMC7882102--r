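## Portable single-file container for grids, and JSON registrations.
##
## Layout: an ASCII header of "key: value" lines terminated by a single
## blank line, then the raw array as little-endian doubles (masks as 8-bit
## 0/1) in column-major order. Round trips are bit-exact.

container_header <- function(kind, g, extra = list()) {
  h <- c(
    "fracdose-container: 1",
    paste0("kind: ", kind),
    paste0("dim: ", paste(g$dim, collapse = " ")),
    paste0("spacing: ", paste(sprintf("%.17g", g$spacing), collapse = " ")),
    paste0("origin: ", paste(sprintf("%.17g", g$origin), collapse = " ")),
    "byte_order: little"
  )
  for (k in names(extra)) {
    if (!is.null(extra[[k]])) h <- c(h, paste0(k, ": ", extra[[k]]))
  }
  h
}

write_container <- function(path, kind, g, payload, dtype, extra = list()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(container_header(kind, g, c(extra, list(dtype = dtype))), "")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (dtype == "float64") {
    writeBin(as.numeric(payload), con, size = 8, endian = "little")
  } else if (dtype == "uint8") {
    writeBin(as.integer(payload), con, size = 1, endian = "little")
  } else stop("unsupported dtype: ", dtype)
  invisible(path)
}

read_container_raw <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- character()
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) stop("truncated container header in ", path)
      if (ch == "\n") break
      line <- c(line, ch)
    }
    line <- paste(line, collapse = "")
    if (line == "") break
    hdr <- c(hdr, line)
  }
  kv <- strsplit(hdr, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), "")
  meta <- stats::setNames(as.list(vals), keys)
  if (is.null(meta[["fracdose-container"]]))
    stop("not a fracdose container: ", path)
  dims <- as.integer(strsplit(meta$dim, " ")[[1]])
  n <- prod(dims)
  payload <- if (meta$dtype == "float64") {
    readBin(con, "numeric", n = n, size = 8, endian = "little")
  } else {
    readBin(con, "integer", n = n, size = 1, signed = FALSE, endian = "little")
  }
  if (length(payload) != n) stop("truncated container payload in ", path)
  list(meta = meta, dims = dims, payload = payload)
}

num3 <- function(s) as.numeric(strsplit(s, " ")[[1]])

#' Write a grid object to the portable container format
#'
#' Single-file interchange format: a plain-text metadata header (kind, dim,
#' spacing, origin, dtype, byte order) followed by the raw little-endian
#' array. Doses and images are stored as float64, masks as 8-bit 0/1.
#' Round trips through [read_grid()] are bit-exact.
#'
#' @param x an `image_volume`, `dose_grid` or `structure_mask`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_grid <- function(x, path) {
  g <- grid_of(x)
  if (inherits(x, "image_volume")) {
    write_container(path, "image_volume", g, x$voxels, "float64",
                    list(fov_radius_mm = x$fov_radius_mm))
  } else if (inherits(x, "dose_grid")) {
    write_container(path, "dose_grid", g, x$dose, "float64",
                    list(frame_id = x$frame_id))
  } else if (inherits(x, "structure_mask")) {
    write_container(path, "structure_mask", g, x$mask, "uint8",
                    list(name = x$name))
  } else stop("unsupported object for write_grid")
  invisible(path)
}

#' Read a grid object from the portable container format
#' @param path file written by [write_grid()]
#' @return an `image_volume`, `dose_grid` or `structure_mask`
#' @export
read_grid <- function(path) {
  rc <- read_container_raw(path)
  m <- rc$meta
  arr <- array(rc$payload, rc$dims)
  switch(m$kind,
    image_volume = image_volume(arr, num3(m$spacing), num3(m$origin),
                                fov_radius_mm =
                                  if (!is.null(m$fov_radius_mm))
                                    as.numeric(m$fov_radius_mm) else NULL),
    dose_grid = dose_grid(arr, num3(m$spacing), num3(m$origin), m$frame_id),
    structure_mask = structure_mask(m$name, array(rc$payload != 0, rc$dims),
                                    num3(m$spacing), num3(m$origin)),
    stop("unknown container kind: ", m$kind)
  )
}

#' Write / read a rigid registration as JSON
#'
#' Interchange for online couch registrations: three translations (mm),
#' three rotations (deg) and the rotation centre (mm).
#' @param tr a `rigid_transform`
#' @param path file path
#' @return `path` (write) or a `rigid_transform` (read)
#' @export
write_registration <- function(tr, path) {
  jsonlite::write_json(list(t = tr$t, r = tr$r, center = tr$center),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_registration
#' @export
read_registration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$t, x$r, x$center)
}
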