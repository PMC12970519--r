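# Localization-table I/O.
#
# The HDF5 dialect follows the Picasso convention: a table named "locs"
# with per-row frame, x, y (camera pixels), lpx, lpy (precision, pixels),
# next to a YAML sidecar carrying pixel_size (nm), width, height (pixels)
# and n_frames.  Extra per-row fields are written and tolerated on read.
# A CSV fallback mirrors the same columns in nm.

sidecar_path <- function(path) {
  sub("\\.(hdf5|h5)$", ".yaml", path, ignore.case = TRUE)
}

#' Write a localization table
#'
#' `write_locs()` writes the Picasso-dialect HDF5 file (dataset `locs`,
#' coordinates converted from nm to camera pixels) plus a YAML sidecar;
#' `write_locs_csv()` writes the CSV fallback with columns
#' `frame,x_nm,y_nm,sigma_nm,channel,origin`.
#'
#' @param table a `localization_table`.
#' @param path output file (`.hdf5`/`.h5`, or `.csv` for the fallback).
#' @param acq acquisition settings providing `pixel_size` and field size;
#'   defaults to the table's `"acq"` attribute.
#' @return `path`, invisibly.
#' @export
write_locs <- function(table, path, acq = NULL) {
  stopifnot(inherits(table, "localization_table") || is.data.frame(table))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    return(write_locs_csv(table, path))
  }
  if (is.null(acq)) acq <- attr(table, "acq")
  if (is.null(acq)) {
    abort("`acq` is required to convert nm to pixels.",
          class = "dybe_argument_error")
  }
  if (nrow(table) > 0 && (any(!is.finite(table$x)) || any(!is.finite(table$y)))) {
    abort("non-finite coordinates.", class = "dybe_format_error")
  }
  px <- acq$pixel_size
  df <- data.frame(frame = as.integer(table$frame),
                   x = table$x / px, y = table$y / px,
                   lpx = table$sigma / px, lpy = table$sigma / px)
  if (!is.null(table$channel)) df$channel <- as.character(table$channel)
  if (!is.null(table$origin)) df$origin <- as.character(table$origin)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(df, path, "locs", DataFrameAsCompound = TRUE)
  rhdf5::h5closeAll()
  meta <- list(pixel_size = px,
               width = acq$field_width / px,
               height = acq$field_height / px,
               n_frames = as.integer(acq$n_frames))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' @rdname write_locs
#' @export
write_locs_csv <- function(table, path) {
  if (nrow(table) > 0 && (any(!is.finite(table$x)) || any(!is.finite(table$y)))) {
    abort("non-finite coordinates.", class = "dybe_format_error")
  }
  out <- tibble(frame = as.integer(table$frame),
                x_nm = table$x, y_nm = table$y, sigma_nm = table$sigma,
                channel = if (is.null(table$channel)) "A" else table$channel,
                origin = if (is.null(table$origin)) "specific" else table$origin)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a localization table
#'
#' Reads the Picasso-dialect HDF5 layout (requires the YAML sidecar for
#' the pixel size) or the CSV fallback, returning coordinates in nm.
#' Extra per-row fields in the HDF5 table are tolerated and dropped.
#'
#' @param path an `.hdf5`/`.h5` file (with YAML sidecar) or `.csv` file.
#' @return A `localization_table` tibble (`frame`, `x`, `y`, `sigma` in nm,
#'   `channel`, `origin`), with the sidecar metadata in the `"meta"`
#'   attribute (HDF5 input).
#' @export
read_locs <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "dybe_format_error")
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    return(read_locs_csv(path))
  }
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    abort(sprintf("missing YAML sidecar: %s", sc), class = "dybe_dialect_error")
  }
  meta <- yaml::read_yaml(sc)
  if (is.null(meta$pixel_size)) {
    abort("sidecar lacks `pixel_size`.", class = "dybe_dialect_error")
  }
  df <- rhdf5::h5read(path, "locs")
  rhdf5::h5closeAll()
  df <- as.data.frame(lapply(df, as.vector))
  need <- c("frame", "x", "y")
  if (!all(need %in% names(df))) {
    abort("HDF5 `locs` table lacks frame/x/y.", class = "dybe_dialect_error")
  }
  px <- meta$pixel_size
  if (nrow(df) > 0 && (any(!is.finite(df$x)) || any(!is.finite(df$y)))) {
    abort("non-finite coordinates.", class = "dybe_format_error")
  }
  sigma <- if (!is.null(df$lpx)) df$lpx * px else rep(px / 10, nrow(df))
  out <- tibble(frame = as.integer(df$frame),
                x = df$x * px, y = df$y * px, sigma = sigma,
                channel = if (!is.null(df$channel)) as.character(df$channel)
                          else rep("A", nrow(df)),
                origin = if (!is.null(df$origin)) as.character(df$origin)
                         else rep("specific", nrow(df)))
  attr(out, "meta") <- meta
  attr(out, "field") <- list(width = meta$width * px, height = meta$height * px)
  class(out) <- c("localization_table", class(out))
  out
}

#' @rdname read_locs
#' @export
read_locs_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("frame", "x_nm", "y_nm")
  if (!all(need %in% names(df))) {
    abort("CSV lacks frame/x_nm/y_nm columns.", class = "dybe_dialect_error")
  }
  if (nrow(df) > 0 && (any(!is.finite(df$x_nm)) || any(!is.finite(df$y_nm)))) {
    abort("non-finite coordinates.", class = "dybe_format_error")
  }
  out <- tibble(frame = as.integer(df$frame), x = df$x_nm, y = df$y_nm,
                sigma = if (!is.null(df$sigma_nm)) df$sigma_nm
                        else rep(10, nrow(df)),
                channel = if (!is.null(df$channel)) as.character(df$channel)
                          else rep("A", nrow(df)),
                origin = if (!is.null(df$origin)) as.character(df$origin)
                         else rep("specific", nrow(df)))
  class(out) <- c("localization_table", class(out))
  out
}
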