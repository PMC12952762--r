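# CSV readers/writers for the segmentation-tool-style tables the pipeline
# consumes. Dialect: UTF-8, comma separator, header row, "." decimal.
# Coordinates are stored in um, origin at the field's top-left, y downward;
# pixel-unit inputs are converted on load.

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(what, " table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
}

.coerce_numeric <- function(df, cols, what) {
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0L) {
        stop(what, " column '", col, "' has non-numeric values in row(s): ",
             paste(utils::head(bad, 10L), collapse = ", "))
      }
      df[[col]] <- vn
    }
  }
  df
}

# If only pixel-unit coordinates are present and a pixel size is declared,
# derive the um columns.
.px_to_um <- function(df, um_cols, px_cols, pixel_size_um, what) {
  for (i in seq_along(um_cols)) {
    if (!um_cols[i] %in% names(df) && px_cols[i] %in% names(df)) {
      if (is.null(pixel_size_um)) {
        stop(what, ": pixel-unit coordinates need a declared pixel_size_um")
      }
      df[[um_cols[i]]] <- df[[px_cols[i]]] * pixel_size_um
    }
  }
  df
}

#' Read a nucleus or spot table from CSV
#'
#' Validates required columns and numeric coordinates; unknown extra
#' columns are preserved. Pixel-unit coordinate columns (`*_px`) are
#' converted to um when `pixel_size_um` is declared.
#'
#' @param path CSV path.
#' @param pixel_size_um Optional pixel size for unit conversion.
#' @return A validated data frame.
#' @rdname read_tables
#' @export
read_nucleus_table <- function(path, pixel_size_um = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- .px_to_um(df, c("centroid_x_um", "centroid_y_um", "area_um2"),
                  c("centroid_x_px", "centroid_y_px", "area_px"),
                  pixel_size_um, "nucleus")
  if (!"area_um2" %in% names(df) && "area_px" %in% names(df) &&
      !is.null(pixel_size_um)) {
    df$area_um2 <- df$area_px * pixel_size_um^2
  }
  .check_columns(df, c("nucleus_id", "field_id", "area_um2", "solidity",
                       "centroid_x_um", "centroid_y_um"), "nucleus")
  .coerce_numeric(df, c("nucleus_id", "area_um2", "solidity",
                        "centroid_x_um", "centroid_y_um"), "nucleus")
}

#' @rdname read_tables
#' @export
read_spot_table <- function(path, pixel_size_um = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- .px_to_um(df, c("x_um", "y_um"), c("x_px", "y_px"),
                  pixel_size_um, "spot")
  .check_columns(df, c("spot_id", "nucleus_id", "channel", "x_um", "y_um",
                       "peak_intensity", "integrated_intensity"), "spot")
  .coerce_numeric(df, c("spot_id", "nucleus_id", "x_um", "y_um",
                        "peak_intensity", "integrated_intensity"), "spot")
}

#' Write a table as CSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read or write a single-channel image as TIFF
#'
#' Images are plain matrices (rows = y). Intensities are stored as 32-bit
#' float samples so arbitrary intensity ranges round-trip; label masks
#' write as 16-bit integers.
#'
#' @param path TIFF path.
#' @rdname image_tiff
#' @return `read_image_tiff()` returns a numeric matrix;
#'   `write_image_tiff()` returns `path` invisibly.
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF input")
  }
  img <- tiff::readTIFF(path, info = TRUE)
  bps <- attr(img, "bits.per.sample")
  if (is.null(bps)) bps <- 16L
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  # intensities are stored as value / 2^16 in float files; integer files
  # hold values scaled by their sample maximum
  scale <- if (bps == 32L) 65536 else 2^bps - 1
  out <- matrix(as.numeric(img) * scale, nrow(img), ncol(img))
  if (bps < 32L) out <- round(out)
  out
}

#' @param image Numeric matrix, or integer label matrix with
#'   `mask = TRUE`.
#' @param mask Write as a 16-bit integer label mask instead of float.
#' @rdname image_tiff
#' @export
write_image_tiff <- function(image, path, mask = FALSE) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF output")
  }
  if (mask) {
    if (any(image < 0 | image > 65535)) stop("mask labels must fit 16 bits")
    tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  } else {
    if (any(image < 0 | image >= 65536)) {
      stop("intensities must lie in [0, 65536) for float TIFF storage")
    }
    # dividing by 2^16 is exact in binary floating point
    tiff::writeTIFF(image / 65536, path, bits.per.sample = 32L)
  }
  invisible(path)
}
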