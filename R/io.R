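#' @name cenquant-io
#' @title Plain-text image and table input/output
#' @description
#' Stacks are exchanged in a plain-text format: `#`-prefixed key/value
#' metadata lines (pixel_size_nm, z_step_nm, exposure_s, value_format)
#' followed by whitespace-separated pixel rows, slices in order.  This
#' stands in for multi-page TIFF, which no installed reader supports here;
#' the format is lossless for calibrated floating-point frames.
#' Measurement and localization tables are ordinary CSV.
NULL

#' Write an image stack as plain text
#' @param stack an [image_stack].
#' @param path output file.
#' @export
write_stack_txt <- function(stack, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- dim(stack$pixels)
  writeLines(c(sprintf("# ny: %d", d[1]), sprintf("# nx: %d", d[2]),
               sprintf("# nz: %d", d[3]),
               sprintf("# pixel_size_nm: %.10g", stack$pixel_size),
               sprintf("# z_step_nm: %.10g", stack$z_step),
               sprintf("# exposure_s: %.10g", stack$exposure),
               sprintf("# value_format: %s", stack$value_format)), con)
  for (z in seq_len(d[3]))
    utils::write.table(stack$pixels[, , z], con, row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}

#' Read an image stack written by [write_stack_txt]
#' @param path input file.
#' @return an [image_stack].
#' @export
read_stack_txt <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":\\s*")[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  body <- lines[!grepl("^#", lines)]
  vals <- scan(text = body, quiet = TRUE)
  ny <- as.integer(meta$ny); nx <- as.integer(meta$nx)
  nz <- as.integer(meta$nz)
  px <- array(0, c(ny, nx, nz))
  per <- ny * nx
  for (z in seq_len(nz)) {
    m <- matrix(vals[((z - 1) * per + 1):(z * per)], ny, nx, byrow = TRUE)
    px[, , z] <- m
  }
  vf <- meta$value_format %||% "raw_adu"
  image_stack(px, pixel_size = as.numeric(meta$pixel_size_nm),
              z_step = as.numeric(meta$z_step_nm),
              exposure = as.numeric(meta$exposure_s),
              calibrated = vf == "calibrated_adu", value_format = vf)
}

#' Write / read localization tables
#'
#' Standard CSV with header `frame, x_nm, y_nm, z_nm, photons,
#' sigma_xy_nm, sigma_z_nm, is_fiducial` (missing columns tolerated on
#' read; bare three-column x/y/z lists are accepted and get frame 0).
#'
#' @param locs localization data.frame.
#' @param path file path.
#' @export
write_localizations <- function(locs, path) {
  utils::write.csv(locs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) == 3L && !all(c("x_nm", "y_nm", "z_nm") %in% names(df))) {
    names(df) <- c("x_nm", "y_nm", "z_nm")
    df$frame <- 0L
  }
  if (!"is_fiducial" %in% names(df)) df$is_fiducial <- FALSE
  df
}

#' Write / read measurement tables as CSV
#' @param measurements list of `cluster_measurement`s or a data.frame.
#' @param path file path.
#' @export
write_measurements <- function(measurements, path) {
  df <- if (is.data.frame(measurements)) measurements else
    measurements_table(measurements)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  hdr <- names(utils::read.csv(path, nrows = 1))
  cc <- rep(NA, length(hdr))
  ## keep stage labels literal: "T" (telophase) must not become logical TRUE
  cc[hdr %in% c("stage", "cell_id")] <- "character"
  utils::read.csv(path, colClasses = cc)
}
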