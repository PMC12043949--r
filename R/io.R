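# CSV and TIFF I/O with strict schemas. Physical calibration (pixel size,
# z-step, frame interval) always comes from arguments/config, never from
# image metadata.

table_schemas <- list(
  relaxation = c("time_s", "stress_kpa"),
  ramp       = c("strain", "stress_kpa"),
  sweep      = c("omega_rad_s", "g_storage", "g_loss"),
  frap       = c("time_s", "intensity", "phase"),
  tracks     = c("track_id", "frame", "t_s", "x_um", "y_um")
)

#' Read a typed CSV table
#'
#' Strict-schema CSV reader for the pipeline's tabular inputs. Column names
#' must match the schema exactly (`tracks` may add `z_um` for 3D); any
#' missing/extra column or non-numeric cell is a schema error naming the
#' offender.
#'
#' @param path CSV file path (comma-delimited, single header row).
#' @param schema One of `"relaxation"`, `"ramp"`, `"sweep"`, `"frap"`,
#'   `"tracks"`.
#' @return Typed records: a [relaxation_curve()], a data frame (`ramp`,
#'   `sweep`), a [frap_trace()], or a list of [trajectory()].
#' @export
read_table <- function(path, schema = names(table_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_io(paste("no such file:", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_schema(paste("unreadable CSV:", conditionMessage(e))))
  if (nrow(df) == 0L) stop_schema("empty table")
  want <- table_schemas[[schema]]
  if (schema == "tracks" && "z_um" %in% names(df)) want <- c(want, "z_um")
  missing_cols <- setdiff(want, names(df))
  extra_cols <- setdiff(names(df), want)
  if (length(missing_cols)) stop_schema(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  if (length(extra_cols)) stop_schema(paste("unexpected column(s):", paste(extra_cols, collapse = ", ")))
  numeric_cols <- setdiff(want, c("phase", "track_id"))
  for (cl in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (any(is.na(v))) {
      row <- c(bad, which(is.na(df[[cl]])))[1]
      stop_schema(sprintf("non-numeric value in column '%s' (row %d)", cl, row))
    }
    df[[cl]] <- v
  }
  switch(schema,
    relaxation = relaxation_curve(df$time_s, df$stress_kpa),
    ramp = df,
    sweep = df,
    frap = {
      pre <- df[df$phase == "prescan", ]
      post <- df[df$phase == "post", ]
      if (nrow(post) == 0L) stop_schema("frap table has no 'post' phase rows")
      frap_trace(post$time_s, post$intensity, pre$intensity,
                 frap_protocol(n_prescan = max(1L, nrow(pre)),
                               n_post = max(10L, nrow(post))))
    },
    tracks = {
      lapply(split(df, df$track_id), function(g) {
        g <- g[order(g$frame), ]
        pos <- as.matrix(g[, intersect(c("x_um", "y_um", "z_um"), names(g))])
        trajectory(g$track_id[1], g$t_s, pos)
      })
    })
}

#' Write particle tracks to CSV
#'
#' @param tracks List of [trajectory()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    d <- ncol(tr$position)
    df <- data.frame(track_id = tr$id, frame = seq_along(tr$time) - 1L,
                     t_s = tr$time, x_um = tr$position[, 1],
                     y_um = tr$position[, 2])
    if (d == 3L) df$z_um <- tr$position[, 3]
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a TIFF image or stack
#'
#' Reads a single- or multi-page grayscale TIFF as a 2D matrix or a
#' [zstack()]. Intensities are returned as floats in the file's stored
#' \[0, 1\] range times `scale`. Physical spacing comes from the arguments,
#' never from TIFF tags.
#'
#' @param path TIFF path.
#' @param voxel_xy Lateral pixel size in um.
#' @param z_step Axial step in um.
#' @param scale Multiplier restoring the intensity scale (default 1).
#' @return A matrix (single page) or [zstack()] (multi-page).
#' @export
read_stack <- function(path, voxel_xy = 0.1, z_step = 0.3, scale = 1) {
  if (!file.exists(path)) stop_io(paste("no such file:", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop_io(paste("unreadable TIFF:", conditionMessage(e))))
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1)))) {
    stop_io("RGB/multi-channel TIFF: extract a single channel before reading")
  }
  pages <- lapply(pages, function(p) p * scale)
  if (length(pages) == 1L) return(pages[[1]])
  zstack(array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))),
         voxel_xy = voxel_xy, z_step = z_step)
}

#' Write a TIFF image or stack
#'
#' Writes 16-bit grayscale; intensities are divided by `scale` and must
#' land in \[0, 1\].
#'
#' @param x A [zstack()], 3D array, or 2D matrix.
#' @param path Output TIFF path.
#' @param scale Divisor mapping intensities into \[0, 1\] (default:
#'   16-bit range).
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, scale = 65535) {
  data <- if (inherits(x, "zstack")) x$data else x
  data <- data / scale
  if (max(data) > 1 || min(data) < 0) stop_io("intensities do not fit the [0,1] write range; adjust `scale`")
  pages <- if (length(dim(data)) == 3L) {
    lapply(seq_len(dim(data)[3]), function(k) data[, , k])
  } else {
    list(as.matrix(data))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}
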