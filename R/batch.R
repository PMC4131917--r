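#' Measure a folder of spheroid images
#'
#' Batch driver for [segment_spheroid()]: every readable PNG/TIFF in the
#' folder is segmented and measured, in sorted-filename order, and one row
#' is emitted per image. Unreadable files do not abort the batch; their rows
#' carry a failure flag. Optionally writes, per image, an RGB copy with the
#' detected outline drawn in blue, and a single CSV of all measurements.
#'
#' @param folder Directory containing the images.
#' @param scale Micrometres per pixel (required calibration).
#' @param invert Passed to [segment_spheroid()].
#' @param out_dir If non-`NULL`, annotated copies (`<name>_outline.png`) and
#'   `measurements.csv` are written there.
#' @return A data frame with columns `source_id`, `area_um2`, `radius_um`,
#'   `diameter_um`, `volume_um3`, `feret_max_um`, `feret_min_um`,
#'   `aspect_ratio`, `empty`, `flags`.
#' @export
batch_measure <- function(folder, scale, invert = FALSE, out_dir = NULL) {
  if (!dir.exists(folder)) stop_("folder not found: %s", folder)
  files <- sort(list.files(folder, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE))
  if (length(files) == 0L) stop_("no images found in folder: %s", folder)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    res <- tryCatch({
      img <- read_gray_image(file.path(folder, f), scale = scale)
      m <- segment_spheroid(img, invert = invert)
      m$source_id <- f
      if (!is.null(out_dir)) {
        write_outline_overlay(img, m, file.path(
          out_dir, paste0(tools::file_path_sans_ext(f), "_outline.png")))
      }
      m
    }, error = function(e) {
      message(sprintf("[spheroscreen] failed to measure '%s': %s", f,
                      conditionMessage(e)))
      empty_morphometry(f, flags = paste0("read_error:", conditionMessage(e)))
    })
    rows[[i]] <- as.data.frame(res)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    write_csv_with_meta(out, file.path(out_dir, "measurements.csv"),
                        config = list(scale_um_per_px = scale, invert = invert))
  }
  out
}

# RGB copy of the image with the detected boundary painted pure blue.
write_outline_overlay <- function(image, morph, path) {
  g <- pmin(pmax(image$pixels, 0), 255) / 255
  arr <- array(g, dim = c(nrow(g), ncol(g), 3L))
  if (!morph$empty && !is.null(morph$outline)) {
    yx <- morph$outline
    arr[cbind(yx[, "y"], yx[, "x"], 1L)] <- 0
    arr[cbind(yx[, "y"], yx[, "x"], 2L)] <- 0
    arr[cbind(yx[, "y"], yx[, "x"], 3L)] <- 1
  }
  png::writePNG(arr, target = path)
  invisible(path)
}
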