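well_address_ok <- function(w) {
  grepl("^[A-H](1[0-2]|[1-9])$", w)
}

#' Define a 96-well plate layout
#'
#' Maps well addresses (letter row A-H, number column 1-12) to their role,
#' condition, concentration and assay. Every sample well must carry a
#' condition; duplicate or malformed addresses are rejected.
#'
#' @param wells Data frame with columns `well`, `role` (one of `sample`,
#'   `negative_control`, `positive_control`, `media_only`), `condition`,
#'   `concentration_uM` (NA for non-sample wells), `assay`.
#' @param plate_id Identifier carried into reports.
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(wells, plate_id = "plate1") {
  need <- c("well", "role")
  if (!all(need %in% names(wells))) {
    stop_("layout needs columns %s", paste(need, collapse = ", "))
  }
  bad <- wells$well[!well_address_ok(wells$well)]
  if (length(bad)) {
    stop_("invalid well address(es): %s (use letter A-H + column 1-12)",
          paste(unique(bad), collapse = ", "))
  }
  dup <- wells$well[duplicated(wells$well)]
  if (length(dup)) {
    stop_("duplicated well address(es) in layout: %s",
          paste(unique(dup), collapse = ", "))
  }
  roles <- c("sample", "negative_control", "positive_control", "media_only")
  if (!all(wells$role %in% roles)) {
    stop_("unknown role(s): %s",
          paste(setdiff(unique(wells$role), roles), collapse = ", "))
  }
  if (!"condition" %in% names(wells)) wells$condition <- NA_character_
  if (!"concentration_uM" %in% names(wells)) wells$concentration_uM <- NA_real_
  if (!"assay" %in% names(wells)) wells$assay <- "volume"
  nocond <- wells$role == "sample" &
    (is.na(wells$condition) | !nzchar(wells$condition))
  if (any(nocond)) {
    stop_("sample well(s) without a condition: %s",
          paste(wells$well[nocond], collapse = ", "))
  }
  structure(list(plate_id = plate_id,
                 wells = wells[, c("well", "role", "condition",
                                   "concentration_uM", "assay")]),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> '%s': %d wells (%s)\n", x$plate_id,
              nrow(x$wells),
              paste(sprintf("%d %s", table(x$wells$role),
                            names(table(x$wells$role))), collapse = ", ")))
  invisible(x)
}

layout_from_readings <- function(readings) {
  plate_layout(readings[, c("well", "role", "condition", "concentration_uM",
                            "assay")])
}

#' Read raw plate readings and join them to a layout
#'
#' The CSV dialect is UTF-8, comma-separated, `.` decimal, with optional
#' `#`-prefixed metadata header lines; data columns are `well` and
#' `reading`. Every well must exist in the layout; malformed or duplicated
#' rows abort with the offending line or address named. Layout wells with
#' no reading are reported in the `"missing_wells"` attribute.
#'
#' @param path CSV of raw readings.
#' @param layout A [plate_layout], or path to a layout CSV (columns `well`,
#'   `role`, `condition`, `concentration_uM`, `assay`).
#' @param run_id Run label attached to the readings.
#' @return Data frame of typed readings with the layout columns joined.
#' @export
read_plate_csv <- function(path, layout, run_id = "run1") {
  if (!file.exists(path)) stop_("plate file not found: %s", path)
  if (is.character(layout)) {
    ltab <- read.csv(layout, comment.char = "#", stringsAsFactors = FALSE)
    layout <- plate_layout(ltab)
  }
  stopifnot(inherits(layout, "plate_layout"))
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("well", "reading") %in% names(tab))) {
    stop_("plate CSV must have a header with columns 'well' and 'reading'")
  }
  readings <- suppressWarnings(as.numeric(tab$reading))
  bad <- which(!is.finite(readings))
  if (length(bad)) {
    stop_("malformed reading at data line %d of %s ('%s')", bad[1], path,
          tab$reading[bad[1]])
  }
  unknown <- setdiff(tab$well, layout$wells$well)
  if (length(unknown)) {
    stop_("well(s) not in layout: %s", paste(unknown, collapse = ", "))
  }
  dup <- tab$well[duplicated(tab$well)]
  if (length(dup)) {
    stop_("duplicated well(s) in plate file: %s",
          paste(unique(dup), collapse = ", "))
  }
  m <- match(tab$well, layout$wells$well)
  out <- data.frame(run_id = run_id, well = tab$well,
                    role = layout$wells$role[m],
                    condition = layout$wells$condition[m],
                    concentration_uM = layout$wells$concentration_uM[m],
                    assay = layout$wells$assay[m],
                    reading = readings, stringsAsFactors = FALSE)
  attr(out, "missing_wells") <- setdiff(layout$wells$well, tab$well)
  out
}

#' Write a data frame as CSV with a metadata comment header
#'
#' Every output file carries `#`-prefixed header lines embedding the
#' package version and a digest of the generating configuration, so results
#' are traceable and byte-identical for identical configurations.
#'
#' @param df Data frame to write.
#' @param path Destination.
#' @param config Named list of parameters to record.
#' @return `path`, invisibly.
#' @export
write_csv_with_meta <- function(df, path, config = list()) {
  cfg <- paste(vapply(names(config), function(k)
    sprintf("%s=%s", k, paste(format(config[[k]]), collapse = ",")),
    character(1)), collapse = "; ")
  hdr <- c(
    sprintf("# spheroscreen %s", as.character(packageVersion("spheroscreen"))),
    sprintf("# config_digest %s", config_hash(cfg)),
    if (nzchar(cfg)) sprintf("# config %s", cfg)
  )
  con <- file(path, open = "wb")   # binary mode: fixed '\n' line endings
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Assemble, read and write a run configuration
#'
#' A flat key-value record of every tunable the pipeline exposes, written
#' as YAML; configurations round-trip losslessly through the file.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    scale_um_per_px = 1.0, invert = FALSE,
    min_object_frac = 0.005, empty_frac = 0.01,
    q_percent = 1.0, alpha = 0.05,
    model = "4pl", combine = "geometric_mean",
    seed = 1L, out_dir = "."
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop_("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
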