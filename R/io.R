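# Plain-text readers and writers. Plates and titrations are CSV; stacks use a
# directory format (meta.json + one CSV per channel, one z-slice per row,
# row-major (y, x) values) because no TIFF reader is available in the target
# environment. All writers are inverse to their readers on their own output.

#' Read a plate-reader CSV
#'
#' Two dialects are supported. `long`: columns `well,read_index,fluorescence`,
#' one row per read. `block5x5`: columns `well,row,v1,v2,v3,v4,v5`, five rows
#' per well (the instrument's 5x5 area-scan block export). Sample wells must
#' carry exactly 25 reads; offending wells are named in the error.
#'
#' @param path Reads CSV.
#' @param map_path Plate-map CSV with columns `well,role,group,condition` and
#'   optionally `density`; wells missing from the map default to role
#'   `"sample"` with empty labels.
#' @param dialect `"long"` or `"block5x5"`.
#' @param plate_id Plate identifier.
#' @return A [plate_read()].
#' @export
read_plate_csv <- function(path, map_path = NULL,
                           dialect = c("long", "block5x5"),
                           plate_id = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    ntk_abort("ntk_io_error", sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "long") {
    need <- c("well", "read_index", "fluorescence")
    if (!all(need %in% names(df))) {
      ntk_abort("ntk_schema_error",
                sprintf("long dialect needs columns %s",
                        paste(need, collapse = ", ")))
    }
    reads_by_well <- split(
      df[order(df$well, df$read_index), "fluorescence"],
      df[order(df$well, df$read_index), "well"])
  } else {
    need <- c("well", "row", paste0("v", 1:5))
    if (!all(need %in% names(df))) {
      ntk_abort("ntk_schema_error",
                sprintf("block5x5 dialect needs columns %s",
                        paste(need, collapse = ", ")))
    }
    df <- df[order(df$well, df$row), ]
    reads_by_well <- lapply(split(df, df$well), function(b) {
      as.numeric(t(as.matrix(b[, paste0("v", 1:5)])))
    })
  }
  map <- NULL
  if (!is.null(map_path)) map <- read_plate_map(map_path)
  wells <- list()
  bad <- character()
  for (id in names(reads_by_well)) {
    reads <- as.numeric(reads_by_well[[id]])
    role <- "sample"; group <- NA_character_
    condition <- "rest"; density <- NA_real_
    if (!is.null(map) && id %in% map$well) {
      r <- map[map$well == id, ][1, ]
      role <- r$role; group <- r$group
      condition <- r$condition; density <- r$density
    }
    if (role == "sample" && length(reads) != 25L) {
      bad <- c(bad, sprintf("%s (%d reads)", id, length(reads)))
      next
    }
    wells[[id]] <- well_read(reads, role = role, group = group,
                             condition = condition, density = density)
  }
  if (length(bad)) {
    ntk_abort("ntk_schema_error",
              sprintf("sample wells without exactly 25 reads: %s",
                      paste(bad, collapse = "; ")))
  }
  plate_read(wells, plate_id = plate_id)
}

#' Read a plate-map CSV
#'
#' @param path CSV with columns `well,role,group,condition` and optionally
#'   `density`.
#' @export
read_plate_map <- function(path) {
  if (!file.exists(path)) {
    ntk_abort("ntk_io_error", sprintf("file not found: %s", path))
  }
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "role", "group", "condition")
  if (!all(need %in% names(map))) {
    ntk_abort("ntk_schema_error",
              sprintf("plate map needs columns %s", paste(need, collapse = ", ")))
  }
  if (!"density" %in% names(map)) map$density <- NA_real_
  map
}

#' Write a plate read (and its map) as CSV
#'
#' @param plate A [plate_read()].
#' @param reads_path Output CSV for the reads (long dialect).
#' @param map_path Optional output CSV for the plate map.
#' @export
write_plate_csv <- function(plate, reads_path, map_path = NULL) {
  stopifnot(inherits(plate, "plate_read"))
  rows <- do.call(rbind, lapply(names(plate$wells), function(id) {
    w <- plate$wells[[id]]
    data.frame(well = id, read_index = seq_along(w$reads),
               fluorescence = w$reads, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, reads_path, row.names = FALSE, quote = FALSE)
  if (!is.null(map_path)) {
    map <- do.call(rbind, lapply(names(plate$wells), function(id) {
      w <- plate$wells[[id]]
      data.frame(well = id, role = w$role, group = w$group,
                 condition = w$condition, density = w$density,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(map, map_path, row.names = FALSE, quote = FALSE)
  }
  invisible(reads_path)
}

#' Read/write a titration series CSV
#'
#' CSV columns: `kx,cell,dff0`.
#'
#' @param path CSV path.
#' @param kr Reference concentration (mM).
#' @export
read_titration_csv <- function(path, kr = 5.4) {
  if (!file.exists(path)) {
    ntk_abort("ntk_io_error", sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("kx", "dff0") %in% names(df))) {
    ntk_abort("ntk_schema_error", "titration CSV needs columns kx, dff0")
  }
  titration_series(df, kr = kr)
}

#' @rdname read_titration_csv
#' @param series A [titration_series()].
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  utils::write.csv(series$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a z-stack to a plain-text directory
#'
#' Layout: `meta.json` (dimensions, pixel size, z-step, refractive index,
#' correction flag) plus `green.csv` and `red.csv`, one z-slice per row with
#' row-major (y, x) values.
#'
#' @param stack A [z_stack()].
#' @param dir Output directory (created if needed).
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "z_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack$green)
  meta <- list(nz = d[1], ny = d[2], nx = d[3],
               xy_pixel_size = stack$xy_pixel_size, z_step = stack$z_step,
               z_origin = stack$z_origin,
               refractive_index = stack$refractive_index,
               z_corrected = stack$z_corrected)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  for (ch in c("green", "red")) {
    arr <- stack[[ch]]
    # rows = slices; within a row, (y, x) values with y fastest (column-major)
    m <- matrix(arr, nrow = d[1])
    data.table::fwrite(data.table::as.data.table(m),
                       file.path(dir, paste0(ch, ".csv")),
                       col.names = FALSE)
  }
  invisible(dir)
}

#' Read a z-stack from a plain-text directory
#'
#' Metadata comes from `meta.json`; `overrides` (a named list, e.g.
#' `list(z_step = 1)`) replaces individual fields. Missing metadata without an
#' override is an error, never a silent default.
#'
#' @param dir Directory written by [write_stack()].
#' @param overrides Named list of metadata overrides.
#' @return A [z_stack()].
#' @export
read_stack <- function(dir, overrides = list()) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) {
    ntk_abort("ntk_missing_metadata_error",
              sprintf("no meta.json in %s", dir))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (k in names(overrides)) meta[[k]] <- overrides[[k]]
  for (k in c("nz", "ny", "nx", "xy_pixel_size", "z_step")) {
    if (is.null(meta[[k]])) {
      ntk_abort("ntk_missing_metadata_error",
                sprintf("metadata field '%s' absent and not overridden", k))
    }
  }
  channels <- lapply(c("green", "red"), function(ch) {
    p <- file.path(dir, paste0(ch, ".csv"))
    if (!file.exists(p)) {
      ntk_abort("ntk_channel_count_error",
                sprintf("channel file missing: %s", p))
    }
    m <- as.matrix(data.table::fread(p, header = FALSE))
    if (nrow(m) != meta$nz || ncol(m) != meta$ny * meta$nx) {
      ntk_abort("ntk_channel_count_error",
                sprintf("%s: expected %d x %d values, got %d x %d",
                        ch, meta$nz, meta$ny * meta$nx, nrow(m), ncol(m)))
    }
    array(as.vector(m), dim = c(meta$nz, meta$ny, meta$nx))
  })
  z_stack(channels[[1]], channels[[2]],
          xy_pixel_size = as.numeric(meta$xy_pixel_size),
          z_step = as.numeric(meta$z_step),
          z_origin = as.numeric(meta$z_origin %||% 0),
          refractive_index = meta$refractive_index %||% 1.33,
          z_corrected = meta$z_corrected %||% TRUE)
}

#' Write / read a simulated scene
#'
#' A scene directory holds `thickness_stack/`, `indent_stack/` and a
#' `truth.json` sidecar.
#'
#' @param scene An `indentation_scene`.
#' @param dir Output directory.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(scene$thickness_stack, file.path(dir, "thickness_stack"))
  write_stack(scene$indent_stack, file.path(dir, "indent_stack"))
  jsonlite::write_json(scene$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  truth_path <- file.path(dir, "truth.json")
  structure(
    list(thickness_stack = read_stack(file.path(dir, "thickness_stack")),
         indent_stack = read_stack(file.path(dir, "indent_stack")),
         truth = if (file.exists(truth_path))
           jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL),
    class = "indentation_scene"
  )
}

# Known run-config keys; unknown keys are rejected on read.
.run_config_keys <- c("elasticity", "ephys", "stack", "plan", "seed",
                      "verbosity")

#' Read a run configuration (JSON)
#'
#' Sections: `elasticity` (fields of [elasticity_config()]), `ephys`
#' (`temperature`, `z_prime`), `stack` (fields of [stack_config()]), `plan`,
#' `seed`, `verbosity`. Unknown top-level keys are rejected.
#'
#' @param path JSON config file.
#' @return List with materialized config objects.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), .run_config_keys)
  if (length(unknown)) {
    ntk_abort("ntk_schema_error",
              sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  list(
    elasticity = do.call(elasticity_config, as.list(raw$elasticity %||% list())),
    ephys = do.call(ephys_constants, as.list(raw$ephys %||% list())),
    stack = do.call(stack_config, as.list(raw$stack %||% list())),
    plan = raw$plan, seed = raw$seed, verbosity = raw$verbosity %||% 1
  )
}
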