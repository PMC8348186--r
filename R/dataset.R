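#' Mean spectrum over a region of interest
#'
#' Per-band arithmetic mean of the reflectance over the masked pixels —
#' one ROI yields one classification observation.
#'
#' @param cube A [hypercube()].
#' @param mask Logical (lines x samples) matrix selecting the ROI.
#' @return Numeric reflectance vector of length `bands`.
#' @export
roi_mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  if (!all(dim(mask) == dim(cube$data)[1:2]))
    stop("mask shape does not match cube spatial dimensions")
  if (!any(mask)) stop("ROI mask is empty")
  .masked_colmeans(.cube_plane_matrix(cube), mask)
}

# cube as (n_pixels x bands) matrix in column-major plane order; cheap view
# for per-band statistics where pixel order is irrelevant
.cube_plane_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, d[1] * d[2], d[3])
}

.masked_colmeans <- function(M, mask) {
  colMeans(M[which(mask), , drop = FALSE])
}

#' Severity/time class code
#'
#' Builds the class label `"Lxy"`/`"Lxyz"`: bruising level `Lx`
#' (1 <= x <= 6) recorded after `y` or `yz` hours, e.g. `L11` (level 1,
#' 1 h) or `L318` (level 3, 18 h). When a `schedule` (the severity table)
#' is supplied, combinations that were never scanned under it — such as
#' level 6 at 72 h — are rejected.
#'
#' @param level Integer severity level 1..6.
#' @param hours Scan instant in 1, 6, 18, 48, 72.
#' @param schedule Optional [severity_table()] against which the
#'   combination is validated.
#' @return Character class code.
#' @export
class_code <- function(level, hours, schedule = NULL) {
  level <- as.integer(level)
  if (is.na(level) || level < 1 || level > 6)
    stop("level must be an integer in 1..6")
  if (!hours %in% SCAN_HOURS)
    stop("hours must be one of ", paste(SCAN_HOURS, collapse = ", "))
  if (!is.null(schedule)) {
    row <- match(paste0("L", level), schedule$code)
    seen <- union(scan_hours_for(schedule$times_scanned_batch1[row]),
                  scan_hours_for(schedule$times_scanned_batch2[row]))
    if (!hours %in% seen)
      stop("L", level, " was never scanned at ", hours, " h under this schedule")
  }
  paste0("L", level, hours)
}

#' Parse a severity/time class code
#'
#' Inverse of [class_code()]: `parse_class_code(class_code(l, h))` returns
#' `list(level = l, hours = h)`.
#'
#' @param code Character class code (`"Lxy"`/`"Lxyz"`) or `"sound"`.
#' @return List with integer `level` and numeric `hours` (both `NA` for
#'   `"sound"`).
#' @export
parse_class_code <- function(code) {
  if (code == "sound") return(list(level = NA_integer_, hours = NA_real_))
  m <- regmatches(code, regexec("^L([1-6])(1|6|18|48|72)$", code))[[1]]
  if (length(m) != 3) stop("not a valid class code: ", code)
  list(level = as.integer(m[2]), hours = as.numeric(m[3]))
}

#' Enumerate all severity/time classes
#'
#' All level x scan-instant combinations plus `"sound"`; with the default
#' six levels and five instants this is the 31-class label set of the
#' quantitative task.
#'
#' @param levels Integer severity levels.
#' @param hours Scan instants.
#' @return Character vector of class codes, `"sound"` first.
#' @export
all_class_codes <- function(levels = 1:6, hours = SCAN_HOURS) {
  codes <- as.vector(t(outer(levels, hours, function(l, h) paste0("L", l, h))))
  c("sound", codes)
}

#' Assemble a labelled spectra table from an experiment manifest
#'
#' Generates (or reads) each cube referenced by the manifest, extracts one
#' mean spectrum per painted bruise disc (the bruised rows) and per sound
#' ROI (discs of the bruise radius placed uniformly inside the fruit at
#' >= 2 radii from any bruise). The requested total number of sound ROIs
#' is distributed round-robin over the cubes, earliest cubes taking the
#' remainder.
#'
#' @param manifest A data.frame from [experiment_manifest()].
#' @param config A [simulation_config()] used to generate the cubes.
#' @param sound_total Total number of sound ROIs across all cubes.
#' @return An object of class `spectra_table`: list with `spectra`
#'   (n x bands matrix), `meta` (data.frame: `status`, `level`, `hours`,
#'   `class_code`, `batch`, `cube_id`) and `wavelengths`.
#' @export
assemble_dataset <- function(manifest, config, sound_total = 287L) {
  need <- c("cube_id", "level", "hours", "batch", "n_bruises", "cube_seed")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols) > 0)
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  n_cubes <- nrow(manifest)
  if (n_cubes == 0) {
    return(structure(list(spectra = matrix(numeric(0), 0, config$band_count),
                          meta = data.frame(status = character(0),
                                            level = character(0),
                                            hours = numeric(0),
                                            class_code = character(0),
                                            batch = integer(0),
                                            cube_id = character(0)),
                          wavelengths = config_wavelengths(config)),
                     class = "spectra_table"))
  }
  # round-robin split of the sound ROI budget
  base <- sound_total %/% n_cubes
  extra <- sound_total %% n_cubes
  sound_per_cube <- rep(base, n_cubes) + c(rep(1L, extra), rep(0L, n_cubes - extra))

  spectra <- list(); meta <- list()
  for (i in seq_len(n_cubes)) {
    row <- manifest[i, ]
    sim <- generate_hypercube(config, level = row$level, hours = row$hours,
                              seed = row$cube_seed, n_bruises = row$n_bruises)
    cube <- sim$cube; truth <- sim$truth
    M <- .cube_plane_matrix(cube)
    # bruised ROIs: one per painted disc
    if (row$n_bruises > 0 && row$level != "sound") {
      for (k in seq_len(row$n_bruises)) {
        m <- truth$bruise_labels == k
        spectra[[length(spectra) + 1]] <- .masked_colmeans(M, m)
        lv <- as.integer(sub("L", "", row$level))
        meta[[length(meta) + 1]] <-
          data.frame(status = "bruised", level = row$level, hours = row$hours,
                     class_code = class_code(lv, row$hours),
                     batch = row$batch, cube_id = row$cube_id)
      }
    }
    # sound ROIs on the same cube, away from the bruises
    n_snd <- sound_per_cube[i]
    if (n_snd > 0) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      set.seed(row$cube_seed + 500000L)
      centers <- .place_discs(config, n_snd,
                              min_sep = config$bruise_radius_px,
                              avoid = .truth_centers(truth),
                              avoid_sep = 2 * config$bruise_radius_px)
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
      for (k in seq_len(n_snd)) {
        m <- .disc_mask(config$lines, config$samples, centers[k, ],
                        config$bruise_radius_px)
        spectra[[length(spectra) + 1]] <- .masked_colmeans(M, m)
        meta[[length(meta) + 1]] <-
          data.frame(status = "sound", level = "none", hours = NA_real_,
                     class_code = "sound", batch = row$batch,
                     cube_id = row$cube_id)
      }
    }
  }
  structure(list(spectra = do.call(rbind, spectra),
                 meta = do.call(rbind, meta),
                 wavelengths = config_wavelengths(config)),
            class = "spectra_table")
}

# centroids of the painted bruise discs, for exclusion zones
.truth_centers <- function(truth) {
  labs <- truth$bruise_labels
  ks <- setdiff(sort(unique(as.vector(labs))), 0L)
  if (length(ks) == 0) return(matrix(numeric(0), 0, 2))
  t(vapply(ks, function(k) {
    pos <- which(labs == k, arr.ind = TRUE)
    c(mean(pos[, 1]), mean(pos[, 2]))
  }, numeric(2)))
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("<spectra_table> %d spectra x %d bands (%d bruised, %d sound)\n",
              nrow(x$spectra), ncol(x$spectra),
              sum(x$meta$status == "bruised"), sum(x$meta$status == "sound")))
  invisible(x)
}

#' Convert a spectra table to a flat data.frame
#'
#' Wavelength columns (`wl_<nm>`) followed by the label columns, the
#' layout used for CSV export.
#'
#' @param x A `spectra_table`.
#' @param ... Unused.
#' @return A data.frame with one row per spectrum.
#' @export
as.data.frame.spectra_table <- function(x, ...) {
  sp <- as.data.frame(x$spectra)
  names(sp) <- paste0("wl_", format(x$wavelengths, trim = TRUE, digits = 6))
  cbind(sp, x$meta)
}

#' Write a spectra table to CSV
#' @param x A `spectra_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
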