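#' Simulation configuration for synthetic bruising hypercubes
#'
#' Bundles the geometry, wavelength grid and noise model used by
#' [generate_hypercube()]. Defaults describe a desk-scale frame; the full
#' instrument frame (404 x 384 pixels, 288 bands from 930 nm in 5.45 nm
#' steps) is obtained by passing `lines = 404, samples = 384`.
#'
#' @param lines,samples Image rows and columns (positive integers).
#' @param band_start_nm First band centre wavelength in nm.
#' @param band_step_nm Band spacing in nm.
#' @param band_count Number of spectral bands (>= 2).
#' @param fruit_axes Length-2 numeric, ellipse semi-axes of the fruit region
#'   in pixels (line axis, sample axis).
#' @param bruise_radius_px Radius of each circular bruise region in pixels.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian reflectance
#'   noise added per pixel and band.
#' @param background_reflectance Mean reflectance of the (dark) background.
#' @param baseline_sd Standard deviation of the per-cube multiplicative
#'   baseline factor emulating fruit-to-fruit reflectance variability.
#' @param amp_jitter_sdlog Log-SD of the per-bruise lognormal amplitude
#'   jitter emulating bruise-to-bruise variability.
#' @param seed Default integer seed for generators that are not given one.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_hypercube()], [sound_spectrum()], [bruise_spectrum()]
#' @export
simulation_config <- function(lines = 96L, samples = 96L,
                              band_start_nm = 930, band_step_nm = 5.45,
                              band_count = 288L,
                              fruit_axes = c(40, 36),
                              bruise_radius_px = 6,
                              noise_sd = 0.01,
                              background_reflectance = 0.02,
                              baseline_sd = 0.005,
                              amp_jitter_sdlog = 0.05,
                              seed = 1L) {
  lines <- as.integer(lines); samples <- as.integer(samples)
  band_count <- as.integer(band_count)
  stopifnot(lines >= 1, samples >= 1, band_count >= 2,
            band_step_nm > 0, noise_sd >= 0, length(fruit_axes) == 2)
  if (2 * fruit_axes[1] >= lines || 2 * fruit_axes[2] >= samples)
    stop("fruit ellipse does not fit inside the frame")
  if (bruise_radius_px >= min(fruit_axes))
    stop("bruise disc does not fit inside the fruit ellipse")
  structure(list(lines = lines, samples = samples,
                 band_start_nm = band_start_nm, band_step_nm = band_step_nm,
                 band_count = band_count, fruit_axes = fruit_axes,
                 bruise_radius_px = bruise_radius_px, noise_sd = noise_sd,
                 background_reflectance = background_reflectance,
                 baseline_sd = baseline_sd,
                 amp_jitter_sdlog = amp_jitter_sdlog,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Wavelength grid of a simulation configuration
#' @param config A [simulation_config()] object.
#' @return Numeric vector of band-centre wavelengths in nm.
#' @export
config_wavelengths <- function(config) {
  config$band_start_nm + config$band_step_nm * (seq_len(config$band_count) - 1)
}

#' Impact energy of a dropped impactor
#'
#' Potential energy released by a free fall, `m * g * h`, rounded to three
#' decimals for reporting (the precision of the experiment bookkeeping).
#'
#' @param mass_kg Impactor mass in kg (> 0).
#' @param height_m Drop height in m (>= 0).
#' @param g Gravitational acceleration in m/s^2.
#' @return Impact energy in joules, rounded to 3 decimal places.
#' @examples
#' energy_from_drop(0.06379, 0.020) # 0.013 J, the lowest severity level
#' @export
energy_from_drop <- function(mass_kg, height_m, g = 9.81) {
  if (any(mass_kg <= 0)) stop("mass_kg must be positive")
  if (any(height_m < 0)) stop("height_m must be non-negative")
  round(mass_kg * g * height_m, 3)
}

# Scan instants (hours after bruising) used throughout the experiment.
SCAN_HOURS <- c(1, 6, 18, 48, 72)

#' Severity table of the bruising experiment
#'
#' The six severity levels L1-L6: drop heights of a 63.79 g steel ball,
#' derived impact energies, per-batch scan counts and the resulting number
#' of bruised spectra per level (6 bruises per batch, one spectrum per
#' bruise per scan).
#'
#' @param mass_kg Impactor mass in kg.
#' @param g Gravitational acceleration in m/s^2.
#' @return A data.frame with columns `code`, `drop_height_m`,
#'   `impact_energy_J`, `times_scanned_batch1`, `times_scanned_batch2`,
#'   `bruises_per_batch` and `samples`; `sum(tbl$samples)` is the grand
#'   total of bruised observations.
#' @export
severity_table <- function(mass_kg = 0.06379, g = 9.81) {
  heights <- c(0.020, 0.040, 0.07, 0.126, 0.219, 0.319)
  b1 <- c(4L, 4L, 4L, 4L, 3L, 3L)
  b2 <- c(2L, 2L, 2L, 1L, 1L, 1L)
  tbl <- data.frame(
    code = paste0("L", 1:6),
    drop_height_m = heights,
    impact_energy_J = energy_from_drop(mass_kg, heights, g),
    times_scanned_batch1 = b1,
    times_scanned_batch2 = b2,
    bruises_per_batch = 6L,
    stringsAsFactors = FALSE
  )
  tbl$samples <- tbl$bruises_per_batch * (b1 + b2)
  tbl
}

#' Scan instants for a batch scanned a given number of times
#'
#' A batch scanned `k` times is observed at the first `k` of the scan
#' schedule 1, 6, 18, 48, 72 h.
#'
#' @param times_scanned Integer, number of scans (0..5).
#' @return Numeric vector of hours.
#' @export
scan_hours_for <- function(times_scanned) {
  stopifnot(times_scanned >= 0, times_scanned <= length(SCAN_HOURS))
  SCAN_HOURS[seq_len(times_scanned)]
}

#' Synthetic sound-tissue reflectance spectrum
#'
#' A smooth positive reflectance curve on (0, 1] with the two water
#' absorption dips near 1450 and 1940 nm that dominate SWIR spectra of
#' fresh produce, plus a gentle seeded random undulation so that different
#' seeds give different (but reproducible) fruit.
#'
#' @param grid Numeric vector of wavelengths in nm, strictly increasing.
#' @param seed Integer seed; the curve is a pure function of (grid, seed).
#' @return Reflectance vector of `length(grid)`, values in (0, 1].
#' @export
sound_spectrum <- function(grid, seed = 1L) {
  if (length(grid) == 0) stop("wavelength grid is empty")
  if (any(diff(grid) <= 0)) stop("wavelength grid must be strictly increasing")
  rng <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    stats::rnorm(6, 0, 1)
  })
  u <- (grid - min(grid)) / diff(range(grid))   # 0..1 across the grid
  base <- 0.58 - 0.10 * u                        # mild downward tilt into SWIR
  # seeded smooth undulation (low-order cosine series, small amplitude)
  und <- 0.008 * (rng[1] * cos(pi * u) + rng[2] * cos(2 * pi * u) +
                    rng[3] * cos(3 * pi * u)) / 3
  dip <- function(center, depth, width) depth * exp(-0.5 * ((grid - center) / width)^2)
  s <- base + und - dip(1450, 0.20, 55) - dip(1940, 0.28, 75) - dip(1200, 0.03, 60)
  pmin(pmax(s, 0.02), 1)
}

# Saturation of the bruise amplitude with time since impact:
# most of the chemical change is in place within the first hour
# (bruised spectra cluster away from sound tissue from the first scan),
# with a slower browning tail over the following days.
.bruise_time_factor <- function(hours, t0 = 0.6, tau = 24) {
  t0 + (1 - t0) * (1 - exp(-hours / tau))
}

#' Expected bruise amplitude for an impact energy and age
#'
#' Peak reflectance decrement of the bruise signature. Any impact above
#' zero produces a substantial baseline signature (cell damage is
#' switch-like), modulated upward by impact energy (square-root scaling:
#' spectral depth saturates while the damage spreads spatially) and by
#' bruise age:
#' `a0 * (e0 + (1-e0)*sqrt(E/Emax)) * (t0 + (1-t0)*(1 - exp(-t/tau)))`
#' for `E > 0`, and exactly 0 at `E = 0`. Strictly increasing in energy,
#' non-decreasing in time.
#'
#' @param energy_J Impact energy in joules (>= 0).
#' @param hours Hours since impact (>= 0).
#' @param a0 Peak decrement at maximum energy and full development.
#' @param energy_max_J Energy at which the energy factor reaches 1.
#' @param e0 Energy-factor floor for any non-zero impact.
#' @return Reflectance decrement (dimensionless).
#' @export
bruise_amplitude <- function(energy_J, hours, a0 = 0.30, energy_max_J = 0.200,
                             e0 = 0.6) {
  if (any(energy_J < 0)) stop("energy_J must be non-negative")
  if (any(hours < 0)) stop("hours must be non-negative")
  efac <- ifelse(energy_J > 0,
                 e0 + (1 - e0) * sqrt(energy_J / energy_max_J), 0)
  a0 * efac * .bruise_time_factor(hours)
}

#' Synthetic bruised-tissue reflectance spectrum
#'
#' Applies the bruise signature to a sound spectrum: Gaussian-shaped
#' absorbance increments (reflectance decrements) centred at 1130, 1285 and
#' 1650 nm, i.e. inside the 952-1377 nm and 1550-1850 nm windows where
#' bruised tissue absorbs more than sound tissue, with an overall amplitude
#' that grows with impact energy and bruise age (see [bruise_amplitude()]).
#'
#' @param sound Sound-tissue reflectance spectrum (same grid).
#' @param energy_J Impact energy in joules (>= 0).
#' @param hours Hours since impact.
#' @param grid Wavelength grid in nm matching `sound`.
#' @param amplitude Optional explicit peak decrement overriding
#'   [bruise_amplitude()] (used for per-bruise jitter).
#' @return Bruised reflectance spectrum; identical to `sound` when
#'   `energy_J == 0`, never above `sound` inside the bruise windows.
#' @export
bruise_spectrum <- function(sound, energy_J, hours, grid, amplitude = NULL) {
  if (energy_J < 0) stop("energy_J must be non-negative")
  stopifnot(length(sound) == length(grid))
  a <- if (is.null(amplitude)) bruise_amplitude(energy_J, hours) else amplitude
  if (energy_J == 0) return(sound)
  # component mix shifts with cause: impact energy deepens the 1130/1285 nm
  # pigment/water pair slightly more, bruise age the 1650 nm band, so
  # severity and age are separately identifiable from the signature shape
  efac <- 0.8 + 0.2 * sqrt(energy_J / 0.200)
  tfac <- 0.8 + 0.2 * .bruise_time_factor(hours)
  shape <- efac * (exp(-0.5 * ((grid - 1130) / 45)^2) +
                     0.9 * exp(-0.5 * ((grid - 1285) / 45)^2)) +
    tfac * 0.6 * exp(-0.5 * ((grid - 1650) / 70)^2)
  pmax(sound - a * shape, 0.01)
}

#' Integrated bruised-vs-sound spectral gap
#'
#' Mean absolute reflectance difference between a sound and a bruised
#' spectrum over the diagnostic windows 952-1377 nm and 1550-1850 nm.
#' Used as the scalar "contrast" in monotonicity checks.
#'
#' @param sound,bruised Reflectance spectra on `grid`.
#' @param grid Wavelength grid in nm.
#' @return Non-negative scalar.
#' @export
spectral_gap <- function(sound, bruised, grid) {
  win <- (grid >= 952 & grid <= 1377) | (grid >= 1550 & grid <= 1850)
  if (!any(win)) stop("grid does not cover the bruise windows")
  mean(abs(sound[win] - bruised[win]))
}

# Hard-edged ellipse / disc masks on a (lines x samples) frame.
.ellipse_mask <- function(lines, samples, center, axes) {
  y <- matrix(seq_len(lines), lines, samples)
  x <- matrix(seq_len(samples), lines, samples, byrow = TRUE)
  ((y - center[1]) / axes[1])^2 + ((x - center[2]) / axes[2])^2 <= 1
}

.disc_mask <- function(lines, samples, center, radius) {
  y <- matrix(seq_len(lines), lines, samples)
  x <- matrix(seq_len(samples), lines, samples, byrow = TRUE)
  (y - center[1])^2 + (x - center[2])^2 <= radius^2
}

# Sample n non-overlapping disc centres inside the fruit ellipse,
# keeping min_sep between centres. Rejection sampling; errors if the
# geometry cannot host the request.
.place_discs <- function(config, n, min_sep, avoid = NULL, avoid_sep = 0) {
  ctr <- c((config$lines + 1) / 2, (config$samples + 1) / 2)
  ax <- config$fruit_axes - config$bruise_radius_px - 1
  if (any(ax <= 0)) stop("bruise disc does not fit inside the fruit ellipse")
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centers) < n) {
    tries <- tries + 1
    if (tries > 5000 * n) stop("could not place ", n, " discs inside the fruit")
    # uniform in the shrunken ellipse
    r <- sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
    p <- ctr + c(ax[1] * r * cos(th), ax[2] * r * sin(th))
    ok <- TRUE
    if (nrow(centers) > 0 &&
        min(sqrt(rowSums(sweep(centers, 2, p)^2))) < min_sep) ok <- FALSE
    if (ok && !is.null(avoid) && nrow(avoid) > 0 &&
        min(sqrt(rowSums(sweep(avoid, 2, p)^2))) < avoid_sep) ok <- FALSE
    if (ok) centers <- rbind(centers, p)
  }
  centers
}

#' Generate a synthetic bruising hypercube with ground truth
#'
#' Paints an elliptical fruit over a dark background, adds `n_bruises`
#' circular bruise regions (none when `level = "sound"`), and applies
#' i.i.d. Gaussian reflectance noise per pixel and band. Per-cube
#' multiplicative baseline variation and per-bruise amplitude jitter
#' emulate biological variability. Deterministic for a fixed
#' (config, level, hours, seed, n_bruises).
#'
#' @param config A [simulation_config()].
#' @param level Severity code `"L1"`..`"L6"` or `"sound"`.
#' @param hours Hours since bruising (ignored for `"sound"`).
#' @param seed Integer seed; default from `config`.
#' @param n_bruises Number of bruise discs painted on the fruit.
#' @return A list with components `cube` (a [hypercube()]) and `truth`
#'   (class `ground_truth`: logical `fruit_mask` and `bruise_mask`,
#'   integer `bruise_labels` image numbering the discs, `level`, `hours`,
#'   and the per-bruise `amplitudes` actually painted).
#' @export
generate_hypercube <- function(config, level = "sound", hours = 1,
                               seed = config$seed, n_bruises = 1L) {
  stopifnot(inherits(config, "sim_config"))
  levels_ok <- c(paste0("L", 1:6), "sound")
  if (!level %in% levels_ok) stop("level must be one of ", paste(levels_ok, collapse = ", "))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  grid <- config_wavelengths(config)
  nl <- config$lines; ns <- config$samples; nb <- config$band_count
  ctr <- c((nl + 1) / 2, (ns + 1) / 2)
  fruit <- .ellipse_mask(nl, ns, ctr, config$fruit_axes)

  baseline <- 1 + stats::rnorm(1, 0, config$baseline_sd)
  snd <- pmin(sound_spectrum(grid, seed = seed) * baseline, 1)

  cube <- array(config$background_reflectance, dim = c(nl, ns, nb))
  npx <- nl * ns
  paint <- function(idx, spec) {
    # broadcast a spectrum over a set of spatial positions, all bands at once
    pos <- rep(idx, times = nb) + rep((seq_len(nb) - 1L) * npx, each = length(idx))
    cube[pos] <<- rep(spec, each = length(idx))
  }
  fidx <- which(fruit)
  paint(fidx, snd)

  bruise_mask <- matrix(FALSE, nl, ns)
  bruise_labels <- matrix(0L, nl, ns)
  amplitudes <- numeric(0)
  if (level != "sound" && n_bruises > 0) {
    tbl <- severity_table()
    energy <- tbl$impact_energy_J[match(level, tbl$code)]
    centers <- .place_discs(config, n_bruises,
                            min_sep = 2.5 * config$bruise_radius_px)
    base_amp <- bruise_amplitude(energy, hours)
    amplitudes <- base_amp * stats::rlnorm(n_bruises, 0, config$amp_jitter_sdlog)
    for (k in seq_len(n_bruises)) {
      disc <- .disc_mask(nl, ns, centers[k, ], config$bruise_radius_px)
      brs <- bruise_spectrum(snd, energy, hours, grid, amplitude = amplitudes[k])
      didx <- which(disc)
      paint(didx, brs)
      bruise_mask <- bruise_mask | disc
      bruise_labels[didx] <- k
    }
  }

  cube <- cube + array(stats::rnorm(nl * ns * nb, 0, config$noise_sd),
                       dim = c(nl, ns, nb))
  hc <- hypercube(cube, grid,
                  metadata = list(level = level,
                                  hours = if (level == "sound") NA_real_ else hours,
                                  seed = seed))
  truth <- structure(list(fruit_mask = fruit, bruise_mask = bruise_mask,
                          bruise_labels = bruise_labels,
                          level = level,
                          hours = if (level == "sound") NA_real_ else hours,
                          amplitudes = amplitudes),
                     class = "ground_truth")
  list(cube = hc, truth = truth)
}

#' Experiment manifest reproducing the bruising-study bookkeeping
#'
#' One row per scanned batch (a cube carrying `bruises_per_batch` bruise
#' regions): level, hours, batch and a derived cube seed. With
#' `schedule = "table1"` the per-batch scan counts of the severity table
#' are honoured (186 bruised spectra in total); with
#' `schedule = "factorial"` every level is scanned at every instant for
#' both batches, which realises the full 6 levels x 5 times class
#' structure.
#'
#' @param schedule `"table1"` or `"factorial"`.
#' @param seed Integer base seed; cube seeds are `seed * 1000 + row`.
#' @param levels Severity codes to include.
#' @param hours Scan instants for the factorial schedule.
#' @return A data.frame with columns `cube_id`, `level`, `hours`, `batch`,
#'   `n_bruises`, `cube_seed`.
#' @export
experiment_manifest <- function(schedule = c("table1", "factorial"),
                                seed = 1L,
                                levels = paste0("L", 1:6),
                                hours = SCAN_HOURS) {
  schedule <- match.arg(schedule)
  tbl <- severity_table()
  rows <- list()
  for (i in seq_len(nrow(tbl))) {
    code <- tbl$code[i]
    if (!code %in% levels) next
    if (schedule == "table1") {
      h1 <- scan_hours_for(tbl$times_scanned_batch1[i])
      h2 <- scan_hours_for(tbl$times_scanned_batch2[i])
    } else {
      h1 <- hours; h2 <- hours
    }
    for (h in h1) rows[[length(rows) + 1]] <-
      data.frame(level = code, hours = h, batch = 1L,
                 n_bruises = tbl$bruises_per_batch[i])
    for (h in h2) rows[[length(rows) + 1]] <-
      data.frame(level = code, hours = h, batch = 2L,
                 n_bruises = tbl$bruises_per_batch[i])
  }
  man <- do.call(rbind, rows)
  man <- man[order(match(man$level, tbl$code), man$batch, man$hours), ,
             drop = FALSE]
  man$cube_id <- sprintf("%s_b%d_h%02d", man$level, man$batch, man$hours)
  man$cube_seed <- as.integer(seed * 1000L + seq_len(nrow(man)))
  rownames(man) <- NULL
  man[, c("cube_id", "level", "hours", "batch", "n_bruises", "cube_seed")]
}
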