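#' Specification of a synthetic NIR-like dataset
#'
#' Describes a Beer-Lambert-style linear mixture emulating a pharmaceutical
#' NIR calibration campaign: one response-linked constituent (the analyte,
#' e.g. the active pharmaceutical ingredient) absorbing at `n_active`
#' Gaussian bands, plus `n_nuisance` nuisance constituents (excipients,
#' moisture) each absorbing at `peaks_per_component` bands. Per-sample
#' constituent concentrations mix the band profiles into smooth spectra; a
#' per-sample linear baseline and iid instrument noise are added on top.
#' The response is the analyte concentration — the quantity a calibration
#' model must recover. The seed fully determines the generated data.
#'
#' Defaults (200 samples, 300 wavelengths over 800-2500 nm, 2 analyte
#' bands + 6 nuisance constituents, SNR about 20) are a reduced-scale
#' stand-in for a realistic campaign on granule spectra.
#'
#' @param n_samples number of samples N.
#' @param n_wavelengths number of wavelength points M.
#' @param n_active number of absorption bands of the response constituent
#'   (real compounds absorb at several overtone/combination bands).
#' @param n_nuisance number of nuisance constituents.
#' @param peaks_per_component number of bands per nuisance constituent
#'   (default 2).
#' @param peak_centers optional numeric vector of band centers in nm: first
#'   the `n_active` analyte bands, then the nuisance bands
#'   (`n_nuisance * peaks_per_component`, constituent-major). Default:
#'   all bands on an evenly spaced slot grid with a small seeded jitter,
#'   assigned to constituents in seeded random order.
#' @param peak_widths Gaussian standard deviations in nm (scalar or one per
#'   constituent, analyte first); default span/34 (about 50 nm, i.e.
#'   roughly 120 nm full width, a typical NIR band).
#' @param peak_amplitudes optional nuisance band amplitudes (matrix
#'   `n_nuisance` x `peaks_per_component` or scalar); default drawn
#'   uniformly in [0.7, 1.3].
#' @param response_coefficients absorption strengths of the analyte's
#'   `n_active` bands; default `seq(1, 0.5, length.out = n_active)`.
#' @param concentration_correlation pairwise correlation (Gaussian copula)
#'   between constituent concentrations, in [0, 0.95]; 0 = independent.
#' @param baseline_amplitude scale of the per-sample baseline drift
#'   (absorbance units).
#' @param baseline_components number of smooth instrument drift modes. The
#'   baseline of each sample is a random combination of a constant offset,
#'   a linear tilt, and `baseline_components - 2` broad Gaussian bumps at
#'   seeded positions (the instrument's drift signature, shared by the
#'   modelling and validation sets; coefficients are drawn per sample).
#'   The default 2 gives the plain offset+tilt baseline; larger values add
#'   multi-scale drift of the kind that forces full-spectrum calibration
#'   models of plant data to large numbers of latent variables.
#' @param noise_sd additive instrument noise standard deviation (the
#'   mid-range level); `NULL` (default) derives it from `snr` as
#'   `sd(clean signal) / snr`.
#' @param snr signal-to-noise ratio used when `noise_sd` is `NULL`.
#' @param edge_noise_factor factor by which the noise standard deviation is
#'   inflated at the extreme ends of the wavelength axis (quadratic ramp
#'   over the first 8% and last 12% of the range), mimicking the SNR
#'   roll-off of NIR instruments near the detector transition and cutoff;
#'   1 = homoscedastic noise.
#' @param n_validation number of samples in the companion validation batch
#'   (0 for none).
#' @param validation_nuisance_shift magnitude of the batch effect in the
#'   validation set: each nuisance constituent's concentration distribution
#'   is shifted by a seeded amount drawn uniformly in +/- this value (on
#'   the Gaussian-copula scale), emulating new excipient lots / process
#'   drift between the modelling campaign and the validation batch. The
#'   analyte is not shifted: its content is the designed calibration
#'   variable and spans the same range in both sets.
#' @param wavelength_range axis limits in nm.
#' @param seed integer seed.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(n_samples = 200L, n_wavelengths = 300L,
                     n_active = 2L, n_nuisance = 6L,
                     peaks_per_component = 2L,
                     peak_centers = NULL, peak_widths = NULL,
                     peak_amplitudes = NULL,
                     response_coefficients = NULL,
                     concentration_correlation = 0,
                     baseline_amplitude = 0.01,
                     baseline_components = 2L,
                     noise_sd = NULL, snr = 20,
                     edge_noise_factor = 4,
                     n_validation = 40L,
                     validation_nuisance_shift = 0.8,
                     wavelength_range = c(800, 2500),
                     seed = 1L) {
  check_scalar(n_samples, "n_samples", lower = 3, integer = TRUE)
  check_scalar(n_wavelengths, "n_wavelengths", lower = 4, integer = TRUE)
  check_scalar(n_active, "n_active", lower = 1, integer = TRUE)
  check_scalar(n_nuisance, "n_nuisance", lower = 0, integer = TRUE)
  check_scalar(peaks_per_component, "peaks_per_component", lower = 1, integer = TRUE)
  check_scalar(concentration_correlation, "concentration_correlation",
               lower = 0, upper = 0.95)
  check_scalar(baseline_amplitude, "baseline_amplitude", lower = 0)
  check_scalar(baseline_components, "baseline_components", lower = 2, integer = TRUE)
  check_scalar(edge_noise_factor, "edge_noise_factor", lower = 1)
  check_scalar(n_validation, "n_validation", lower = 0, integer = TRUE)
  check_scalar(validation_nuisance_shift, "validation_nuisance_shift", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  n_bands <- n_active + n_nuisance * peaks_per_component
  if (!is.null(peak_centers) && length(peak_centers) != n_bands) {
    stop(sprintf("peak_centers must have %d entries (analyte bands first)", n_bands),
         call. = FALSE)
  }
  if (!is.null(noise_sd)) check_scalar(noise_sd, "noise_sd", lower = 0)
  else check_scalar(snr, "snr", lower = 0, open_lower = TRUE)
  if (is.null(response_coefficients)) {
    response_coefficients <- seq(1, 0.5, length.out = n_active)
  }
  if (length(response_coefficients) != n_active) {
    stop("response_coefficients must have length n_active", call. = FALSE)
  }
  span <- diff(wavelength_range)
  if (span <= 0) stop("wavelength_range must be increasing", call. = FALSE)
  if (!is.null(peak_centers) &&
      (any(peak_centers < wavelength_range[1]) || any(peak_centers > wavelength_range[2]))) {
    stop("peak_centers must lie within wavelength_range", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_wavelengths = as.integer(n_wavelengths),
                 n_active = as.integer(n_active),
                 n_nuisance = as.integer(n_nuisance),
                 peaks_per_component = as.integer(peaks_per_component),
                 peak_centers = peak_centers, peak_widths = peak_widths,
                 peak_amplitudes = peak_amplitudes,
                 response_coefficients = as.numeric(response_coefficients),
                 concentration_correlation = concentration_correlation,
                 baseline_amplitude = baseline_amplitude,
                 baseline_components = as.integer(baseline_components),
                 noise_sd = noise_sd, snr = snr,
                 edge_noise_factor = edge_noise_factor,
                 n_validation = as.integer(n_validation),
                 validation_nuisance_shift = validation_nuisance_shift,
                 wavelength_range = as.numeric(wavelength_range),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generate a synthetic spectra dataset with ground truth
#'
#' Draws constituent concentrations (uniform marginals, optional pairwise
#' correlation via a Gaussian copula), mixes them through the constituents'
#' Gaussian band profiles, adds the baseline and noise, and sets the
#' response to the analyte concentration. The ground truth records which
#' wavelength indices belong to analyte ("active") versus nuisance bands —
#' a wavelength belongs to a constituent's region where its profile
#' exceeds 1% of that profile's maximum.
#'
#' When `n_validation > 0` a companion validation batch is generated with
#' the same band structure and noise level but a seeded batch effect on the
#' nuisance concentrations (see [sim_spec()]), emulating validation samples
#' prepared separately from the modelling campaign.
#'
#' @param spec a [sim_spec()].
#' @return list with `dataset` (the modelling set, a [spectra_dataset()]),
#'   `validation` (the shifted batch, or `NULL`), and `truth`:
#'   `active_idx`, `nuisance_idx`, `concentrations` (analyte first
#'   column), `profiles` (constituents x wavelengths, analyte first row),
#'   `peak_centers`, `response_coefficients`, `batch_shift`, `noise_sd`.
#' @examples
#' sim <- simulate_spectra(sim_spec(n_samples = 50, n_wavelengths = 60))
#' range(sim$dataset$y)
#' @export
simulate_spectra <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_samples; m <- spec$n_wavelengths
    A <- spec$n_active; B <- spec$n_nuisance
    kpp <- spec$peaks_per_component
    n_const <- 1L + B
    wl <- seq(spec$wavelength_range[1], spec$wavelength_range[2], length.out = m)
    span <- diff(spec$wavelength_range)
    widths <- spec$peak_widths
    if (is.null(widths)) widths <- span / 34
    widths <- rep(widths, length.out = n_const)
    n_bands <- A + B * kpp
    centers <- spec$peak_centers
    if (is.null(centers)) {
      slot_pos <- spec$wavelength_range[1] + span * seq_len(n_bands) / (n_bands + 1)
      slot_pos <- slot_pos + stats::runif(n_bands, -0.2, 0.2) * span / (n_bands + 1)
      centers <- slot_pos[sample.int(n_bands)]
    }
    act_centers <- centers[seq_len(A)]
    nuis_centers <- if (B > 0) matrix(centers[-seq_len(A)], B, kpp) else NULL
    amps <- spec$peak_amplitudes
    if (is.null(amps)) amps <- stats::runif(B * kpp, 0.7, 1.3)
    if (B > 0) amps <- matrix(amps, B, kpp)
    gauss <- function(center, width) exp(-(wl - center)^2 / (2 * width^2))
    profiles <- matrix(0, n_const, m)
    for (r in seq_len(A)) {
      profiles[1L, ] <- profiles[1L, ] +
        spec$response_coefficients[r] * gauss(act_centers[r], widths[1L])
    }
    for (j in seq_len(B)) {
      for (r in seq_len(kpp)) {
        profiles[j + 1L, ] <- profiles[j + 1L, ] +
          amps[j, r] * gauss(nuis_centers[j, r], widths[j + 1L])
      }
    }
    # concentrations: uniform marginals via a Gaussian copula; `shift`
    # displaces constituents on the copula scale (batch effect)
    draw_conc <- function(nn, shift = NULL) {
      rho <- spec$concentration_correlation
      Z <- matrix(stats::rnorm(nn * n_const), nn, n_const)
      if (rho > 0) Z <- sqrt(rho) * stats::rnorm(nn) + sqrt(1 - rho) * Z
      if (!is.null(shift)) Z <- sweep(Z, 2, shift, `+`)
      stats::pnorm(Z)
    }
    u <- (wl - spec$wavelength_range[1]) / span
    # detector SNR roll-off at the range edges
    ramp <- 1 + (spec$edge_noise_factor - 1) *
      (pmax(0, (0.08 - u) / 0.08)^2 + pmax(0, (u - 0.88) / 0.12)^2)
    # instrument drift modes: offset, tilt, and broad bumps at seeded
    # positions (shared by all batches from this instrument)
    qb <- spec$baseline_components
    drift <- rbind(rep(1, m), u)
    if (qb > 2L) {
      bump_c <- stats::runif(qb - 2L, 0, 1)
      bump_w <- span / 8
      drift <- rbind(drift, t(vapply(bump_c, function(b)
        exp(-(wl - (spec$wavelength_range[1] + b * span))^2 / (2 * bump_w^2)),
        numeric(m))))
    }
    noise_sd <- spec$noise_sd
    assemble <- function(conc, prefix) {
      nn <- nrow(conc)
      clean <- conc %*% profiles
      if (is.null(noise_sd)) noise_sd <<- stats::sd(as.vector(clean)) / spec$snr
      baseline <- matrix(stats::rnorm(nn * qb, sd = spec$baseline_amplitude),
                         nn, qb) %*% drift
      noise <- matrix(stats::rnorm(nn * m), nn, m) %*% diag(noise_sd * ramp, m)
      X <- clean + baseline + noise
      spectra_dataset(X, y = conc[, 1L], wavelengths = round(wl, 3),
                      sample_ids = sprintf("%s%04d", prefix, seq_len(nn)))
    }
    conc <- draw_conc(n)
    dataset <- assemble(conc, "s")
    validation <- NULL
    batch_shift <- NULL
    if (spec$n_validation > 0) {
      batch_shift <- c(0, stats::runif(B, -1, 1) * spec$validation_nuisance_shift)
      conc_val <- draw_conc(spec$n_validation, shift = batch_shift)
      validation <- assemble(conc_val, "v")
    }
    region <- function(j) which(profiles[j, ] > 0.01 * max(profiles[j, ]))
    active_idx <- sort(region(1L))
    nuisance_idx <- if (B > 0) {
      sort(setdiff(unique(unlist(lapply(2L:n_const, region))), active_idx))
    } else integer(0)
    list(dataset = dataset,
         validation = validation,
         truth = list(active_idx = active_idx,
                      nuisance_idx = nuisance_idx,
                      concentrations = conc,
                      profiles = profiles,
                      peak_centers = centers, peak_widths = widths,
                      response_coefficients = spec$response_coefficients,
                      batch_shift = batch_shift,
                      noise_sd = noise_sd))
  })
}
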