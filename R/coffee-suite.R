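# Technique-matched synthetic coffee suite: one cohort of 97 samples
# (75 Arabica across six Latin-American origins, 22 Robusta) measured on the
# three standard grids, with species- and origin-discriminating peaks,
# scatter/baseline/confounder structure, and a fixed panel of gross outliers.

coffee_cohort <- function() {
  arabica <- c(Colombia = 34, Guatemala = 15, Peru = 11, Brazil = 9,
               `Costa Rica` = 5, Panama = 1)
  robusta <- c(Vietnam = 8, India = 4, Uganda = 3, Indonesia = 3,
               Togo = 1, Tanzania = 1, `Ivory Coast` = 1, Cameroon = 1)
  country <- c(rep(names(arabica), arabica), rep(names(robusta), robusta))
  species <- rep(c("Arabica", "Robusta"), c(sum(arabica), sum(robusta)))
  tibble::tibble(
    sample_id = sprintf("cof%03d", seq_along(country)),
    species = species,
    country = country,
    origin = ifelse(country == "Colombia", "Colombia", "Other")
  )
}

# fixed outlier panel: which cohort members come out corrupted on which
# instrument. The union removes 9 Arabica and 3 Robusta, so a clean QC pass
# leaves 66 Arabica / 19 Robusta.
coffee_outlier_panel <- function(cohort) {
  nth_of <- function(ctry, k) cohort$sample_id[cohort$country == ctry][k]
  list(
    `ATR-mIR` = c(nth_of("Peru", 1), nth_of("Vietnam", 1)),
    NIR = c(nth_of("Colombia", 1:2), nth_of("Guatemala", 1),
            nth_of("Brazil", 1), nth_of("Vietnam", 2)),
    NMR = c(nth_of("Colombia", 3:4), nth_of("Peru", 2),
            nth_of("Panama", 1), nth_of("Vietnam", 3))
  )
}

# peak tables with separate species and origin amplitude factors
coffee_peaks <- function(technique) {
  pk <- function(center, width, amplitude, species_effect = 1, origin_effect = 1,
                 shape = "gaussian") {
    tibble::tibble(center = center, width = width, amplitude = amplitude,
                   species_effect = species_effect, origin_effect = origin_effect,
                   shape = shape)
  }
  switch(technique,
    "ATR-mIR" = dplyr::bind_rows(
      pk(900, 25, 0.8), pk(1080, 30, 1.0), pk(1160, 20, 0.7),
      pk(1245, 18, 0.6, species_effect = 2.2),
      pk(1380, 22, 0.9, origin_effect = 1.25),
      pk(1450, 20, 0.8),
      pk(1550, 18, 0.5, species_effect = 2.2),
      pk(1650, 25, 1.1, origin_effect = 1.25),
      pk(1740, 15, 0.9),
      pk(2900, 40, 0.6), pk(3300, 120, 0.5)
    ),
    NIR = dplyr::bind_rows(
      pk(4300, 80, 1.0), pk(4700, 90, 0.8),
      pk(5200, 100, 1.1, origin_effect = 1.04),
      pk(5600, 60, 0.6, species_effect = 2.5),
      pk(6300, 120, 0.7, origin_effect = 1.04),
      pk(6900, 70, 0.9, species_effect = 2.5),
      pk(8300, 150, 0.5), pk(9500, 180, 0.3)
    ),
    NMR = dplyr::bind_rows(
      pk(0.9, 0.03, 0.9, shape = "lorentzian"),
      pk(1.3, 0.03, 1.1, shape = "lorentzian"),
      pk(2.0, 0.04, 0.7, shape = "lorentzian"),
      pk(2.7, 0.03, 0.6, origin_effect = 1.1, shape = "lorentzian"),
      pk(3.9, 0.04, 0.8, shape = "lorentzian"),
      pk(4.3, 0.03, 0.5, origin_effect = 1.1, shape = "lorentzian"),
      pk(5.3, 0.03, 0.6, shape = "lorentzian"),
      # Kahweol-like Arabica-specific signals
      pk(5.8, 0.02, 0.15, species_effect = 3, shape = "lorentzian"),
      pk(6.2, 0.02, 0.12, species_effect = 3, shape = "lorentzian"),
      pk(6.3, 0.02, 0.12, species_effect = 3, shape = "lorentzian"),
      pk(7.3, 0.02, 0.15, species_effect = 3, shape = "lorentzian"),
      pk(8.4, 0.03, 0.5, shape = "lorentzian")
    ),
    abort_bad_arg(sprintf("unknown technique '%s'", technique))
  )
}

coffee_noise <- function(technique) {
  switch(technique,
    "ATR-mIR" = list(scatter_slope_sd = 0.06, scatter_offset_sd = 0.02,
                     baseline_amplitude = 0.03, noise_sd = 0.02,
                     confounder_amplitude = 0.15),
    NIR = list(scatter_slope_sd = 0.10, scatter_offset_sd = 0.04,
               baseline_amplitude = 0.04, noise_sd = 0.02,
               confounder_amplitude = 0.30),
    # NMR of standardised extracts at fixed receiver gain shows almost no
    # multiplicative scatter — which is why its chain applies no
    # normalisation; scatter is a particle-size (IR) phenomenon
    NMR = list(scatter_slope_sd = 0.01, scatter_offset_sd = 0.005,
               baseline_amplitude = 0.02, noise_sd = 0.05,
               confounder_amplitude = 0.10)
  )
}

# spurious sharp features for a corrupted acquisition: narrow artifact peaks
# at instrument-characteristic (fixed) positions, with a random overall
# amplitude per corrupted sample. A shared signature mimics how shim or
# detector artifacts distort every bad acquisition the same way, and makes
# the corruption a single high-variance direction.
corrupt_profile <- function(axis, scale) {
  lo <- min(axis); span <- max(axis) - lo
  centers <- lo + c(0.07, 0.18, 0.30, 0.55, 0.75) * span
  widths <- c(0.002, 0.0015, 0.0025, 0.0015, 0.002) * span
  rel <- c(0.8, 1, 0.7, 0.9, 0.6)
  out <- numeric(length(axis))
  for (j in seq_along(centers)) {
    out <- out + rel[j] * peak_profile(axis, centers[j], widths[j], "gaussian")
  }
  stats::runif(1L, 0.5, 1) * scale * out
}

#' Generate the three-technique synthetic coffee suite
#'
#' One cohort of 97 samples (75 Arabica of which 34 Colombian, 22 Robusta) is
#' simulated on the three standard grids: ATR-mIR 650-4000 cm^-1 at
#' 0.96 cm^-1, NIR 4000-10000 cm^-1 at 4 cm^-1 (1500 points), and a dense NMR
#' grid over 0.5-9.5 ppm (80501 points by default) meant to be binned to 1100
#' variables by the preprocessing chain. Species information sits on a few
#' strong peaks (for NMR, Kahweol-like signals at 5.8/6.2/6.3/7.3 ppm that are
#' much weaker in Robusta); origin information sits on smaller amplitude
#' factors, weakest for NIR. A fixed panel of corrupted acquisitions (2 on
#' mIR, 5 on NIR, 5 on NMR; 12 distinct samples, 9 Arabica + 3 Robusta) is
#' planted by adding narrow artifact peaks at instrument-characteristic
#' positions, `outlier_scale` times as tall as the spectrum itself.
#'
#' @param seed integer seed; the suite is a pure function of it.
#' @param n_points_nmr size of the dense NMR grid (inclusive ends).
#' @param outlier_scale artifact height relative to the spectrum maximum.
#' @return named list of three [spectra_set()]s (`"ATR-mIR"`, `"NIR"`,
#'   `"NMR"`), each with `species`/`origin`/`country` labels and a
#'   planted-truth attribute flagging its outliers.
#' @export
generate_coffee_suite <- function(seed = 1L, n_points_nmr = 80501L,
                                  outlier_scale = 8) {
  cohort <- coffee_cohort()
  panel <- coffee_outlier_panel(cohort)
  grids <- list(
    "ATR-mIR" = make_grid(650, 4000, 0.96),
    NIR = make_grid(4000, 10000, 4),
    NMR = seq(0.5, 9.5, length.out = n_points_nmr)
  )
  out <- lapply(seq_along(grids), function(gi) {
    technique <- names(grids)[gi]
    axis <- grids[[gi]]
    peaks <- coffee_peaks(technique)
    nz <- coffee_noise(technique)
    n <- nrow(cohort)
    amp <- outer(rep(1, n), peaks$amplitude)
    is_ara <- cohort$species == "Arabica"
    is_col <- cohort$origin == "Colombia"
    amp[is_ara, ] <- amp[is_ara, , drop = FALSE] *
      rep(peaks$species_effect, each = sum(is_ara))
    amp[is_col, ] <- amp[is_col, , drop = FALSE] *
      rep(peaks$origin_effect, each = sum(is_col))

    planted <- cohort$sample_id %in% panel[[technique]]
    sim <- withr::with_seed(as.integer(seed) + gi, {
      s <- simulate_spectra(axis, peaks, amp, nz$scatter_slope_sd,
                            nz$scatter_offset_sd, nz$baseline_amplitude,
                            nz$noise_sd, nz$confounder_amplitude)
      # corrupt the planted outliers the way acquisition errors corrupt real
      # spectra: spurious narrow artifact peaks that survive derivative
      # filtering and reshape the normalised profile
      for (i in which(planted)) {
        s$x[i, ] <- s$x[i, ] +
          corrupt_profile(axis, max(abs(s$x[i, ])) * outlier_scale)
      }
      s
    })
    x <- sim$x
    rownames(x) <- cohort$sample_id

    set <- spectra_set(x, axis, technique, labels = cohort,
                       sample_ids = cohort$sample_id)
    attr(set, "truth") <- tibble::tibble(
      sample_id = cohort$sample_id, species = cohort$species,
      origin = cohort$origin, confounder = sim$u, is_outlier = planted
    )
    attr(set, "class_peaks") <- list(
      species = peaks$center[peaks$species_effect != 1],
      origin = peaks$center[peaks$origin_effect != 1]
    )
    set
  })
  names(out) <- names(grids)
  out
}
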