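#' Configuration for the synthetic grape study generator
#'
#' Describes a simulated multi-season on-vine ripening study: samples per
#' season, number of varieties (split red/white), replicate spectra per
#' sample and presentation mode, the ripening-trajectory noise, the
#' per-replicate scatter model, and the strength of the regime-dependent
#' nonlinearity that makes global calibrations locally biased. The defaults
#' emulate a three-season field campaign: 108/120/135 samples in seasons
#' 2006-2008, 25 varieties, 8 replicate spectra per sample, and both bunch
#' and must presentations (bunch with roughly three times the scatter
#' variance of must).
#'
#' @param n_per_season integer vector of samples per season.
#' @param seasons season labels, same length.
#' @param n_varieties number of varieties (roughly half flagged red).
#' @param replicates replicate spectra per sample and presentation.
#' @param presentations subset of `c("bunch", "must")`.
#' @param wl_lo,wl_hi,wl_step wavelength grid in nm.
#' @param mult_sd multiplicative scatter SD per replicate (must mode).
#' @param add_sd additive baseline offset SD (absorbance units).
#' @param tilt_sd SD of the linear baseline tilt across the grid.
#' @param noise_sd white-noise SD per wavelength point.
#' @param bunch_scatter_factor scatter inflation for bunch presentation.
#' @param nonlinearity strength of the soluble-solids-dependent path-length
#'   factor (0 = fully linear mixing).
#' @param seed root seed; all stage substreams derive from it.
#' @return a `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_per_season = c(108, 120, 135),
                             seasons = c(2006, 2007, 2008),
                             n_varieties = 25, replicates = 8,
                             presentations = c("bunch", "must"),
                             wl_lo = 380, wl_hi = 1700, wl_step = 2,
                             mult_sd = 0.03, add_sd = 0.02, tilt_sd = 0.015,
                             noise_sd = 0.002, bunch_scatter_factor = 1.8,
                             nonlinearity = 0.15, seed = 1) {
  if (length(n_per_season) != length(seasons))
    stop("n_per_season and seasons must align")
  presentations <- match.arg(presentations, c("bunch", "must"),
                             several.ok = TRUE)
  sds <- c(mult_sd, add_sd, tilt_sd, noise_sd)
  if (any(sds < 0)) stop("scatter/noise SDs must be >= 0")
  if (is.null(seed)) stop("seed is mandatory")
  structure(list(n_per_season = as.integer(n_per_season),
                 seasons = seasons, n_varieties = as.integer(n_varieties),
                 replicates = as.integer(replicates),
                 presentations = presentations,
                 wl_lo = wl_lo, wl_hi = wl_hi, wl_step = wl_step,
                 mult_sd = mult_sd, add_sd = add_sd, tilt_sd = tilt_sd,
                 noise_sd = noise_sd,
                 bunch_scatter_factor = bunch_scatter_factor,
                 nonlinearity = nonlinearity, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Small fast-test variant of the synthetic study
#'
#' @param n_per_season samples per season (default 10 in each of 3 seasons).
#' @param seed root seed.
#' @param ... overrides passed to [synthetic_config()].
#' @return a `SyntheticConfig`.
#' @export
fixture_config <- function(n_per_season = c(10, 10, 10), seed = 1, ...) {
  synthetic_config(n_per_season = n_per_season, n_varieties = 6,
                   replicates = 3, seed = seed, ...)
}

# analyte ranges enforced on generated chemistry (calibration-set ranges of
# a three-season grape ripening campaign)
analyte_ranges <- list(
  ssc_brix = c(10.60, 58.60),
  reducing_sugar_gL = c(81.50, 586.40),
  ph = c(2.48, 4.60),
  titratable_acidity_gL = c(0.20, 20.50),
  tartaric_gL = c(4.90, 18.60),
  malic_gL = c(0.10, 14.50),
  potassium_mgL = c(841.00, 2737.00))

#' Stylized Vis-NIR absorption band library
#'
#' Gaussian absorption bands per analyte plus water and pigment background
#' bands. Centers and widths are plausible for O-H/C-H overtone chemistry
#' (water at ~970/1190/1450 nm, sugar bands in the 900-1450 nm region,
#' visible pigment bands for red varieties) but are stylized: the generator
#' exists to exercise calibration algorithms, not to reproduce vibrational
#' assignments.
#'
#' @return a `BandLibrary`: list with `analytes` (per-analyte data.frame of
#'   center nm, width nm, absorptivity per concentration unit), `water`,
#'   `pigment_red`, `chlorophyll`.
#' @export
band_library <- function() {
  bl <- list(
    analytes = list(
      ssc_brix = data.frame(center = c(910, 1430), width = c(28, 35),
                            absorptivity = c(6.0e-3, 4.5e-3)),
      reducing_sugar_gL = data.frame(center = c(984, 1580),
                                     width = c(30, 40),
                                     absorptivity = c(6.4e-4, 4.4e-4)),
      ph = data.frame(center = 1140, width = 32, absorptivity = 7.0e-2),
      titratable_acidity_gL = data.frame(center = 1245, width = 28,
                                         absorptivity = 1.2e-2),
      tartaric_gL = data.frame(center = 1330, width = 26,
                               absorptivity = 1.2e-2),
      malic_gL = data.frame(center = 1540, width = 30,
                            absorptivity = 1.2e-2),
      potassium_mgL = data.frame(center = 1615, width = 35,
                                 absorptivity = 1.0e-4)),
    water = data.frame(center = c(970, 1190, 1450),
                       width = c(45, 55, 50),
                       amplitude = c(0.18, 0.25, 0.75)),
    pigment_red = data.frame(center = c(530, 640), width = c(45, 35),
                             amplitude = c(0.50, 0.20)),
    chlorophyll = data.frame(center = 678, width = 25, amplitude = 0.30))
  for (a in names(bl$analytes)) {
    rng <- range(c(bl$analytes[[a]]$center, 380, 1700))
    stopifnot(rng[1] >= 380, rng[2] <= 1700)
  }
  class(bl) <- "BandLibrary"
  bl
}

gaussian_bands <- function(wl, centers, widths, amplitudes) {
  out <- numeric(length(wl))
  for (i in seq_along(centers))
    out <- out + amplitudes[i] * exp(-0.5 * ((wl - centers[i]) / widths[i])^2)
  out
}

#' Generate synthetic grape reference chemistry
#'
#' Each sample receives a latent ripeness in (0, 1) uniform within its
#' season; analytes follow ripening trajectories — soluble solids, reducing
#' sugars and pH increase with ripeness while titratable acidity, tartaric
#' and malic acid decrease (malic quadratically, as it is metabolized), and
#' potassium rises weakly, coupled to acidity. Reducing sugars track
#' soluble solids at about 9.7 g/L per degree Brix, the ratio of their
#' calibration-set means. All values are clipped to the calibration ranges
#' of a multi-season ripening campaign.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `reference` (a [reference_table()]), `meta` (sample_id,
#'   variety, variety_class, season, date, ripeness).
#' @export
generate_chemistry <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  n_tot <- sum(cfg$n_per_season)
  with_seed(cfg$seed, {
    season <- rep(cfg$seasons, cfg$n_per_season)
    sample_id <- sprintf("S%s_%03d", season,
                         unlist(lapply(cfg$n_per_season, seq_len)))
    variety <- paste0("V", 1 + (seq_len(n_tot) - 1) %% cfg$n_varieties)
    variety_class <- ifelse(as.integer(sub("V", "", variety)) %%
                              2 == 0, "white", "red")
    ripeness <- stats::runif(n_tot)
    seas_shift <- stats::rnorm(length(cfg$seasons), 0, 0.3)[match(season, cfg$seasons)]
    clip <- function(v, a) pmin(pmax(v, analyte_ranges[[a]][1]),
                                analyte_ranges[[a]][2])
    ssc <- clip(11 + 16 * ripeness + seas_shift + stats::rnorm(n_tot, 0, 1.5),
                "ssc_brix")
    rsug <- clip(9.7 * ssc + stats::rnorm(n_tot, 0, 8), "reducing_sugar_gL")
    ph <- clip(2.8 + 1.05 * ripeness + stats::rnorm(n_tot, 0, 0.1), "ph")
    tita <- clip(12.5 - 10.5 * ripeness + stats::rnorm(n_tot, 0, 1.2),
                 "titratable_acidity_gL")
    tart <- clip(12.8 - 6.2 * ripeness + stats::rnorm(n_tot, 0, 1.1),
                 "tartaric_gL")
    malic <- clip(9.5 * (1 - ripeness)^2 + stats::rnorm(n_tot, 0, 0.7),
                  "malic_gL")
    pot <- clip(1050 + 950 * ripeness + 25 * tita +
                  stats::rnorm(n_tot, 0, 220), "potassium_mgL")
    date <- sprintf("%s-%02d-%02d", season,
                    7 + floor(ripeness * 2.99), 1 + floor(stats::runif(n_tot) * 28))
    ref <- reference_table(data.frame(
      sample_id = sample_id, ssc_brix = ssc, reducing_sugar_gL = rsug,
      ph = ph, titratable_acidity_gL = tita, tartaric_gL = tart,
      malic_gL = malic, potassium_mgL = pot, stringsAsFactors = FALSE))
    meta <- data.frame(sample_id = sample_id, variety = variety,
                       variety_class = variety_class, season = season,
                       date = date, ripeness = ripeness,
                       stringsAsFactors = FALSE)
    list(reference = ref, meta = meta)
  })
}

#' Generate replicated Vis-NIR spectra for a reference table
#'
#' Clean spectra are additive mixtures: a smooth sloping baseline, water
#' and pigment background bands (pigment amplitude scales with unripeness
#' and variety class), plus one Gaussian band set per analyte weighted by
#' its concentration. Two mild regime-dependent effects then distort the
#' linear mixture: a path-length factor
#' `1 + nonlinearity * tanh((SSC - 20) / 8)` that multiplies only the NIR
#' side of the spectrum (smooth onset around 950 nm, as water-dominated
#' tissue scattering changes with sugar loading), and a sugar band-center
#' shift proportional to the same saturating ripeness term. Both survive
#' scatter correction, so a single global linear model carries
#' regime-dependent bias that memory-based local calibration can remove.
#' Each replicate adds multiplicative scatter, an additive baseline offset,
#' a linear tilt, and white noise; bunch presentation carries more scatter
#' variance than must.
#'
#' @param ref a [reference_table()].
#' @param meta sample metadata from [generate_chemistry()].
#' @param bands a [band_library()].
#' @param cfg a [synthetic_config()].
#' @return a replicated `SpectraSet` (one row per sample x presentation x
#'   replicate).
#' @export
generate_spectra <- function(ref, meta, bands = band_library(), cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"), inherits(bands, "BandLibrary"))
  wl <- seq(cfg$wl_lo, cfg$wl_hi, by = cfg$wl_step)
  missing_analytes <- setdiff(setdiff(names(ref), "sample_id"),
                              names(bands$analytes))
  if (length(missing_analytes))
    stop("analyte(s) missing from band library: ",
         paste(missing_analytes, collapse = ", "))
  n <- nrow(ref)
  baseline <- 0.45 + 2.0e-4 * (wl - cfg$wl_lo)
  water <- gaussian_bands(wl, bands$water$center, bands$water$width,
                          bands$water$amplitude)

  nir_onset <- 1 / (1 + exp(-(wl - 950) / 60))   # smooth Vis -> NIR ramp
  clean <- matrix(0.0, n, length(wl))
  for (i in seq_len(n)) {
    sp <- baseline + water
    unripe <- 1 - meta$ripeness[i]
    sp <- sp + unripe * gaussian_bands(wl, bands$chlorophyll$center,
                                       bands$chlorophyll$width,
                                       bands$chlorophyll$amplitude)
    if (meta$variety_class[i] == "red")
      sp <- sp + (0.4 + 0.6 * meta$ripeness[i]) *
        gaussian_bands(wl, bands$pigment_red$center, bands$pigment_red$width,
                       bands$pigment_red$amplitude)
    regime <- tanh((ref$ssc_brix[i] - 20) / 8)   # saturating ripeness term
    for (a in names(bands$analytes)) {
      conc <- ref[[a]][i]
      if (is.null(conc) || is.na(conc)) next
      bb <- bands$analytes[[a]]
      centers <- bb$center
      if (a == "ssc_brix")   # sugar bands drift with the matrix regime
        centers <- centers + cfg$nonlinearity * 20 * regime
      sp <- sp + conc * gaussian_bands(wl, centers, bb$width,
                                       bb$absorptivity)
    }
    path <- 1 + cfg$nonlinearity * regime * nir_onset
    clean[i, ] <- sp * path
  }

  modes <- cfg$presentations
  reps <- cfg$replicates
  total <- n * length(modes) * reps
  x <- matrix(0.0, total, length(wl))
  meta_rows <- vector("list", total)
  tilt <- (wl - mean(wl)) / diff(range(wl))
  row <- 0L
  with_seed(cfg$seed + 1L, {
    for (i in seq_len(n)) {
      for (mode in modes) {
        f <- if (mode == "bunch") cfg$bunch_scatter_factor else 1
        for (r in seq_len(reps)) {
          row <- row + 1L
          g <- 1 + stats::rnorm(1, 0, cfg$mult_sd * f)
          off <- stats::rnorm(1, 0, cfg$add_sd * f)
          tl <- stats::rnorm(1, 0, cfg$tilt_sd * f)
          x[row, ] <- clean[i, ] * g + off + tl * tilt +
            stats::rnorm(length(wl), 0, cfg$noise_sd)
          meta_rows[[row]] <- data.frame(
            sample_id = meta$sample_id[i], replicate = r,
            variety = meta$variety[i], season = meta$season[i],
            date = meta$date[i], presentation = mode,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  spectra_set(x, wl, do.call(rbind, meta_rows))
}

#' Generate a full synthetic study on disk
#'
#' Writes the spectra CSV, the reference CSV and a JSON manifest recording
#' every generator parameter and the seed, so a study can be regenerated
#' byte-identically. The default configuration emits a three-season study
#' (363 samples); [fixture_config()] emits a small variant for fast tests.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return list with the file paths (`spectra`, `reference`, `manifest`) and
#'   the in-memory objects (`spectra_set`, `reference_table`, `meta`).
#' @export
generate_study <- function(cfg = synthetic_config(), out_dir) {
  chem <- generate_chemistry(cfg)
  sp <- generate_spectra(chem$reference, chem$meta, band_library(), cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  spectra_path <- file.path(out_dir, "spectra.csv")
  reference_path <- file.path(out_dir, "reference.csv")
  manifest_path <- file.path(out_dir, "manifest.json")
  write_spectra_csv(sp, spectra_path)
  write_reference_csv(chem$reference, reference_path)
  jsonlite::write_json(unclass(cfg), manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(spectra = spectra_path, reference = reference_path,
       manifest = manifest_path, spectra_set = sp,
       reference_table = chem$reference, meta = chem$meta)
}
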