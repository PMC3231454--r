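# Shared fixtures, built in code and memoized for the test session.

.gn_cache <- new.env(parent = emptyenv())

gn_memo <- function(key, expr) {
  if (!exists(key, envir = .gn_cache)) assign(key, expr, envir = .gn_cache)
  get(key, envir = .gn_cache)
}

# a tiny deterministic SpectraSet: n spectra on a p-point 2 nm grid
gn_tiny_set <- function(n = 4, p = 24, seed = 42, presentation = "bunch") {
  x <- with_test_seed(seed, matrix(rnorm(n * p, mean = 1), n, p))
  spectra_set(x, seq(380, by = 2, length.out = p),
              data.frame(sample_id = sprintf("T%02d", seq_len(n)),
                         replicate = 1L, variety = "V1", season = 2008,
                         date = "2008-08-01", presentation = presentation))
}

with_test_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# the full-size synthetic study (bunch only), averaged and pretreated with
# the reference treatment; memoized per nonlinearity setting
gn_study <- function(nonlinearity = 0.15, seed = 1) {
  gn_memo(sprintf("study_%s_%d", format(nonlinearity), seed), {
    cfg <- synthetic_config(seed = seed, presentations = "bunch",
                            nonlinearity = nonlinearity)
    chem <- generate_chemistry(cfg)
    sp <- generate_spectra(chem$reference, chem$meta, band_library(), cfg)
    avg <- average_replicates(sp)
    pre <- apply_pretreatment(avg, pretreatment_spec("snv_detrend", "2,5,5,1",
                                                     c(380, 1650)))
    y <- function(analyte)
      chem$reference[[analyte]][match(avg$meta$sample_id,
                                      chem$reference$sample_id)]
    list(cfg = cfg, chem = chem, avg = avg, pre = pre, y = y)
  })
}

# CENTER split of the 2008 season of the default study
gn_split <- function(nonlinearity = 0.15) {
  gn_memo(sprintf("split_%s", format(nonlinearity)), {
    st <- gn_study(nonlinearity)
    s08 <- subset_rows(st$pre, st$pre$meta$season == 2008)
    cm <- fit_center(s08)
    list(split = split_by_center(s08, cm, 0.27), center = cm, s08 = s08)
  })
}

# the main 21-cell LOCAL optimization grid for soluble solids on the
# nonlinear study, plus the matched global model statistics
gn_local_ssc <- function() {
  gn_memo("local_ssc", {
    st <- gn_study(0.15)
    sp <- gn_split(0.15)
    y <- st$y("ssc_brix")
    is_val <- st$pre$meta$sample_id %in% sp$split$validation_ids
    cv <- cross_validate(st$pre$x[!is_val, , drop = FALSE], y[!is_val],
                         max_factors = 16, n_groups = 4, seed = 3,
                         mode = "mpls")
    pv <- predict_pls(cv$model, st$pre$x[is_val, , drop = FALSE],
                      cv$chosen_factors)
    global <- eval_stats(y[is_val], pv, "prediction",
                         sd_ref = sd(y[!is_val]))
    og <- optimize_local_grid(subset_rows(st$pre, !is_val), y[!is_val],
                              subset_rows(st$pre, is_val), y[is_val],
                              k_grid = c(25, 50, 75, 100, 110, 125, 150),
                              l_grid = 14:16)
    list(cv = cv, global = global, grid = og, is_val = is_val, y = y)
  })
}

# a small on-disk fixture study, memoized per session temp dir
gn_fixture_paths <- function(seed = 7) {
  gn_memo(sprintf("fixture_%d", seed), {
    dir <- file.path(tempdir(), sprintf("gn_fixture_%d", seed))
    generate_study(fixture_config(seed = seed), dir)
  })
}
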