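#' Construct a SpectraSet
#'
#' A `SpectraSet` couples an absorbance matrix (samples in rows, wavelengths
#' in columns, values on the log(1/R) scale) with the shared wavelength grid
#' and per-row metadata. It is the object every stage of the workflow
#' transforms: replicate averaging, window slicing, scatter correction,
#' derivatives, and calibration all take and return a `SpectraSet`.
#'
#' @param x numeric matrix, `n_samples x n_wavelengths`, no missing values.
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing; its length must equal `ncol(x)`. A uniform step is required
#'   (2 nm for the default instrument grid) unless `check_step = FALSE`,
#'   which derivative-pretreated sets use because truncation breaks grid
#'   uniformity at removed edges only, never in the interior.
#' @param meta data.frame with one row per spectrum. Must contain a
#'   `sample_id` column; `replicate`, `variety`, `season`, `date` and
#'   `presentation` (`"bunch"` or `"must"`) are carried when present.
#' @param check_step logical; enforce a constant wavelength step.
#'
#' @return An object of class `SpectraSet`: a list with elements `x`,
#'   `wavelengths`, `meta`.
#' @export
spectra_set <- function(x, wavelengths, meta, check_step = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (ncol(x) != length(wavelengths))
    stop("ncol(x) must equal length(wavelengths)")
  if (anyNA(x)) stop("spectral matrix contains missing values")
  if (length(wavelengths) > 1) {
    d <- diff(wavelengths)
    if (any(d <= 0)) stop("wavelengths must be strictly increasing")
    if (check_step && diff(range(d)) > 1e-8)
      stop("non-uniform wavelength grid (constant step required)")
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != nrow(x))
    stop("meta must have one row per spectrum")
  if (is.null(meta$sample_id)) stop("meta must contain a sample_id column")
  meta$sample_id <- as.character(meta$sample_id)
  if (!is.null(meta$presentation)) {
    bad <- setdiff(unique(meta$presentation), c("bunch", "must"))
    if (length(bad))
      stop("unknown presentation mode(s): ", paste(bad, collapse = ", "))
  }
  dimnames(x) <- NULL
  structure(list(x = x, wavelengths = wavelengths, meta = meta),
            class = "SpectraSet")
}

#' @export
print.SpectraSet <- function(x, ...) {
  cat(sprintf("SpectraSet: %d spectra x %d wavelengths (%.0f-%.0f nm)\n",
              nrow(x$x), ncol(x$x), min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$meta$presentation))
    cat("  presentation:", paste(names(table(x$meta$presentation)),
                                 table(x$meta$presentation),
                                 sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.SpectraSet <- function(x) dim(x$x)

#' Number of spectra in a SpectraSet
#' @param s a `SpectraSet`.
#' @return integer count of rows.
#' @export
n_spectra <- function(s) nrow(s$x)

analyte_columns <- c("ssc_brix", "reducing_sugar_gL", "ph",
                     "titratable_acidity_gL", "tartaric_gL", "malic_gL",
                     "potassium_mgL")

#' Validate a reference-chemistry table
#'
#' The reference table holds one row per `sample_id` with wet-chemistry
#' values: soluble solids (`ssc_brix`, degrees Brix), reducing sugars
#' (`reducing_sugar_gL`), pH (`ph`), titratable acidity as tartaric-acid
#' equivalents (`titratable_acidity_gL`), tartaric and malic acid (g/L) and
#' optionally potassium (`potassium_mgL`). Values must be finite and
#' nonnegative; pH must lie in `[0, 14]`. Missing (NA) cells are allowed and
#' simply exclude the sample from models of that analyte.
#'
#' @param ref data.frame with a `sample_id` column and analyte columns.
#' @return the validated data.frame, with `sample_id` as character.
#' @export
reference_table <- function(ref) {
  ref <- as.data.frame(ref, stringsAsFactors = FALSE)
  if (is.null(ref$sample_id)) stop("reference table needs a sample_id column")
  ref$sample_id <- as.character(ref$sample_id)
  if (anyDuplicated(ref$sample_id))
    stop("duplicate sample_id in reference table")
  for (col in intersect(analyte_columns, names(ref))) {
    v <- ref[[col]]
    if (!is.numeric(v)) stop("reference column ", col, " must be numeric")
    ok <- is.na(v) | (is.finite(v) & v >= 0)
    if (col == "ph") ok <- ok & (is.na(v) | v <= 14)
    if (!all(ok)) stop("invalid values in reference column ", col)
  }
  ref
}

#' Load a spectra CSV and a reference-chemistry CSV
#'
#' The spectra file has header
#' `sample_id,replicate,variety,season,date,presentation,<wl1>,<wl2>,...`
#' with wavelength column names in nm and one row per replicate spectrum.
#' The reference file has header
#' `sample_id,ssc_brix,reducing_sugar_gL,ph,titratable_acidity_gL,tartaric_gL,malic_gL,potassium_mgL`
#' with empty cells read as missing.
#'
#' Samples present in the spectra file but absent from the reference file are
#' dropped with a warning and reported in the `excluded` element.
#'
#' @param spectra_path path to the spectra CSV.
#' @param reference_path path to the reference CSV.
#' @return list with elements `spectra` (a [spectra_set()]), `reference`
#'   (a [reference_table()]) and `excluded` (character vector of sample ids
#'   lacking reference chemistry).
#' @export
load_dataset <- function(spectra_path, reference_path) {
  if (!file.exists(spectra_path)) stop("spectra file not found: ", spectra_path)
  if (!file.exists(reference_path)) stop("reference file not found: ", reference_path)
  raw <- utils::read.csv(spectra_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  meta_cols <- c("sample_id", "replicate", "variety", "season", "date",
                 "presentation")
  meta_cols <- intersect(meta_cols, names(raw))
  wl_cols <- setdiff(names(raw), meta_cols)
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl))
    stop("non-numeric wavelength column header(s): ",
         paste(wl_cols[is.na(wl)][1:min(3, sum(is.na(wl)))], collapse = ", "))
  o <- order(wl)
  s <- spectra_set(as.matrix(raw[, wl_cols[o], drop = FALSE]), wl[o],
                   raw[, meta_cols, drop = FALSE])
  ref <- reference_table(utils::read.csv(reference_path,
                                         stringsAsFactors = FALSE))
  excluded <- setdiff(unique(s$meta$sample_id), ref$sample_id)
  if (length(excluded)) {
    warning(length(excluded),
            " sample(s) in spectra have no reference chemistry; excluded")
    keep <- !(s$meta$sample_id %in% excluded)
    s <- spectra_set(s$x[keep, , drop = FALSE], s$wavelengths,
                     s$meta[keep, , drop = FALSE])
  }
  list(spectra = s, reference = ref, excluded = excluded)
}

#' Write a SpectraSet to the spectra CSV dialect
#'
#' Inverse of the spectra half of [load_dataset()]. Values are written with
#' 12 significant digits so a write/read round trip is lossless at working
#' precision.
#'
#' @param s a `SpectraSet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(s, path) {
  out <- cbind(s$meta, as.data.frame(s$x))
  names(out) <- c(names(s$meta), format(s$wavelengths, trim = TRUE,
                                        scientific = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  num <- vapply(out, is.numeric, logical(1)) &
    names(out) %in% format(s$wavelengths, trim = TRUE, scientific = FALSE)
  body <- do.call(paste, c(lapply(seq_along(out), function(j) {
    if (num[j]) formatC(out[[j]], digits = 12, format = "g")
    else as.character(out[[j]])
  }), sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Write a reference table to the reference CSV dialect
#'
#' @param ref a [reference_table()] data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference_csv <- function(ref, path) {
  cols <- c("sample_id", analyte_columns)
  for (m in setdiff(cols, names(ref))) ref[[m]] <- NA_real_
  utils::write.csv(ref[, cols], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Average replicate spectra
#'
#' Field protocols capture several spectra per sample (eight in the
#' reference workflow) and use their arithmetic mean in all calculations.
#' Rows are grouped by `sample_id` and, when present, `presentation`; the
#' per-wavelength mean of each group becomes one output row.
#'
#' @param s a `SpectraSet` with replicate rows.
#' @return a `SpectraSet` with one row per (sample_id, presentation) group.
#'   Metadata are collapsed (replicate column replaced by `n_replicates`);
#'   conflicting metadata within a group is an error.
#' @export
average_replicates <- function(s) {
  key <- s$meta$sample_id
  if (!is.null(s$meta$presentation))
    key <- paste(key, s$meta$presentation, sep = "\r")
  groups <- split(seq_along(key), key)
  # stable order: first appearance
  groups <- groups[order(vapply(groups, min, integer(1)))]
  const_cols <- intersect(c("sample_id", "variety", "season", "date",
                            "presentation"), names(s$meta))
  meta_rows <- lapply(groups, function(idx) {
    m <- s$meta[idx, const_cols, drop = FALSE]
    for (cc in const_cols) {
      if (length(unique(m[[cc]])) > 1)
        stop("conflicting metadata within sample group '",
             s$meta$sample_id[idx[1]], "' (column ", cc, ")")
    }
    out <- m[1, , drop = FALSE]
    out$n_replicates <- length(idx)
    out
  })
  xbar <- t(vapply(groups,
                   function(idx) colMeans(s$x[idx, , drop = FALSE]),
                   numeric(ncol(s$x))))
  spectra_set(xbar, s$wavelengths, do.call(rbind, meta_rows),
              check_step = FALSE)
}

#' Restrict a SpectraSet to a wavelength window
#'
#' Keeps wavelengths `w` with `lo <= w <= hi` (closed interval; on-grid
#' endpoints are retained). The noisy long-wavelength end of the instrument
#' range is conventionally discarded this way (e.g. keeping 380-1650 nm of a
#' 380-1700 nm acquisition).
#'
#' @param s a `SpectraSet`.
#' @param lo,hi window bounds in nm, `lo < hi`.
#' @return the sliced `SpectraSet`; metadata unchanged.
#' @export
slice_range <- function(s, lo, hi) {
  if (lo >= hi) stop("lo must be < hi")
  keep <- s$wavelengths >= lo & s$wavelengths <= hi
  if (!any(keep)) stop("window [", lo, ", ", hi, "] does not intersect grid")
  spectra_set(s$x[, keep, drop = FALSE], s$wavelengths[keep], s$meta,
              check_step = FALSE)
}

#' Subset spectra rows
#'
#' @param s a `SpectraSet`.
#' @param idx integer or logical row index.
#' @return the row-subset `SpectraSet`.
#' @export
subset_rows <- function(s, idx) {
  spectra_set(s$x[idx, , drop = FALSE], s$wavelengths,
              s$meta[idx, , drop = FALSE], check_step = FALSE)
}
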