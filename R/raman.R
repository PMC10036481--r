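#' Baseline-normalized 750 cm^-1 band intensity
#'
#' The cytochrome band intensity at 750 cm^-1, normalized by subtracting the
#' median of the local baseline sampled from 735-740 and 760-765 cm^-1. The
#' intensity at 750 is read at the nearest grid point; if that point is more
#' than 1 cm^-1 away, linear interpolation is used. The result is invariant
#' to additive offsets and scales linearly with multiplicative ones.
#'
#' @param spectrum A [raman_spectrum()] covering at least 735-765 cm^-1.
#' @return Normalized band intensity (a.u.).
#' @export
band_intensity_750 <- function(spectrum) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  wn <- spectrum$wavenumber
  it <- spectrum$intensity
  base_idx <- which((wn >= 735 & wn <= 740) | (wn >= 760 & wn <= 765))
  if (!any(wn >= 735 & wn <= 740) || !any(wn >= 760 & wn <= 765))
    stop("spectrum does not cover both baseline windows (735-740, 760-765)",
         call. = FALSE)
  nearest <- which.min(abs(wn - 750))
  i750 <- if (abs(wn[nearest] - 750) > 1)
    approx(wn, it, xout = 750)$y else it[nearest]
  i750 - median(it[base_idx])
}

#' Quality control of a paired spectrum
#'
#' Paired spectra are kept only if they are similar within the pair, with no
#' major shift in the C-H stretching region: after per-spectrum median
#' centering, the Pearson correlation of the two spectra over `region` must
#' reach `min_correlation`.
#'
#' @param pair A [spectrum_pair()].
#' @param region C-H region bounds in cm^-1 (default 2800-3000).
#' @param min_correlation Pass threshold (default 0.9).
#' @return A list of class `qc_result`: `pass`, `correlation`,
#'   `zero_variance`.
#' @export
pair_qc <- function(pair, region = c(2800, 3000), min_correlation = 0.9) {
  stopifnot(inherits(pair, "spectrum_pair"))
  wn <- pair$near$wavenumber
  sel <- wn >= region[1] & wn <= region[2]
  if (sum(sel) < 3)
    stop("spectra do not cover the C-H region", call. = FALSE)
  a <- pair$near$intensity[sel]
  b <- pair$far$intensity[sel]
  a <- a - median(a)
  b <- b - median(b)
  if (sd(a) == 0 || sd(b) == 0)
    return(structure(list(pass = FALSE, correlation = NA_real_,
                          zero_variance = TRUE), class = "qc_result"))
  r <- cor(a, b)
  structure(list(pass = r >= min_correlation, correlation = r,
                 zero_variance = FALSE), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("pair QC: %s (C-H correlation %.4f)\n",
              if (x$pass) "pass" else "FAIL", x$correlation))
  invisible(x)
}

#' Paired test of the cytochrome redox shift
#'
#' For each QC-passing pair the difference `d = band_750(near) -
#' band_750(far)` is computed and a two-sided paired Student t-test is run on
#' the differences. High 750 cm^-1 band values indicate reduced cytochromes,
#' so a negative mean difference means cells are more oxidized next to the
#' filament.
#'
#' @param pairs A list of [spectrum_pair()] objects.
#' @param qc Apply [pair_qc()] and drop failing pairs first (default `TRUE`).
#' @param ... Passed to [pair_qc()].
#' @return A `flock_test` with extra fields `differences` and `n_excluded`.
#' @export
redox_shift_test <- function(pairs, qc = TRUE, ...) {
  if (inherits(pairs, "spectrum_pair")) pairs <- list(pairs)
  n0 <- length(pairs)
  if (qc) {
    keep <- vapply(pairs, function(p) pair_qc(p, ...)$pass, logical(1))
    pairs <- pairs[keep]
  }
  if (length(pairs) < 2)
    stop("need at least 2 QC-passing pairs", call. = FALSE)
  d <- vapply(pairs, function(p)
    band_intensity_750(p$near) - band_intensity_750(p$far), numeric(1))
  if (sd(d) == 0) {
    equal <- all(d == 0)
    return(new_test_result(if (equal) 0 else Inf * sign(mean(d)),
                           length(d) - 1, if (equal) 1 else 0,
                           c(mean_difference = mean(d)), length(d),
                           "paired t-test (two-sided)",
                           extra = list(differences = d,
                                        n_excluded = n0 - length(d))))
  }
  tt <- t.test(d)
  new_test_result(tt$statistic, tt$parameter, tt$p.value,
                  c(mean_difference = mean(d)), length(d),
                  "paired t-test (two-sided)",
                  extra = list(differences = d, n_excluded = n0 - length(d)))
}

#' Read / write two-column spectrum files
#'
#' Plain-text spectra: two whitespace- or comma-delimited columns
#' (wavenumber in cm^-1, intensity in a.u.), optionally with a header line.
#'
#' @param path File path.
#' @param label,cell_id Metadata attached on read.
#' @return `read_spectrum()` returns a [raman_spectrum()].
#' @export
read_spectrum <- function(path, label = "near", cell_id = NA_character_) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\s*[-0-9.eE+]+[,\\s]", first)
  df <- utils::read.table(path, header = has_header,
                          sep = if (grepl(",", first)) "," else "")
  raman_spectrum(df[[1]], df[[2]], label = label, cell_id = cell_id)
}

#' @rdname read_spectrum
#' @param spectrum A [raman_spectrum()] to write.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  utils::write.table(
    data.frame(wavenumber_cm1 = spectrum$wavenumber,
               intensity = spectrum$intensity),
    path, row.names = FALSE, quote = FALSE, sep = " ")
  invisible(path)
}
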