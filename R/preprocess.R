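#' Scatter-removal band parameters
#'
#' Band definitions for excising first- and second-order Rayleigh scattering
#' and the solvent Raman band from an EEM. Widths are TOTAL band widths in
#' nm: a cell is flagged when its emission wavelength lies within +/- width/2
#' of the band centre. The defaults are the study settings: 35 nm for
#' first-order Rayleigh, 5 nm for Raman, 5 nm for second-order Rayleigh.
#'
#' The Raman band centre for excitation wavelength `lx` (nm) and Raman shift
#' `s` (cm^-1) is `1 / (1/lx - s * 1e-7)` nm; the default shift 3382 cm^-1 is
#' the water OH stretch.
#'
#' @param rayleigh1_width Total width (nm) of the first-order Rayleigh band.
#' @param raman_width Total width (nm) of the Raman band.
#' @param rayleigh2_width Total width (nm) of the second-order Rayleigh band.
#' @param raman_shift Solvent Raman shift in cm^-1.
#' @param below_rayleigh_policy `"zero"` (default) fills flagged runs that
#'   touch the emission-axis boundary with 0; `"interpolate"` extends the
#'   nearest unflagged value instead.
#' @return An object of class `scatter_params`.
#' @export
scatter_params <- function(rayleigh1_width = 35, raman_width = 5,
                           rayleigh2_width = 5, raman_shift = 3382,
                           below_rayleigh_policy = c("zero", "interpolate")) {
  below_rayleigh_policy <- match.arg(below_rayleigh_policy)
  if (rayleigh1_width <= 0 || raman_width <= 0 || rayleigh2_width <= 0)
    stop("scatter_params: band widths must be positive", call. = FALSE)
  if (raman_shift <= 0)
    stop("scatter_params: raman_shift must be positive", call. = FALSE)
  structure(list(rayleigh1_width = rayleigh1_width,
                 raman_width = raman_width,
                 rayleigh2_width = rayleigh2_width,
                 raman_shift = raman_shift,
                 below_rayleigh_policy = below_rayleigh_policy),
            class = "scatter_params")
}

#' Raman band centre for a given excitation wavelength
#'
#' @param ex Excitation wavelength(s) in nm.
#' @param raman_shift Raman shift in cm^-1 (default 3382, water OH stretch).
#' @return Emission wavelength(s) of the Raman band centre, in nm.
#' @export
raman_emission <- function(ex, raman_shift = 3382) {
  1 / (1 / ex - raman_shift * 1e-7)
}

#' Average a set of blank EEMs
#'
#' Cell-wise arithmetic mean of blank-sample EEMs measured on one grid; the
#' result is subtracted from every sample by [subtract_blank()].
#'
#' @param blanks Non-empty list of [eem_sample()] on identical grids.
#' @return An [eem_sample()] with `sample_id = "blank-average"` and
#'   `role = "blank"`.
#' @export
average_blanks <- function(blanks) {
  if (!is.list(blanks) || length(blanks) == 0L)
    stop("average_blanks: need at least one blank", call. = FALSE)
  ref <- blanks[[1L]]
  acc <- matrix(0, nrow(ref$intensity), ncol(ref$intensity))
  for (b in blanks) {
    if (!grids_identical(b$grid, ref$grid))
      stop(sprintf("average_blanks: grid mismatch for blank '%s'", b$sample_id),
           call. = FALSE)
    acc <- acc + b$intensity
  }
  eem_sample(acc / length(blanks), ref$grid, sample_id = "blank-average",
             role = "blank")
}

#' Subtract a blank EEM from a sample
#'
#' Cell-wise difference; negative residuals are retained (use
#' [clip_negative()] to zero them if desired).
#'
#' @param sample,blank [eem_sample()] objects on identical grids.
#' @return The background-corrected [eem_sample()].
#' @export
subtract_blank <- function(sample, blank) {
  if (!grids_identical(sample$grid, blank$grid))
    stop("subtract_blank: sample and blank grids differ", call. = FALSE)
  out <- sample
  out$intensity <- sample$intensity - blank$intensity
  out
}

#' Build the boolean scatter mask for a grid
#'
#' Flags cell (j, k) when its emission wavelength falls inside any of the
#' three bands of [scatter_params()]: first-order Rayleigh
#' (`|em - ex| <= rayleigh1_width/2`), second-order Rayleigh
#' (`|em - 2*ex| <= rayleigh2_width/2`), or the Raman band
#' (`|em - raman_emission(ex)| <= raman_width/2`).
#'
#' @param grid A [wavelength_grid()].
#' @param params A [scatter_params()].
#' @return Logical matrix (emission x excitation), class `scatter_mask`.
#' @export
build_scatter_mask <- function(grid, params = scatter_params()) {
  stopifnot(inherits(grid, "wavelength_grid"), inherits(params, "scatter_params"))
  em <- grid$emission
  ex <- grid$excitation
  ray1 <- outer(em, ex, function(m, x) abs(m - x) <= params$rayleigh1_width / 2)
  ray2 <- outer(em, ex, function(m, x) abs(m - 2 * x) <= params$rayleigh2_width / 2)
  ram <- outer(em, ex, function(m, x)
    abs(m - raman_emission(x, params$raman_shift)) <= params$raman_width / 2)
  structure(ray1 | ray2 | ram, class = c("scatter_mask", "matrix"))
}

#' Interpolate over flagged scatter cells
#'
#' For each excitation column, every contiguous run of flagged emission cells
#' is replaced by a natural cubic spline fitted to the unflagged cells of the
#' same column. Runs touching the emission-axis boundaries cannot be bridged
#' from both sides: a run at the short-wavelength end lies at or below the
#' first-order Rayleigh line (the anti-Stokes region, which carries no
#' fluorescence signal) and is filled according to
#' `params$below_rayleigh_policy` -- `"zero"` (default) sets it to 0,
#' `"interpolate"` extends the nearest unflagged value; a run at the
#' long-wavelength end is filled by extending the nearest unflagged value.
#' Unflagged cells are never altered.
#'
#' @param sample An [eem_sample()].
#' @param mask A mask from [build_scatter_mask()] aligned to the sample grid.
#' @param params The [scatter_params()] used to build the mask.
#' @return The scatter-corrected [eem_sample()].
#' @export
remove_scatter <- function(sample, mask, params = scatter_params()) {
  stopifnot(inherits(sample, "eem_sample"))
  if (!all(dim(mask) == dim(sample$intensity)))
    stop("remove_scatter: mask shape does not match sample", call. = FALSE)
  em <- sample$grid$emission
  out <- sample$intensity
  J <- length(em)
  for (k in seq_len(ncol(out))) {
    flagged <- mask[, k]
    if (!any(flagged)) next
    if (all(flagged))
      stop(sprintf("remove_scatter: excitation column %d is entirely flagged", k),
           call. = FALSE)
    good <- which(!flagged)
    runs <- split(which(flagged), cumsum(c(1, diff(which(flagged)) != 1)))
    sf <- NULL
    for (run in runs) {
      if (run[1L] == 1L) {
        out[run, k] <- if (params$below_rayleigh_policy == "zero") 0 else
          out[min(good), k]
      } else if (run[length(run)] == J) {
        out[run, k] <- out[max(good), k]
      } else {
        if (is.null(sf))
          sf <- stats::splinefun(em[good], sample$intensity[good, k],
                                 method = "natural")
        out[run, k] <- sf(em[run])
      }
    }
  }
  res <- sample
  res$intensity <- out
  res
}

#' Zero out negative intensities
#'
#' Optional final step: fluorescence intensity is physically nonnegative, so
#' negative residuals left by blank subtraction or interpolation can be
#' clipped to 0.
#'
#' @param sample An [eem_sample()].
#' @return The clipped [eem_sample()].
#' @export
clip_negative <- function(sample) {
  sample$intensity[sample$intensity < 0] <- 0
  sample
}

#' Full preprocessing pipeline
#'
#' Applies, in order: crop to the fingerprint region, blank averaging and
#' subtraction, scatter masking and interpolation, and (optionally) negative
#' clipping. Blanks are cropped with the samples so grids stay aligned.
#'
#' @param samples List of [eem_sample()] to correct.
#' @param blanks List of blank [eem_sample()]; `NULL` skips blank subtraction.
#' @param params A [scatter_params()].
#' @param ex_range,em_range Fingerprint region (closed intervals, nm).
#' @param clip Zero negative residuals after correction? Default `FALSE`.
#' @param verbose Emit one log line per stage per sample? Default `FALSE`.
#' @return List of corrected [eem_sample()] objects, same order as input.
#' @export
preprocess_pipeline <- function(samples, blanks = NULL,
                                params = scatter_params(),
                                ex_range = c(200, 375), em_range = c(270, 550),
                                clip = FALSE, verbose = FALSE) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  note <- function(id, stage) {
    if (verbose) message(sprintf("[preprocess] %s: %s", id, stage))
  }
  samples <- lapply(samples, function(s) {
    note(s$sample_id, "crop")
    crop_region(s, ex_range, em_range)
  })
  blank_avg <- NULL
  if (!is.null(blanks) && length(blanks) > 0L) {
    blanks <- lapply(blanks, crop_region, ex_range = ex_range,
                     em_range = em_range)
    blank_avg <- average_blanks(blanks)
  }
  mask <- build_scatter_mask(samples[[1L]]$grid, params)
  lapply(samples, function(s) {
    if (!is.null(blank_avg)) {
      note(s$sample_id, "blank subtraction")
      s <- subtract_blank(s, blank_avg)
    }
    note(s$sample_id, "scatter interpolation")
    s <- remove_scatter(s, mask, params)
    if (clip) {
      note(s$sample_id, "negative clipping")
      s <- clip_negative(s)
    }
    s
  })
}
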