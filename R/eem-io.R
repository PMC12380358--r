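#' EEM sample container
#'
#' One sample's fluorescence landscape: an intensity matrix on a
#' [wavelength_grid()] with rows indexed by emission wavelength and columns
#' by excitation wavelength, plus the metadata used downstream (origin label,
#' species, train/validation role).
#'
#' @param intensity Numeric matrix, `length(grid$emission)` rows x
#'   `length(grid$excitation)` columns. All values must be finite; negative
#'   values are permitted (they can arise before preprocessing completes).
#' @param grid A [wavelength_grid()].
#' @param sample_id Character scalar.
#' @param origin Origin label (e.g. one of the seven origin codes), or `NA`.
#' @param species Species label (`"PL"` or `"PV"`), or `NA`.
#' @param role One of `"train"`, `"external_validation"`, `"blank"`, or `NA`.
#'
#' @return An object of class `eem_sample`.
#' @export
eem_sample <- function(intensity, grid, sample_id = NA_character_,
                       origin = NA_character_, species = NA_character_,
                       role = NA_character_) {
  stopifnot(inherits(grid, "wavelength_grid"))
  intensity <- as.matrix(intensity)
  if (!is.numeric(intensity) || length(intensity) == 0L)
    stop("eem_sample: intensity must be a non-empty numeric matrix", call. = FALSE)
  if (nrow(intensity) != length(grid$emission) ||
      ncol(intensity) != length(grid$excitation))
    stop(sprintf(
      "eem_sample: intensity is %d x %d but grid requires %d (emission) x %d (excitation)",
      nrow(intensity), ncol(intensity),
      length(grid$emission), length(grid$excitation)), call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("eem_sample: intensity contains non-finite values", call. = FALSE)
  dimnames(intensity) <- NULL
  structure(list(sample_id = as.character(sample_id),
                 grid = grid,
                 intensity = intensity,
                 origin = as.character(origin),
                 species = as.character(species),
                 role = as.character(role)),
            class = "eem_sample")
}

#' @export
print.eem_sample <- function(x, ...) {
  cat(sprintf("eem_sample '%s' [origin=%s species=%s role=%s]\n",
              x$sample_id, x$origin, x$species, x$role))
  print(x$grid)
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Read an EEM from a delimited text file
#'
#' The EEM-CSV dialect: UTF-8 comma-delimited; the top-left cell is blank or
#' `"em\\ex"`; the remainder of the header row lists the excitation
#' wavelengths (nm); the first column of every following row is the emission
#' wavelength; the body is the intensity matrix.
#'
#' @param path Path to an EEM-CSV file.
#' @return An [eem_sample()] with metadata fields unset (they are joined from
#'   the manifest by [load_manifest()] users).
#' @seealso [write_eem()], [load_manifest()]
#' @export
read_eem <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_eem: file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L)
    stop(sprintf("format error in %s: need a header row and >= 2 data rows", path),
         call. = FALSE)
  cells <- strsplit(lines, ",", fixed = TRUE)
  header <- cells[[1L]]
  ex <- suppressWarnings(as.numeric(header[-1L]))
  if (anyNA(ex))
    stop(sprintf("parse error in %s: non-numeric excitation header at column %d",
                 path, which(is.na(ex))[1L] + 1L), call. = FALSE)
  ncol_expected <- length(header)
  body <- cells[-1L]
  nc <- lengths(body)
  if (any(nc != ncol_expected))
    stop(sprintf("format error in %s: ragged row %d (%d cells, expected %d)",
                 path, which(nc != ncol_expected)[1L] + 1L,
                 nc[which(nc != ncol_expected)[1L]], ncol_expected), call. = FALSE)
  mat <- matrix(NA_real_, nrow = length(body), ncol = ncol_expected)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]]))
    if (anyNA(v))
      stop(sprintf("parse error in %s: non-numeric cell at row %d, column %d",
                   path, i + 1L, which(is.na(v))[1L]), call. = FALSE)
    mat[i, ] <- v
  }
  em <- mat[, 1L]
  grid <- wavelength_grid(excitation = ex, emission = em)
  eem_sample(intensity = mat[, -1L, drop = FALSE], grid = grid)
}

#' Write an EEM to a delimited text file
#'
#' Inverse of [read_eem()]; values are written at full double precision so
#' the round trip is bit-identical.
#'
#' @param sample An [eem_sample()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_eem <- function(sample, path) {
  stopifnot(inherits(sample, "eem_sample"))
  if (!is.matrix(sample$intensity) || length(sample$intensity) == 0L ||
      !is.numeric(sample$intensity))
    stop("write_eem: sample has no valid intensity matrix", call. = FALSE)
  fmt <- function(v) format(v, digits = 17, trim = TRUE, scientific = FALSE)
  header <- paste(c("em\\ex", fmt(sample$grid$excitation)), collapse = ",")
  rows <- vapply(seq_along(sample$grid$emission), function(j) {
    paste(c(fmt(sample$grid$emission[j]), fmt(sample$intensity[j, ])),
          collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

.origin_vocab <- c("hb", "hlj", "ln", "gs", "nmg", "sc", "sl")
.species_vocab <- c("PL", "PV")
.role_vocab <- c("train", "external_validation", "blank")

#' Load a sample manifest
#'
#' The manifest is a CSV with columns `sample_id`, `file`, `origin`,
#' `species`, `role` linking each EEM file to its metadata. Origin codes are
#' restricted to the seven study codes (`hb`, `hlj`, `ln`, `gs`, `nmg`, `sc`,
#' `sl`) unless `origin_vocab` is supplied; blank rows may leave origin and
#' species empty. Missing roles default to `"train"`.
#'
#' @param path Path to the manifest CSV.
#' @param origin_vocab Character vector of admissible origin codes.
#' @return A data.frame with the five manifest columns.
#' @export
load_manifest <- function(path, origin_vocab = .origin_vocab) {
  if (!file.exists(path))
    stop(sprintf("load_manifest: file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  required <- c("sample_id", "file", "origin", "species", "role")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("load_manifest: missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  df <- df[, required]
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop(sprintf("load_manifest: duplicate sample_id: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  df$role[is.na(df$role) | df$role == ""] <- "train"
  bad_role <- setdiff(unique(df$role), .role_vocab)
  if (length(bad_role))
    stop(sprintf("load_manifest: unknown role(s): %s",
                 paste(bad_role, collapse = ", ")), call. = FALSE)
  non_blank <- df$role != "blank"
  bad_origin <- setdiff(unique(df$origin[non_blank]), origin_vocab)
  bad_origin <- bad_origin[!is.na(bad_origin) & bad_origin != ""]
  if (length(bad_origin))
    stop(sprintf("load_manifest: unknown origin code(s): %s",
                 paste(bad_origin, collapse = ", ")), call. = FALSE)
  bad_sp <- setdiff(unique(df$species[non_blank]), .species_vocab)
  bad_sp <- bad_sp[!is.na(bad_sp) & bad_sp != ""]
  if (length(bad_sp))
    stop(sprintf("load_manifest: unknown species code(s): %s",
                 paste(bad_sp, collapse = ", ")), call. = FALSE)
  df
}

#' Crop an EEM to a wavelength window
#'
#' Keeps the lattice points whose wavelengths fall inside the closed
#' intervals `ex_range` and `em_range`; boundary points are retained.
#' Cropping to the same range twice is a no-op.
#'
#' @param sample An [eem_sample()].
#' @param ex_range,em_range Length-2 numeric `c(lo, hi)` in nm.
#' @return The cropped [eem_sample()].
#' @export
crop_region <- function(sample, ex_range = c(200, 375), em_range = c(270, 550)) {
  stopifnot(inherits(sample, "eem_sample"),
            length(ex_range) == 2L, length(em_range) == 2L)
  keep_ex <- which(sample$grid$excitation >= min(ex_range) &
                   sample$grid$excitation <= max(ex_range))
  keep_em <- which(sample$grid$emission >= min(em_range) &
                   sample$grid$emission <= max(em_range))
  if (length(keep_ex) == 0L || length(keep_em) == 0L)
    stop("crop_region: requested range does not intersect the grid", call. = FALSE)
  grid <- wavelength_grid(excitation = sample$grid$excitation[keep_ex],
                          emission = sample$grid$emission[keep_em])
  eem_sample(intensity = sample$intensity[keep_em, keep_ex, drop = FALSE],
             grid = grid, sample_id = sample$sample_id,
             origin = sample$origin, species = sample$species,
             role = sample$role)
}

#' Stack EEM samples into a three-way tensor
#'
#' Aligns a list of samples sharing an identical wavelength grid into the
#' three-way array (samples x emission x excitation) that the trilinear
#' decomposition operates on. Sample order is preserved.
#'
#' @param samples List of [eem_sample()] objects (>= 2) on identical grids.
#' @return An object of class `eem_tensor` with elements `samples`
#'   (sample ids), `grid`, and `data` (array `I x J x K`).
#' @export
stack_tensor <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("stack_tensor: need at least two samples", call. = FALSE)
  stopifnot(all(vapply(samples, inherits, logical(1), "eem_sample")))
  ref <- samples[[1L]]$grid
  for (s in samples) {
    if (!grids_identical(s$grid, ref))
      stop(sprintf("stack_tensor: grid mismatch for sample '%s'", s$sample_id),
           call. = FALSE)
  }
  I <- length(samples)
  J <- length(ref$emission)
  K <- length(ref$excitation)
  data <- array(0, dim = c(I, J, K))
  for (i in seq_len(I)) data[i, , ] <- samples[[i]]$intensity
  structure(list(samples = vapply(samples, `[[`, character(1), "sample_id"),
                 grid = ref, data = data),
            class = "eem_tensor")
}

#' @export
print.eem_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("eem_tensor: I=%d samples x J=%d emission x K=%d excitation\n",
              d[1], d[2], d[3]))
  invisible(x)
}
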