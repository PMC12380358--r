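#' Fluorophore component specification
#'
#' A synthetic fluorophore: Gaussian excitation and emission bands with the
#' Stokes constraint `em_center > ex_center`.
#'
#' @param ex_center,em_center Band centres in nm.
#' @param ex_width,em_width Gaussian sigma in nm (> 0).
#' @param name Component name.
#' @return Object of class `component_spec`.
#' @export
component_spec <- function(ex_center, ex_width, em_center, em_width,
                           name = "component") {
  if (em_center <= ex_center)
    stop("component_spec: em_center must exceed ex_center (Stokes shift)",
         call. = FALSE)
  if (ex_width <= 0 || em_width <= 0)
    stop("component_spec: widths must be positive", call. = FALSE)
  structure(list(ex_center = ex_center, ex_width = ex_width,
                 em_center = em_center, em_width = em_width, name = name),
            class = "component_spec")
}

#' Draw a set of distinguishable fluorophores
#'
#' Places `n` component specs on jittered, evenly spaced excitation and
#' emission slots inside the fingerprint region, with a guaranteed minimum
#' pairwise centre spacing of `min_spacing` nm on the excitation axis and
#' `1.5 * min_spacing` nm on the emission axis, so the components stay
#' spectrally distinguishable (well-conditioned loading matrices). The
#' Stokes shift is at least 90 nm, which keeps the emission bands
#' (sigma <= 30 nm) clear of the first-order Rayleigh region, as for real
#' plant fluorophores. Deterministic for a fixed seed.
#'
#' @param n Number of components (>= 1).
#' @param grid The [wavelength_grid()] the components must live on.
#' @param seed Integer seed.
#' @param min_spacing Minimum pairwise excitation-centre distance in nm
#'   (default 20).
#' @return List of [component_spec()] objects, in order of increasing
#'   excitation centre.
#' @export
make_components <- function(n, grid = default_grid(), seed = 1,
                            min_spacing = 20) {
  stopifnot(n >= 1)
  ex_lo <- min(grid$excitation) + 28
  ex_hi <- max(grid$excitation) - 15
  em_lo <- min(grid$emission) + 50
  em_hi <- max(grid$emission) - 40
  set.seed(seed)
  if (n > 1 && (ex_hi - ex_lo) / (n - 1) < min_spacing + 12)
    stop("make_components: could not place components with the requested spacing",
         call. = FALSE)
  ex_slots <- if (n == 1) mean(c(ex_lo, ex_hi)) else
    seq(ex_lo, ex_hi, length.out = n)
  jit <- if (n == 1) 0 else (diff(ex_slots)[1] - min_spacing) / 2
  ex_c <- sort(ex_slots + stats::runif(n, -jit, jit))
  em_gap <- 1.5 * min_spacing
  em_c <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(if (i > 1) em_c[i - 1] + em_gap else em_lo,
              em_lo + (i - 1) * (em_gap + 8), ex_c[i] + 90)
    em_c[i] <- lo + stats::runif(1, 0, 8)
  }
  if (em_c[n] > em_hi + 10)
    stop("make_components: could not place components with the requested spacing",
         call. = FALSE)
  ex_w <- stats::runif(n, 12, 18)
  em_w <- stats::runif(n, 22, 30)
  lapply(seq_len(n), function(i)
    component_spec(ex_c[i], ex_w[i], em_c[i], em_w[i],
                   name = paste0("component_", i)))
}

component_profiles <- function(components, grid) {
  em <- vapply(components, function(cp)
    exp(-(grid$emission - cp$em_center)^2 / (2 * cp$em_width^2)),
    numeric(length(grid$emission)))
  ex <- vapply(components, function(cp)
    exp(-(grid$excitation - cp$ex_center)^2 / (2 * cp$ex_width^2)),
    numeric(length(grid$excitation)))
  list(em = em, ex = ex)
}

#' Render a clean (exactly trilinear) EEM
#'
#' `M[j,k] = sum_n conc[n] * exp(-(em_j - em_c_n)^2 / (2 em_w_n^2)) *
#' exp(-(ex_k - ex_c_n)^2 / (2 ex_w_n^2))`.
#'
#' @param concentrations Numeric vector, one nonnegative value per component.
#' @param components List of [component_spec()].
#' @param grid A [wavelength_grid()].
#' @return Intensity matrix (emission x excitation).
#' @export
render_clean_eem <- function(concentrations, components, grid = default_grid()) {
  stopifnot(length(concentrations) == length(components))
  pr <- component_profiles(components, grid)
  pr$em %*% (concentrations * t(pr$ex))
}

#' Add scattering ridges to an EEM
#'
#' Adds Gaussian ridges along the first-order Rayleigh line (`em = ex`), the
#' second-order line (`em = 2 ex`), and the solvent Raman line. The ridge
#' cross-section sigmas (default 5, 1.2 and 1.2 nm) are deliberately narrower
#' than the default removal bands of [scatter_params()], so scatter removal
#' can be complete in principle.
#'
#' @param intensity Intensity matrix (emission x excitation).
#' @param grid The matching [wavelength_grid()].
#' @param amplitudes Numeric length-3: peak heights of the first-order
#'   Rayleigh, second-order Rayleigh, and Raman ridges.
#' @param raman_shift Raman shift in cm^-1 (default 3382).
#' @param sigmas Ridge cross-section sigmas in nm, same order as
#'   `amplitudes`.
#' @return The intensity matrix with ridges added.
#' @export
add_scatter <- function(intensity, grid, amplitudes, raman_shift = 3382,
                        sigmas = c(5, 1.2, 1.2)) {
  stopifnot(length(amplitudes) == 3L, all(amplitudes >= 0))
  em <- grid$emission; ex <- grid$excitation
  ridge <- function(center_of_ex, a, s)
    a * exp(-outer(em, center_of_ex, `-`)^2 / (2 * s^2))
  intensity +
    ridge(ex, amplitudes[1], sigmas[1]) +
    ridge(2 * ex, amplitudes[2], sigmas[2]) +
    ridge(raman_emission(ex, raman_shift), amplitudes[3], sigmas[3])
}

#' Synthetic study design
#'
#' The default design mirrors the origin-tracing study layout: 7 origins x 6
#' replicates (42 training samples), 4 external-validation samples drawn from
#' four of the origins, 3 blanks, and 5 underlying fluorophores. Two origins
#' (`gs`, `sc`) carry species `PV`, the other five `PL`.
#'
#' Group concentration structure: four of the five components carry the
#' between-group signal (their group means sit on a fixed 7-point skeleton in
#' four dimensions, jittered per seed and scaled so that the minimum pairwise
#' group separation -- see [separation_level()] -- equals
#' `12 * between_group_scale` within-group standard deviations). One
#' designated component (`low_variance_component`, default 3) is
#' concentration-coupled to the others with near-constant level across
#' groups, emulating a fluorophore whose abundance tracks the shared
#' metabolic pool rather than geographic origin.
#'
#' @param n_per_group Replicates per origin (default 6).
#' @param n_components Number of fluorophores (default 5).
#' @param n_blanks Number of blank samples (default 3).
#' @param within_cv Within-group coefficient of variation of the lognormal
#'   concentration multipliers (default 0.10).
#' @param noise_sigma Additive Gaussian intensity noise, as a fraction of the
#'   peak clean intensity of the dataset (default 0.01).
#' @param scatter_amplitudes Ridge peak heights (first-order Rayleigh,
#'   second-order Rayleigh, Raman) as fractions of the peak clean intensity.
#' @param raman_shift Raman shift in cm^-1.
#' @param between_group_scale Multiplier on the between-group separation
#'   (default 1; the baseline separation is 12).
#' @param low_variance_component Index of the origin-uninformative component.
#' @param grid Acquisition [wavelength_grid()].
#' @param seed Integer seed driving every random draw of the simulation.
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_per_group = 6, n_components = 5, n_blanks = 3,
                         within_cv = 0.10, noise_sigma = 0.01,
                         scatter_amplitudes = c(rayleigh1 = 1.0,
                                                rayleigh2 = 0.3,
                                                raman = 0.2),
                         raman_shift = 3382, between_group_scale = 1,
                         low_variance_component = 3,
                         grid = default_grid(), seed = 42) {
  if (noise_sigma < 0) stop("study_design: negative noise_sigma", call. = FALSE)
  if (within_cv < 0) stop("study_design: negative within_cv", call. = FALSE)
  if (n_per_group < 1 || n_components < 1)
    stop("study_design: empty design", call. = FALSE)
  origins <- c("hb", "hlj", "ln", "gs", "nmg", "sc", "sl")
  species <- c(hb = "PL", hlj = "PL", ln = "PL", gs = "PV",
               nmg = "PL", sc = "PV", sl = "PL")
  holdout_origins <- c("hb", "ln", "nmg", "gs")
  structure(list(origins = origins, species = species,
                 holdout_origins = holdout_origins,
                 n_per_group = as.integer(n_per_group),
                 n_components = as.integer(n_components),
                 n_blanks = as.integer(n_blanks),
                 within_cv = within_cv, noise_sigma = noise_sigma,
                 scatter_amplitudes = scatter_amplitudes,
                 raman_shift = raman_shift,
                 between_group_scale = between_group_scale,
                 base_separation = 12,
                 low_variance_component = as.integer(low_variance_component),
                 coupling = 0.15, coupling_jitter_cv = 0.015,
                 scatter_cv = 0.10,
                 grid = grid, seed = as.integer(seed)),
            class = "study_design")
}

# 7-group skeleton in the 4 informative concentration dimensions. Every
# group mean is an exposed vertex of the convex hull -- no group sits
# between two others, which would mask it for linear indicator classifiers.
# The two species-PV groups (gs, sc) share a high level on dimension 1
# (one-sided species margin against the five PL groups) and differ from
# each other only along dimension 4, the weakest, so all four dimensions are
# needed to resolve the seven groups. Column weights grade the
# per-dimension between-group spread in the order mapped to components
# 1 > 2 > 5 > 4.
.group_skeleton <- function() {
  D <- rbind(hb  = c(-0.80,  0.00,  0.00,  0.00),
             hlj = c( 0.00,  0.80,  0.00,  0.00),
             ln  = c( 0.00, -0.80,  0.00,  0.00),
             gs  = c( 0.90,  0.00,  0.00,  0.55),
             nmg = c( 0.00,  0.00,  0.75,  0.00),
             sc  = c( 0.90,  0.00,  0.00, -0.55),
             sl  = c( 0.00,  0.00, -0.75,  0.00))
  weights <- c(1.0, 0.95, 0.9, 0.55)
  sweep(D, 2, weights, "*")
}

# Group mean concentrations for the informative components, scaled so the
# minimum pairwise separation is `base_separation * between_group_scale`
# within-group sds. Deterministic given the RNG state.
group_mean_matrix <- function(design, base) {
  n_info <- length(base) - 1L
  D <- .group_skeleton()[, seq_len(min(4L, n_info)), drop = FALSE]
  if (ncol(D) < n_info)
    D <- cbind(D, matrix(0, nrow(D), n_info - ncol(D)))
  D <- D + 0.04 * matrix(stats::rnorm(length(D)), nrow(D))
  # shift each dimension to nonnegative values: positivity of concentrations
  # is then guaranteed for any separation scale (distances are unaffected)
  D <- sweep(D, 2, apply(D, 2, min))
  D <- D / min(stats::dist(D))
  s <- design$within_cv * design$base_separation * design$between_group_scale
  # map skeleton dimensions to components in decreasing between-group
  # spread: columns of D go to components 1, 2, 5, 4, ...
  info <- setdiff(seq_along(base), design$low_variance_component)
  comp_order <- intersect(c(1L, 2L, 5L, 4L, seq_along(base)), info)
  M <- matrix(base, nrow = nrow(D), ncol = length(base), byrow = TRUE,
              dimnames = list(rownames(D), NULL))
  for (d in seq_len(ncol(D)))
    M[, comp_order[d]] <- base[comp_order[d]] * pmax(1 + s * D[, d], 0.05)
  M
}

#' Minimum between-group separation of a design
#'
#' Smallest pairwise distance between group mean concentration vectors, in
#' units of the within-group standard deviation per component
#' (`within_cv * base concentration`): a Mahalanobis-style diagnostic of how
#' hard the classification task is. The shipped default design yields a
#' value slightly above 12, and it scales linearly with
#' `between_group_scale`.
#'
#' @param design A [study_design()].
#' @return Scalar separation (0 when all group means coincide).
#' @export
separation_level <- function(design) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  base <- draw_base_concentrations(design)
  M <- group_mean_matrix(design, base)
  su <- design$within_cv * base
  min(stats::dist(sweep(M, 2, su, "/")))
}

draw_base_concentrations <- function(design) {
  # baseline (grand-mean) concentration per component, O(1), seeded
  stats::runif(design$n_components, 0.8, 1.2)
}

#' Simulate a full EEM study dataset
#'
#' Generates, from a single seed: the fluorophore set, group-structured
#' per-sample concentrations (lognormal within-group multipliers with
#' coefficient of variation `within_cv`; the designated low-variance
#' component is coupled to the others, see [study_design()]), exactly
#' trilinear clean EEMs, scatter ridges with per-sample amplitude variation,
#' additive Gaussian noise, blanks containing only scatter and noise, and
#' four external-validation samples drawn from four of the origin
#' distributions. The ground truth (profiles, concentrations, clean EEMs) is
#' retained for testing.
#'
#' @param design A [study_design()].
#' @return List with `samples` (list of [eem_sample()]: training samples,
#'   then external-validation samples, then blanks) and `truth` (list:
#'   `components`, `em_profiles`, `ex_profiles`, `concentrations`, `clean`
#'   (list of clean matrices, train + holdout), `labels` data.frame,
#'   `group_means`, `peak_intensity`).
#' @export
simulate_dataset <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  base <- draw_base_concentrations(design)
  M <- group_mean_matrix(design, base)
  components <- make_components(design$n_components, design$grid,
                                seed = design$seed)
  set.seed(design$seed + 1L)

  lv <- design$low_variance_component
  info <- setdiff(seq_len(design$n_components), lv)
  sdlog <- sqrt(log(1 + design$within_cv^2))
  gamma <- design$coupling * rep_len(c(1, -1), length(info))

  draw_sample <- function(origin) {
    m <- M[origin, ]
    conc <- numeric(design$n_components)
    mult <- stats::rlnorm(length(info), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    conc[info] <- m[info] + base[info] * (mult - 1)
    z <- conc[info] / base[info] - 1
    jit_sd <- sqrt(log(1 + design$coupling_jitter_cv^2))
    jitter <- stats::rlnorm(1, meanlog = -jit_sd^2 / 2, sdlog = jit_sd)
    conc[lv] <- base[lv] * (1 + sum(gamma * z)) * jitter
    pmax(conc, 0)
  }

  origins_train <- rep(design$origins, each = design$n_per_group)
  ids_train <- paste0(origins_train,
                      rep(seq_len(design$n_per_group), times = length(design$origins)))
  origins_hold <- design$holdout_origins
  ids_hold <- paste0("pred", seq_along(origins_hold))
  all_origins <- c(origins_train, origins_hold)
  conc <- t(vapply(all_origins, draw_sample, numeric(design$n_components)))
  rownames(conc) <- c(ids_train, ids_hold)

  clean <- lapply(seq_len(nrow(conc)), function(i)
    render_clean_eem(conc[i, ], components, design$grid))
  peak <- max(vapply(clean, max, numeric(1)))

  amp_base <- design$scatter_amplitudes * peak
  scatter_sdlog <- sqrt(log(1 + design$scatter_cv^2))
  noise_sd <- design$noise_sigma * peak
  J <- length(design$grid$emission); K <- length(design$grid$excitation)

  make_noisy <- function(mat) {
    amps <- amp_base * stats::rlnorm(3, meanlog = -scatter_sdlog^2 / 2,
                                     sdlog = scatter_sdlog)
    out <- add_scatter(mat, design$grid, amps, design$raman_shift)
    if (noise_sd > 0)
      out <- out + matrix(stats::rnorm(J * K, sd = noise_sd), J, K)
    out
  }

  samples <- vector("list", nrow(conc) + design$n_blanks)
  for (i in seq_len(nrow(conc))) {
    origin <- all_origins[i]
    role <- if (i <= length(ids_train)) "train" else "external_validation"
    samples[[i]] <- eem_sample(make_noisy(clean[[i]]), design$grid,
                               sample_id = rownames(conc)[i],
                               origin = origin,
                               species = design$species[[origin]],
                               role = role)
  }
  for (b in seq_len(design$n_blanks)) {
    blank <- make_noisy(matrix(0, J, K))
    samples[[nrow(conc) + b]] <- eem_sample(blank, design$grid,
                                            sample_id = paste0("blank", b),
                                            role = "blank")
  }

  pr <- component_profiles(components, design$grid)
  labels <- data.frame(
    sample_id = c(rownames(conc), paste0("blank", seq_len(design$n_blanks))),
    origin = c(all_origins, rep(NA_character_, design$n_blanks)),
    species = c(unname(design$species[all_origins]),
                rep(NA_character_, design$n_blanks)),
    role = c(rep("train", length(ids_train)),
             rep("external_validation", length(ids_hold)),
             rep("blank", design$n_blanks)))

  list(samples = samples,
       truth = list(components = components, em_profiles = pr$em,
                    ex_profiles = pr$ex, concentrations = conc,
                    clean = clean, labels = labels, group_means = M,
                    base_concentrations = base, peak_intensity = peak))
}
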