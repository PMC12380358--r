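test_that("blank averaging is the cell-wise mean", {
  g <- tiny_grid()
  J <- length(g$emission); K <- length(g$excitation)
  set.seed(3)
  M <- matrix(abs(rnorm(J * K)), J, K)
  b1 <- eem_sample(M, g, "b1"); b2 <- eem_sample(M, g, "b2")
  expect_equal(average_blanks(list(b1, b2, b1))$intensity, M)
  z <- eem_sample(matrix(0, J, K), g, "z")
  two <- eem_sample(2 * M, g, "two")
  expect_equal(average_blanks(list(z, two))$intensity, M)
  expect_error(average_blanks(list()), "at least one")
  # simulated scatter-ridge blanks: averaged ridge amplitude recovered
  # (first-order Rayleigh peaks exactly on the em = ex lattice cells)
  gd <- default_grid()
  a <- 3.7
  set.seed(6)
  blanks <- lapply(1:3, function(i)
    eem_sample(add_scatter(matrix(0, 57, 36), gd,
                           c(a * runif(1, 0.9, 1.1), 0, 0)), gd,
               paste0("rb", i)))
  avg <- average_blanks(blanks)
  manual <- Reduce(`+`, lapply(blanks, `[[`, "intensity")) / 3
  expect_equal(avg$intensity, manual)
  expect_equal(max(avg$intensity), a, tolerance = 0.1)
})

test_that("blank subtraction is exact and keeps negatives", {
  g <- tiny_grid()
  set.seed(4)
  J <- length(g$emission); K <- length(g$excitation)
  signal <- matrix(abs(rnorm(J * K)), J, K)
  blank <- matrix(abs(rnorm(J * K)), J, K)
  s <- eem_sample(signal + blank, g, "s")
  b <- eem_sample(blank, g, "b")
  expect_equal(subtract_blank(s, b)$intensity, signal)
  expect_equal(subtract_blank(s, s)$intensity, matrix(0, J, K))
  big <- eem_sample(blank + 10, g, "big")
  res <- subtract_blank(s, big)
  expect_true(any(res$intensity < 0))
})

test_that("the scatter mask flags exactly the three scatter-band geometries", {
  g <- default_grid()
  p <- scatter_params()
  mask <- build_scatter_mask(g, p)
  jx <- function(em, ex) c(which(g$emission == em), which(g$excitation == ex))
  i <- jx(300, 300); expect_true(mask[i[1], i[2]])   # first-order centre
  i <- jx(500, 250); expect_true(mask[i[1], i[2]])   # second-order centre
  i <- jx(450, 300); expect_false(mask[i[1], i[2]])
  # brute-force enumeration over every grid cell from the band definitions
  brute <- matrix(FALSE, length(g$emission), length(g$excitation))
  for (j in seq_along(g$emission)) for (k in seq_along(g$excitation)) {
    em <- g$emission[j]; ex <- g$excitation[k]
    raman_centre <- 1 / (1 / ex - 3382e-7)
    brute[j, k] <- abs(em - ex) <= 17.5 || abs(em - 2 * ex) <= 2.5 ||
      abs(em - raman_centre) <= 2.5
  }
  expect_identical(unclass(mask), brute, ignore_attr = TRUE)
  # raman centre formula at 300 nm excitation
  expect_equal(raman_emission(300), 1 / (1 / 300 - 3382e-7))
})

test_that("masked fraction grows monotonically with each band width", {
  g <- default_grid()
  base <- mean(build_scatter_mask(g, scatter_params()))
  wider <- list(scatter_params(rayleigh1_width = 50),
                scatter_params(raman_width = 15),
                scatter_params(rayleigh2_width = 15))
  for (p in wider)
    expect_gte(mean(build_scatter_mask(g, p)), base)
})

test_that("scatter interpolation restores the clean signal and never touches unflagged cells", {
  g <- default_grid()
  comps <- make_components(3, g, seed = 11)
  clean <- render_clean_eem(c(1, 0.8, 1.2), comps, g)
  dirty <- add_scatter(clean, g, amplitudes = c(1, 0.3, 0.2) * max(clean))
  p <- scatter_params()
  mask <- build_scatter_mask(g, p)
  fixed <- remove_scatter(eem_sample(dirty, g, "d"), mask, p)
  # unflagged cells bit-identical
  expect_identical(fixed$intensity[!mask], dirty[!mask])
  # interior flagged cells (not boundary-touching runs) close to clean signal
  interior <- mask
  interior[1, ] <- FALSE; interior[nrow(mask), ] <- FALSE
  for (k in seq_len(ncol(mask))) {
    runs <- rle(mask[, k])
    ends <- cumsum(runs$lengths)
    if (runs$values[1]) interior[seq_len(runs$lengths[1]), k] <- FALSE
    nr <- length(runs$values)
    if (runs$values[nr]) interior[(ends[nr - 1] + 1):ends[nr], k] <- FALSE
  }
  rms_err <- sqrt(mean((fixed$intensity[interior] - clean[interior])^2))
  rms_clean <- sqrt(mean(clean^2))
  expect_lt(rms_err, 0.05 * rms_clean)
  # all-false mask: identity
  none <- build_scatter_mask(g, p)
  none[] <- FALSE
  expect_identical(remove_scatter(eem_sample(dirty, g), none, p)$intensity,
                   dirty)
})

test_that("a single flagged cell in a linear field is interpolated to the linear value", {
  g <- tiny_grid()
  J <- length(g$emission); K <- length(g$excitation)
  lin <- outer(g$emission, rep(1, K)) * 0.01
  mask <- matrix(FALSE, J, K)
  mask[5, 2] <- TRUE
  fixed <- remove_scatter(eem_sample(lin, g), mask, scatter_params())
  expect_equal(fixed$intensity[5, 2], lin[5, 2], tolerance = 1e-8)
  # a fully flagged column cannot be interpolated
  mask[, 3] <- TRUE
  expect_error(remove_scatter(eem_sample(lin, g), mask, scatter_params()),
               "entirely flagged")
})

test_that("negative clipping zeroes only negatives", {
  g <- tiny_grid()
  J <- length(g$emission); K <- length(g$excitation)
  set.seed(5)
  M <- matrix(rnorm(J * K), J, K)
  clipped <- clip_negative(eem_sample(M, g))
  expect_equal(min(clipped$intensity), 0)
  expect_identical(clipped$intensity[M >= 0], M[M >= 0])
  allpos <- abs(M) + 1
  expect_identical(clip_negative(eem_sample(allpos, g))$intensity, allpos)
  expect_equal(clip_negative(eem_sample(matrix(-1, J, K), g))$intensity,
               matrix(0, J, K))
})

test_that("the full pipeline is exact on additive constructions", {
  design <- study_design(seed = 8)
  sim <- simulate_dataset(design)
  out <- preprocess_pipeline(sim$samples[1:46], blanks = sim$samples[47:49])
  expect_length(out, 46)
  for (s in out) expect_equal(dim(s$intensity), c(57, 36))
  # pipeline applied to a blank: near zero after subtraction + interpolation
  b <- preprocess_pipeline(sim$samples[47], blanks = sim$samples[47])
  expect_equal(max(abs(b[[1]]$intensity)), 0)
  # scatter-free, blank-free synthetic input: identity up to cropping (the
  # flagged cells are re-interpolated from the smooth clean signal, so the
  # pipeline is the identity up to interpolation error there)
  clean_s <- eem_sample(sim$truth$clean[[1]], design$grid, "clean")
  ident <- preprocess_pipeline(list(clean_s), blanks = NULL)
  rel <- sqrt(sum((ident[[1]]$intensity - clean_s$intensity)^2) /
              sum(clean_s$intensity^2))
  expect_lt(rel, 0.01)
  # correction quality isolated from the irreducible cell noise: on a
  # noise-free batch the corrected samples sit within 5% of the clean truth
  d0 <- study_design(seed = 8, noise_sigma = 0)
  sim0 <- simulate_dataset(d0)
  out0 <- preprocess_pipeline(sim0$samples[1:46], blanks = sim0$samples[47:49])
  rel0 <- sapply(1:46, function(i)
    sqrt(sum((out0[[i]]$intensity - sim0$truth$clean[[i]])^2) /
         sum(sim0$truth$clean[[i]]^2)))
  expect_lt(max(rel0), 0.05)
  # with noise present the residual stays near the additive-noise floor
  rel_err <- sapply(1:46, function(i)
    sqrt(sum((out[[i]]$intensity - sim$truth$clean[[i]])^2) /
         sum(sim$truth$clean[[i]]^2)))
  floor_rel <- design$noise_sigma * sim$truth$peak_intensity *
    sqrt(57 * 36) / sapply(sim$truth$clean[1:46], function(M) sqrt(sum(M^2)))
  expect_lt(mean(rel_err), 1.5 * mean(floor_rel))
})
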