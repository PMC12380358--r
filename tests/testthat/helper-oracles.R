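# Shared fixtures and independent oracles for the test suite.

# small wavelength lattice for fast unit tests
tiny_grid <- function() {
  wavelength_grid(excitation = seq(220, 360, by = 20),
                  emission = seq(290, 530, by = 20))
}

# generic trilinear tensor from random positive Gaussian-band factors,
# independent of the study design
make_tri_tensor <- function(I = 12, n = 3, grid = tiny_grid(), seed = 1,
                            noise_sd = 0) {
  comps <- make_components(n, grid, seed = seed)
  set.seed(seed + 1000L)
  conc <- matrix(stats::runif(I * n, 0.3, 1.5), I, n)
  samples <- lapply(seq_len(I), function(i) {
    m <- render_clean_eem(conc[i, ], comps, grid)
    if (noise_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), sd = noise_sd * max(m)),
                      nrow(m))
    eem_sample(m, grid, sample_id = paste0("s", i))
  })
  pr <- eemtrace:::component_profiles(comps, grid)
  list(tensor = stack_tensor(samples),
       truth = list(em_loadings = pr$em, ex_loadings = pr$ex, scores = conc),
       components = comps, conc = conc, grid = grid)
}

# independent PARAFAC-ALS reference: random init, plain normal-equation
# solves, coded separately from the package implementation
als_oracle <- function(tensor, N, maxit = 2000, tol = 1e-12, seed = 99) {
  X <- tensor$data
  d <- dim(X)
  set.seed(seed)
  A <- matrix(stats::rnorm(d[1] * N), d[1], N)
  B <- matrix(stats::rnorm(d[2] * N), d[2], N)
  E <- matrix(stats::rnorm(d[3] * N), d[3], N)
  ssx <- sum(X^2)
  X1 <- matrix(aperm(X, c(1, 2, 3)), d[1])
  X2 <- matrix(aperm(X, c(2, 3, 1)), d[2])
  X3 <- matrix(aperm(X, c(3, 1, 2)), d[3])
  kr <- function(P, Q)
    vapply(seq_len(ncol(P)), function(j) kronecker(P[, j], Q[, j]),
           numeric(nrow(P) * nrow(Q)))
  prev <- Inf
  for (it in seq_len(maxit)) {
    A <- X1 %*% kr(E, B) %*% solve(crossprod(E) * crossprod(B))
    B <- X2 %*% kr(A, E) %*% solve(crossprod(A) * crossprod(E))
    E <- X3 %*% kr(B, A) %*% solve(crossprod(B) * crossprod(A))
    rss <- ssx - 2 * sum(X3 * (E %*% t(kr(B, A)))) +
      sum(crossprod(E) * crossprod(B) * crossprod(A))
    if (is.finite(prev) && abs(prev - rss) / ssx < tol) break
    prev <- rss
  }
  list(scores = A, em_loadings = B, ex_loadings = E,
       explained_variance = 1 - rss / ssx)
}

# least-squares Tucker3 core solved brute-force from the explicit normal
# equations of the full design matrix Z = E (x) B (x) A
core_normal_equations <- function(tensor, model) {
  A <- model$scores; B <- model$em_loadings; E <- model$ex_loadings
  N <- ncol(A)
  d <- dim(tensor$data)
  x <- as.vector(tensor$data) # index order i fastest, then j, then k
  Z <- matrix(0, length(x), N^3)
  col <- 0L
  for (r in seq_len(N)) for (q in seq_len(N)) for (p in seq_len(N)) {
    col <- col + 1L
    Z[, col] <- as.vector(outer(outer(A[, p], B[, q]), E[, r]))
  }
  g <- solve(crossprod(Z), crossprod(Z, x))
  array(g, dim = c(N, N, N)) # p fastest -> dims (p, q, r)
}

# default-design pipeline products shared by the acceptance tests; computed
# once per test run
study_fixture_env <- new.env()
study_fixture <- function(seed = 42) {
  key <- as.character(seed)
  if (!is.null(study_fixture_env[[key]])) return(study_fixture_env[[key]])
  design <- study_design(seed = seed)
  sim <- simulate_dataset(design)
  n_data <- length(sim$samples) - design$n_blanks
  corrected <- preprocess_pipeline(sim$samples[seq_len(n_data)],
                                   blanks = sim$samples[-seq_len(n_data)])
  tensor <- stack_tensor(corrected)
  model <- atld_fit(tensor, design$n_components)
  labels <- sim$truth$labels
  idx <- match(model$sample_ids, labels$sample_id)
  is_train <- labels$role[idx] == "train"
  train <- feature_table(model$sample_ids[is_train],
                         labels$origin[idx][is_train],
                         model$scores[is_train, , drop = FALSE])
  holdout <- feature_table(model$sample_ids[!is_train],
                           labels$origin[idx][!is_train],
                           model$scores[!is_train, , drop = FALSE])
  species_train <- feature_table(train$ids, labels$species[idx][is_train],
                                 train$features)
  out <- list(design = design, sim = sim, corrected = corrected,
              tensor = tensor, model = model, train = train,
              holdout = holdout, species_train = species_train)
  study_fixture_env[[key]] <- out
  out
}
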