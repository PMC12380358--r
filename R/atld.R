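#' ATLD solver configuration
#'
#' Knobs of the alternating trilinear decomposition solver.
#'
#' @param tol Stopping threshold: iteration stops when the change in residual
#'   sum of squares between sweeps, relative to the total sum of squares of
#'   the tensor, falls below `tol`.
#' @param max_iter Iteration cap.
#' @param init `"svd"` (deterministic, from singular vectors of the mode
#'   unfoldings) or `"random"`.
#' @param seed Integer seed, required when `init = "random"`.
#' @param pinv_truncation Rank used in the truncated Moore-Penrose
#'   pseudoinverses; defaults to the component number.
#' @return An object of class `atld_config`.
#' @export
atld_config <- function(tol = 1e-6, max_iter = 200,
                        init = c("svd", "random"), seed = NULL,
                        pinv_truncation = NULL) {
  init <- match.arg(init)
  if (tol <= 0) stop("atld_config: tol must be positive", call. = FALSE)
  if (max_iter < 1) stop("atld_config: max_iter must be >= 1", call. = FALSE)
  if (init == "random" && is.null(seed))
    stop("atld_config: random init requires a seed", call. = FALSE)
  structure(list(tol = tol, max_iter = as.integer(max_iter), init = init,
                 seed = seed, pinv_truncation = pinv_truncation),
            class = "atld_config")
}

# Moore-Penrose pseudoinverse truncated at rank `rank`.
pinv_trunc <- function(M, rank = min(dim(M))) {
  sv <- svd(M)
  keep <- which(sv$d > max(sv$d[1], .Machine$double.eps) * 1e-12)
  keep <- keep[seq_len(min(length(keep), rank))]
  if (length(keep) == 0L) return(matrix(0, ncol(M), nrow(M)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

# Mode-n unfolding of an I x J x K array. Mode 1 gives I x (JK) with J
# running fastest; modes 2 and 3 analogously.
unfold <- function(X, mode) {
  d <- dim(X)
  perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(2, 3, 1), `3` = c(3, 1, 2))
  matrix(aperm(X, perm), nrow = d[mode])
}

#' Fit a trilinear model by alternating trilinear decomposition
#'
#' Fits the trilinear model
#' `x[i,j,k] = sum_n scores[i,n] * em_loadings[j,n] * ex_loadings[k,n] + e[i,j,k]`
#' to an EEM tensor by ATLD: each mode's parameters are refreshed from the
#' diagonal of products of truncated Moore-Penrose pseudoinverses of the other
#' two loading matrices with the corresponding tensor slices. The scheme
#' converges rapidly (typically well under ten sweeps on low-noise EEM data)
#' and tolerates an overestimated component number, presenting excess
#' components as low-intensity background.
#'
#' After convergence the emission and excitation loading columns are scaled
#' to unit Euclidean norm (all scale moves into the score matrix), each
#' loading column's largest-magnitude entry is made positive, and components
#' are sorted by decreasing contribution to the explained variance.
#'
#' @param tensor An [stack_tensor()] result (class `eem_tensor`).
#' @param n_components Number of trilinear components N (>= 1).
#' @param config An [atld_config()].
#' @return An object of class `trilinear_model`: `n_components`,
#'   `em_loadings` (J x N), `ex_loadings` (K x N), `scores` (I x N),
#'   `n_iter`, `loss_history` (residual sum of squares per sweep), and
#'   `explained_variance`.
#' @export
atld_fit <- function(tensor, n_components, config = atld_config()) {
  stopifnot(inherits(tensor, "eem_tensor"), inherits(config, "atld_config"))
  X <- tensor$data
  if (any(!is.finite(X)))
    stop("atld_fit: tensor contains non-finite entries", call. = FALSE)
  ssx <- sum(X^2)
  if (ssx == 0)
    stop("atld_fit: degenerate input (all-zero tensor)", call. = FALSE)
  N <- as.integer(n_components)
  if (N < 1) stop("atld_fit: n_components must be >= 1", call. = FALSE)
  d <- dim(X)
  I <- d[1]; J <- d[2]; K <- d[3]
  r <- if (is.null(config$pinv_truncation)) N else config$pinv_truncation

  if (config$init == "svd") {
    B <- svd(unfold(X, 2), nu = min(N, J))$u
    E <- svd(unfold(X, 3), nu = min(N, K))$u
    if (ncol(B) < N) B <- cbind(B, matrix(1e-8, J, N - ncol(B)))
    if (ncol(E) < N) E <- cbind(E, matrix(1e-8, K, N - ncol(E)))
  } else {
    set.seed(config$seed)
    B <- matrix(stats::rnorm(J * N), J, N)
    E <- matrix(stats::rnorm(K * N), K, N)
  }
  A <- matrix(1, I, N)

  # pre-sliced views of the tensor for the three update directions
  slices_i <- lapply(seq_len(I), function(i) X[i, , ])            # J x K
  slices_j <- lapply(seq_len(J), function(j) t(X[, j, ]))         # K x I
  slices_k <- lapply(seq_len(K), function(k) X[, , k])            # I x J

  rss <- function(A, B, E) {
    s <- 0
    for (i in seq_len(I)) {
      R <- slices_i[[i]] - B %*% (A[i, ] * t(E))
      s <- s + sum(R^2)
    }
    s
  }

  loss_history <- numeric(0)
  prev <- Inf
  n_iter <- 0L
  for (it in seq_len(config$max_iter)) {
    Bp <- pinv_trunc(B, r)                       # N x J
    Ep <- pinv_trunc(E, r)                       # N x K
    for (i in seq_len(I))
      A[i, ] <- rowSums((Bp %*% slices_i[[i]]) * Ep)
    Ap <- pinv_trunc(A, r)                       # N x I
    for (j in seq_len(J))
      B[j, ] <- rowSums((Ep %*% slices_j[[j]]) * Ap)
    Bp <- pinv_trunc(B, r)
    for (k in seq_len(K))
      E[k, ] <- rowSums((Ap %*% slices_k[[k]]) * Bp)
    cur <- rss(A, B, E)
    loss_history <- c(loss_history, cur)
    n_iter <- it
    if (is.finite(prev) && abs(prev - cur) / ssx < config$tol) break
    prev <- cur
  }

  # normalize: unit-norm loading columns, scale into scores, positive sign
  nb <- sqrt(colSums(B^2)); nb[nb == 0] <- 1
  ne <- sqrt(colSums(E^2)); ne[ne == 0] <- 1
  B <- sweep(B, 2, nb, "/")
  E <- sweep(E, 2, ne, "/")
  A <- sweep(A, 2, nb * ne, "*")
  for (n in seq_len(N)) {
    sb <- sign(B[which.max(abs(B[, n])), n]); if (sb < 0) { B[, n] <- -B[, n]; A[, n] <- -A[, n] }
    se <- sign(E[which.max(abs(E[, n])), n]); if (se < 0) { E[, n] <- -E[, n]; A[, n] <- -A[, n] }
  }
  contrib <- colSums(A^2)
  ord <- order(contrib, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  B <- B[, ord, drop = FALSE]
  E <- E[, ord, drop = FALSE]

  final_rss <- rss(A, B, E)
  structure(list(n_components = N,
                 em_loadings = B, ex_loadings = E, scores = A,
                 n_iter = n_iter, loss_history = loss_history,
                 explained_variance = 1 - final_rss / ssx,
                 sample_ids = tensor$samples, grid = tensor$grid),
            class = "trilinear_model")
}

#' @export
print.trilinear_model <- function(x, ...) {
  cat(sprintf("trilinear_model: N=%d, %d iterations, explained variance %.6f\n",
              x$n_components, x$n_iter, x$explained_variance))
  invisible(x)
}

#' Reconstruct the tensor implied by a trilinear model
#'
#' @param model A [atld_fit()] result.
#' @param grid Optional [wavelength_grid()] (defaults to the model's).
#' @param samples Optional sample ids (defaults to the model's).
#' @return An `eem_tensor` with `data[i,j,k] = sum_n scores[i,n] *
#'   em_loadings[j,n] * ex_loadings[k,n]`.
#' @export
reconstruct <- function(model, grid = model$grid, samples = model$sample_ids) {
  stopifnot(inherits(model, "trilinear_model"))
  I <- nrow(model$scores); J <- nrow(model$em_loadings); K <- nrow(model$ex_loadings)
  data <- array(0, dim = c(I, J, K))
  for (i in seq_len(I))
    data[i, , ] <- model$em_loadings %*% (model$scores[i, ] * t(model$ex_loadings))
  structure(list(samples = samples, grid = grid, data = data),
            class = "eem_tensor")
}

#' Explained variance of a model on a tensor
#'
#' `1 - ||X - Xhat||^2_F / ||X||^2_F`.
#'
#' @param tensor An `eem_tensor`.
#' @param model A `trilinear_model`.
#' @return Scalar fraction (1 for an exact fit).
#' @export
explained_variance <- function(tensor, model) {
  ssx <- sum(tensor$data^2)
  if (ssx == 0) stop("explained_variance: zero tensor", call. = FALSE)
  1 - sum((tensor$data - reconstruct(model)$data)^2) / ssx
}

#' Core-consistency diagnostic (CORCONDIA)
#'
#' Solves the least-squares Tucker3 core G (N x N x N) implied by the fitted
#' loadings -- `vec(G) = pinv(E (x) B (x) A) vec(X)`, computed as successive
#' mode products with the loading pseudoinverses -- and compares it to the
#' superidentity T (ones on the superdiagonal): consistency is
#' `100 * (1 - sum((G - T)^2) / sum(T^2))`. Values near 100 indicate that the
#' data conform to the trilinear model; the selection rule used here accepts
#' component numbers with consistency of at least 60 percent.
#'
#' @param tensor The `eem_tensor` the model was fitted to.
#' @param model A `trilinear_model`.
#' @return Object of class `corcondia_result`: `n_components`,
#'   `core_consistency` (percent, at most 100, may be negative), `fit`
#'   (explained variance), `core` (the N x N x N core), and `rank_deficient`
#'   (flag set when a loading matrix is numerically rank-deficient, in which
#'   case the diagnostic is unreliable).
#' @export
corcondia <- function(tensor, model) {
  stopifnot(inherits(tensor, "eem_tensor"), inherits(model, "trilinear_model"))
  N <- model$n_components
  loadings <- list(model$scores, model$em_loadings, model$ex_loadings)
  rank_def <- any(vapply(loadings, function(M) {
    d <- svd(M, nu = 0, nv = 0)$d
    d[length(d)] < d[1] * 1e-10 || length(d) < N
  }, logical(1)))
  if (rank_def)
    warning("corcondia: rank-deficient loadings; diagnostic unreliable")
  G <- tensor$data
  # mode products with pseudoinverses: G = X x1 A+ x2 B+ x3 E+
  for (mode in 1:3) {
    P <- pinv_trunc(loadings[[mode]], N)        # N x dim
    d <- dim(G)
    Gm <- P %*% unfold(G, mode)                 # N x (prod other dims)
    d[mode] <- N
    perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(3, 1, 2), `3` = c(2, 3, 1))
    G <- aperm(array(Gm, dim = d[switch(mode, `1` = c(1, 2, 3),
                                        `2` = c(2, 3, 1), `3` = c(3, 1, 2))]),
               perm)
  }
  T_ <- array(0, dim = c(N, N, N))
  for (n in seq_len(N)) T_[n, n, n] <- 1
  consistency <- 100 * (1 - sum((G - T_)^2) / N)
  structure(list(n_components = N, core_consistency = consistency,
                 fit = explained_variance(tensor, model), core = G,
                 rank_deficient = rank_def),
            class = "corcondia_result")
}

#' @export
print.corcondia_result <- function(x, ...) {
  cat(sprintf("corcondia: N=%d, core consistency %.2f%%, fit %.4f\n",
              x$n_components, x$core_consistency, x$fit))
  invisible(x)
}

#' Least-squares trilinear (PARAFAC) fit by alternating least squares
#'
#' Unconstrained PARAFAC-ALS with deterministic SVD initialization. This is
#' the fitting procedure the core-consistency diagnostic is defined on:
#' unlike ATLD, a least-squares fit forces surplus components to chase noise,
#' so its core collapses sharply when the component number is overestimated,
#' which is what makes the 60-percent rule selective.
#'
#' @param tensor An `eem_tensor`.
#' @param n_components Component number.
#' @param tol Relative change of the residual sum of squares (w.r.t. the
#'   total sum of squares) at which iteration stops.
#' @param max_iter Iteration cap. The default is generous because ALS can
#'   pass through long low-progress plateaus ("swamps") when factors are
#'   correlated across modes; stopping inside one leaves a spuriously
#'   degenerate solution.
#' @return A `trilinear_model` (same conventions as [atld_fit()]).
#' @export
parafac_als <- function(tensor, n_components, tol = 1e-9, max_iter = 1000) {
  stopifnot(inherits(tensor, "eem_tensor"))
  X <- tensor$data
  if (any(!is.finite(X)))
    stop("parafac_als: tensor contains non-finite entries", call. = FALSE)
  ssx <- sum(X^2)
  if (ssx == 0) stop("parafac_als: all-zero tensor", call. = FALSE)
  N <- as.integer(n_components)
  d <- dim(X); I <- d[1]; J <- d[2]; K <- d[3]
  X1 <- unfold(X, 1); X2 <- unfold(X, 2); X3 <- unfold(X, 3)
  kr <- function(P, Q)
    vapply(seq_len(ncol(P)), function(n) kronecker(P[, n], Q[, n]),
           numeric(nrow(P) * nrow(Q)))
  pad <- function(M, rows) if (ncol(M) < N)
    cbind(M, matrix(1e-8, rows, N - ncol(M))) else M
  A <- pad(svd(X1, nu = min(N, I))$u, I)
  B <- pad(svd(X2, nu = min(N, J))$u, J)
  E <- pad(svd(X3, nu = min(N, K))$u, K)
  # exact normal-equation solves (no truncation): when the component number
  # is overestimated the equations become near-singular and the surplus
  # components blow up, which is exactly what makes the core-consistency
  # diagnostic collapse for overfactored least-squares fits
  slv <- function(M, Y) tryCatch(t(solve(M, t(Y))), error = function(e)
    Y %*% pinv_trunc(M, N))
  loss_history <- numeric(0)
  prev <- Inf
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    A <- slv(crossprod(E) * crossprod(B), X1 %*% kr(E, B))
    B <- slv(crossprod(A) * crossprod(E), X2 %*% kr(A, E))
    E <- slv(crossprod(B) * crossprod(A), X3 %*% kr(B, A))
    rss <- ssx - 2 * sum(X3 * (E %*% t(kr(B, A)))) +
      sum(crossprod(E) * crossprod(B) * crossprod(A))
    loss_history <- c(loss_history, rss)
    n_iter <- it
    if (is.finite(prev) && abs(prev - rss) / ssx < tol) break
    prev <- rss
  }
  nb <- sqrt(colSums(B^2)); nb[nb == 0] <- 1
  ne <- sqrt(colSums(E^2)); ne[ne == 0] <- 1
  B <- sweep(B, 2, nb, "/"); E <- sweep(E, 2, ne, "/")
  A <- sweep(A, 2, nb * ne, "*")
  for (n in seq_len(N)) {
    if (B[which.max(abs(B[, n])), n] < 0) { B[, n] <- -B[, n]; A[, n] <- -A[, n] }
    if (E[which.max(abs(E[, n])), n] < 0) { E[, n] <- -E[, n]; A[, n] <- -A[, n] }
  }
  ord <- order(colSums(A^2), decreasing = TRUE)
  structure(list(n_components = N,
                 em_loadings = B[, ord, drop = FALSE],
                 ex_loadings = E[, ord, drop = FALSE],
                 scores = A[, ord, drop = FALSE],
                 n_iter = n_iter, loss_history = loss_history,
                 explained_variance = 1 - loss_history[n_iter] / ssx,
                 sample_ids = tensor$samples, grid = tensor$grid),
            class = "trilinear_model")
}

#' Scan component numbers and select by core consistency
#'
#' Fits the tensor at each candidate component number, computes the
#' core-consistency diagnostic, and selects the largest N whose consistency
#' reaches `threshold` (percent). Candidate fits use the least-squares
#' procedure ([parafac_als()]) by default: the diagnostic is defined on
#' least-squares cores, and ATLD's tolerance of overestimated component
#' numbers -- a virtue when decomposing -- keeps its overfactored cores
#' benign, which would defeat the threshold rule. The final decomposition at
#' the selected N is then performed with ATLD. When the best attainable fit
#' is poor (explained variance below 0.5) the result carries a low-fit
#' warning flag.
#'
#' @param tensor An `eem_tensor`.
#' @param n_range Integer vector of candidate component numbers.
#' @param config An [atld_config()] (used when `fit_method = "atld"`).
#' @param threshold Acceptance threshold in percent (default 60).
#' @param fit_method `"als"` (default) or `"atld"`.
#' @return Object of class `corcondia_scan`: `results` (data.frame with
#'   `n_components`, `core_consistency`, `fit`), `selected`, and `low_fit`.
#' @export
scan_components <- function(tensor, n_range = 1:8, config = atld_config(),
                            threshold = 60, fit_method = c("als", "atld")) {
  fit_method <- match.arg(fit_method)
  n_range <- sort(unique(as.integer(n_range)))
  if (length(n_range) == 0L)
    stop("scan_components: empty candidate range", call. = FALSE)
  rows <- lapply(n_range, function(N) {
    m <- if (fit_method == "als") parafac_als(tensor, N) else
      atld_fit(tensor, N, config)
    cc <- suppressWarnings(corcondia(tensor, m))
    data.frame(n_components = N, core_consistency = cc$core_consistency,
               fit = cc$fit)
  })
  res <- do.call(rbind, rows)
  # the component number is increased until the core consistency first drops
  # below the acceptance threshold; the selected N is the largest candidate
  # in the initial run of acceptable values (an isolated re-ascent above the
  # threshold beyond the drop reflects a fortuitously benign overfactored
  # solution, not restored trilinearity)
  acceptable <- cumprod(res$core_consistency >= threshold) == 1
  selected <- if (any(acceptable))
    max(res$n_components[acceptable]) else min(n_range)
  low_fit <- res$fit[res$n_components == selected] < 0.5
  if (low_fit) {
    # with most variance unexplained the trilinearity diagnostic carries no
    # information; the selection degenerates to the smallest candidate
    selected <- min(n_range)
    warning(sprintf(
      "scan_components: explained variance %.2f at best candidate; data may not be trilinear",
      max(res$fit)))
  }
  structure(list(results = res, selected = selected, low_fit = low_fit),
            class = "corcondia_scan")
}

#' @export
print.corcondia_scan <- function(x, ...) {
  shown <- x$results
  shown$core_consistency <- round(shown$core_consistency, 2)
  shown$fit <- round(shown$fit, 4)
  print(shown, row.names = FALSE)
  cat(sprintf("selected N = %d%s\n", x$selected,
              if (x$low_fit) " (low fit)" else ""))
  invisible(x)
}

perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
          sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
  }))
}

cosine_cols <- function(M1, M2) {
  # absolute cosine between corresponding columns
  num <- abs(colSums(M1 * M2))
  den <- sqrt(colSums(M1^2) * colSums(M2^2))
  den[den == 0] <- 1
  num / den
}

#' Tucker congruence between two trilinear models
#'
#' Matches the components of two models (or of a model and a ground-truth
#' factor set) by the permutation maximizing the mean, over components, of
#' the product of the per-mode absolute cosines, and reports the per-mode
#' congruences under that matching. The permutation search is exhaustive
#' (intended for N <= 6).
#'
#' @param model_a,model_b `trilinear_model` objects, or lists with elements
#'   `em_loadings`, `ex_loadings`, `scores`.
#' @return List with `permutation` (columns of `model_b` matched to each
#'   component of `model_a`), `congruence` (3 x N matrix, rows = scores,
#'   emission, excitation), and `mean_congruence`.
#' @export
congruence <- function(model_a, model_b) {
  N <- ncol(model_a$em_loadings)
  if (ncol(model_b$em_loadings) != N)
    stop("congruence: models have different component numbers", call. = FALSE)
  if (N > 6L)
    stop("congruence: exhaustive matching limited to N <= 6", call. = FALSE)
  perms <- perm_matrix(N)
  best <- NULL; best_val <- -Inf; best_perm <- NULL
  for (row in seq_len(nrow(perms))) {
    p <- perms[row, ]
    ca <- cosine_cols(model_a$scores, model_b$scores[, p, drop = FALSE])
    cb <- cosine_cols(model_a$em_loadings, model_b$em_loadings[, p, drop = FALSE])
    ce <- cosine_cols(model_a$ex_loadings, model_b$ex_loadings[, p, drop = FALSE])
    val <- mean(ca * cb * ce)
    if (val > best_val) {
      best_val <- val
      best <- rbind(scores = ca, emission = cb, excitation = ce)
      best_perm <- p
    }
  }
  list(permutation = best_perm, congruence = best, mean_congruence = best_val)
}

#' Export a trilinear model as delimited text
#'
#' Writes one CSV per mode (emission loadings, excitation loadings, sample
#' scores) with wavelengths or sample ids as the first column, plus the
#' iteration residual trace, so downstream spectra and intensity plots can be
#' rebuilt from plain files.
#'
#' @param model A `trilinear_model`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
export_model <- function(model, dir, prefix = "atld") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cn <- paste0("component_", seq_len(model$n_components))
  em <- data.frame(emission_nm = model$grid$emission, model$em_loadings)
  ex <- data.frame(excitation_nm = model$grid$excitation, model$ex_loadings)
  sc <- data.frame(sample_id = model$sample_ids, model$scores)
  names(em)[-1] <- cn; names(ex)[-1] <- cn; names(sc)[-1] <- cn
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("em_loadings", "ex_loadings", "scores",
                                   "residual_trace"), ".csv"))
  utils::write.csv(em, paths[1], row.names = FALSE)
  utils::write.csv(ex, paths[2], row.names = FALSE)
  utils::write.csv(sc, paths[3], row.names = FALSE)
  utils::write.csv(data.frame(iteration = seq_along(model$loss_history),
                              rss = model$loss_history),
                   paths[4], row.names = FALSE)
  invisible(paths)
}
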