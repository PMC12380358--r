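# well-separated two-group toy table
toy_table <- function(n_per = 10, gap = 10, p = 3, seed = 40) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = gap), n_per))
  feature_table(paste0("s", seq_len(2 * n_per)),
                rep(c("a", "b"), each = n_per), X)
}

test_that("autoscaling centres, scales, and is idempotent", {
  ft <- feature_table(c("x", "y"), c("a", "b"), cbind(v = c(1, 3)))
  expect_warning(a1 <- autoscale(ft), NA)
  expect_equal(as.vector(a1$features), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  twice <- autoscale(a1)
  expect_equal(twice$features, a1$features, tolerance = 1e-12)
  const <- feature_table(c("x", "y", "z"), c("a", "b", "a"),
                         cbind(u = c(1, 2, 3), w = c(5, 5, 5)))
  expect_warning(ac <- autoscale(const), "constant")
  expect_equal(as.vector(ac$features[, "w"]), c(0, 0, 0))
})

test_that("pca fractions behave on symmetric, rank-1 and truncated inputs", {
  set.seed(41)
  iso <- feature_table(paste0("s", 1:500), rep("a", 500),
                       matrix(rnorm(1000), 500))
  fr <- pca_features(iso)$var_fraction
  expect_equal(fr, c(0.5, 0.5), tolerance = 0.1)
  rank1 <- feature_table(paste0("s", 1:10), rep("a", 10),
                         cbind(1:10, 2 * (1:10), -1 * (1:10)))
  expect_equal(pca_features(rank1)$var_fraction[1], 1, tolerance = 1e-10)
  expect_warning(tr <- pca_features(rank1, n_pc = 3), "truncated")
  expect_lte(ncol(tr$scores), 2)
})

test_that("hierarchical clustering recovers separated groups deterministically", {
  ft <- toy_table(gap = 30)
  cl <- hier_cluster(autoscale(ft), "ward", k = 2)
  expect_equal(length(unique(cl[1:10])), 1)
  expect_equal(length(unique(cl[11:20])), 1)
  expect_false(cl[1] == cl[11])
  expect_identical(cl, hier_cluster(autoscale(ft), "ward", k = 2))
  singletons <- hier_cluster(ft, "average", k = nrow(ft$features))
  expect_equal(length(unique(singletons)), nrow(ft$features))
})

test_that("kNN votes by distance with nearest-neighbour tie-break", {
  # 1-D two-class data {0,0,1,1}, query 0.4, k=3: neighbours {0,0,1} -> class a
  tr <- feature_table(paste0("t", 1:4), c("a", "a", "b", "b"),
                      cbind(x = c(0, 0, 1, 1)))
  qu <- feature_table("q", "a", cbind(x = 0.4))
  out <- knn_classify(tr, qu, k = 3)
  expect_equal(as.character(out$predictions), "a")
  expect_equal(out$neighbors$distance, sort(out$neighbors$distance))
  # query equal to a training point at k = 1: that class at distance 0
  out1 <- knn_classify(tr, feature_table("q0", "b", cbind(x = 1)), k = 1)
  expect_equal(as.character(out1$predictions), "b")
  expect_equal(out1$neighbors$distance[1], 0)
  # k = 2 tie between a and b: nearest neighbour (class b) wins
  out2 <- knn_classify(tr, feature_table("qt", "b", cbind(x = 0.6)), k = 2)
  expect_equal(as.character(out2$predictions), "b")
  expect_error(knn_classify(tr, qu, k = 0), ">= 1")
  expect_error(knn_classify(tr, qu, k = 9), "exceeds")
})

test_that("the kNN neighbour report lists the seven nearest with ids and distances", {
  fx <- study_fixture()
  out <- knn_classify(fx$train, fx$holdout, k = 3)
  expect_equal(sort(unique(out$neighbors$rank)), 1:7)
  expect_equal(nrow(out$neighbors), 4 * 7)
  # every holdout's nearest neighbours come from its own generating origin
  first <- out$neighbors[out$neighbors$rank == 1, ]
  expect_equal(first$neighbor_class,
               as.character(fx$holdout$labels))
})

test_that("random forests separate well-separated classes and are seed-deterministic", {
  ft <- toy_table(gap = 30)
  rf1 <- rf_fit(ft, n_trees = 100, seed = 7)
  expect_equal(unname(rf1$forest$err.rate[100, "OOB"]), 0)
  rf2 <- rf_fit(ft, n_trees = 100, seed = 7)
  expect_identical(rf1$importance, rf2$importance)
  expect_equal(sum(rf1$importance), 1, tolerance = 1e-12)
  expect_true(all(rf1$importance >= 0))
  one_class <- feature_table(c("u", "v"), c("a", "a"), cbind(1:2))
  expect_error(rf_fit(one_class, seed = 1), "two classes")
})

test_that("PLS-DA separates two classes and reduces to least squares at full rank", {
  ft <- toy_table(gap = 30)
  m <- plsda_fit(ft, n_latent = 1)
  expect_equal(as.character(predict(m, ft$features)),
               as.character(ft$labels))
  expect_error(plsda_fit(ft, n_latent = 0), ">= 1")
  # at full rank the fitted indicators equal the OLS fit on the scaled data
  set.seed(43)
  ft3 <- feature_table(paste0("s", 1:30), rep(c("a", "b", "c"), 10),
                       matrix(rnorm(90), 30))
  mf <- plsda_fit(ft3, n_latent = 3)
  X <- scale(ft3$features)
  Y <- outer(as.character(ft3$labels), c("a", "b", "c"), `==`) * 1
  ols <- cbind(1, X) %*% solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), Y))
  pls_pred <- X %*% mf$coefficients
  pls_pred <- sweep(pls_pred, 2, mf$ymean, "+")
  expect_equal(pls_pred, ols, tolerance = 1e-8, ignore_attr = TRUE)
  # balanced classes at full rank: indicator rows sum to about one
  expect_equal(rowSums(pls_pred), rep(1, 30), tolerance = 1e-8)
  # rejection threshold: the midpoint between the classes has indicators
  # near 0.5 each and is rejected at a higher threshold
  mid <- matrix(colMeans(ft$features), 1)
  pr <- predict(m, mid, threshold = 0.9)
  expect_equal(as.character(pr), "unassigned")
  expect_false("unassigned" %in% predict(m, ft$features, threshold = 0.9))
})

test_that("LV selection applies the one-standard-error parsimony rule", {
  ft <- toy_table(gap = 30)
  single <- select_lv(ft, lv_range = 2, seed = 1)
  expect_equal(single$selected, 2)
  # perfect fit from LV 1 on: smallest LV achieving the best accuracy
  sel <- select_lv(ft, lv_range = 1:3, seed = 1)
  expect_equal(sel$selected, 1)
  expect_error(select_lv(ft, lv_range = integer(0)), "empty")
})

test_that("classification reports reconcile with their confusion matrices", {
  truth <- c("a", "a", "a", "b", "b", "c", "c", "c")
  pred <- c("a", "a", "b", "b", "unassigned", "c", "c", "a")
  rep_ <- classification_report(truth, pred)
  expect_equal(unname(rowSums(rep_$confusion)), c(3, 2, 3))
  m <- rep_$metrics
  # hand-computed one-vs-rest values
  expect_equal(m$sensitivity[m$class == "a"], 100 * 2 / 3)
  expect_equal(m$specificity[m$class == "a"], 100 * 4 / 5)  # 1 FP among 5
  expect_equal(m$reject_rate[m$class == "b"], 100 * 1 / 2)
  expect_equal(m$false_recognition_rate[m$class == "c"], 100 * 1 / 3)
  expect_equal(rep_$accuracy, 100 * 5 / 8)
  # no rejections: accuracy equals trace / total
  rep2 <- classification_report(truth, truth)
  expect_equal(rep2$accuracy, 100)
  expect_equal(sum(diag(rep2$confusion)), 8)
})

test_that("cross-validation refits scaling per fold and kNN k=1 resubstitutes perfectly", {
  ft <- toy_table(gap = 30)
  cv <- cross_validate(ft, list(method = "knn", k = 1), scheme = "loo")
  expect_equal(cv$accuracy, 100)
  # resubstitution with k = 1 is trivially perfect (self-match at distance 0)
  self <- knn_classify(ft, ft, k = 1)
  expect_equal(as.character(self$predictions), as.character(ft$labels))
  # stratified scheme keeps marginals intact
  cvs <- cross_validate(ft, list(method = "rf", seed = 1),
                        scheme = "stratified", k_folds = 5, seed = 2)
  expect_equal(unname(rowSums(cvs$confusion)), c(10, 10))
  # a singleton class falls back to LOO with a warning
  ft1 <- feature_table(paste0("s", 1:7), c(rep("a", 6), "b"),
                       cbind(c(rnorm(6), 50)))
  expect_warning(cross_validate(ft1, list(method = "knn", k = 1),
                                scheme = "stratified"),
                 "single member")
})

test_that("identical-feature classes score at chance and label permutation destroys accuracy", {
  set.seed(44)
  # features carry no class information
  junk <- feature_table(paste0("s", 1:40), rep(c("a", "b"), 20),
                        matrix(rnorm(120), 40))
  cv <- cross_validate(junk, list(method = "knn", k = 3))
  # binomial 95% band around chance (p = 0.5, n = 40)
  expect_lt(abs(cv$accuracy - 50), 100 * 1.96 * sqrt(0.25 / 40) * 2)
  # permuting real labels of separable data drives accuracy to chance
  ft <- toy_table(gap = 30)
  set.seed(45)
  accs <- replicate(30, {
    perm <- feature_table(ft$ids, sample(as.character(ft$labels)),
                          ft$features)
    cross_validate(perm, list(method = "knn", k = 3))$accuracy
  })
  expect_lt(mean(accs), 65)
  expect_gt(mean(accs), 35)
})

test_that("accuracy rises monotonically with the generator's group separation", {
  accs <- sapply(c(0.1, 0.4, 1), function(sc) {
    design <- study_design(seed = 9, between_group_scale = sc)
    sim <- simulate_dataset(design)
    labels <- sim$truth$labels
    tr <- which(labels$role == "train")
    ft <- feature_table(labels$sample_id[tr], labels$origin[tr],
                        sim$truth$concentrations[tr, ])
    cross_validate(ft, list(method = "rf", seed = 1), seed = 1)$accuracy
  })
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[3], 100)
})

test_that("external validation handles holdout, resubstitution and empty input", {
  ft <- toy_table(gap = 30)
  resub <- external_validate(ft, ft, list(method = "rf", seed = 1))
  expect_equal(resub$accuracy, 100)
  empty <- feature_table(character(0), character(0),
                         matrix(0, 0, ncol(ft$features)))
  expect_error(external_validate(ft, empty, list(method = "knn", k = 1)),
               "empty holdout")
})
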