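make_design <- function(n_pairs, n_batches = 1) {
  pats <- sprintf("p%02d", seq_len(n_pairs))
  suppressWarnings(cohort_design(
    sample_id = c(paste0(pats, "_T"), paste0(pats, "_N")),
    patient_id = rep(pats, 2),
    tissue = rep(c("tumor", "nat"), each = n_pairs),
    batch = paste0("B", rep_len(seq_len(n_batches), 2 * n_pairs))))
}

test_that("per-feature AUC screens observed cells and skips one-class features", {
  d <- make_design(10)
  v <- rbind(ind = as.numeric(d$tissue == "tumor"),   # tissue indicator
             noise = rnorm(20))
  colnames(v) <- d$sample_id
  prov <- v * 0
  prov["noise", d$tissue == "nat"] <- 1  # only tumor cells observed
  pm <- structure(list(values = v, provenance = prov, glycoform = NULL,
                       design = d), class = "processed_matrix")
  res <- per_feature_auc(pm)
  expect_equal(res$auc[res$feature == "ind"], 1)
  expect_false("noise" %in% res$feature)
  expect_true("noise" %in% attr(res, "skipped"))
})

test_that("permuted labels give mean per-feature AUC near 0.5", {
  set.seed(21)
  d <- make_design(20)
  v <- matrix(rnorm(500 * 40), 500, 40,
              dimnames = list(paste0("f", 1:500), d$sample_id))
  pm <- structure(list(values = v, provenance = v * 0, glycoform = NULL,
                       design = d), class = "processed_matrix")
  res <- per_feature_auc(pm)
  expect_lt(abs(mean(res$auc) - 0.5), 0.02)
})

test_that("top glycoprotein selection ranks, gates on detection, and breaks ties lexicographically", {
  keys <- data.frame(
    protein = c("B", "B", "B", "A", "A", "A", "C"),
    site = c(10L, 10L, 30L, 10L, 10L, 30L, 10L),
    peptide = "AANKT",
    composition = c("Hex[5]HexNAc[2]NeuAc[0]Fuc[0]",
                    "Hex[6]HexNAc[2]NeuAc[0]Fuc[0]",
                    "Hex[5]HexNAc[4]NeuAc[1]Fuc[0]",
                    "Hex[5]HexNAc[2]NeuAc[0]Fuc[0]",
                    "Hex[7]HexNAc[2]NeuAc[0]Fuc[0]",
                    "Hex[5]HexNAc[4]NeuAc[0]Fuc[1]",
                    "Hex[5]HexNAc[2]NeuAc[0]Fuc[0]"))
  ab <- matrix(1, 7, 10, dimnames = list(NULL, paste0("s", 1:10)))
  ab[7, 2:10] <- NA          # C detected in 10% of samples only
  ab[4:6, ] <- 5             # A has the higher total abundance
  igp <- igp_table(keys, ab)
  # by n_igps: A and B tie at 3 IGPs -> lexicographic, A first
  expect_identical(select_top_glycoproteins(igp, k = 2, min_detect = 0.5),
                   c("A", "B"))
  # k = 1 by abundance: A wins on summed intensity
  expect_identical(select_top_glycoproteins(igp, k = 1, min_detect = 0.5,
                                            rank_by = "abundance"), "A")
  # detection gate removes C even when ranked
  expect_false("C" %in% select_top_glycoproteins(igp, k = 3, min_detect = 0.9))
  expect_warning(select_top_glycoproteins(igp, k = 10), "fewer than k")
})

test_that("ridge IRLS recovers known coefficients and satisfies the score equations", {
  set.seed(31)
  n <- 500
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  eta <- 0.3 + X %*% c(1, -2)
  y <- rbinom(n, 1, stats::plogis(eta))
  fit <- fit_logistic(X, y, ridge = 1e-4)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients["x1"]), 1, tolerance = 0.3)
  expect_equal(unname(fit$coefficients["x2"]), -2, tolerance = 0.3)
  # penalized score equations hold at the optimum (standardized scale)
  ctr <- fit$center; scl <- fit$scale
  Xs <- cbind(1, sweep(sweep(X, 2, ctr), 2, scl, "/"))
  mu <- stats::plogis(drop(Xs %*% fit$beta_std))
  grad <- drop(t(Xs) %*% (y - mu)) - c(0, 1e-4 * fit$beta_std[-1])
  expect_lt(max(abs(grad)), 1e-6)
  # matches an unpenalized glm fit closely at this tiny ridge
  ref <- stats::glm(y ~ X, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)[-1]),
               tolerance = 1e-3)
})

test_that("intercept-only balanced fit predicts exactly 0.5; separation is handled", {
  y <- rep(c(1, 0), 10)
  X0 <- matrix(numeric(0), nrow = 20, ncol = 0)
  fit <- fit_logistic(X0, y)
  expect_equal(unname(predict(fit, X0)), rep(0.5, 20), tolerance = 1e-12)
  # one perfectly separating feature still converges with ridge > 0
  Xs <- matrix(c(rep(1, 10), rep(-1, 10)), dimnames = list(NULL, "sep"))
  fit2 <- fit_logistic(Xs, rep(c("tumor", "nat"), each = 10), ridge = 1e-2)
  expect_true(fit2$converged)
  expect_equal(auc_mann_whitney(predict(fit2, Xs),
                                rep(c("tumor", "nat"), each = 10)), 1)
})

test_that("in-sample AUC of the combination is at least that of its best member", {
  set.seed(41)
  d <- make_design(25)
  lab <- d$tissue
  X <- cbind(good = rnorm(50) + 2 * (lab == "tumor"),
             weak = rnorm(50) + 0.3 * (lab == "tumor"))
  rownames(X) <- d$sample_id
  fit <- fit_logistic(X, lab)
  single <- max(auc_mann_whitney(X[, "good"], lab),
                auc_mann_whitney(X[, "weak"], lab))
  expect_gte(auc_mann_whitney(predict(fit, X), lab), single - 0.02)
})

test_that("stratified split keeps patients intact and tissue proportions within one sample", {
  d <- make_design(45)
  sp <- stratified_split(d, 0.3, seed = 7)
  expect_equal(sort(c(sp$train, sp$test)), sort(d$sample_id))
  expect_lte(abs(length(sp$test) - 27), 1)
  # both tissues of each patient on the same side
  pt <- d$patient_id[match(sp$test, d$sample_id)]
  expect_true(all(!(unique(pt) %in% d$patient_id[match(sp$train, d$sample_id)])))
  # tissue balance in the test set
  tt <- table(d$tissue[match(sp$test, d$sample_id)])
  expect_lte(abs(tt["tumor"] - tt["nat"]), 1)
  # deterministic per seed, different across seeds
  expect_identical(sp, stratified_split(d, 0.3, seed = 7))
  expect_false(identical(sp, stratified_split(d, 0.3, seed = 8)))
  expect_error(stratified_split(d, 0), "test_fraction")
})

test_that("cross-validated AUC separates signal from noise and is seed-deterministic", {
  set.seed(51)
  d <- make_design(25)
  lab <- d$tissue
  Xsig <- matrix(rnorm(50, sd = 0.5) + 10 * (lab == "tumor"),
                 dimnames = list(d$sample_id, "f"))
  cv <- cross_validated_auc(Xsig, lab, d, folds = 5, seed = 2)
  expect_equal(cv$mean_auc, 1)
  Xnull <- matrix(rnorm(50), dimnames = list(d$sample_id, "f"))
  cvn <- cross_validated_auc(Xnull, lab, d, folds = 5, seed = 2)
  expect_lt(abs(cvn$mean_auc - 0.5), 0.25)
  expect_identical(cvn, cross_validated_auc(Xnull, lab, d, folds = 5, seed = 2))
})
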