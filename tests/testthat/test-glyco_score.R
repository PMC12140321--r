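test_that("glycoform medians summarise each class per sample, mean-of-middle for even counts", {
  keys <- data.frame(protein = paste0("P", 1:5), site = 10L, peptide = "AANKT",
                     composition = c("Hex[5]HexNAc[2]NeuAc[0]Fuc[0]",  # H
                                     "Hex[6]HexNAc[2]NeuAc[0]Fuc[0]",  # H
                                     "Hex[7]HexNAc[2]NeuAc[0]Fuc[0]",  # H
                                     "Hex[5]HexNAc[4]NeuAc[1]Fuc[0]",  # A
                                     "Hex[5]HexNAc[4]NeuAc[2]Fuc[0]")) # A
  ab <- matrix(c(1, 3, 5, 2, 4,
                 2, 2, 2, 10, 20), ncol = 2,
               dimnames = list(NULL, c("x", "y")))
  igp <- igp_table(keys, t(t(ab)))
  med <- suppressWarnings(glycoform_medians(igp))
  expect_equal(med["x", "H"], 3)    # median of 1,3,5
  expect_equal(med["x", "A"], 3)    # even count {2,4} -> 3
  expect_equal(med["y", "A"], 15)
  expect_true(all(is.na(med[, "F"])))
  expect_true("F" %in% attr(med, "missing_classes"))

  # permuting IGP rows leaves medians unchanged
  perm <- c(3, 1, 5, 2, 4)
  igp2 <- igp_table(keys[perm, ], igp$abundance[perm, ])
  expect_equal(suppressWarnings(glycoform_medians(igp2)), med)
})

test_that("ratio scores are scale-invariant sums of disjoint class medians", {
  med <- matrix(c(2, 1, 1,
                  4, 2, 2), nrow = 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("H", "A", "N")))
  sc <- ratio_score(med, "H", c("A", "N"))
  expect_equal(unname(sc), c(1, 1))  # doubling all medians: same score
  expect_error(ratio_score(med, "A", "A"), "disjoint")
  expect_error(ratio_score(med, character(0), "A"), "non-empty")
  med2 <- med; med2["s1", c("A", "N")] <- 0
  expect_warning(sc2 <- ratio_score(med2, "H", c("A", "N")), "s1")
  expect_true(is.na(sc2["s1"]))
})

test_that("Mann-Whitney AUC equals brute-force concordance, with invariances", {
  expect_equal(auc_mann_whitney(c(3, 1, 2, 0),
                                c("tumor", "tumor", "nat", "nat")), 0.75)
  expect_equal(auc_mann_whitney(c(5, 6, 1, 2),
                                c("tumor", "tumor", "nat", "nat")), 1.0)
  set.seed(99)
  for (i in 1:200) {
    nt <- sample(2:20, 1); nn <- sample(2:20, 1)
    s <- c(rnorm(nt), rnorm(nn))
    if (i %% 3 == 0) s <- round(s)  # inject ties
    lab <- rep(c("tumor", "nat"), c(nt, nn))
    expect_equal(auc_mann_whitney(s, lab), brute_auc(s, lab),
                 tolerance = 1e-12)
  }
  # invariant under strictly monotone transform
  s <- rnorm(30); lab <- rep(c("tumor", "nat"), 15)
  expect_equal(auc_mann_whitney(s, lab), auc_mann_whitney(exp(s), lab))
  expect_error(auc_mann_whitney(1:3, rep("tumor", 3)), "both classes")
})

test_that("ratio combination enumeration matches the inclusion-exclusion count", {
  set.seed(1)
  d <- suppressWarnings(cohort_design(
    sample_id = paste0("s", 1:10), patient_id = paste0("p", 1:10),
    tissue = rep(c("tumor", "nat"), 5), batch = "B1"))
  for (k in 2:5) {
    classes <- c("A", "F", "FA", "H", "N")[1:k]
    med <- matrix(abs(rnorm(10 * k)) + 0.1, 10, k,
                  dimnames = list(d$sample_id, classes))
    combos <- enumerate_ratio_combinations(med, d)
    expect_equal(nrow(combos), 3^k - 2 * 2^k + 1)
    # brute-force cross-check of the pair count
    subs <- unlist(lapply(1:k, function(r) utils::combn(classes, r, simplify = FALSE)),
                   recursive = FALSE)
    n_pairs <- sum(vapply(subs, function(a) {
      sum(vapply(subs, function(b) length(intersect(a, b)) == 0, logical(1)))
    }, numeric(1)))
    expect_equal(nrow(combos), n_pairs)
    # ranked by AUC descending
    expect_true(all(diff(combos$auc) <= 1e-12))
  }
})

test_that("the top enumerated combination beats every single-class median marker", {
  set.seed(2)
  d <- suppressWarnings(cohort_design(
    sample_id = paste0("s", 1:20), patient_id = paste0("p", 1:20),
    tissue = rep(c("tumor", "nat"), 10), batch = "B1"))
  med <- matrix(abs(rnorm(100)) + 0.1, 20, 5,
                dimnames = list(d$sample_id, c("A", "F", "FA", "H", "N")))
  med[d$tissue == "tumor", "A"] <- med[d$tissue == "tumor", "A"] + 1
  combos <- enumerate_ratio_combinations(med, d)
  lab <- d$tissue
  single <- vapply(colnames(med), function(cl) auc_mann_whitney(med[, cl], lab),
                   numeric(1))
  expect_gte(max(combos$auc), max(single))
})

test_that("Youden cutoff maximizes J with ties to the lower threshold", {
  # perfectly separated
  y1 <- youden_cutoff(c(10, 9, 1, 2), c("tumor", "tumor", "nat", "nat"))
  expect_equal(y1$sensitivity, 1)
  expect_equal(y1$specificity, 1)
  expect_equal(y1$youden, 1)
  # identical distributions: no discriminative threshold
  y2 <- youden_cutoff(c(1, 2, 1, 2), c("tumor", "tumor", "nat", "nat"))
  expect_equal(y2$youden, 0)
  # two thresholds tie at J = 0.5; the lower one (0.5) wins
  y3 <- youden_cutoff(c(3, 1, 2, 0), c("tumor", "tumor", "nat", "nat"))
  expect_equal(y3$youden, 0.5)
  expect_equal(y3$threshold, 0.5)
  expect_equal(y3$sensitivity, 1.0)
  expect_equal(y3$specificity, 0.5)
})

test_that("per-class Wilcoxon summary reports group medians and p-values", {
  set.seed(4)
  d <- suppressWarnings(cohort_design(
    sample_id = paste0("s", 1:40), patient_id = paste0("p", 1:40),
    tissue = rep(c("tumor", "nat"), each = 20), batch = "B1"))
  med <- matrix(abs(rnorm(80)) + 1, 40, 2,
                dimnames = list(d$sample_id, c("A", "H")))
  med[d$tissue == "tumor", "A"] <- med[d$tissue == "tumor", "A"] + 3
  tab <- wilcoxon_glycoform_summary(med, d)
  expect_equal(nrow(tab), 2)
  a <- tab[tab$glycoform == "A", ]
  expect_gt(a$tumor_median, a$nat_median)
  expect_lt(a$p_wilcoxon, 0.001)
  expect_gt(tab$p_wilcoxon[tab$glycoform == "H"], 0.05)
})

test_that("score-protein Pearson correlations recover known correlation structure", {
  set.seed(8)
  n <- 90
  score <- stats::setNames(rnorm(n), paste0("s", 1:n))
  rho <- 0.8
  prot <- rbind(
    mirror = score,
    anti = -score,
    corr = rho * score + rnorm(n, sd = sqrt(1 - rho^2)),
    flat = rep(1, n))
  colnames(prot) <- names(score)
  res <- score_protein_correlations(score, prot)
  expect_equal(res$r[res$protein == "mirror"], 1, tolerance = 1e-12)
  expect_equal(res$r[res$protein == "anti"], -1, tolerance = 1e-12)
  expect_equal(res$r[res$protein == "corr"], 0.8, tolerance = 0.1)
  expect_false("flat" %in% res$protein)
  expect_true("flat" %in% attr(res, "skipped"))
  expect_true(all(diff(res$r) <= 0))  # ranked by r descending
})

test_that("PTM ratio is the summed IGP over summed protein intensity per sample", {
  igp <- impute_sample_min(tiny_igp())
  prot <- tiny_protein()
  r <- ptm_ratio(igp, prot)
  expect_equal(unname(r["s1"]), sum(igp$abundance[, "s1"]) / 6)
  # joint scaling leaves it unchanged; scaling IGP alone doubles it
  igp2 <- igp; igp2$abundance <- igp2$abundance * 2
  pm2 <- protein_table(unclass(prot) * 2)
  expect_equal(ptm_ratio(igp2, pm2), r)
  expect_equal(ptm_ratio(igp2, prot), r * 2)
})
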