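test_that("detection filter applies a strict inequality over samples", {
  # 28/90 = 0.3111 > 0.30 kept; 27/90 = 0.30 exactly dropped
  ab <- matrix(NA_real_, 3, 90, dimnames = list(NULL, paste0("s", 1:90)))
  ab[1, 1:28] <- 1
  ab[2, 1:27] <- 1
  ab[3, ] <- 1
  keys <- data.frame(protein = paste0("P", 1:3), site = 10L, peptide = "AANKT",
                     composition = "Hex[5]HexNAc[2]NeuAc[0]Fuc[0]")
  igp <- igp_table(keys, ab)
  kept <- filter_by_detection(igp, 0.30)
  expect_identical(kept$keys$protein, c("P1", "P3"))

  expect_error(filter_by_detection(igp_table(keys[0, ], ab[0, , drop = FALSE])),
               "empty")
  igp_sparse <- igp_table(keys[1:2, ], ab[1:2, , drop = FALSE])
  expect_warning(filter_by_detection(igp_sparse, 0.99), "no feature")
})

test_that("per-sample minimum imputation fills each column with its own minimum", {
  m <- matrix(c(10, NA, 4,
                7, 5, NA), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  keys <- data.frame(protein = paste0("P", 1:3), site = 5L, peptide = "AANKT",
                     composition = "Hex[5]HexNAc[2]NeuAc[0]Fuc[0]")
  igp <- igp_table(keys, m)
  imp <- impute_sample_min(igp)
  expect_equal(unname(imp$abundance[, "a"]), c(10, 4, 4))
  expect_equal(unname(imp$abundance[, "b"]), c(7, 5, 5))
  expect_equal(sum(imp$imputed), 2)
  # idempotent: no missing left, second pass is the identity
  expect_equal(impute_sample_min(imp)$abundance, imp$abundance)

  m2 <- matrix(c(NA, NA, 1, 2), ncol = 2,
               dimnames = list(NULL, c("dead", "ok")))
  igp2 <- igp_table(keys[1:2, ], m2)
  expect_error(impute_sample_min(igp2), "dead")
})

test_that("protein normalization divides cell-wise and respects missingness", {
  igp <- tiny_igp()
  prot <- tiny_protein()
  norm <- suppressWarnings(normalize_to_protein(impute_sample_min(igp), prot))
  expect_equal(unname(norm$abundance[1, "s1"]), 10 / 2)
  expect_equal(unname(norm$abundance[3, "s1"]), 5 / 4)

  # missing protein cell -> missing normalized cell
  pm <- unclass(prot); pm["APMAP", "s2"] <- NA
  norm2 <- normalize_to_protein(igp, protein_table(pm))
  expect_true(all(is.na(norm2$abundance[1:2, "s2"])))

  # unknown accession retained unnormalized with a warning
  pm3 <- unclass(prot)[2, , drop = FALSE]
  expect_warning(norm3 <- normalize_to_protein(igp, protein_table(pm3)),
                 "APMAP")
  expect_equal(norm3$abundance[1, ], igp$abundance[1, ])
  expect_false(norm3$keys$normalized[1])
  expect_true(norm3$keys$normalized[3])
})

test_that("joint per-sample scaling of IGP and protein leaves normalized values unchanged", {
  igp <- impute_sample_min(tiny_igp())
  prot <- tiny_protein()
  base <- suppressWarnings(normalize_to_protein(igp, prot))

  c_scale <- 7.3
  igp2 <- igp; igp2$abundance[, "s2"] <- igp2$abundance[, "s2"] * c_scale
  pm <- unclass(prot); pm[, "s2"] <- pm[, "s2"] * c_scale
  scaled <- suppressWarnings(normalize_to_protein(igp2, protein_table(pm)))
  expect_equal(scaled$abundance, base$abundance, tolerance = 1e-12)
})

test_that("log2 transform validates positivity and carries provenance", {
  igp <- impute_sample_min(tiny_igp())
  pm <- log2_transform(igp, tiny_design())
  expect_equal(unname(pm$values[1, "s1"]), log2(10))
  expect_equal(sum(pm$provenance), 2)
  expect_identical(unname(pm$glycoform), c("H", "A", "F"))

  bad <- igp; bad$abundance[1, 1] <- 0
  expect_error(log2_transform(bad), "non-positive")
  expect_error(log2_transform(tiny_igp()), "impute")
})

test_that("batch centering removes additive offsets exactly and protects the tissue contrast", {
  # 2 batches x 2 tissues, balanced; pure offset delta on batch B2
  set.seed(42)
  d <- suppressWarnings(cohort_design(
    sample_id = paste0("s", 1:8),
    patient_id = paste0("p", 1:8),
    tissue = rep(c("tumor", "nat"), 4),
    batch = rep(c("B1", "B2"), each = 4)))
  delta <- 3
  # pure additive model: feature mean + tissue effect, no noise
  tau <- c(f1 = 2, f2 = -1)
  base <- rbind(f1 = 5 + tau["f1"] * (d$tissue == "tumor"),
                f2 = 1 + tau["f2"] * (d$tissue == "tumor"))
  colnames(base) <- d$sample_id
  shifted <- base
  shifted[, d$batch == "B2"] <- shifted[, d$batch == "B2"] + delta
  pm <- structure(list(values = shifted,
                       provenance = matrix(0, 2, 8, dimnames = dimnames(base)),
                       glycoform = NULL, design = d),
                  class = "processed_matrix")
  cen <- batch_center(pm)
  tissue <- d$tissue
  for (f in 1:2) {
    # tumor - nat mean difference is preserved
    expect_equal(mean(cen$values[f, tissue == "tumor"]) -
                   mean(cen$values[f, tissue == "nat"]),
                 mean(base[f, tissue == "tumor"]) -
                   mean(base[f, tissue == "nat"]), tolerance = 1e-12)
    # offset removed exactly (up to a feature-wide constant)
    resid <- cen$values[f, ] - base[f, ]
    expect_lt(diff(range(resid)), 1e-12)
  }
  # single batch -> identity; idempotent on its own output
  d1 <- d; d1$batch <- "B1"
  expect_equal(batch_center(pm, d1)$values, pm$values)
  expect_equal(batch_center(cen)$values, cen$values, tolerance = 1e-12)
  # constant feature unchanged
  pmc <- pm; pmc$values[1, ] <- 5
  expect_equal(unname(batch_center(pmc)$values[1, ]), rep(5, 8))
})

test_that("batch centering matches limma's removeBatchEffect on a balanced design", {
  skip_if_not_installed("limma")
  set.seed(7)
  d <- suppressWarnings(cohort_design(
    sample_id = paste0("s", 1:12),
    patient_id = paste0("p", 1:12),
    tissue = rep(c("tumor", "nat"), 6),
    batch = rep(c("B1", "B2", "B3"), each = 4)))
  v <- matrix(rnorm(5 * 12), 5, 12, dimnames = list(paste0("f", 1:5), d$sample_id))
  v[, d$batch == "B2"] <- v[, d$batch == "B2"] + 2
  v[, d$batch == "B3"] <- v[, d$batch == "B3"] - 1
  pm <- structure(list(values = v, provenance = v * 0, glycoform = NULL,
                       design = d), class = "processed_matrix")
  ours <- batch_center(pm)$values
  ref <- limma::removeBatchEffect(v, batch = factor(d$batch),
                                  design = stats::model.matrix(~factor(d$tissue)))
  # both estimators remove the same batch means up to a per-feature constant
  for (f in 1:5) {
    expect_lt(diff(range(ours[f, ] - ref[f, ])), 1e-8)
  }
})
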