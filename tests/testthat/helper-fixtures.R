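# Small in-code fixtures shared across test files.

# A 3-IGP, 4-sample table: two proteins, one multi-glycan site.
tiny_igp <- function() {
  keys <- data.frame(
    protein = c("APMAP", "APMAP", "GPX"),
    site = c(196L, 196L, 20L),
    peptide = c("VLNKT", "VLNKT", "AANCS"),
    composition = c("Hex[4]HexNAc[2]NeuAc[0]Fuc[0]",
                    "Hex[5]HexNAc[4]NeuAc[1]Fuc[0]",
                    "Hex[5]HexNAc[4]NeuAc[0]Fuc[1]"),
    stringsAsFactors = FALSE)
  ab <- matrix(c(10, 8, 6, 4,
                 20, NA, 12, 8,
                 5, 4, NA, 2), nrow = 3, byrow = TRUE,
               dimnames = list(NULL, c("s1", "s2", "s3", "s4")))
  igp_table(keys, ab)
}

tiny_design <- function() {
  suppressWarnings(cohort_design(
    sample_id = c("s1", "s2", "s3", "s4"),
    patient_id = c("p1", "p2", "p1", "p2"),
    tissue = c("tumor", "tumor", "nat", "nat"),
    batch = c("B1", "B1", "B1", "B1")))
}

tiny_protein <- function() {
  protein_table(matrix(c(2, 2, 2, 2,
                         4, 4, 4, 4),
                       nrow = 2, byrow = TRUE,
                       dimnames = list(c("APMAP", "GPX"),
                                       c("s1", "s2", "s3", "s4"))))
}

# exact two-sided Wilcoxon rank-sum p by enumerating all group assignments
exact_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2  # observed U
  idx <- utils::combn(N, n)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - n * (n + 1) / 2)
  mu <- n * (N - n) / 2
  mean(abs(u_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# brute-force pairwise-concordance AUC
brute_auc <- function(scores, labels) {
  t <- scores[labels == "tumor"]; n <- scores[labels == "nat"]
  tot <- 0
  for (a in t) for (b in n) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(t) * length(n))
}

# independent glycoform rule table (vectorized, no shared code path)
oracle_glycoform <- function(hex, hexnac, neuac, fuc) {
  ifelse(neuac > 0 & fuc > 0, "FA",
    ifelse(neuac > 0, "A",
      ifelse(fuc > 0, "F",
        ifelse(hexnac == 2, "H", "N"))))
}
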