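#' Glycoform medians, ratio combinations, and ROC screening
#'
#' Each sample is summarised by the median abundance of its IGPs within
#' each glycoform class. Ratio scores divide the summed medians of one
#' class subset by those of a disjoint subset; all such combinations are
#' enumerated and ranked by Mann-Whitney AUC against the tumor/NAT label.
#' The combination with median high-mannose (H) over the summed
#' sialylated (A) and high-HexNAc (N) medians is the named optimum of
#' this family in colorectal tissue.
#'
#' @name glyco_score
NULL

.GLYCOFORM_CLASSES <- c("A", "F", "FA", "H", "N")

#' Per-sample glycoform median table
#'
#' @param igp A classified `igp_table` with imputed (no-missing) linear
#'   abundances, typically protein-normalized.
#' @return Numeric matrix samples x classes (A, F, FA, H, N); classes with
#'   no IGPs are `NA` columns, flagged in attribute `missing_classes`.
#' @export
glycoform_medians <- function(igp) {
  stopifnot(inherits(igp, "igp_table"))
  m <- igp$abundance
  out <- matrix(NA_real_, length(igp$sample_ids), length(.GLYCOFORM_CLASSES),
                dimnames = list(igp$sample_ids, .GLYCOFORM_CLASSES))
  for (cl in .GLYCOFORM_CLASSES) {
    rows <- igp$keys$glycoform == cl
    if (any(rows)) {
      out[, cl] <- apply(m[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    }
  }
  missing <- .GLYCOFORM_CLASSES[colSums(!is.na(out)) == 0]
  if (length(missing)) {
    warning("glycoform class(es) with no IGPs: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  attr(out, "missing_classes") <- missing
  out
}

#' Ratio score from glycoform medians
#'
#' `score(sample) = sum(medians[num]) / sum(medians[den])` with `num` and
#' `den` disjoint non-empty class subsets. A zero denominator yields a
#' missing score with a warning.
#'
#' @param medians Matrix from [glycoform_medians()].
#' @param num,den Character vectors of class labels.
#' @return Named numeric vector of per-sample scores.
#' @export
ratio_score <- function(medians, num, den) {
  classes <- colnames(medians)
  stopifnot(all(num %in% classes), all(den %in% classes))
  if (!length(num) || !length(den)) {
    stop("numerator and denominator must be non-empty", call. = FALSE)
  }
  if (length(intersect(num, den))) {
    stop("numerator and denominator must be disjoint", call. = FALSE)
  }
  top <- rowSums(medians[, num, drop = FALSE])
  bot <- rowSums(medians[, den, drop = FALSE])
  zero <- !is.na(bot) & bot == 0
  if (any(zero)) {
    warning("zero denominator for sample(s): ",
            paste(rownames(medians)[zero], collapse = ", "), call. = FALSE)
    bot[zero] <- NA
  }
  top / bot
}

#' Mann-Whitney AUC of a score against the tumor/NAT label
#'
#' AUC = P(score_tumor > score_nat) + 1/2 P(tie), tumor as the positive
#' class, computed from ranks. Missing scores are dropped. The value is
#' reported as-is and may fall below 0.5 when the score is lower in
#' tumors.
#'
#' @param scores Numeric vector.
#' @param labels Character/factor vector, `"tumor"` / `"nat"`, aligned to
#'   `scores`.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.character(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  nt <- sum(labels == "tumor"); nn <- sum(labels == "nat")
  if (nt == 0 || nn == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == "tumor"]) - nt * (nt + 1) / 2) / (nt * nn)
}

.subsets <- function(x) {
  # all non-empty subsets as a list
  n <- length(x)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    out[[mask]] <- x[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
  }
  out
}

#' Enumerate all glycoform ratio combinations, ranked by AUC
#'
#' All ordered pairs of disjoint non-empty subsets of the available
#' classes (3^k - 2*2^k + 1 pairs for k classes; 180 for all five) are
#' scored on every sample and ranked by raw tumor-positive AUC,
#' descending, ties broken lexicographically. `auc_directed`
#' (`max(auc, 1 - auc)`, the automatic-direction convention of standard
#' ROC software) is reported alongside; the enumeration itself contains
#' each ratio's reciprocal, so the raw ranking loses nothing.
#'
#' @param medians Matrix from [glycoform_medians()].
#' @param design `cohort_design` covering the samples.
#' @return data.frame: `numerator`, `denominator`, `auc`, `auc_directed`,
#'   sorted by `auc` descending.
#' @export
enumerate_ratio_combinations <- function(medians, design) {
  classes <- setdiff(colnames(medians), attr(medians, "missing_classes"))
  if (length(classes) < 2) stop("need >= 2 glycoform classes", call. = FALSE)
  labels <- design$tissue[match(rownames(medians), design$sample_id)]
  if (!all(c("tumor", "nat") %in% labels)) {
    stop("both tissues must be present", call. = FALSE)
  }
  subs <- .subsets(classes)
  rows <- list()
  for (num in subs) {
    for (den in subs) {
      if (length(intersect(num, den))) next
      sc <- suppressWarnings(ratio_score(medians, num, den))
      rows[[length(rows) + 1L]] <- data.frame(
        numerator = paste(num, collapse = "+"),
        denominator = paste(den, collapse = "+"),
        auc = auc_mann_whitney(sc, labels),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$auc_directed <- pmax(out$auc, 1 - out$auc)
  out[order(-out$auc, out$numerator, out$denominator), , drop = FALSE]
}

#' Youden-optimal classification threshold for a score
#'
#' Scans the midpoints between consecutive sorted unique scores, calling
#' a sample tumor when its score exceeds the threshold, and maximizes
#' the Youden index J = sensitivity + specificity - 1. Ties in J go to
#' the lower threshold.
#'
#' @param scores Numeric vector.
#' @param labels `"tumor"` / `"nat"` aligned to `scores`.
#' @return List: `threshold`, `sensitivity`, `specificity`, `accuracy`,
#'   `youden`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.character(labels)
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  nt <- sum(labels == "tumor"); nn <- sum(labels == "nat")
  if (nt == 0 || nn == 0) stop("both classes must be present", call. = FALSE)
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  best <- NULL
  for (th in cand) {
    pred_tumor <- scores > th
    sens <- sum(pred_tumor & labels == "tumor") / nt
    spec <- sum(!pred_tumor & labels == "nat") / nn
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden + 1e-12) {
      best <- list(threshold = th, sensitivity = sens, specificity = spec,
                   accuracy = (sens * nt + spec * nn) / (nt + nn), youden = j)
    }
  }
  best
}

#' Per-class tumor/NAT medians with Wilcoxon p-values
#'
#' @param medians Matrix from [glycoform_medians()].
#' @param design `cohort_design`.
#' @return data.frame: `glycoform`, `tumor_median`, `nat_median`,
#'   `p_wilcoxon`, one row per class with data.
#' @export
wilcoxon_glycoform_summary <- function(medians, design) {
  labels <- design$tissue[match(rownames(medians), design$sample_id)]
  classes <- setdiff(colnames(medians), attr(medians, "missing_classes"))
  out <- lapply(classes, function(cl) {
    v <- medians[, cl]
    data.frame(glycoform = cl,
               tumor_median = stats::median(v[labels == "tumor"], na.rm = TRUE),
               nat_median = stats::median(v[labels == "nat"], na.rm = TRUE),
               p_wilcoxon = wilcoxon_rank_sum(v[labels == "tumor"],
                                              v[labels == "nat"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pearson correlation between a score and every protein
#'
#' @param scores Named per-sample score vector.
#' @param prot A `processed_matrix` of protein log2 values (or a plain
#'   matrix proteins x samples).
#' @param min_samples Minimum shared samples per protein (default 3).
#' @return data.frame `protein`, `r`, `p`, `n`, ranked by `r` descending;
#'   zero-variance proteins are skipped and listed in attribute
#'   `skipped`.
#' @export
score_protein_correlations <- function(scores, prot, min_samples = 3) {
  m <- if (inherits(prot, "processed_matrix")) prot$values else as.matrix(prot)
  shared <- intersect(names(scores), colnames(m))
  if (length(shared) < min_samples) stop("too few shared samples", call. = FALSE)
  m <- m[, shared, drop = FALSE]
  s <- scores[shared]
  rows <- list(); skipped <- character(0)
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    ok <- !is.na(v) & !is.na(s)
    if (sum(ok) < min_samples) next
    if (stats::sd(v[ok]) == 0 || stats::sd(s[ok]) == 0) {
      skipped <- c(skipped, rownames(m)[i]); next
    }
    ct <- stats::cor.test(v[ok], s[ok], method = "pearson")
    rows[[length(rows) + 1L]] <- data.frame(
      protein = rownames(m)[i], r = unname(ct$estimate), p = ct$p.value,
      n = sum(ok), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$r), , drop = FALSE]
  attr(out, "skipped") <- skipped
  out
}

#' Global PTM ratio per sample
#'
#' Total IGP intensity over total protein intensity, per sample; a crude
#' overall glycosylation-load index. (The exact definition used for the
#' published figure is not stated; this summed-intensity ratio is the
#' adopted reading, see the methods vignette.)
#'
#' @param igp `igp_table` (raw linear intensities).
#' @param prot `protein_table`.
#' @return Named numeric vector per sample; `NA` where the protein sum is
#'   zero.
#' @export
ptm_ratio <- function(igp, prot) {
  pm <- unclass(prot)
  shared <- intersect(igp$sample_ids, colnames(pm))
  if (!length(shared)) stop("no shared samples", call. = FALSE)
  top <- colSums(igp$abundance[, shared, drop = FALSE], na.rm = TRUE)
  bot <- colSums(pm[, shared, drop = FALSE], na.rm = TRUE)
  out <- top / bot
  out[bot == 0] <- NA
  out
}
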