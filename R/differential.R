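#' Tumor-vs-NAT differential statistics and the six-group classification
#'
#' Per feature: Brown-Forsythe (Levene) variance test on log2 values, a
#' t-test whose pooled/Welch variant is switched by the Levene p-value,
#' a Wilcoxon rank-sum test, and the median fold change on linear scale.
#' A feature is called significant when p < 0.05 and |FC| > 2
#' (|log2FC| > 1). Glycoproteins are then classified into six groups:
#' direction {Up, Down, NoChange} by the two-thirds sign rule over their
#' IGP log2 fold changes, crossed with glycoform dominance {S, Hm} by
#' counting sialylated (A + FA) versus high-mannose (H) IGPs.
#'
#' @name differential_network
NULL

#' Median fold change (log2) between two groups
#'
#' @param tumor,nat Linear-scale abundance vectors.
#' @return `log2(median(tumor) / median(nat))`.
#' @export
median_fold_change <- function(tumor, nat) {
  tumor <- tumor[is.finite(tumor)]
  nat <- nat[is.finite(nat)]
  if (!length(tumor) || !length(nat)) {
    stop("both groups need at least one finite value", call. = FALSE)
  }
  mn <- stats::median(nat)
  if (mn == 0) stop("median of the reference group is 0", call. = FALSE)
  log2(stats::median(tumor) / mn)
}

#' Brown-Forsythe variance homogeneity test
#'
#' Median-centered Levene test for two groups: absolute deviations from
#' each group median are compared by a one-way ANOVA F test. This is the
#' default behaviour of `car::leveneTest`.
#'
#' @param x,y Numeric vectors, each with >= 2 values.
#' @return Two-sided p-value; 1 when both groups have zero spread.
#' @export
levene_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  zx <- abs(x - stats::median(x))
  zy <- abs(y - stats::median(y))
  n1 <- length(zx); n2 <- length(zy); n <- n1 + n2
  ssw <- sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2)
  gm <- mean(c(zx, zy))
  ssb <- n1 * (mean(zx) - gm)^2 + n2 * (mean(zy) - gm)^2
  if (ssw == 0) {
    # no within-group deviation: identical spreads -> no evidence either way
    return(if (ssb == 0) 1 else 0)
  }
  f <- (ssb / 1) / (ssw / (n - 2))
  stats::pf(f, 1, n - 2, lower.tail = FALSE)
}

#' Two-sample t-test p-value
#'
#' Thin wrapper over [stats::t.test]; Welch by default, pooled-variance
#' when `equal_var = TRUE`. Degenerate input (zero variance in both
#' groups, equal means) returns p = 1.
#'
#' @param x,y Numeric vectors, each with >= 2 values.
#' @param equal_var Use the pooled-variance Student t-test.
#' @return Two-sided p-value.
#' @export
t_test <- function(x, y, equal_var = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = equal_var)$p.value
}

#' Wilcoxon rank-sum p-value
#'
#' Exact p when both groups have at most 50 values and no ties; otherwise
#' the normal approximation with tie and continuity corrections (the
#' behaviour of [stats::wilcox.test]).
#'
#' @param x,y Numeric vectors, each with >= 1 value.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) {
    stop("both groups need at least one value", call. = FALSE)
  }
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) return(1)  # all tied: no evidence
  p <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE)$p.value)
  if (is.nan(p)) 1 else p
}

#' Per-feature differential table
#'
#' For every feature of a processed (log2) matrix: Levene p, t-test p
#' (Welch when Levene p < 0.05, pooled otherwise), Wilcoxon p, the median
#' fold change computed on linear scale (2^log2 values), a BH-adjusted
#' q-value for the headline t-test, and the significance flag
#' (p_t < `p_cut` and |log2FC| > `lfc_cut`).
#'
#' @param m A `processed_matrix` with a design (or pass `design`).
#' @param design `cohort_design`; defaults to `m$design`.
#' @param p_cut Significance p threshold (default 0.05).
#' @param lfc_cut |log2FC| threshold (default 1, i.e. fold change 2).
#' @return data.frame of class `differential_result` with one row per
#'   feature: `feature`, `glycoform`, `log2fc`, `p_levene`, `p_t`,
#'   `p_wilcoxon`, `q_t`, `significant`.
#' @export
differential_table <- function(m, design = m$design, p_cut = 0.05,
                               lfc_cut = 1) {
  stopifnot(inherits(m, "processed_matrix"), !is.null(design))
  idx <- match(colnames(m$values), design$sample_id)
  tissue <- design$tissue[idx]
  if (!all(c("tumor", "nat") %in% tissue)) {
    stop("both tissues must be present", call. = FALSE)
  }
  it <- tissue == "tumor"; inat <- tissue == "nat"
  v <- m$values
  nfeat <- nrow(v)
  out <- data.frame(
    feature = rownames(v) %||% as.character(seq_len(nfeat)),
    glycoform = if (!is.null(m$glycoform)) unname(m$glycoform) else NA_character_,
    log2fc = NA_real_, p_levene = NA_real_, p_t = NA_real_,
    p_wilcoxon = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nfeat)) {
    xt <- v[i, it]; xn <- v[i, inat]
    out$log2fc[i] <- median_fold_change(2^xt, 2^xn)
    if (stats::sd(xt) == 0 && stats::sd(xn) == 0) {
      out$p_levene[i] <- 1
      out$p_t[i] <- if (mean(xt) == mean(xn)) 1 else 0
      out$p_wilcoxon[i] <- wilcoxon_rank_sum(xt, xn)
      next
    }
    out$p_levene[i] <- levene_test(xt, xn)
    out$p_t[i] <- t_test(xt, xn, equal_var = out$p_levene[i] >= 0.05)
    out$p_wilcoxon[i] <- wilcoxon_rank_sum(xt, xn)
  }
  out$q_t <- stats::p.adjust(out$p_t, method = "BH")
  out$significant <- out$p_t < p_cut & abs(out$log2fc) > lfc_cut
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Direction of a glycoprotein from its IGP fold changes
#'
#' Up if at least two-thirds of the IGP log2 fold changes are > 0, Down if
#' at least two-thirds are < 0, otherwise NoChange. Zero fold changes
#' count toward neither direction.
#'
#' @param igp_log2fcs Numeric vector of per-IGP log2 fold changes.
#' @return `"Up"`, `"Down"`, or `"NoChange"`.
#' @export
classify_direction <- function(igp_log2fcs) {
  igp_log2fcs <- igp_log2fcs[is.finite(igp_log2fcs)]
  if (!length(igp_log2fcs)) stop("need at least one fold change", call. = FALSE)
  n <- length(igp_log2fcs)
  if (sum(igp_log2fcs > 0) / n >= 2 / 3) return("Up")
  if (sum(igp_log2fcs < 0) / n >= 2 / 3) return("Down")
  "NoChange"
}

#' Glycoform dominance of a glycoprotein
#'
#' Counts sialylated IGPs (classes A and FA) against high-mannose IGPs
#' (class H); the larger count wins, ties go to S.
#'
#' @param igp_classes Character vector of glycoform class labels.
#' @return `"S"` or `"Hm"`.
#' @export
classify_dominance <- function(igp_classes) {
  if (!length(igp_classes)) stop("need at least one IGP class", call. = FALSE)
  s <- sum(igp_classes %in% c("A", "FA"))
  hm <- sum(igp_classes == "H")
  if (hm > s) "Hm" else "S"
}

#' Six-group glycosite-protein classification
#'
#' Every glycoprotein gets a combined label `direction-dominance`, one of
#' Up-S, Up-Hm, Down-S, Down-Hm, NoChange-S, NoChange-Hm.
#'
#' @param diff A `differential_result` covering the IGP features.
#' @param igp The classified `igp_table` the features came from.
#' @return data.frame `protein`, `direction`, `dominance`, `label`,
#'   `n_igps`; label counts are reported to stderr.
#' @export
build_six_groups <- function(diff, igp) {
  stopifnot(inherits(igp, "igp_table"))
  keys <- igp$keys
  idx <- match(keys$feature_id, diff$feature)
  if (anyNA(idx)) {
    keys <- keys[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  lfc <- diff$log2fc[idx]
  proteins <- unique(keys$protein)
  res <- data.frame(protein = proteins, direction = NA_character_,
                    dominance = NA_character_, n_igps = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(proteins)) {
    sel <- keys$protein == proteins[i]
    res$direction[i] <- classify_direction(lfc[sel])
    res$dominance[i] <- classify_dominance(keys$glycoform[sel])
    res$n_igps[i] <- sum(sel)
  }
  res$label <- paste(res$direction, res$dominance, sep = "-")
  counts <- table(res$label)
  message("six-group counts: ",
          paste(names(counts), counts, sep = "=", collapse = ", "))
  res
}

#' Export the glycoprotein-site-glycan tree for network viewers
#'
#' Writes a SIF edge file (protein -> site, site -> IGP) and a node
#' attribute TSV (node, type, label, log2fc, glycoform, group) loadable
#' by Cytoscape.
#'
#' @param groups Output of [build_six_groups()].
#' @param igp The `igp_table`.
#' @param diff The `differential_result`.
#' @param sif_path,attr_path Output paths.
#' @return Invisibly, a list with the edge and node data frames.
#' @export
export_network <- function(groups, igp, diff, sif_path, attr_path) {
  keys <- igp$keys
  site_id <- sprintf("%s.N%d", keys$protein, keys$site)
  e1 <- unique(data.frame(source = keys$protein, interaction = "has_site",
                          target = site_id, stringsAsFactors = FALSE))
  e2 <- data.frame(source = site_id, interaction = "has_glycan",
                   target = keys$feature_id, stringsAsFactors = FALSE)
  edges <- rbind(e1, e2)
  lfc <- diff$log2fc[match(keys$feature_id, diff$feature)]
  nodes <- rbind(
    data.frame(node = unique(keys$protein), type = "protein",
               log2fc = NA_real_, glycoform = NA_character_,
               group = groups$label[match(unique(keys$protein), groups$protein)],
               stringsAsFactors = FALSE),
    data.frame(node = unique(site_id), type = "site", log2fc = NA_real_,
               glycoform = NA_character_, group = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(node = keys$feature_id, type = "igp", log2fc = lfc,
               glycoform = keys$glycoform, group = NA_character_,
               stringsAsFactors = FALSE))
  utils::write.table(edges, sif_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  .write_df(nodes, attr_path)
  invisible(list(edges = edges, nodes = nodes))
}
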