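#' Detection filtering, imputation, normalization and batch centering
#'
#' The fixed preprocessing order is: detection filter, per-sample minimum
#' imputation, protein normalization, log2 transform, batch centering.
#' Imputation before normalization is the default; the convenience wrapper
#' [preprocess_igp()] exposes the alternative order.
#'
#' @name preprocess
NULL

.abund <- function(table) {
  if (inherits(table, "igp_table")) table$abundance else unclass(table)
}

.set_abund <- function(table, m) {
  if (inherits(table, "igp_table")) {
    table$abundance <- m
    table
  } else {
    cls <- class(table)
    table <- m
    class(table) <- cls
    table
  }
}

#' Filter features by detection fraction
#'
#' Keeps features observed (non-missing) in strictly more than
#' `min_fraction` of the samples; row order is preserved.
#'
#' @param table An `igp_table` or `protein_table`.
#' @param min_fraction Detection threshold in (0, 1); default 0.30, i.e.
#'   a feature survives only if detected in more than 30% of samples.
#' @return The filtered table, same type.
#' @export
filter_by_detection <- function(table, min_fraction = 0.30) {
  stopifnot(min_fraction > 0, min_fraction < 1)
  m <- .abund(table)
  if (nrow(m) == 0) stop("table is empty", call. = FALSE)
  frac <- rowMeans(!is.na(m))
  keep <- frac > min_fraction
  if (!any(keep)) warning("no feature passes the detection filter", call. = FALSE)
  if (inherits(table, "igp_table")) {
    igp_table(table$keys[keep, c("protein", "site", "peptide", "composition",
                                 "glycoform"), drop = FALSE],
              m[keep, , drop = FALSE])
  } else {
    .set_abund(table, m[keep, , drop = FALSE])
  }
}

#' Impute missing cells with the per-sample minimum
#'
#' Each missing cell is replaced by the smallest observed intensity of its
#' own sample (column). An `imputed` logical matrix is attached so
#' downstream steps can tell observed from imputed cells.
#'
#' @param table An `igp_table` or `protein_table` (linear intensities).
#' @return Same type, no missing cells, with attribute/field `imputed`.
#' @export
impute_sample_min <- function(table) {
  m <- .abund(table)
  imputed <- is.na(m)
  empty <- colSums(!imputed) == 0
  if (any(empty)) {
    stop("sample(s) entirely missing: ",
         paste(colnames(m)[empty], collapse = ", "), call. = FALSE)
  }
  mins <- apply(m, 2, min, na.rm = TRUE)
  for (j in which(colSums(imputed) > 0)) m[imputed[, j], j] <- mins[j]
  out <- .set_abund(table, m)
  if (inherits(out, "igp_table")) out$imputed <- imputed
  else attr(out, "imputed") <- imputed
  out
}

#' Normalize IGP intensities to protein abundance
#'
#' Divides each IGP intensity cell-wise by the abundance of its parent
#' protein in the same sample, removing protein-level dynamics so that
#' glycosylation changes can be read off directly. Cells whose protein
#' value is missing become missing; protein value 0 also yields missing
#' (with a warning). IGPs whose accession is absent from the protein
#' table are retained unnormalized, flagged in `keys$normalized`.
#'
#' @param igp An `igp_table`.
#' @param prot A `protein_table` with matching sample columns.
#' @return An `igp_table` of normalized ratios.
#' @export
normalize_to_protein <- function(igp, prot) {
  stopifnot(inherits(igp, "igp_table"))
  pm <- unclass(prot)
  common <- intersect(igp$sample_ids, colnames(pm))
  if (!setequal(igp$sample_ids, colnames(pm))) {
    stop("IGP and protein tables have different sample columns", call. = FALSE)
  }
  pm <- pm[, igp$sample_ids, drop = FALSE]
  m <- igp$abundance
  have <- igp$keys$protein %in% rownames(pm)
  if (any(!have)) {
    warning("accession(s) absent from protein table, left unnormalized: ",
            paste(unique(igp$keys$protein[!have]), collapse = ", "),
            call. = FALSE)
  }
  zero_hit <- FALSE
  for (i in which(have)) {
    pv <- pm[igp$keys$protein[i], ]
    pv[!is.na(pv) & pv == 0] <- NA
    if (anyNA(pv) && any(!is.na(pm[igp$keys$protein[i], ]) &
                         pm[igp$keys$protein[i], ] == 0)) zero_hit <- TRUE
    m[i, ] <- m[i, ] / pv
  }
  if (zero_hit) {
    warning("protein intensity 0 encountered; affected cells set missing",
            call. = FALSE)
  }
  out <- igp
  out$abundance <- m
  out$keys$normalized <- have
  out$imputed <- NULL  # imputation provenance no longer cell-accurate
  out
}

#' Log2-transform a table into a processed matrix
#'
#' @param table An `igp_table`, `protein_table`, or plain matrix of
#'   strictly positive intensities (no missing cells).
#' @param design Optional `cohort_design` carried along for downstream
#'   group statistics.
#' @return A `processed_matrix`: list with `values` (features x samples,
#'   log2), `provenance` (0 observed / 1 imputed), `glycoform` (per
#'   feature, if available) and `design`.
#' @export
log2_transform <- function(table, design = NULL) {
  m <- .abund(table)
  if (anyNA(m)) stop("missing cells; impute before log2_transform", call. = FALSE)
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive value at feature %s, sample %s",
                 rownames(m)[bad[1, 1]] %||% bad[1, 1],
                 colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  prov <- if (inherits(table, "igp_table") && !is.null(table$imputed)) {
    table$imputed * 1L
  } else if (!is.null(attr(table, "imputed"))) {
    attr(table, "imputed") * 1L
  } else {
    matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  }
  structure(list(values = log2(m), provenance = prov,
                 glycoform = if (inherits(table, "igp_table"))
                   stats::setNames(table$keys$glycoform, table$keys$feature_id)
                 else NULL,
                 design = design),
            class = "processed_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.processed_matrix <- function(x, ...) {
  cat(sprintf("processed_matrix: %d features x %d samples (%.1f%% imputed)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$provenance)))
  invisible(x)
}

#' Mean-center batch effects with the tissue contrast protected
#'
#' Two-way means model: per feature, tissue-group means are removed first,
#' batch means are estimated on those residuals and subtracted, and the
#' grand residual mean is restored. For an additive batch offset under a
#' balanced design the offset is removed exactly while the tumor-NAT mean
#' difference is untouched. With a single batch this is the identity.
#'
#' @param m A `processed_matrix` (log2 scale).
#' @param design A `cohort_design` covering every sample column.
#' @return A `processed_matrix` with batch means removed.
#' @export
batch_center <- function(m, design = m$design) {
  stopifnot(inherits(m, "processed_matrix"), !is.null(design))
  idx <- match(colnames(m$values), design$sample_id)
  if (anyNA(idx)) stop("design does not cover all samples", call. = FALSE)
  batch <- factor(design$batch[idx])
  tissue <- factor(design$tissue[idx])
  if (nlevels(batch) < 2) return(m)
  small <- names(which(table(batch) < 2))
  if (length(small)) {
    warning("batch(es) with fewer than 2 samples: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  v <- m$values
  tissue_means <- t(apply(v, 1, function(row) stats::ave(row, tissue)))
  r <- v - tissue_means
  batch_means <- t(apply(r, 1, function(row) stats::ave(row, batch)))
  m$values <- v - batch_means + rowMeans(r)
  m
}

#' Run the standard preprocessing chain on an IGP table
#'
#' filter -> impute -> normalize -> log2 -> batch-center (the default
#' order); `impute_after_normalize = TRUE` swaps the imputation and
#' normalization steps.
#'
#' @param igp Raw `igp_table`.
#' @param prot `protein_table`, or `NULL` to skip protein normalization.
#' @param design `cohort_design`.
#' @param min_fraction Detection threshold (default 0.30).
#' @param impute_after_normalize Logical; default `FALSE`.
#' @param batch_correct Logical; default `TRUE`.
#' @return List with `processed` (a `processed_matrix`, log2 scale),
#'   `linear` (the imputed, normalized `igp_table` on linear scale, used
#'   by the glycoform score), and `igp_filtered`.
#' @export
preprocess_igp <- function(igp, prot, design, min_fraction = 0.30,
                           impute_after_normalize = FALSE,
                           batch_correct = TRUE) {
  flt <- filter_by_detection(igp, min_fraction)
  if (is.null(prot)) {
    lin <- impute_sample_min(flt)
  } else if (impute_after_normalize) {
    lin <- impute_sample_min(normalize_to_protein(flt, prot))
  } else {
    lin <- normalize_to_protein(impute_sample_min(flt), prot)
    # normalization can reintroduce missing cells (missing protein values)
    if (anyNA(lin$abundance)) lin <- impute_sample_min(lin)
  }
  pm <- log2_transform(lin, design)
  if (batch_correct) pm <- batch_center(pm, design)
  list(processed = pm, linear = lin, igp_filtered = flt)
}
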