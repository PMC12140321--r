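#' Per-feature AUC screening and logistic biomarker combinations
#'
#' Candidate biomarkers are screened by per-feature Mann-Whitney AUC, the
#' top glycoproteins are selected (by IGP count or total IGP abundance)
#' subject to a detection-fraction gate, and selected panels are combined
#' with a ridge-penalized logistic model fitted by iteratively reweighted
#' least squares. Splitting and cross-validation keep all samples of a
#' patient on the same side, so a tumor can never be evaluated against
#' its own patient's NAT.
#'
#' @name biomarker_screen
NULL

#' Per-feature AUC against the tumor/NAT label
#'
#' AUC is computed on observed cells only (imputed cells, flagged in the
#' provenance matrix, are excluded). Features observed in a single class
#' are skipped and listed in attribute `skipped`.
#'
#' @param m A `processed_matrix`.
#' @param design `cohort_design`; defaults to `m$design`.
#' @return data.frame `feature`, `glycoform`, `n_observed`, `auc`.
#' @export
per_feature_auc <- function(m, design = m$design) {
  stopifnot(inherits(m, "processed_matrix"), !is.null(design))
  labels <- design$tissue[match(colnames(m$values), design$sample_id)]
  if (!all(c("tumor", "nat") %in% labels)) {
    stop("both tissues must be present", call. = FALSE)
  }
  rows <- list(); skipped <- character(0)
  for (i in seq_len(nrow(m$values))) {
    obs <- m$provenance[i, ] == 0
    lab <- labels[obs]
    if (!("tumor" %in% lab) || !("nat" %in% lab)) {
      skipped <- c(skipped, rownames(m$values)[i]); next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      feature = rownames(m$values)[i] %||% as.character(i),
      glycoform = if (!is.null(m$glycoform)) unname(m$glycoform[i]) else NA_character_,
      n_observed = sum(obs),
      auc = auc_mann_whitney(m$values[i, obs], lab),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' Select top glycoproteins by glycosylation load
#'
#' Ranks glycoproteins either by the number of distinct IGPs they carry
#' (`rank_by = "n_igps"`, the default) or by total IGP abundance summed
#' over samples (`rank_by = "abundance"`), takes the top `k`, and keeps
#' those detected (>= 1 observed IGP) in strictly more than `min_detect`
#' of the samples. Ties are broken by lexicographic accession order.
#'
#' @param igp A classified `igp_table` (raw, with missingness intact).
#' @param k Number of proteins to shortlist (default 10).
#' @param min_detect Detection-fraction gate (default 0.9).
#' @param rank_by `"n_igps"` or `"abundance"`.
#' @return Character vector of accessions (length <= k).
#' @export
select_top_glycoproteins <- function(igp, k = 10, min_detect = 0.9,
                                     rank_by = c("n_igps", "abundance")) {
  rank_by <- match.arg(rank_by)
  stopifnot(k >= 1)
  prots <- unique(igp$keys$protein)
  if (length(prots) < k) {
    warning("fewer than k glycoproteins available; returning all", call. = FALSE)
  }
  stat <- vapply(prots, function(p) {
    sel <- igp$keys$protein == p
    if (rank_by == "n_igps") sum(sel)
    else sum(igp$abundance[sel, , drop = FALSE], na.rm = TRUE)
  }, numeric(1))
  ord <- order(-stat, prots)
  top <- prots[ord][seq_len(min(k, length(prots)))]
  detect <- vapply(top, function(p) {
    sel <- igp$keys$protein == p
    mean(colSums(!is.na(igp$abundance[sel, , drop = FALSE])) > 0)
  }, numeric(1))
  top[detect > min_detect]
}

#' Ridge-penalized logistic regression by IRLS
#'
#' Maximizes the penalized binomial log-likelihood
#' `loglik - ridge/2 * ||beta||^2` (intercept unpenalized) by iteratively
#' reweighted least squares on internally standardized predictors;
#' coefficients are reported back on the original scale. The small
#' default penalty guards against complete separation.
#'
#' @param features Numeric matrix, samples x features, no missing cells.
#' @param labels `"tumor"` / `"nat"` (tumor = 1) or a 0/1 vector.
#' @param ridge Penalty >= 0 (default 1e-4).
#' @param max_iter IRLS iteration cap (default 100).
#' @param tol Convergence tolerance on the coefficient step (default 1e-10).
#' @return A `logistic_model`: list with `coefficients` (named, original
#'   scale), `intercept`, `ridge`, `converged`, `iterations`, `deviance`.
#' @export
fit_logistic <- function(features, labels, ridge = 1e-4, max_iter = 100,
                         tol = 1e-10) {
  features <- as.matrix(features)
  if (anyNA(features)) stop("features must have no missing cells", call. = FALSE)
  y <- if (is.numeric(labels)) as.numeric(labels)
       else as.numeric(as.character(labels) == "tumor")
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("need >= 2 samples per class", call. = FALSE)
  }
  n <- nrow(features); p <- ncol(features)
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[scl == 0] <- 1
  X <- cbind(1, sweep(sweep(features, 2, ctr), 2, scl, "/"))
  pen <- diag(c(0, rep(ridge, p)), p + 1)
  beta <- rep(0, p + 1)
  dev_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X + pen, XtW %*% z)
    dev_trace <- c(dev_trace,
                   -2 * sum(y * log(pmax(mu, 1e-12)) +
                            (1 - y) * log(pmax(1 - mu, 1e-12))))
    step <- max(abs(beta_new - beta)) / (1 + max(abs(beta_new)))
    beta <- drop(beta_new)
    dev_flat <- it > 1 &&
      abs(dev_trace[it] - dev_trace[it - 1]) < 1e-9 * (1 + abs(dev_trace[it]))
    if (step < tol || dev_flat) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("IRLS did not converge in ", max_iter, " iterations; deviance trace: ",
         paste(signif(utils::tail(dev_trace, 5), 6), collapse = ", "),
         call. = FALSE)
  }
  coef_std <- beta[-1]
  coef_orig <- coef_std / scl
  intercept <- beta[1] - sum(coef_std * ctr / scl)
  structure(list(coefficients = stats::setNames(coef_orig, colnames(features)),
                 intercept = intercept, ridge = ridge, converged = converged,
                 iterations = it, deviance = utils::tail(dev_trace, 1),
                 center = ctr, scale = scl, beta_std = beta),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("logistic_model: %d features, ridge %g, %d IRLS iterations\n",
              length(x$coefficients), x$ridge, x$iterations))
  invisible(x)
}

#' Predicted tumor probabilities from a logistic model
#'
#' @param object A `logistic_model`.
#' @param newdata Samples x features matrix with matching columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.logistic_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stats::plogis(object$intercept +
                drop(newdata %*% object$coefficients[colnames(newdata)]))
}

#' Patient-stratified train/test split
#'
#' Splits at the patient level (both tissues of a patient fall on the
#' same side) while preserving tissue proportions within one sample of
#' the target fraction. Deterministic for a given seed.
#'
#' @param design `cohort_design`.
#' @param test_fraction Proportion of samples for the test side, in (0,1).
#' @param seed Integer seed.
#' @return List with `train` and `test` sample-id vectors.
#' @export
stratified_split <- function(design, test_fraction = 0.3, seed = 1) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  pat <- split(design$sample_id, design$patient_id)
  # group patients by their tissue signature so strata stay balanced
  sig <- vapply(pat, function(ids) {
    paste(sort(design$tissue[match(ids, design$sample_id)]), collapse = "+")
  }, character(1))
  test_ids <- with_substream(seed, "split", {
    out <- character(0)
    for (s in unique(sig)) {
      members <- names(pat)[sig == s]
      n_test <- round(length(members) * test_fraction)
      if (length(members) >= 2 && n_test == 0) n_test <- 1
      if (n_test > 0) {
        picked <- if (length(members) == 1) members
                  else sample(members, n_test)
        out <- c(out, unlist(pat[picked], use.names = FALSE))
      }
    }
    out
  })
  if (length(test_ids) == 0 || length(test_ids) == nrow(design)) {
    stop("classes too small to stratify at this test_fraction", call. = FALSE)
  }
  list(train = setdiff(design$sample_id, test_ids), test = test_ids)
}

#' Patient-stratified k-fold cross-validated AUC
#'
#' Patients are dealt into `folds` folds; per fold the logistic model is
#' refit on the remaining samples and AUC measured on the held-out fold.
#'
#' @param features Samples x features matrix (rownames = sample ids).
#' @param labels `"tumor"`/`"nat"` aligned to rows.
#' @param design `cohort_design` (for patient grouping).
#' @param folds Number of folds (default 5).
#' @param seed Integer seed.
#' @param ridge Ridge penalty passed to [fit_logistic()].
#' @return List: `mean_auc`, `fold_aucs`.
#' @export
cross_validated_auc <- function(features, labels, design, folds = 5, seed = 1,
                                ridge = 1e-4) {
  stopifnot(folds >= 2)
  features <- as.matrix(features)
  labels <- as.character(labels)
  ids <- rownames(features)
  patients <- design$patient_id[match(ids, design$sample_id)]
  upat <- unique(patients)
  shuffled <- with_substream(seed, "cv", sample(upat))
  fold_of_pat <- stats::setNames(rep(seq_len(folds), length.out = length(upat)),
                                 shuffled)
  fold <- fold_of_pat[patients]
  aucs <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- fold == f
    if (length(unique(labels[test])) < 2 || length(unique(labels[!test])) < 2) {
      stop("fold without both classes; reduce folds", call. = FALSE)
    }
    fit <- fit_logistic(features[!test, , drop = FALSE], labels[!test],
                        ridge = ridge)
    pr <- predict(fit, features[test, , drop = FALSE])
    aucs[f] <- auc_mann_whitney(pr, labels[test])
  }
  list(mean_auc = mean(aucs), fold_aucs = aucs)
}
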