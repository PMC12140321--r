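#' Synthetic paired tumor/NAT glycoproteomics cohort with ground truth
#'
#' Emulates the statistical structure of a paired tumor / normal-adjacent-
#' tissue intact-glycopeptide study: a protein -> site -> glycan hierarchy
#' with multiple glycans per site, log-normal abundances, glycoform-class-
#' specific tumor effects ordered Sia > Fuc/FA > high-mannose, a negative
#' coupling from glycosylation changes back onto protein abundance,
#' intensity-dependent (MNAR) missingness, patient pairing and batch
#' structure. Every random stage draws from its own named substream of
#' the single seed, so outputs are bit-reproducible and stages are
#' independent.
#'
#' @name synthetic_cohort
NULL

#' Default simulation parameters
#'
#' Defaults encode the emulated study design: 45 tumor/NAT pairs, ~300
#' glycoproteins, per-class tumor log2 effects A 1.5 > N 1.2 > F = FA 1.0
#' > H 0.4 (sialylation rising fastest, high mannose slowest), protein
#' level itself unchanged in tumors, coupling -0.5 from mean IGP
#' deviation to protein abundance, and ~20% MNAR missing cells.
#'
#' @param n_pairs Number of patients, each with one tumor and one NAT
#'   sample (default 45).
#' @param n_proteins Number of glycoproteins (default 300).
#' @param sites_per_protein Probability weights over 1..9 sites.
#' @param glycans_per_site Probability weights over 1..12 glycans.
#' @param glycoform_mixture Named probabilities over A, F, FA, H, N.
#' @param log2_effect Named per-class tumor log2 effects.
#' @param igp_protein_coupling Coefficient from the mean IGP log2
#'   deviation of a protein to its own abundance (default -0.5).
#' @param missing_a,missing_b MNAR logistic parameters:
#'   `P(missing) = plogis(missing_a - missing_b * log2 intensity)`.
#' @param n_batches Number of batches (default 3).
#' @param base_log_mean,base_log_sd Log2 baseline intensity distribution.
#' @param noise_sd Per-cell measurement noise sd (log2).
#' @param effect_sd Per-IGP effect noise sd around the class effect.
#' @param patient_sd Patient (sample-loading) random effect sd.
#' @param batch_sd Batch offset sd.
#' @param protein_log2_effect Tumor effect on protein abundance
#'   (default 0: the proteome itself does not shift).
#' @param protein_noise_sd Protein measurement noise sd.
#' @param seed Integer seed.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(
    n_pairs = 45, n_proteins = 300,
    sites_per_protein = c(0.35, 0.25, 0.15, 0.10, 0.06, 0.04, 0.02, 0.02, 0.01),
    glycans_per_site = c(0.18, 0.17, 0.15, 0.12, 0.10, 0.08,
                         0.06, 0.05, 0.04, 0.03, 0.01, 0.01),
    glycoform_mixture = c(A = 0.15, F = 0.38, FA = 0.10, H = 0.30, N = 0.07),
    log2_effect = c(A = 1.5, F = 1.0, FA = 1.0, H = 0.4, N = 1.2),
    igp_protein_coupling = -0.5,
    missing_a = 6.6, missing_b = 0.4,
    n_batches = 3,
    base_log_mean = 20, base_log_sd = 2,
    noise_sd = 1.0, effect_sd = 0.5,
    patient_sd = 0.3, batch_sd = 0.3,
    protein_log2_effect = 0, protein_noise_sd = 0.5,
    seed = 1) {
  stopifnot(n_pairs >= 2, n_proteins >= 1,
            abs(sum(glycoform_mixture) - 1) < 1e-8,
            all(is.finite(log2_effect)),
            all(names(glycoform_mixture) == c("A", "F", "FA", "H", "N")))
  p <- as.list(environment())
  class(p) <- "simulation_params"
  p
}

# draw one composition of the requested class
.sample_composition <- function(class) {
  comp <- switch(class,
    H = glycan_composition(hex = sample(3:11, 1), hexnac = 2),
    A = glycan_composition(hex = sample(3:7, 1), hexnac = sample(3:6, 1),
                           neuac = sample(1:4, 1)),
    F = glycan_composition(hex = sample(3:7, 1), hexnac = sample(3:6, 1),
                           fuc = sample(1:3, 1)),
    FA = glycan_composition(hex = sample(3:7, 1), hexnac = sample(3:6, 1),
                            neuac = sample(1:4, 1), fuc = sample(1:3, 1)),
    N = glycan_composition(hex = sample(0:6, 1), hexnac = sample(3:7, 1)),
    stop("unknown class ", class, call. = FALSE))
  if (classify_glycoform(comp) != class) {
    stop("composition sampler cannot produce class ", class, call. = FALSE)
  }
  comp
}

.random_protein_seq <- function(n_sites) {
  len <- 20L * n_sites + 20L
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  s <- sample(aa, len, replace = TRUE)
  pos <- 10L + 20L * (seq_len(n_sites) - 1L)
  for (p in pos) {
    s[p] <- "N"
    s[p + 1] <- sample(setdiff(aa, "P"), 1)
    s[p + 2] <- sample(c("S", "T", "C"), 1)
  }
  list(seq = paste(s, collapse = ""), sites = pos)
}

#' Generate a synthetic paired cohort
#'
#' @param params A `simulation_params` list.
#' @return List of class `synthetic_cohort`: `igp` (`igp_table` with
#'   missing cells), `prot` (`protein_table`), `design`
#'   (`cohort_design`), `truth` (`ground_truth`), `fasta` (named sequence
#'   vector with valid sequons at every declared site).
#' @export
generate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  seed <- params$seed

  # --- hierarchy: proteins, sites, glycans, sequences ---------------------
  hier <- with_substream(seed, "hierarchy", {
    keys <- list(); seqs <- character(params$n_proteins)
    accs <- sprintf("GP%04d", seq_len(params$n_proteins))
    names(seqs) <- accs
    classes <- names(params$glycoform_mixture)
    for (g in seq_len(params$n_proteins)) {
      ns <- sample(seq_along(params$sites_per_protein), 1,
                   prob = params$sites_per_protein)
      sq <- .random_protein_seq(ns)
      seqs[g] <- sq$seq
      for (si in seq_len(ns)) {
        ng <- sample(seq_along(params$glycans_per_site), 1,
                     prob = params$glycans_per_site)
        seen <- character(0)
        for (k in seq_len(ng)) {
          for (try in 1:50) {
            cls <- sample(classes, 1, prob = params$glycoform_mixture)
            comp <- .sample_composition(cls)
            txt <- format(comp)
            if (!(txt %in% seen)) break
          }
          if (txt %in% seen) next
          seen <- c(seen, txt)
          pep <- substr(sq$seq, max(1, sq$sites[si] - 5), sq$sites[si] + 5)
          keys[[length(keys) + 1L]] <- data.frame(
            protein = accs[g], site = sq$sites[si], peptide = pep,
            composition = txt, glycoform = cls, stringsAsFactors = FALSE)
        }
      }
    }
    list(keys = do.call(rbind, keys), seqs = seqs)
  })
  keys <- hier$keys
  n_igp <- nrow(keys)

  # --- design: patients, tissues, batches ---------------------------------
  patients <- sprintf("PT%02d", seq_len(params$n_pairs))
  design_df <- data.frame(
    sample_id = c(paste0(patients, "_T"), paste0(patients, "_N")),
    patient_id = rep(patients, 2),
    tissue = rep(c("tumor", "nat"), each = params$n_pairs),
    stringsAsFactors = FALSE)
  batch_info <- with_substream(seed, "batch", {
    pb <- sample(rep_len(seq_len(params$n_batches), params$n_pairs))
    list(patient_batch = stats::setNames(pb, patients),
         offsets = stats::rnorm(params$n_batches, 0, params$batch_sd))
  })
  design <- cohort_design(design_df$sample_id, design_df$patient_id,
                          design_df$tissue,
                          paste0("B", batch_info$patient_batch[design_df$patient_id]))
  n_samp <- nrow(design)
  is_tumor <- design$tissue == "tumor"
  samp_batch_off <- batch_info$offsets[batch_info$patient_batch[design$patient_id]]

  # --- abundances ---------------------------------------------------------
  ab <- with_substream(seed, "abundance", {
    b_igp <- stats::rnorm(n_igp, params$base_log_mean, params$base_log_sd)
    effect <- params$log2_effect[keys$glycoform] +
      stats::rnorm(n_igp, 0, params$effect_sd)
    u_pat <- stats::setNames(stats::rnorm(params$n_pairs, 0, params$patient_sd),
                             patients)
    u_s <- u_pat[design$patient_id]
    igp_log2 <- matrix(0, n_igp, n_samp,
                       dimnames = list(NULL, design$sample_id))
    for (s in seq_len(n_samp)) {
      igp_log2[, s] <- b_igp + u_s[s] + samp_batch_off[s] +
        if (is_tumor[s]) effect else 0
    }
    igp_log2 <- igp_log2 + matrix(stats::rnorm(n_igp * n_samp, 0, params$noise_sd),
                                  n_igp, n_samp)
    # protein abundance, negatively coupled to its IGPs' mean deviation
    accs <- unique(keys$protein)
    bp <- stats::setNames(stats::rnorm(length(accs),
                                       params$base_log_mean + 2,
                                       params$base_log_sd), accs)
    dev <- igp_log2 - b_igp  # remove IGP baselines
    dev <- sweep(dev, 2, u_s + samp_batch_off)  # leave tumor effect + noise
    prot_log2 <- matrix(0, length(accs), n_samp,
                        dimnames = list(accs, design$sample_id))
    for (a in accs) {
      rows_a <- which(keys$protein == a)
      mean_dev <- colMeans(dev[rows_a, , drop = FALSE])
      prot_log2[a, ] <- bp[a] + u_s + samp_batch_off +
        ifelse(is_tumor, params$protein_log2_effect, 0) +
        params$igp_protein_coupling * mean_dev +
        stats::rnorm(n_samp, 0, params$protein_noise_sd)
    }
    list(igp_log2 = igp_log2, prot_log2 = prot_log2, effect = effect,
         b_igp = b_igp)
  })

  igp_lin <- 2^ab$igp_log2
  prot_lin <- 2^ab$prot_log2

  # --- MNAR missingness ---------------------------------------------------
  miss <- with_substream(seed, "missing", {
    p_igp <- stats::plogis(params$missing_a - params$missing_b * ab$igp_log2)
    p_prot <- stats::plogis(params$missing_a - params$missing_b * ab$prot_log2)
    list(igp = matrix(stats::runif(length(p_igp)) < p_igp, nrow(p_igp)),
         prot = matrix(stats::runif(length(p_prot)) < p_prot, nrow(p_prot)))
  })
  igp_lin[miss$igp] <- NA
  prot_lin[miss$prot] <- NA

  igp <- igp_table(keys, igp_lin)
  prot <- protein_table(prot_lin)

  truth <- structure(list(
    igp_effect = stats::setNames(unname(ab$effect), igp$keys$feature_id),
    igp_class = stats::setNames(igp$keys$glycoform, igp$keys$feature_id),
    protein_direction = NULL,  # filled below
    batch_offsets = stats::setNames(batch_info$offsets,
                                    paste0("B", seq_len(params$n_batches))),
    params = params), class = "ground_truth")
  dir_ <- vapply(unique(igp$keys$protein), function(a) {
    classify_direction(truth$igp_effect[igp$keys$protein == a])
  }, character(1))
  dom_ <- vapply(unique(igp$keys$protein), function(a) {
    classify_dominance(igp$keys$glycoform[igp$keys$protein == a])
  }, character(1))
  truth$protein_direction <- dir_
  truth$protein_label <- paste(dir_, dom_, sep = "-")
  names(truth$protein_label) <- unique(igp$keys$protein)

  structure(list(igp = igp, prot = prot, design = design, truth = truth,
                 fasta = hier$seqs),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d IGPs / %d proteins / %d samples\n",
              nrow(x$igp$keys), nrow(x$prot), nrow(x$design)))
  invisible(x)
}

#' Summarise the ground truth of a synthetic cohort
#'
#' @param gt A `ground_truth` (the `truth` element of a cohort).
#' @return List: `class_effects` (data.frame glycoform x mean true
#'   effect), `protein_labels` (named expected six-group labels).
#' @export
truth_summary <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  cls <- sort(unique(gt$igp_class))
  ce <- data.frame(glycoform = cls,
                   mean_effect = vapply(cls, function(c)
                     mean(gt$igp_effect[gt$igp_class == c]), numeric(1)),
                   n_igps = vapply(cls, function(c)
                     sum(gt$igp_class == c), integer(1)),
                   stringsAsFactors = FALSE)
  list(class_effects = ce, protein_labels = gt$protein_label)
}

#' Write a synthetic cohort to disk
#'
#' Writes the IGP, protein and design TSVs, a FASTA of the protein
#' sequences (valid sequons at every declared site) and a JSON ground
#' truth sidecar.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(igp = file.path(dir, "igp_table.tsv"),
             prot = file.path(dir, "protein_table.tsv"),
             design = file.path(dir, "cohort_design.tsv"),
             fasta = file.path(dir, "proteins.fasta"),
             truth = file.path(dir, "ground_truth.json"))
  write_table(cohort$igp, paths["igp"])
  write_table(cohort$prot, paths["prot"])
  write_table(cohort$design, paths["design"])
  writeLines(paste0(">", names(cohort$fasta), "\n", cohort$fasta),
             paths["fasta"])
  tr <- cohort$truth
  jsonlite::write_json(list(igp_effect = as.list(tr$igp_effect),
                            protein_label = as.list(tr$protein_label),
                            batch_offsets = as.list(tr$batch_offsets)),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
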