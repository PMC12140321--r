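#' Sequon windows, residue enrichment, and annotation joins
#'
#' Glycosylation sites are summarised as 15-residue windows (7 residues
#' either side of the asparagine, `-`-padded at sequence ends). Position-
#' wise residue frequencies of a foreground window set are compared to a
#' background set as percentage-point differences with two-proportion
#' z-tests, an enrichment matrix in the spirit of sequence-logo tools.
#'
#' @name motif_annotation
NULL

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Extract padded +/-7 windows around glycosylation sites
#'
#' @param seqs Named character vector, accession -> uppercase sequence.
#' @param sites data.frame with columns `accession`, `position` (1-based).
#' @param flank Residues each side (default 7 -> 15-mer windows).
#' @return data.frame `accession`, `position`, `window`, `center_is_N`;
#'   sites whose accession is missing from `seqs` are skipped with a
#'   warning, sites beyond the sequence end are an error.
#' @export
extract_site_windows <- function(seqs, sites, flank = 7) {
  stopifnot(all(c("accession", "position") %in% names(sites)))
  missing_acc <- setdiff(unique(sites$accession), names(seqs))
  if (length(missing_acc)) {
    warning("accession(s) not in FASTA, sites skipped: ",
            paste(missing_acc, collapse = ", "), call. = FALSE)
    sites <- sites[sites$accession %in% names(seqs), , drop = FALSE]
  }
  n <- nrow(sites)
  win <- character(n); center_ok <- logical(n)
  for (i in seq_len(n)) {
    s <- seqs[[sites$accession[i]]]
    pos <- as.integer(sites$position[i])
    if (pos < 1 || pos > nchar(s)) {
      stop(sprintf("site position %d outside sequence %s (length %d)",
                   pos, sites$accession[i], nchar(s)), call. = FALSE)
    }
    lo <- pos - flank; hi <- pos + flank
    core <- substr(s, max(1, lo), min(nchar(s), hi))
    w <- paste0(strrep("-", max(0, 1 - lo)), core,
                strrep("-", max(0, hi - nchar(s))))
    win[i] <- w
    center_ok[i] <- substr(w, flank + 1, flank + 1) == "N"
  }
  if (n > 0 && !all(center_ok)) {
    warning(sum(!center_ok), " window(s) without N at the center (flagged)",
            call. = FALSE)
  }
  data.frame(accession = sites$accession, position = sites$position,
             window = win, center_is_N = center_ok, stringsAsFactors = FALSE)
}

#' All valid sequon sites of a sequence set
#'
#' Scans every sequence for N-X-S/T/C (X != P) and returns the asparagine
#' positions; useful as a motif-enrichment background.
#'
#' @param seqs Named character vector of sequences.
#' @return data.frame `accession`, `position`.
#' @export
find_sequon_sites <- function(seqs) {
  rows <- lapply(names(seqs), function(acc) {
    s <- seqs[[acc]]
    L <- nchar(s)
    if (L < 3) return(NULL)
    pos <- which(vapply(seq_len(L - 2), function(i) {
      is_valid_sequon(substr(s, i, i + 2))
    }, logical(1)))
    if (!length(pos)) return(NULL)
    data.frame(accession = acc, position = pos, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(accession = character(0), position = integer(0))
  else out
}

#' Position-wise residue enrichment of foreground vs background windows
#'
#' Per window position and residue: percentage frequency in the
#' foreground minus the background (pads excluded from denominators),
#' with a two-proportion z-test p-value.
#'
#' @param fg,bg Character vectors of equal-length windows (or the
#'   data.frames from [extract_site_windows()]).
#' @return List with matrices `diff` (percentage points) and `p`
#'   (positions x residues), plus `fg_freq`, `bg_freq`.
#' @export
residue_enrichment <- function(fg, bg) {
  if (is.data.frame(fg)) fg <- fg$window
  if (is.data.frame(bg)) bg <- bg$window
  if (!length(fg) || !length(bg)) stop("empty window set", call. = FALSE)
  L <- nchar(fg[1])
  stopifnot(all(nchar(c(fg, bg)) == L))
  count_mat <- function(w) {
    m <- matrix(0L, L, length(.AA20), dimnames = list(NULL, .AA20))
    for (s in w) {
      ch <- strsplit(s, "")[[1]]
      for (i in seq_len(L)) {
        if (ch[i] %in% .AA20) m[i, ch[i]] <- m[i, ch[i]] + 1L
      }
    }
    m
  }
  cf <- count_mat(fg); cb <- count_mat(bg)
  nf <- rowSums(cf); nb <- rowSums(cb)  # pads excluded per position
  ff <- sweep(cf, 1, pmax(nf, 1), "/") * 100
  fb <- sweep(cb, 1, pmax(nb, 1), "/") * 100
  dd <- ff - fb
  pp <- matrix(1, L, length(.AA20), dimnames = list(NULL, .AA20))
  for (i in seq_len(L)) {
    if (nf[i] == 0 || nb[i] == 0) next
    for (j in seq_along(.AA20)) {
      p1 <- cf[i, j] / nf[i]; p2 <- cb[i, j] / nb[i]
      pool <- (cf[i, j] + cb[i, j]) / (nf[i] + nb[i])
      se <- sqrt(pool * (1 - pool) * (1 / nf[i] + 1 / nb[i]))
      if (se == 0) next
      pp[i, j] <- 2 * stats::pnorm(-abs((p1 - p2) / se))
    }
  }
  pos_lab <- as.character(seq_len(L) - (L + 1) %/% 2)
  rownames(dd) <- rownames(pp) <- rownames(ff) <- rownames(fb) <- pos_lab
  list(diff = dd, p = pp, fg_freq = ff, bg_freq = fb)
}

#' Join features with a category annotation
#'
#' @param features Character vector of accessions, or a data.frame with a
#'   `protein` column.
#' @param annotation Named character vector accession -> category, or a
#'   data.frame with `accession`, `category` columns (duplicates: last
#'   wins, with a warning).
#' @return data.frame with a `category` column; unannotated features get
#'   `"unknown"`.
#' @export
annotate_categories <- function(features, annotation) {
  if (is.data.frame(annotation)) {
    if (anyDuplicated(annotation$accession)) {
      warning("duplicate accession(s) in annotation, last wins", call. = FALSE)
    }
    annotation <- stats::setNames(annotation$category, annotation$accession)
    annotation <- annotation[!duplicated(names(annotation), fromLast = TRUE)]
  }
  df <- if (is.data.frame(features)) features
        else data.frame(protein = features, stringsAsFactors = FALSE)
  cat_ <- unname(annotation[df$protein])
  cat_[is.na(cat_)] <- "unknown"
  df$category <- cat_
  df
}

#' Category-by-glycoform contingency table with a chi-square test
#'
#' @param igp A classified `igp_table`.
#' @param annotation As in [annotate_categories()].
#' @return List: `counts` (category x glycoform), `chisq_p`, `reliable`
#'   (FALSE when any expected count < 1, or the table is degenerate).
#' @export
glycoform_category_counts <- function(igp, annotation) {
  ann <- annotate_categories(igp$keys, annotation)
  counts <- table(category = ann$category, glycoform = ann$glycoform)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    return(list(counts = counts, chisq_p = 1, reliable = FALSE))
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(counts = counts, chisq_p = ct$p.value,
       reliable = all(ct$expected >= 1))
}
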