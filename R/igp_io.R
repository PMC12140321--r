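#' Data containers and tabular I/O
#'
#' The pipeline moves three tables around: an IGP quantification table
#' (one row per protein.site.glycan feature with per-sample intensities),
#' a protein abundance table, and a cohort design mapping samples to
#' patients, tissue (tumor / NAT) and batch. All on-disk formats are TSV,
#' UTF-8, "." decimal; missing intensities are empty cells or "NA" on
#' disk and `NA` in memory. A measured zero is a value, never missing.
#'
#' @name igp_io
NULL

.TISSUE_LEVELS <- c("tumor", "nat")

#' Construct a cohort design
#'
#' @param sample_id,patient_id,tissue,batch Character vectors of equal
#'   length; `tissue` must be `"tumor"` or `"nat"`.
#' @return A `cohort_design` data.frame.
#' @export
cohort_design <- function(sample_id, patient_id, tissue, batch) {
  tissue <- tolower(as.character(tissue))
  d <- data.frame(sample_id = as.character(sample_id),
                  patient_id = as.character(patient_id),
                  tissue = tissue,
                  batch = as.character(batch),
                  stringsAsFactors = FALSE)
  bad <- setdiff(unique(d$tissue), .TISSUE_LEVELS)
  if (length(bad)) {
    stop("tissue labels must be 'tumor' or 'nat'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(d$sample_id)) {
    stop("duplicate sample_id in design: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  tab <- table(d$patient_id, d$tissue)
  if (any(tab > 1)) {
    off <- rownames(tab)[apply(tab > 1, 1, any)]
    stop("patient(s) with more than one sample per tissue: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  unpaired <- rownames(tab)[rowSums(tab > 0) < 2]
  if (length(unpaired)) {
    warning("unpaired patient(s): ", paste(unpaired, collapse = ", "),
            call. = FALSE)
  }
  class(d) <- c("cohort_design", "data.frame")
  d
}

#' Construct an IGP table
#'
#' @param keys data.frame with columns `protein`, `site` (1-based integer),
#'   `peptide`, `composition`; a `glycoform` column is added by
#'   classification if absent.
#' @param abundance Numeric matrix, rows aligned to `keys`, columns named
#'   by sample id; `NA` marks missing, values must be >= 0.
#' @return An `igp_table`.
#' @export
igp_table <- function(keys, abundance) {
  stopifnot(is.data.frame(keys),
            all(c("protein", "site", "peptide", "composition") %in% names(keys)))
  abundance <- as.matrix(abundance)
  if (nrow(keys) != nrow(abundance)) {
    stop("keys and abundance row counts differ", call. = FALSE)
  }
  if (is.null(colnames(abundance))) {
    stop("abundance matrix must have sample ids as column names", call. = FALSE)
  }
  if (nrow(keys) > 0) {
    keys$site <- as.integer(keys$site)
    if (any(keys$site < 1L)) stop("site positions must be >= 1", call. = FALSE)
    if (any(!nzchar(keys$peptide))) stop("empty peptide sequence", call. = FALSE)
    if (is.null(keys$glycoform)) {
      keys$glycoform <- classify_glycoforms(keys$composition)
    }
    keys$feature_id <- igp_feature_id(keys$protein, keys$site, keys$composition)
    dup <- duplicated(keys[c("protein", "site", "peptide", "composition")])
    if (any(dup)) {
      stop("duplicate IGP key(s): ",
           paste(unique(keys$feature_id[dup]), collapse = ", "), call. = FALSE)
    }
    if (any(abundance < 0, na.rm = TRUE)) {
      stop("negative intensity in IGP table", call. = FALSE)
    }
    rownames(abundance) <- keys$feature_id
  } else {
    keys$glycoform <- character(0)
    keys$feature_id <- character(0)
  }
  structure(list(keys = keys, abundance = abundance,
                 sample_ids = colnames(abundance)),
            class = "igp_table")
}

#' @export
print.igp_table <- function(x, ...) {
  cat(sprintf("igp_table: %d IGPs x %d samples (%d proteins, %d sites)\n",
              nrow(x$keys), length(x$sample_ids),
              length(unique(x$keys$protein)),
              length(unique(paste(x$keys$protein, x$keys$site)))))
  invisible(x)
}

#' Construct a protein abundance table
#'
#' @param abundance Numeric matrix, rownames = accessions, colnames =
#'   sample ids, `NA` missing, values >= 0.
#' @return A `protein_table` (a classed matrix).
#' @export
protein_table <- function(abundance) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || anyDuplicated(rownames(abundance))) {
    stop("protein table needs unique accession rownames", call. = FALSE)
  }
  if (any(abundance < 0, na.rm = TRUE)) {
    stop("negative intensity in protein table", call. = FALSE)
  }
  class(abundance) <- c("protein_table", class(abundance))
  abundance
}

# column-name aliases for the pglyco dialect
.PGLYCO_ALIASES <- list(
  protein = c("protein", "proteins", "proteinname", "accession"),
  site = c("site", "prosites", "prosite", "glycosite", "glycositepos"),
  peptide = c("peptide", "peptideseq"),
  composition = c("composition", "glycancomposition", "glycan", "glycancomp")
)

.match_alias <- function(cols, dialect) {
  lc <- tolower(cols)
  out <- list()
  for (canon in names(.PGLYCO_ALIASES)) {
    cands <- if (dialect == "pglyco") .PGLYCO_ALIASES[[canon]] else canon
    hit <- which(lc %in% cands)
    if (length(hit) == 0) {
      stop(sprintf("required column '%s' not found in header", canon),
           call. = FALSE)
    }
    out[[canon]] <- cols[hit[1]]
  }
  out
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    colClasses = "character")
}

.as_intensity <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("non-numeric intensity '%s' in %s (row %d)",
                 x[bad[1]], what, bad[1]), call. = FALSE)
  }
  if (any(out < 0, na.rm = TRUE)) {
    stop("negative intensity in ", what, call. = FALSE)
  }
  out
}

#' Read an IGP quantification table
#'
#' Expects a TSV whose header declares `protein`, `site`, `peptide`,
#' `composition` plus one numeric column per sample. Site accepts `"196"`
#' or `"N196"`. The `pglyco` dialect additionally recognises vendor column
#' names (`Proteins`, `ProSites`, `GlycanComposition`, ...); unknown extra
#' columns are ignored with a message to stderr.
#'
#' @param path TSV path.
#' @param dialect `"canonical"` or `"pglyco"`.
#' @param design Optional `cohort_design`; when given, the sample columns
#'   must exactly match `design$sample_id`.
#' @return An `igp_table`, with the glycoform class of every row filled in.
#' @export
read_igp_table <- function(path, dialect = c("canonical", "pglyco"),
                           design = NULL) {
  dialect <- match.arg(dialect)
  raw <- .read_tsv(path)
  cols <- .match_alias(names(raw), dialect)
  key_cols <- unlist(cols, use.names = FALSE)
  sample_cols <- setdiff(names(raw), key_cols)
  if (!is.null(design)) {
    extra <- setdiff(sample_cols, design$sample_id)
    if (dialect == "pglyco" && length(extra)) {
      message("ignoring non-sample column(s): ", paste(extra, collapse = ", "))
      sample_cols <- setdiff(sample_cols, extra)
    }
    if (!setequal(sample_cols, design$sample_id)) {
      stop("sample columns do not match the cohort design", call. = FALSE)
    }
    sample_cols <- design$sample_id[design$sample_id %in% sample_cols]
  }
  site_raw <- raw[[cols$site]]
  site <- suppressWarnings(as.integer(sub("^[Nn]", "", site_raw)))
  if (nrow(raw) > 0 && anyNA(site)) {
    stop("unparseable site position at data row ",
         which(is.na(site))[1], call. = FALSE)
  }
  comp_txt <- raw[[cols$composition]]
  glycoform <- character(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    glycoform[i] <- tryCatch(classify_glycoform(parse_composition(comp_txt[i])),
      error = function(e) {
        stop(sprintf("row %d: %s", i, conditionMessage(e)), call. = FALSE)
      })
  }
  abund <- matrix(NA_real_, nrow(raw), length(sample_cols),
                  dimnames = list(NULL, sample_cols))
  for (s in sample_cols) abund[, s] <- .as_intensity(raw[[s]], paste0("sample ", s))
  keys <- data.frame(protein = raw[[cols$protein]], site = site,
                     peptide = toupper(raw[[cols$peptide]]),
                     composition = comp_txt, glycoform = glycoform,
                     stringsAsFactors = FALSE)
  igp_table(keys, abund)
}

#' Read a protein abundance table
#'
#' TSV with an `accession` column followed by numeric sample columns.
#' Blank and `"NA"` cells become missing; non-numeric text is an error.
#'
#' @param path TSV path.
#' @return A `protein_table`.
#' @export
read_protein_table <- function(path) {
  raw <- .read_tsv(path)
  acc_col <- names(raw)[tolower(names(raw)) %in% c("accession", "protein")][1]
  if (is.na(acc_col)) stop("no 'accession' column found", call. = FALSE)
  sample_cols <- setdiff(names(raw), acc_col)
  m <- matrix(NA_real_, nrow(raw), length(sample_cols),
              dimnames = list(raw[[acc_col]], sample_cols))
  for (s in sample_cols) m[, s] <- .as_intensity(raw[[s]], paste0("sample ", s))
  protein_table(m)
}

#' Read a cohort design table
#'
#' TSV with columns `sample_id`, `patient_id`, `tissue`, `batch`.
#'
#' @param path TSV path.
#' @return A validated `cohort_design`; tumor/NAT counts are reported to
#'   stderr.
#' @export
read_cohort_design <- function(path) {
  raw <- .read_tsv(path)
  need <- c("sample_id", "patient_id", "tissue", "batch")
  if (!all(need %in% tolower(names(raw)))) {
    stop("design must have columns sample_id, patient_id, tissue, batch",
         call. = FALSE)
  }
  names(raw) <- tolower(names(raw))
  d <- cohort_design(raw$sample_id, raw$patient_id, raw$tissue, raw$batch)
  message(sprintf("design: %d tumor, %d NAT samples, %d patients, %d batches",
                  sum(d$tissue == "tumor"), sum(d$tissue == "nat"),
                  length(unique(d$patient_id)), length(unique(d$batch))))
  d
}

#' Read protein sequences from FASTA
#'
#' UniProt-style headers (`sp|ACC|NAME`) are reduced to the accession;
#' plain headers are used as-is up to the first whitespace. Sequences are
#' uppercased. On duplicate accessions the last record wins, with a
#' warning.
#'
#' @param path FASTA path.
#' @return Named character vector, accession -> sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !startsWith(first, ">")) {
    stop("not a FASTA file (no '>' header): ", path, call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  acc <- vapply(hdr, function(h) {
    h <- strsplit(h, "[[:space:]]")[[1]][1]
    parts <- strsplit(h, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2 && parts[1] %in% c("sp", "tr")) parts[2] else h
  }, character(1), USE.NAMES = FALSE)
  seqs <- toupper(as.character(aa))
  if (anyDuplicated(acc)) {
    warning("duplicate accession(s) in FASTA, last record wins: ",
            paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  out <- stats::setNames(seqs, acc)
  out[!duplicated(acc, fromLast = TRUE)]
}

.fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_,
         formatC(signif(x, 6), format = "g", digits = 6))
}

#' Write a pipeline table to TSV
#'
#' Generic writer for the pipeline's result types. Numeric values are
#' written at 6 significant digits; missing cells are written as `NA`.
#' `write_table` then its matching reader round-trips at that precision.
#'
#' @param obj An `igp_table`, `protein_table`, `cohort_design`, or
#'   data.frame result.
#' @param path Output TSV path.
#' @return `invisible(path)`.
#' @export
write_table <- function(obj, path) UseMethod("write_table")

.write_df <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @export
write_table.data.frame <- function(obj, path) {
  cls <- class(obj)
  class(obj) <- "data.frame"
  .write_df(obj, path)
}

#' @export
write_table.cohort_design <- function(obj, path) {
  class(obj) <- "data.frame"
  .write_df(obj, path)
}

#' @export
write_table.igp_table <- function(obj, path) {
  df <- cbind(obj$keys[c("protein", "site", "peptide", "composition")],
              as.data.frame(obj$abundance, check.names = FALSE))
  .write_df(df, path)
}

#' @export
write_table.protein_table <- function(obj, path) {
  m <- unclass(obj)
  df <- cbind(data.frame(accession = rownames(m), stringsAsFactors = FALSE),
              as.data.frame(m, check.names = FALSE))
  rownames(df) <- NULL
  .write_df(df, path)
}
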