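#' Glycan composition parsing and five-class glycoform taxonomy
#'
#' N-glycan compositions are reported by search engines such as pGlyco as
#' monosaccharide count strings, e.g. `"Hex[4]HexNAc[2]NeuAc[0]Fuc[0]"`.
#' These functions parse such strings into count vectors and classify each
#' composition into one of five mutually exclusive glycoform classes:
#'
#' * `A`  - sialylated (contains sialic acid, no fucose)
#' * `F`  - fucosylated (contains fucose, no sialic acid)
#' * `FA` - both sialylated and fucosylated
#' * `H`  - high mannose (exactly two HexNAc, every other residue a hexose)
#' * `N`  - high HexNAc (everything else)
#'
#' Precedence FA > A > F > H > N makes the classes a true partition: a
#' sialylated *and* fucosylated glycan is `FA`, never `A` or `F`.
#'
#' @name glycoform
NULL

# residue names treated as sialic acids when counting "Sia"
.SIALIC_NAMES <- c("NeuAc", "NeuGc", "Neu5Ac", "Neu5Gc")

#' Parse a glycan composition string
#'
#' Accepts repeated `Name[count]` or `Name(count)` tokens in any order;
#' residues not listed default to count 0. Unknown residue names (e.g.
#' `NeuGc`, `Xyl`) are kept in the `other` slot.
#'
#' @param text Composition string, e.g. `"Hex[4]HexNAc[2]NeuAc[0]Fuc[0]"`.
#' @return An object of class `glycan_composition`: a list with integer
#'   fields `hex`, `hexnac`, `neuac`, `fuc` and a named integer vector
#'   `other`.
#' @examples
#' parse_composition("Hex[4]HexNAc[2]NeuAc[0]Fuc[0]")
#' parse_composition("HexNAc(2)Hex(5)")
#' @export
parse_composition <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("composition string must be a single non-empty string", call. = FALSE)
  }
  pat <- "([A-Za-z][A-Za-z0-9]*)[\\[(]([0-9]+)[\\])]"
  mlist <- gregexpr(pat, text, perl = TRUE)
  m <- mlist[[1]]
  if (m[1] == -1L) {
    stop(sprintf("cannot parse composition '%s': no Name[count] token found", text),
         call. = FALSE)
  }
  # the tokens must tile the whole string (no stray characters between them)
  ends <- m + attr(m, "match.length") - 1L
  covered <- unlist(Map(seq.int, m, ends))
  leftover <- setdiff(seq_len(nchar(text)), covered)
  if (length(leftover) > 0L) {
    stop(sprintf("cannot parse composition '%s': unexpected character at position %d",
                 text, leftover[1]), call. = FALSE)
  }
  tokens <- regmatches(text, mlist)[[1]]
  names_ <- sub(pat, "\\1", tokens, perl = TRUE)
  counts <- as.integer(sub(pat, "\\2", tokens, perl = TRUE))
  comp <- list(hex = 0L, hexnac = 0L, neuac = 0L, fuc = 0L,
               other = integer(0))
  for (i in seq_along(names_)) {
    nm <- names_[i]
    ct <- counts[i]
    if (nm == "Hex") comp$hex <- comp$hex + ct
    else if (nm == "HexNAc") comp$hexnac <- comp$hexnac + ct
    else if (nm == "NeuAc") comp$neuac <- comp$neuac + ct
    else if (nm == "Fuc" || nm == "dHex") comp$fuc <- comp$fuc + ct
    else {
      comp$other[nm] <- if (nm %in% names(comp$other)) comp$other[[nm]] + ct else ct
    }
  }
  structure(comp, class = "glycan_composition")
}

#' Construct a glycan composition from counts
#'
#' @param hex,hexnac,neuac,fuc Non-negative integer residue counts.
#' @param other Named integer vector of additional residues.
#' @return A `glycan_composition`.
#' @export
glycan_composition <- function(hex = 0L, hexnac = 0L, neuac = 0L, fuc = 0L,
                               other = integer(0)) {
  counts <- c(hex, hexnac, neuac, fuc, other)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("residue counts must be non-negative integers", call. = FALSE)
  }
  structure(list(hex = as.integer(hex), hexnac = as.integer(hexnac),
                 neuac = as.integer(neuac), fuc = as.integer(fuc),
                 other = if (length(other)) {
                   storage.mode(other) <- "integer"; other
                 } else integer(0)),
            class = "glycan_composition")
}

#' @export
format.glycan_composition <- function(x, ...) {
  base <- sprintf("Hex[%d]HexNAc[%d]NeuAc[%d]Fuc[%d]",
                  x$hex, x$hexnac, x$neuac, x$fuc)
  if (length(x$other)) {
    base <- paste0(base, paste0(names(x$other), "[", x$other, "]", collapse = ""))
  }
  base
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

.sia_count <- function(comp) {
  extra <- comp$other[names(comp$other) %in% .SIALIC_NAMES]
  comp$neuac + sum(extra)
}

#' Classify a glycan composition into a glycoform class
#'
#' Rules, applied in order: `FA` if sialylated and fucosylated; `A` if
#' sialylated only; `F` if fucosylated only; `H` if exactly two HexNAc and
#' all remaining residues are hexoses; otherwise `N`. Sialylated means any
#' sialic-acid residue (NeuAc, NeuGc, ...).
#'
#' @param comp A `glycan_composition` or a composition string.
#' @return One of `"A"`, `"F"`, `"FA"`, `"H"`, `"N"`.
#' @examples
#' classify_glycoform("Hex[4]HexNAc[2]NeuAc[0]Fuc[0]")   # "H"
#' classify_glycoform(glycan_composition(5, 4, 1, 1))    # "FA"
#' @export
classify_glycoform <- function(comp) {
  if (is.character(comp)) comp <- parse_composition(comp)
  stopifnot(inherits(comp, "glycan_composition"))
  sia <- .sia_count(comp)
  non_sia_other <- comp$other[!(names(comp$other) %in% .SIALIC_NAMES)]
  if (sia > 0 && comp$fuc > 0) return("FA")
  if (sia > 0) return("A")
  if (comp$fuc > 0) return("F")
  if (comp$hexnac == 2L && sum(non_sia_other) == 0L) return("H")
  "N"
}

#' Vectorised glycoform classification of composition strings
#'
#' @param texts Character vector of composition strings.
#' @return Character vector of class labels.
#' @export
classify_glycoforms <- function(texts) {
  vapply(texts, function(t) classify_glycoform(parse_composition(t)),
         character(1), USE.NAMES = FALSE)
}

#' Test a 3-residue window for the N-glycosylation sequon
#'
#' The consensus sequon is Asn-X-Ser/Thr/Cys with X != Pro.
#'
#' @param window A 3-character uppercase string.
#' @return `TRUE` iff the window matches N-X-S/T/C, X != P.
#' @examples
#' is_valid_sequon("NKS")  # TRUE
#' is_valid_sequon("NPT")  # FALSE (proline at X)
#' @export
is_valid_sequon <- function(window) {
  if (!is.character(window) || length(window) != 1L || nchar(window) != 3L) {
    stop("sequon window must be a single 3-residue string", call. = FALSE)
  }
  ch <- strsplit(window, "")[[1]]
  ch[1] == "N" && ch[2] != "P" && ch[3] %in% c("S", "T", "C")
}

#' Canonical 4-digit composition code
#'
#' Encodes (Hex, HexNAc, NeuAc, Fuc) as a 4-digit string, e.g. `(4,2,0,0)`
#' -> `"4200"`, used in feature identifiers such as `APMAP.N196.4200`.
#' Counts above 9 cannot be digit-encoded and fall back to the bracket form.
#'
#' @param comp A `glycan_composition` or composition string.
#' @return A character scalar.
#' @export
canonical_composition_digits <- function(comp) {
  if (is.character(comp)) comp <- parse_composition(comp)
  stopifnot(inherits(comp, "glycan_composition"))
  counts <- c(comp$hex, comp$hexnac, comp$neuac, comp$fuc)
  if (any(counts > 9L) || length(comp$other)) {
    return(format(comp))
  }
  paste0(counts, collapse = "")
}

#' Canonical feature identifier for an IGP
#'
#' `"{accession}.N{site}.{digits}"`, e.g. `"APMAP.N196.4200"`.
#'
#' @param accession Protein accession.
#' @param site 1-based site position on the protein sequence.
#' @param comp Composition (string or `glycan_composition`).
#' @return Character vector of feature ids.
#' @export
igp_feature_id <- function(accession, site, comp) {
  digits <- if (is.character(comp)) {
    vapply(comp, function(x) canonical_composition_digits(parse_composition(x)),
           character(1), USE.NAMES = FALSE)
  } else {
    canonical_composition_digits(comp)
  }
  sprintf("%s.N%d.%s", accession, as.integer(site), digits)
}
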