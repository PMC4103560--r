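# FASTA and delimited-table I/O. Parsing is delegated to Biostrings; this
# layer normalizes to the package's tibble conventions (id, description, seq).

#' Read a FASTA file into a sequence tibble
#'
#' The id is the header text up to the first whitespace; anything after it is
#' kept separately as the description. Residues are normalized to the
#' canonical upper-case DNA alphabet (U becomes T); gaps are allowed so
#' aligned FASTA reads through the same path.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A tibble with columns `id`, `description`, `seq`, in file order.
#'   An empty file yields a zero-row tibble.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  tibble::tibble(
    id = ids,
    description = desc,
    seq = unname(normalize_sequence(as.character(set), allow_gap = TRUE))
  )
}

#' Write sequences to a FASTA file
#'
#' @param seqs A tibble with columns `id` and `seq` (optional `description`),
#'   or a named character vector.
#' @param path Destination path.
#' @param line_width Residues per line (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, line_width = 70L) {
  if (is.character(seqs)) {
    seqs <- tibble::tibble(id = names(seqs), description = "",
                           seq = unname(seqs))
  }
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  desc <- rep_len(ifelse(is.na(desc), "", desc), nrow(seqs))
  headers <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  set <- Biostrings::BStringSet(seqs$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = line_width)
  invisible(path)
}

#' Read primer definitions from a delimited file
#'
#' Expects (at least) three columns: `name`, `seq` (5'->3' IUPAC, no gaps)
#' and `orientation` (`forward` or `reverse`); an optional `citation` column
#' is carried through. Tab- or comma-delimited, with header.
#'
#' @param path Path to the primer table.
#' @return A primer tibble as produced by [primer()].
#' @export
read_primers <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- suppressMessages(readr::read_delim(
    path, delim = if (grepl("\\.csv$", path)) "," else "\t",
    show_col_types = FALSE, trim_ws = TRUE))
  stopifnot(all(c("name", "seq", "orientation") %in% names(tab)))
  primer(tab$name, tab$seq, tab$orientation,
         citation = if ("citation" %in% names(tab)) tab$citation else NA)
}

#' Construct a primer tibble
#'
#' A primer is a named 5'->3' IUPAC oligonucleotide with an orientation.
#' Lengths must be between 15 and 35 nt and gaps are not allowed; the
#' degeneracy (product of per-position expansion-set sizes) is computed and
#' stored.
#'
#' @param name Character vector of primer names.
#' @param seq Character vector of 5'->3' IUPAC sequences.
#' @param orientation `"forward"` or `"reverse"` (recycled).
#' @param citation Optional provenance text.
#' @return A tibble with columns `name`, `seq`, `orientation`, `length`,
#'   `degeneracy`, `citation`.
#' @export
primer <- function(name, seq, orientation, citation = NA_character_) {
  seq <- normalize_sequence(seq, allow_gap = FALSE)
  orientation <- match.arg(orientation, c("forward", "reverse"),
                           several.ok = TRUE)
  len <- nchar(seq)
  if (any(len < 15L | len > 35L)) {
    stop("primer length must be within [15, 35] nt", call. = FALSE)
  }
  tibble::tibble(
    name = as.character(name), seq = seq,
    orientation = rep_len(orientation, length(seq)),
    length = len, degeneracy = degeneracy(seq),
    citation = rep_len(as.character(citation), length(seq))
  )
}

#' Published peritrich 18S rDNA assay primers
#'
#' The universal eukaryotic forward primer EukA and the four peritrich-clade
#' primers used throughout the package examples: two forward (Peri974F,
#' Peri979F) and two reverse (Peri1004R, Peri1403R), named after their
#' 5'-anchor coordinates on the *Opisthonecta henneguyi* 18S rRNA gene
#' reference.
#'
#' @return A primer tibble (see [primer()]).
#' @examples
#' assay_primers()
#' @export
assay_primers <- function() {
  primer(
    name = c("EukA", "Peri974F", "Peri979F", "Peri1004R", "Peri1403R"),
    seq = c("AACCTGGTTGATCCTGCCAGT",
            "GGAAACTCATCAGGRCAAGAAGATT",
            "CTCATCAGGRCAAGAAGATT",
            "TCCTAYAATCTTCTTGYCCTGATG",
            "GGGCGRTGTGTACATTTTG"),
    orientation = c("forward", "forward", "forward", "reverse", "reverse"),
    citation = c("Medlin et al. 1988", "clade-specific", "clade-specific",
                 "clade-specific", "clade-specific")
  )
}
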