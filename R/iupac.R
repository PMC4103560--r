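# IUPAC nucleotide degeneracy algebra.
#
# Every base is represented internally as a 4-bit mask over {A, C, G, T}
# (A = 1, C = 2, G = 4, T = 8); two codes are compatible iff their masks
# intersect.  The gap character maps to 0 and is compatible with nothing.

.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # G/C
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L,
  "-" = 0L
)

# mask -> minimal IUPAC code (DNA alphabet; index = mask + 1, mask 0 -> "-")
.MASK_CODE <- c("-", "A", "C", "M", "G", "R", "S", "V",
                "T", "W", "Y", "H", "K", "D", "B", "N")

# per-code GC fraction: |set ∩ {G,C}| / |set|
.GC_FRAC <- vapply(.IUPAC_MASK, function(m) {
  if (m == 0L) return(NA_real_)
  bits <- as.integer(intToBits(m))[1:4]
  sum(bits[c(2L, 3L)]) / sum(bits)
}, numeric(1))

# complement swaps A<->T (1<->8) and C<->G (2<->4)
.COMP_MASK <- vapply(0:15, function(m) {
  b <- as.integer(intToBits(m))[1:4] # A C G T
  sum(rev(b) * c(1L, 2L, 4L, 8L))
}, numeric(1))

.mask_sizes <- vapply(0:15, function(m) sum(as.integer(intToBits(m))[1:4]),
                      integer(1))

#' Normalize a nucleotide string to the canonical IUPAC DNA alphabet
#'
#' Upper-cases the input and converts U to T. Used by every function that
#' accepts sequence text; normalization is idempotent.
#'
#' @param x Character vector of nucleotide strings.
#' @param allow_gap Should `-` be accepted?
#' @return Character vector of the same length, upper-case DNA alphabet.
#' @export
normalize_sequence <- function(x, allow_gap = TRUE) {
  out <- chartr("U", "T", toupper(x))
  bad <- validate_iupac(out, allow_gap = allow_gap)
  if (!is.null(bad)) {
    stop("non-IUPAC character '", bad$char, "' at position ", bad$pos,
         " of sequence ", bad$seq_index, call. = FALSE)
  }
  out
}

# returns NULL if ok, else list(seq_index, pos, char)
validate_iupac <- function(x, allow_gap = TRUE) {
  alphabet <- names(.IUPAC_MASK)
  if (!allow_gap) alphabet <- setdiff(alphabet, "-")
  for (i in seq_along(x)) {
    ch <- strsplit(x[[i]], "", fixed = TRUE)[[1]]
    hit <- which(!(ch %in% alphabet))
    if (length(hit)) {
      return(list(seq_index = i, pos = hit[[1]], char = ch[[hit[[1]]]]))
    }
  }
  NULL
}

# encode one normalized string as an integer mask vector
encode_masks <- function(seq) {
  unname(.IUPAC_MASK[strsplit(seq, "", fixed = TRUE)[[1]]])
}

decode_masks <- function(masks) {
  paste(.MASK_CODE[masks + 1L], collapse = "")
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' IUPAC-correct complementation (R<->Y, S<->S, W<->W, K<->M, B<->V, D<->H,
#' N<->N); gaps are preserved in place. The operation is an involution.
#'
#' @param seq Character vector of IUPAC strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("GGGCGRTGTGTACATTTTG")
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_sequence(seq)
  vapply(seq, function(s) {
    m <- encode_masks(s)
    decode_masks(rev(.COMP_MASK[m + 1L]))
  }, character(1), USE.NAMES = FALSE)
}

#' Number of concrete sequences a degenerate oligo represents
#'
#' @param seq IUPAC string (no gaps).
#' @return Integer product of per-position expansion-set sizes.
#' @export
degeneracy <- function(seq) {
  seq <- normalize_sequence(seq, allow_gap = FALSE)
  vapply(seq, function(s) prod(.mask_sizes[encode_masks(s) + 1L]),
         numeric(1), USE.NAMES = FALSE)
}

#' Expand a degenerate IUPAC string into its concrete A/C/G/T sequences
#'
#' @param seq A single IUPAC string without gaps.
#' @param max_expansions Cap on the number of expansions; exceeding it is an
#'   error (the count is reported), so a pathological oligo cannot explode
#'   memory.
#' @return Character vector of concrete sequences in lexicographic order.
#' @examples
#' expand_degenerate("RY")
#' @export
expand_degenerate <- function(seq, max_expansions = 4096L) {
  stopifnot(length(seq) == 1L, max_expansions >= 1L)
  seq <- normalize_sequence(seq, allow_gap = FALSE)
  n <- degeneracy(seq)
  if (n > max_expansions) {
    stop("degenerate expansion would produce ", n, " sequences (cap ",
         max_expansions, ")", call. = FALSE)
  }
  sets <- lapply(encode_masks(seq), function(m) {
    c("A", "C", "G", "T")[as.logical(intToBits(m)[1:4])]
  })
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(out)
}

#' Expected GC content of a (possibly degenerate) oligonucleotide
#'
#' Each position contributes the GC fraction of its expansion set (e.g. R
#' contributes 1/2, S contributes 1), so the result equals the mean GC% over
#' all concrete expansions. This degenerate-average convention is fixed, not
#' configurable.
#'
#' @param seq Character vector of IUPAC strings (no gaps).
#' @return Numeric vector of GC percentages in \[0, 100\].
#' @examples
#' gc_content("GGAAACTCATCAGGRCAAGAAGATT") # 42
#' @export
gc_content <- function(seq) {
  seq <- normalize_sequence(seq, allow_gap = FALSE)
  vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (!length(ch)) stop("empty sequence", call. = FALSE)
    100 * mean(.GC_FRAC[ch])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Melting-temperature range of a degenerate oligonucleotide
#'
#' Computes Tm for every concrete expansion with the selected method and
#' returns the min and max; a non-degenerate oligo has `tm_min == tm_max`.
#' Two methods are provided: `"wallace"` (2(A+T) + 4(G+C), the rule of
#' thumb for short oligos) and `"salt_gc"`, the salt-adjusted GC formula
#' 81.5 + 16.6 log10(\[Na+\]) + 0.41 GC% - 600/length. Neither is claimed to
#' reproduce any particular published Tm column; vendor formulas vary.
#'
#' @param seq Character vector of IUPAC strings (no gaps).
#' @param method `"salt_gc"` (default) or `"wallace"`.
#' @param na_molar Monovalent cation concentration in mol/L (salt_gc only).
#' @param max_expansions Expansion cap passed to [expand_degenerate()].
#' @return A tibble with columns `seq`, `method`, `tm_min`, `tm_max` (degC).
#' @export
melting_temperature <- function(seq, method = c("salt_gc", "wallace"),
                                na_molar = 0.05, max_expansions = 4096L) {
  if (is.character(method) && length(method) == 1L &&
      !method %in% c("salt_gc", "wallace")) {
    stop("unknown Tm method '", method, "'", call. = FALSE)
  }
  method <- match.arg(method)
  seq <- normalize_sequence(seq, allow_gap = FALSE)
  tm_one <- function(concrete) {
    n <- nchar(concrete)
    gc_n <- vapply(strsplit(concrete, "", fixed = TRUE),
                   function(ch) sum(ch %in% c("G", "C")), numeric(1))
    switch(method,
      wallace = 2 * (n - gc_n) + 4 * gc_n,
      salt_gc = 81.5 + 16.6 * log10(na_molar) + 0.41 * (100 * gc_n / n) - 600 / n
    )
  }
  rows <- lapply(seq, function(s) {
    tms <- tm_one(expand_degenerate(s, max_expansions = max_expansions))
    tibble::tibble(seq = s, method = method,
                   tm_min = min(tms), tm_max = max(tms))
  })
  dplyr::bind_rows(rows)
}
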