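# In-silico PCR: amplicon prediction from a primer pair, and semi-nested
# screening of clone libraries. Product length follows the inclusive-span
# convention: from the forward primer's 5' base to the plus-strand image of
# the reverse primer's 5' base, both primer footprints included.

#' Predict PCR products of a primer pair on template sequences
#'
#' Finds every (forward site, downstream reverse site) pair where the
#' forward primer binds the plus strand and the reverse primer binds the
#' minus strand, each with at most `max_mismatches` incompatible positions.
#' With `forbid_3p_terminal_mismatch = TRUE` (the default) a site whose
#' 3'-terminal primer base is mismatched cannot prime, mirroring polymerase
#' extension requirements. An empty result means no amplification.
#'
#' @param templates A tibble with columns `id`, `seq` (or named character).
#' @param fwd,rev Primer sequence strings or 1-row primer tibbles (both
#'   given 5'->3' as synthesized).
#' @param max_mismatches Per-primer mismatch tolerance.
#' @param forbid_3p_terminal_mismatch Disallow a mismatch at the primer 3'
#'   terminus.
#' @param length_bounds Allowed product length range in bp.
#' @return A tibble sorted by template and product length: `template_id`,
#'   `fwd_start`, `fwd_mismatches`, `rev_start`, `rev_end`,
#'   `rev_mismatches`, `product_length`, `product_seq` (template plus-strand
#'   bases, primer footprints included).
#' @export
predict_amplicons <- function(templates, fwd, rev, max_mismatches = 2L,
                              forbid_3p_terminal_mismatch = TRUE,
                              length_bounds = c(50L, 5000L)) {
  tab <- .as_templates(templates)
  fseq <- .as_primer_seq(fwd)
  rseq <- .as_primer_seq(rev)
  out <- list()
  for (i in seq_len(nrow(tab))) {
    fhits <- scan_primer(tab[i, ], fseq, max_mismatches, strands = "plus")
    rhits <- scan_primer(tab[i, ], rseq, max_mismatches, strands = "minus")
    if (forbid_3p_terminal_mismatch) {
      fhits <- dplyr::filter(fhits, !.data$terminal_3p_mismatch)
      rhits <- dplyr::filter(rhits, !.data$terminal_3p_mismatch)
    }
    if (!nrow(fhits) || !nrow(rhits)) next
    for (a in seq_len(nrow(fhits))) {
      for (b in seq_len(nrow(rhits))) {
        if (rhits$start[[b]] <= fhits$end[[a]]) next  # reverse site not downstream
        len <- rhits$end[[b]] - fhits$start[[a]] + 1L
        if (len < length_bounds[[1]] || len > length_bounds[[2]]) next
        out[[length(out) + 1L]] <- tibble::tibble(
          template_id = tab$id[[i]],
          fwd_start = fhits$start[[a]],
          fwd_mismatches = fhits$mismatch_count[[a]],
          rev_start = rhits$start[[b]],
          rev_end = rhits$end[[b]],
          rev_mismatches = rhits$mismatch_count[[b]],
          product_length = len,
          product_seq = substr(tab$seq[[i]], fhits$start[[a]], rhits$end[[b]])
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(template_id = character(), fwd_start = integer(),
                          fwd_mismatches = integer(), rev_start = integer(),
                          rev_end = integer(), rev_mismatches = integer(),
                          product_length = integer(), product_seq = character()))
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, match(.data$template_id, tab$id), .data$product_length)
}

#' Semi-nested screening of templates with an outer and an inner primer pair
#'
#' Emulates colony-PCR screening: a template is outer-positive if the outer
#' pair predicts a product, and inner-positive only if an inner product lies
#' entirely within an outer product of the same template (the inner amplicon
#' is semi-nested within the outer one). Outer-positive templates without a
#' nested inner product are screen-negative.
#'
#' @param templates A tibble with columns `id`, `seq`.
#' @param outer_fwd,outer_rev Outer primer pair.
#' @param inner_fwd,inner_rev Inner primer pair.
#' @param max_mismatches,forbid_3p_terminal_mismatch,length_bounds Settings
#'   applied to both pairs, see [predict_amplicons()].
#' @return A tibble with one row per template: `template_id`,
#'   `outer_product`, `inner_positive`.
#' @export
nested_screen <- function(templates, outer_fwd, outer_rev, inner_fwd,
                          inner_rev, max_mismatches = 2L,
                          forbid_3p_terminal_mismatch = TRUE,
                          length_bounds = c(50L, 5000L)) {
  tab <- .as_templates(templates)
  outer <- predict_amplicons(tab, outer_fwd, outer_rev, max_mismatches,
                             forbid_3p_terminal_mismatch, length_bounds)
  inner <- predict_amplicons(tab, inner_fwd, inner_rev, max_mismatches,
                             forbid_3p_terminal_mismatch, length_bounds)
  purrr::map_dfr(seq_len(nrow(tab)), function(i) {
    id <- tab$id[[i]]
    o <- dplyr::filter(outer, .data$template_id == id)
    k <- dplyr::filter(inner, .data$template_id == id)
    nested <- FALSE
    if (nrow(o) && nrow(k)) {
      for (a in seq_len(nrow(k))) {
        if (any(k$fwd_start[[a]] >= o$fwd_start &
                k$rev_end[[a]] <= o$rev_end)) {
          nested <- TRUE
          break
        }
      }
    }
    tibble::tibble(template_id = id, outer_product = nrow(o) > 0,
                   inner_positive = nested)
  })
}

# ---- restriction digestion / RFLP ------------------------------------------

#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param site Recognition site as an IUPAC string.
#' @param cut_offset Bases after the site's 5' start on the top strand at
#'   which the enzyme cuts (0 <= offset <= site length); MspI (C^CGG) has
#'   site `"CCGG"` and offset 1.
#' @return A 1-row tibble `name`, `site`, `cut_offset`.
#' @examples
#' enzyme_mspi()
#' @export
restriction_enzyme <- function(name, site, cut_offset) {
  site <- normalize_sequence(site, allow_gap = FALSE)
  cut_offset <- as.integer(cut_offset)
  stopifnot(all(cut_offset >= 0L), all(cut_offset <= nchar(site)))
  tibble::tibble(name = as.character(name), site = site,
                 cut_offset = cut_offset)
}

#' @rdname restriction_enzyme
#' @export
enzyme_mspi <- function() restriction_enzyme("MspI", "CCGG", 1L)

#' Read restriction-enzyme definitions from a delimited file
#'
#' Expects columns `name`, `site`, `cut_offset` (tab- or comma-delimited,
#' with header).
#'
#' @param path Path to the enzyme table.
#' @return An enzyme tibble, see [restriction_enzyme()].
#' @export
read_enzymes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- suppressMessages(readr::read_delim(
    path, delim = if (grepl("\\.csv$", path)) "," else "\t",
    show_col_types = FALSE, trim_ws = TRUE))
  stopifnot(all(c("name", "site", "cut_offset") %in% names(tab)))
  restriction_enzyme(tab$name, tab$site, tab$cut_offset)
}

#' Digest a molecule with a restriction enzyme
#'
#' Cuts at every IUPAC-aware occurrence of the recognition site on the plus
#' strand (a palindromic site such as CCGG covers both strands). A linear
#' molecule with n cuts yields n+1 fragments; a circular one yields n
#' fragments (and a single full-length "fragment" when uncut). Fragment
#' lengths always sum to the molecule length.
#'
#' @param molecule A sequence string (or 1-row tibble with `seq`).
#' @param enzyme A 1-row enzyme tibble, see [restriction_enzyme()].
#' @param topology `"linear"` or `"circular"`.
#' @return Integer vector of fragment lengths, descending.
#' @examples
#' digest("AACCGGTT", enzyme_mspi())  # 5 3
#' @export
digest <- function(molecule, enzyme, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  seq <- if (is.data.frame(molecule)) molecule$seq[[1]] else molecule
  seq <- normalize_sequence(seq, allow_gap = FALSE)
  n <- nchar(seq)
  stopifnot(n >= 1L)
  hits <- scan_primer(c(molecule = seq), enzyme$site[[1]],
                      max_mismatches = 0L, strands = "plus")
  cuts <- sort(unique(hits$start + enzyme$cut_offset[[1]] - 1L))
  cuts <- cuts[cuts >= 1L & cuts < n]   # a cut at position k splits k | k+1
  if (topology == "linear") {
    frags <- diff(c(0L, cuts, n))
  } else if (!length(cuts)) {
    frags <- n
  } else {
    frags <- diff(c(cuts, cuts[[1]] + n))
  }
  sort(as.integer(frags), decreasing = TRUE)
}

#' Group amplicons by restriction-fragment pattern (RFLP typing)
#'
#' Digests each amplicon and groups equal patterns: two patterns share a
#' type iff they have the same number of fragments and each corresponding
#' (rank-sorted) fragment pair differs by at most `size_tolerance_bp`,
#' emulating gel resolution. Grouping is greedy against the first-seen
#' representative after a canonical sort, so it is deterministic under
#' input permutation.
#'
#' @param amplicons A tibble with columns `template_id` and `product_seq`
#'   (e.g. from [predict_amplicons()]), or a named character vector of
#'   sequences.
#' @param enzyme A 1-row enzyme tibble.
#' @param size_tolerance_bp Per-fragment size tolerance in bp (default 10).
#' @param topology Passed to [digest()].
#' @return A tibble with one row per amplicon: `template_id`,
#'   `pattern` (fragment lengths, descending, as text), `pattern_key`
#'   (the group representative's pattern), `rflp_type` (integer type index).
#' @export
rflp_group <- function(amplicons, enzyme, size_tolerance_bp = 10L,
                       topology = "linear") {
  stopifnot(size_tolerance_bp >= 0L)
  if (is.character(amplicons)) {
    ids <- names(amplicons)
    if (is.null(ids)) ids <- paste0("amplicon", seq_along(amplicons))
    amplicons <- tibble::tibble(template_id = ids,
                                product_seq = unname(amplicons))
  }
  stopifnot(all(c("template_id", "product_seq") %in% names(amplicons)))
  pats <- lapply(amplicons$product_seq, digest, enzyme = enzyme,
                 topology = topology)
  pat_txt <- vapply(pats, paste, character(1), collapse = "|")
  # canonical processing order: by fragment count, then lengths, then id
  ord <- order(lengths(pats), pat_txt, amplicons$template_id)
  reps <- list()
  type_of <- integer(nrow(amplicons))
  for (i in ord) {
    assigned <- FALSE
    for (g in seq_along(reps)) {
      r <- reps[[g]]
      if (length(r) == length(pats[[i]]) &&
          all(abs(r - pats[[i]]) <= size_tolerance_bp)) {
        type_of[[i]] <- g
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps[[length(reps) + 1L]] <- pats[[i]]
      type_of[[i]] <- length(reps)
    }
  }
  tibble::tibble(
    template_id = amplicons$template_id,
    pattern = pat_txt,
    pattern_key = vapply(reps[type_of], paste, character(1), collapse = "|"),
    rflp_type = type_of
  )
}
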