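# IUPAC-aware primer-template matching with end-resolved mismatch
# accounting. Degenerate bases are matched as compatible sets (non-empty
# intersection of expansion sets), never by enumerating expansions; the
# equivalence of the two routes is asserted in the test suite.

#' Are two IUPAC codes compatible?
#'
#' Two codes are compatible iff their expansion sets intersect: R (A/G) is
#' compatible with A but not with Y (C/T); N is compatible with every base.
#' The relation is symmetric. Gaps are not bases and raise an error.
#'
#' @param primer_base,template_base Single IUPAC characters (vectorized,
#'   recycled).
#' @return Logical vector.
#' @examples
#' base_compatible("R", "A")
#' base_compatible("R", "Y")
#' @export
base_compatible <- function(primer_base, template_base) {
  p <- normalize_sequence(primer_base, allow_gap = TRUE)
  t <- normalize_sequence(template_base, allow_gap = TRUE)
  if (any(p == "-") || any(t == "-")) {
    stop("gap character is not a base", call. = FALSE)
  }
  stopifnot(all(nchar(p) == 1L), all(nchar(t) == 1L))
  bitwAnd(as.integer(.IUPAC_MASK[p]), as.integer(.IUPAC_MASK[t])) > 0L
}

# primer masks as bound to the plus strand at the site: for a minus-strand
# site the reverse complement of the primer is what lies along the plus
# strand, and primer 5' offsets run right-to-left across the site.
.primer_site_masks <- function(pm, strand) {
  if (strand == "plus") pm else rev(as.integer(.COMP_MASK[pm + 1L]))
}

# mismatch counts for every offset of pm (site-oriented masks) along tm
.mm_counts <- function(tm, pm) {
  L <- length(pm)
  noff <- length(tm) - L + 1L
  if (noff < 1L) return(integer(0))
  mm <- integer(noff)
  for (j in seq_len(L)) {
    mm <- mm + (bitwAnd(pm[j], tm[j:(j + noff - 1L)]) == 0L)
  }
  mm
}

#' Evaluate one primer-template binding position
#'
#' Positions are 1-based on the template plus strand; `start` is the
#' 5'-most template coordinate of the site interval regardless of strand
#' (a minus-strand site is reported by its plus-strand interval). Mismatch
#' positions are reported as offsets from both primer ends, and a count of
#' ambiguous template bases inside the site is carried for transparency
#' (a template N is compatible with any primer base).
#'
#' @param template A single template sequence string (or 1-row tibble with
#'   `id`, `seq`).
#' @param primer A primer sequence string or 1-row primer tibble.
#' @param start 1-based start of the site on the plus strand.
#' @param strand `"plus"` or `"minus"`.
#' @return A 1-row tibble: `template_id`, `start`, `end`, `strand`,
#'   `mismatch_count`, `mismatch_offsets_5p`, `mismatch_offsets_3p`
#'   (list-columns of 1-based offsets), `terminal_3p_mismatch`,
#'   `n_ambiguous_template`.
#' @export
match_at <- function(template, primer, start, strand = c("plus", "minus")) {
  strand <- match.arg(strand)
  tpl <- .as_template(template)
  prm <- .as_primer_seq(primer)
  tm <- encode_masks(tpl$seq)
  pm <- encode_masks(prm)
  L <- length(pm)
  if (start < 1L || start + L - 1L > length(tm)) {
    stop("primer (length ", L, ") overhangs template '", tpl$id,
         "' at start ", start, call. = FALSE)
  }
  site <- tm[start:(start + L - 1L)]
  sm <- .primer_site_masks(pm, strand)
  bad <- which(bitwAnd(sm, site) == 0L)             # site coordinates
  off5 <- if (strand == "plus") bad else L - bad + 1L # primer 5' offsets
  off5 <- sort(off5)
  tibble::tibble(
    template_id = tpl$id,
    start = as.integer(start),
    end = as.integer(start + L - 1L),
    strand = strand,
    mismatch_count = length(bad),
    mismatch_offsets_5p = list(as.integer(off5)),
    mismatch_offsets_3p = list(as.integer(sort(L - off5 + 1L))),
    terminal_3p_mismatch = (L %in% off5),
    n_ambiguous_template = sum(.mask_sizes[site + 1L] > 1L)
  )
}

#' Scan a primer along templates
#'
#' Reports every binding position (on the requested strands) with at most
#' `max_mismatches` incompatible positions, sorted by template, start and
#' strand. Matching is ungapped; with `max_mismatches = 0` and a
#' non-degenerate primer this reduces to exact substring search.
#'
#' @param templates A tibble with columns `id` and `seq`, a named character
#'   vector, or a single string.
#' @param primer A primer sequence string or 1-row primer tibble.
#' @param max_mismatches Maximum tolerated incompatible positions.
#' @param strands Subset of `c("plus", "minus")`.
#' @return A tibble of [match_at()] rows (zero rows if nothing binds).
#' @export
scan_primer <- function(templates, primer, max_mismatches = 0L,
                        strands = c("plus", "minus")) {
  stopifnot(max_mismatches >= 0L)
  strands <- match.arg(strands, c("plus", "minus"), several.ok = TRUE)
  tab <- .as_templates(templates)
  prm <- .as_primer_seq(primer)
  pm <- encode_masks(prm)
  out <- vector("list", 0L)
  for (i in seq_len(nrow(tab))) {
    tm <- encode_masks(tab$seq[[i]])
    for (strand in strands) {
      mm <- .mm_counts(tm, .primer_site_masks(pm, strand))
      hits <- which(mm <= max_mismatches)
      for (s in hits) {
        out[[length(out) + 1L]] <-
          match_at(tab[i, ], prm, s, strand)
      }
    }
  }
  if (!length(out)) {
    return(match_at(.EMPTY_TEMPLATE, "NNNNNNNNNNNNNNN", 1L)[0, ])
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, match(.data$template_id, tab$id), .data$start,
                 .data$strand)
}

.EMPTY_TEMPLATE <- tibble::tibble(id = "empty",
                                  seq = strrep("N", 15))

#' Group-specificity profile of a primer
#'
#' For every sequence, finds the best (minimum-mismatch) binding site on
#' either strand under a permissive mismatch ceiling, and summarizes by
#' group: how many target sequences carry a perfect (0-mismatch) site, the
#' corresponding percentage, and the minimum mismatch count observed in any
#' non-target. Sequences with no site at or below the ceiling get
#' `min_mismatches = NA` (reported as beyond the ceiling).
#'
#' @param sequences A tibble with columns `id`, `group` (values `"target"` /
#'   `"nontarget"`) and `seq`. Both groups must be non-empty.
#' @param primer A primer sequence string or 1-row primer tibble.
#' @param max_mismatches Permissive ceiling for the per-sequence search.
#' @return A `specificity_report` object; see [tidy.specificity_report()]
#'   and [glance.specificity_report()].
#' @export
specificity_profile <- function(sequences, primer, max_mismatches = 5L) {
  stopifnot(all(c("id", "group", "seq") %in% names(sequences)))
  if (!all(c("target", "nontarget") %in% sequences$group)) {
    stop("both a target and a nontarget group are required", call. = FALSE)
  }
  prm <- .as_primer_seq(primer)
  prm_name <- .as_primer_name(primer)
  pm <- encode_masks(prm)
  rows <- lapply(seq_len(nrow(sequences)), function(i) {
    tm <- encode_masks(sequences$seq[[i]])
    best <- NULL
    for (strand in c("plus", "minus")) {
      mm <- .mm_counts(tm, .primer_site_masks(pm, strand))
      if (!length(mm)) next
      s <- which.min(mm)
      if (is.null(best) || mm[s] < best$mm) {
        best <- list(mm = mm[s], start = s, strand = strand)
      }
    }
    if (is.null(best) || best$mm > max_mismatches) {
      return(tibble::tibble(
        id = sequences$id[[i]], group = sequences$group[[i]],
        min_mismatches = NA_integer_, best_start = NA_integer_,
        strand = NA_character_, terminal_3p_mismatch = NA,
        n_ambiguous_template = NA_integer_))
    }
    det <- match_at(sequences[i, c("id", "seq")], prm, best$start, best$strand)
    tibble::tibble(
      id = sequences$id[[i]], group = sequences$group[[i]],
      min_mismatches = det$mismatch_count,
      best_start = det$start, strand = det$strand,
      terminal_3p_mismatch = det$terminal_3p_mismatch,
      n_ambiguous_template = det$n_ambiguous_template)
  })
  per_seq <- dplyr::bind_rows(rows)
  tgt <- dplyr::filter(per_seq, .data$group == "target")
  non <- dplyr::filter(per_seq, .data$group == "nontarget")
  n_perfect <- sum(!is.na(tgt$min_mismatches) & tgt$min_mismatches == 0L)
  structure(list(
    primer = prm_name,
    primer_seq = prm,
    max_mismatches = max_mismatches,
    per_sequence = per_seq,
    n_target = nrow(tgt),
    n_nontarget = nrow(non),
    n_perfect_target = n_perfect,
    pct_perfect_target = 100 * n_perfect / nrow(tgt),
    min_nontarget_mismatches =
      if (all(is.na(non$min_mismatches))) NA_integer_
      else min(non$min_mismatches, na.rm = TRUE)
  ), class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("Specificity profile for primer", x$primer, "(", x$primer_seq, ")\n")
  cat(sprintf("  targets: %d, perfect sites: %d (%.1f%%)\n",
              x$n_target, x$n_perfect_target, x$pct_perfect_target))
  cat(sprintf("  non-targets: %d, minimum mismatches: %s (ceiling %d)\n",
              x$n_nontarget,
              ifelse(is.na(x$min_nontarget_mismatches), paste0(">", x$max_mismatches),
                     x$min_nontarget_mismatches),
              x$max_mismatches))
  invisible(x)
}

#' Per-sequence rows of a specificity report
#'
#' @param x A `specificity_report`.
#' @param ... Unused.
#' @return A tibble with one row per input sequence.
#' @export
tidy.specificity_report <- function(x, ...) x$per_sequence

#' One-row summary of a specificity report
#'
#' @param x A `specificity_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.specificity_report <- function(x, ...) {
  tibble::tibble(
    primer = x$primer,
    n_target = x$n_target,
    n_nontarget = x$n_nontarget,
    n_perfect_target = x$n_perfect_target,
    pct_perfect_target = x$pct_perfect_target,
    min_nontarget_mismatches = x$min_nontarget_mismatches
  )
}

#' Write the per-sequence specificity table as delimited text
#'
#' One row per sequence: id, group, min_mismatches, best_site_start, strand,
#' terminal_3p_mismatch. Tab-separated.
#'
#' @param report A `specificity_report`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
export_specificity <- function(report, path) {
  tab <- dplyr::rename(report$per_sequence, best_site_start = "best_start")
  readr::write_tsv(tab, path)
  invisible(path)
}

# ---- coercion helpers -------------------------------------------------------

.as_primer_seq <- function(primer) {
  if (is.data.frame(primer)) {
    stopifnot(nrow(primer) == 1L, "seq" %in% names(primer))
    primer <- primer$seq
  }
  stopifnot(is.character(primer), length(primer) == 1L)
  normalize_sequence(primer, allow_gap = FALSE)
}

.as_primer_name <- function(primer) {
  if (is.data.frame(primer) && "name" %in% names(primer)) return(primer$name[[1]])
  "primer"
}

.as_template <- function(template) {
  if (is.data.frame(template)) {
    stopifnot(nrow(template) == 1L, all(c("id", "seq") %in% names(template)))
    return(list(id = template$id[[1]],
                seq = normalize_sequence(template$seq[[1]])))
  }
  stopifnot(is.character(template), length(template) == 1L)
  id <- if (!is.null(names(template))) names(template) else "template"
  list(id = id, seq = normalize_sequence(unname(template)))
}

.as_templates <- function(templates) {
  if (is.data.frame(templates)) {
    stopifnot(all(c("id", "seq") %in% names(templates)))
    return(tibble::tibble(id = templates$id,
                          seq = normalize_sequence(templates$seq)))
  }
  stopifnot(is.character(templates))
  ids <- names(templates)
  if (is.null(ids)) ids <- paste0("template", seq_along(templates))
  tibble::tibble(id = ids, seq = normalize_sequence(unname(templates)))
}
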