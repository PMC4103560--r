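# Candidate discovery of group-specific degenerate primers from a grouped
# multiple alignment. The procedure formalizes by-eye design: slide windows
# over the alignment, build a degenerate consensus from the target rows,
# and keep windows that cover the targets while staying well separated
# (>= a mismatch floor) from every non-target.
#
# Evaluation is two-stage: a fast screen on alignment columns discards
# windows that cannot qualify (a non-target already binds too well at the
# aligned offset), then survivors are re-scored by scanning the consensus
# against the ungapped member sequences, because PCR acts on unaligned
# molecules. All reported numbers come from the ungapped stage.

.aln_mask_matrix <- function(seqs) {
  chs <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chs)
  if (length(unique(lens)) != 1L) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  matrix(as.integer(.IUPAC_MASK[unlist(chs)]), nrow = length(seqs),
         ncol = lens[[1]], byrow = TRUE)
}

# per-column fractional base frequencies among non-gap rows; ambiguity
# codes contribute 1/|set| to each member base
.column_base_freqs <- function(mask_mat) {
  dm <- dim(mask_mat)
  sizes <- array(.mask_sizes[mask_mat + 1L], dim = dm)
  sizes[sizes == 0L] <- NA_integer_      # gaps contribute nothing
  freq <- matrix(0, nrow = 4L, ncol = ncol(mask_mat),
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  for (b in 1:4) {
    present <- array(bitwAnd(mask_mat, as.integer(2^(b - 1))) > 0L, dim = dm)
    w <- ifelse(present, 1 / sizes, 0)
    w[is.na(w)] <- 0
    freq[b, ] <- colSums(w)
  }
  n_nongap <- colSums(mask_mat != 0L)
  list(freq = freq, n_nongap = n_nongap,
       gap_frac = 1 - n_nongap / nrow(mask_mat))
}

#' Degenerate consensus of aligned target sequences
#'
#' For each column, the consensus symbol is the minimal IUPAC code covering
#' every base whose (fractional) frequency among non-gap rows is at least
#' `min_base_freq`; if no base reaches the threshold the majority base is
#' used. Columns whose gap fraction exceeds `max_gap_freq` are rejected
#' with an error of class `cladeassay_gap_column`.
#'
#' @param seqs Character vector of equal-length aligned sequences (the
#'   target rows of the window).
#' @param min_base_freq Minimum base frequency for inclusion (default 0.10).
#' @param max_gap_freq Maximum tolerated per-column gap fraction.
#' @return A single IUPAC string, one symbol per column.
#' @examples
#' degenerate_consensus(c("ACGA", "ACGG"))  # "ACGR"
#' @export
degenerate_consensus <- function(seqs, min_base_freq = 0.10,
                                 max_gap_freq = 0.5) {
  mat <- .aln_mask_matrix(normalize_sequence(seqs))
  st <- .column_base_freqs(mat)
  bad <- which(st$gap_frac > max_gap_freq)
  if (length(bad)) {
    stop(structure(class = c("cladeassay_gap_column", "error", "condition"),
                   list(message = paste0("column ", bad[[1]],
                                         " is gap-dominated"),
                        call = NULL)))
  }
  .consensus_from_freqs(st$freq, st$n_nongap, min_base_freq)
}

.consensus_from_freqs <- function(freq, n_nongap, min_base_freq) {
  masks <- vapply(seq_len(ncol(freq)), function(j) {
    rel <- freq[, j] / n_nongap[[j]]
    keep <- which(rel >= min_base_freq)
    if (!length(keep)) keep <- which.max(rel)
    sum(as.integer(2^(keep - 1L)))
  }, numeric(1))
  decode_masks(as.integer(masks))
}

#' Discover candidate group-specific primer windows
#'
#' Slides windows of every length in `window_len` over a grouped alignment,
#' builds the degenerate target consensus for each window, and retains
#' windows that (re-scored against the ungapped member sequences, both
#' strands) cover at least `min_target_coverage` of the targets at
#' `coverage_mismatches` or fewer mismatches while every non-target carries
#' at least `min_nontarget_mm` mismatches at its best binding site.
#'
#' Candidates are ranked by non-target separation (descending), target
#' coverage (descending), degeneracy (ascending) and start column
#' (ascending, the deterministic tie-break). Reverse-orientation candidates
#' are reported as the reverse complement of the window consensus, so all
#' thresholds refer to the primer as synthesized.
#'
#' @param alignment A tibble with columns `id` and `seq` (equal-length
#'   aligned rows, gaps allowed).
#' @param groups A tibble with columns `id` and `group`
#'   (`"target"`/`"nontarget"`), jointly covering the alignment.
#' @param window_len Length range `c(min, max)` of candidate windows.
#' @param max_degeneracy Maximum allowed product of per-position
#'   expansion-set sizes.
#' @param min_target_coverage Minimum fraction of targets covered.
#' @param coverage_mismatches Mismatch allowance defining "covered".
#' @param min_nontarget_mm Minimum best-site mismatches required of every
#'   non-target.
#' @param orientation `"forward"`, `"reverse"` or `"both"`.
#' @param min_base_freq,max_gap_freq Consensus parameters, see
#'   [degenerate_consensus()].
#' @return A ranked tibble of candidates: `start_col`, `end_col`,
#'   `window_length`, `orientation`, `seq`, `degeneracy`,
#'   `target_coverage`, `min_nontarget_mismatches`, `gc_percent`,
#'   `tm_min`, `tm_max`. Zero rows when nothing qualifies.
#' @export
design_candidates <- function(alignment, groups,
                              window_len = c(18L, 26L),
                              max_degeneracy = 8L,
                              min_target_coverage = 0.9,
                              coverage_mismatches = 1L,
                              min_nontarget_mm = 3L,
                              orientation = c("both", "forward", "reverse"),
                              min_base_freq = 0.10,
                              max_gap_freq = 0.5) {
  orientation <- match.arg(orientation)
  stopifnot(all(c("id", "seq") %in% names(alignment)),
            all(c("id", "group") %in% names(groups)))
  grp <- groups$group[match(alignment$id, groups$id)]
  if (anyNA(grp)) stop("every alignment row needs a group", call. = FALSE)
  is_tgt <- grp == "target"
  if (sum(is_tgt) < 2L || sum(!is_tgt) < 1L) {
    stop("need >= 2 targets and >= 1 non-target", call. = FALSE)
  }
  aln <- normalize_sequence(alignment$seq)
  mat <- .aln_mask_matrix(aln)
  C <- ncol(mat)

  st <- .column_base_freqs(mat[is_tgt, , drop = FALSE])
  cons <- .consensus_from_freqs(st$freq, st$n_nongap, min_base_freq)
  cons_masks <- encode_masks(cons)
  col_ok <- st$gap_frac <= max_gap_freq
  log_deg <- log2(.mask_sizes[cons_masks + 1L])

  # alignment-column compatibility of every row with the column consensus
  compat <- array(bitwAnd(mat, matrix(cons_masks, nrow = nrow(mat), ncol = C,
                                      byrow = TRUE)) > 0L, dim = dim(mat))
  cs_mm <- t(apply(!compat, 1L, cumsum))       # cumulative mismatches
  cs_ok <- cumsum(col_ok)
  cs_deg <- cumsum(log_deg)

  degapped <- gsub("-", "", aln, fixed = TRUE)
  enc <- lapply(degapped, encode_masks)

  win_sum <- function(cs, s, e) if (s == 1L) cs[e] else cs[e] - cs[s - 1L]

  rows <- list()
  for (L in seq(window_len[[1]], window_len[[2]])) {
    if (L > C) next
    for (s in seq_len(C - L + 1L)) {
      e <- s + L - 1L
      if (win_sum(cs_ok, s, e) < L) next                      # gappy column
      if (win_sum(cs_deg, s, e) > log2(max_degeneracy) + 1e-9) next
      mm_aln <- if (s == 1L) cs_mm[, e] else cs_mm[, e] - cs_mm[, s - 1L]
      # screen: a non-target already below the floor at this offset can
      # only get better over all offsets -> reject
      if (any(mm_aln[!is_tgt] < min_nontarget_mm)) next
      if (mean(mm_aln[is_tgt] <= coverage_mismatches) < min_target_coverage) next

      wseq <- substr(cons, s, e)
      pm <- encode_masks(wseq)
      site_masks <- list(pm, .primer_site_masks(pm, "minus"))
      best <- vapply(enc, function(tm) {
        m <- Inf
        for (sm in site_masks) {
          cnt <- .mm_counts(tm, sm)
          if (length(cnt)) m <- min(m, min(cnt))
        }
        m
      }, numeric(1))
      cov <- mean(best[is_tgt] <= coverage_mismatches)
      non_mm <- min(best[!is_tgt])
      if (cov < min_target_coverage || non_mm < min_nontarget_mm) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        start_col = s, end_col = e, window_length = L, seq = wseq,
        degeneracy = unname(degeneracy(wseq)),
        target_coverage = cov,
        min_nontarget_mismatches = if (is.finite(non_mm)) as.integer(non_mm)
                                   else NA_integer_)
    }
  }
  if (!length(rows)) return(.empty_candidates())
  out <- dplyr::bind_rows(rows)
  orientations <- switch(orientation, both = c("forward", "reverse"),
                         forward = "forward", reverse = "reverse")
  out <- dplyr::bind_rows(lapply(orientations, function(o) {
    x <- out
    x$orientation <- o
    if (o == "reverse") x$seq <- reverse_complement(x$seq)
    x
  }))
  tm <- melting_temperature(out$seq)
  out$gc_percent <- gc_content(out$seq)
  out$tm_min <- tm$tm_min
  out$tm_max <- tm$tm_max
  out <- dplyr::arrange(out,
                        dplyr::desc(.data$min_nontarget_mismatches),
                        dplyr::desc(.data$target_coverage),
                        .data$degeneracy, .data$start_col,
                        .data$orientation)
  dplyr::select(out, "start_col", "end_col", "window_length", "orientation",
                "seq", "degeneracy", "target_coverage",
                "min_nontarget_mismatches", "gc_percent", "tm_min", "tm_max")
}

.empty_candidates <- function() {
  tibble::tibble(start_col = integer(), end_col = integer(),
                 window_length = integer(), orientation = character(),
                 seq = character(), degeneracy = numeric(),
                 target_coverage = numeric(),
                 min_nontarget_mismatches = integer(),
                 gc_percent = numeric(), tm_min = numeric(),
                 tm_max = numeric())
}

#' Map an alignment column to an ungapped reference coordinate
#'
#' Returns the 1-based position, on the ungapped reference sequence, of the
#' first reference non-gap character at or after `start_col` within the
#' window. Errors if the window lies entirely inside a reference gap run.
#'
#' @param alignment A tibble with columns `id` and `seq`.
#' @param reference_id Row id of the reference sequence.
#' @param start_col,end_col 1-based alignment columns of the window
#'   (`end_col` defaults to `start_col`).
#' @return Integer ungapped reference position.
#' @export
map_to_reference <- function(alignment, reference_id, start_col,
                             end_col = start_col) {
  i <- match(reference_id, alignment$id)
  if (is.na(i)) stop("reference row '", reference_id, "' not in alignment",
                     call. = FALSE)
  ch <- strsplit(normalize_sequence(alignment$seq[[i]]), "", fixed = TRUE)[[1]]
  stopifnot(start_col >= 1L, end_col <= length(ch), start_col <= end_col)
  nongap <- ch != "-"
  in_win <- which(nongap[start_col:end_col])
  if (!length(in_win)) {
    stop("window [", start_col, ", ", end_col,
         "] falls entirely in a reference gap", call. = FALSE)
  }
  col <- start_col + in_win[[1]] - 1L
  as.integer(sum(nongap[seq_len(col)]))
}

#' Conventional positional primer name
#'
#' Formats `"<prefix><position><F|R>"`, the field convention of naming
#' clade primers after their reference anchor coordinate.
#'
#' @param prefix Name prefix (e.g. a clade abbreviation).
#' @param position Ungapped reference position (see [map_to_reference()]).
#' @param orientation `"forward"` or `"reverse"`.
#' @return Character name.
#' @examples
#' format_primer_name("Peri", 974, "forward")
#' @export
format_primer_name <- function(prefix, position, orientation) {
  orientation <- match.arg(orientation, c("forward", "reverse"),
                           several.ok = TRUE)
  paste0(prefix, position, ifelse(orientation == "forward", "F", "R"))
}
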