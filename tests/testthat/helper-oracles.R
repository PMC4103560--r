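# Independent brute-force oracles. These deliberately avoid the package's
# internal representations: degeneracy is handled by full enumeration of
# concrete sequences, clustering by re-deriving the linkage from the raw
# distance matrix at every step.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_expand <- function(seq) {
  sets <- ORACLE_SETS[strsplit(seq, "")[[1]]]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  sort(out)
}

oracle_collapse <- function(strings) {
  chars <- do.call(rbind, strsplit(strings, ""))
  codes <- vapply(seq_len(ncol(chars)), function(j) {
    set <- sort(unique(chars[, j]))
    names(Filter(function(s) identical(sort(s), set), ORACLE_SETS))[1]
  }, character(1))
  paste(codes, collapse = "")
}

oracle_revcomp <- function(seq) {
  rc <- vapply(oracle_expand(seq), function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1))
  oracle_collapse(rc)
}

oracle_gc <- function(seq) {
  exp <- oracle_expand(seq)
  mean(vapply(exp, function(s) {
    ch <- strsplit(s, "")[[1]]
    100 * mean(ch %in% c("G", "C"))
  }, numeric(1)))
}

# minimum Hamming distance over all concrete expansions of the primer
# against the concrete template window at each offset; template assumed
# concrete A/C/G/T. Expansions may be precomputed and passed in.
oracle_min_mm_at <- function(template, primer, start,
                             expansions = oracle_expand(primer)) {
  L <- nchar(primer)
  wch <- strsplit(substr(template, start, start + L - 1L), "")[[1]]
  exp_mat <- do.call(rbind, strsplit(expansions, ""))
  min(rowSums(exp_mat != matrix(wch, nrow(exp_mat), L, byrow = TRUE)))
}

oracle_scan_plus <- function(template, primer, max_mm) {
  L <- nchar(primer)
  n <- nchar(template)
  if (L > n) return(integer(0))
  exp_mat <- do.call(rbind, strsplit(oracle_expand(primer), ""))
  tch <- strsplit(template, "")[[1]]
  starts <- seq_len(n - L + 1L)
  mm <- vapply(starts, function(s) {
    win <- matrix(tch[s:(s + L - 1L)], nrow(exp_mat), L, byrow = TRUE)
    min(rowSums(exp_mat != win))
  }, numeric(1))
  starts[mm <= max_mm]
}

# furthest-neighbour clustering recomputed from first principles: at every
# step scan all cluster pairs, derive the complete linkage by enumerating
# member pairs in the original matrix, merge the smallest (lexicographic
# smallest-member tie-break)
oracle_fn_cluster <- function(D, cutoff) {
  ids <- rownames(D)
  clusters <- as.list(ids)
  repeat {
    k <- length(clusters)
    if (k < 2L) break
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (!is.finite(d) || d > cutoff) next
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        better <- is.null(best) || d < best$d ||
          (d == best$d && (key[1] < best$key[1] ||
                           (key[1] == best$key[1] && key[2] < best$key[2])))
        if (better) best <- list(d = d, i = i, j = j, key = key)
      }
    }
    if (is.null(best)) break
    clusters[[best$i]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters <- clusters[-best$j]
  }
  clusters <- clusters[order(vapply(clusters, min, character(1)))]
  labels <- integer(length(ids))
  names(labels) <- ids
  for (g in seq_along(clusters)) labels[clusters[[g]]] <- g
  labels
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

random_iupac <- function(n, len, codes = names(ORACLE_SETS)) {
  vapply(seq_len(n), function(i) {
    paste(sample(codes, len, replace = TRUE), collapse = "")
  }, character(1))
}

partition_key <- function(labels, ids) {
  split(ids, labels[ids]) |>
    lapply(sort) |>
    (\(x) x[order(vapply(x, `[`, character(1), 1))])() |>
    vapply(paste, character(1), collapse = ",") |>
    paste(collapse = " | ")
}
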