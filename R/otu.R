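# Kimura two-parameter distances and furthest-neighbour (complete-linkage)
# OTU clustering at a distance cutoff, with cross-sample OTU accounting.

.CONCRETE <- c(A = 1L, C = 2L, G = 4L, T = 8L)

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites where either sequence carries a gap or an ambiguity code are
#' excluded (pairwise deletion). With P the transition and Q the
#' transversion proportion among valid sites, d = -1/2 ln((1-2P-Q) *
#' sqrt(1-2Q)), in substitutions per site. Saturated pairs (log argument
#' <= 0) return `Inf`.
#'
#' @param a,b Equal-length aligned sequence strings.
#' @return Distance in substitutions per site (`Inf` when saturated).
#' @examples
#' k2p_distance("AAAA", "AGAA")  # -0.5 * log(0.5)
#' @export
k2p_distance <- function(a, b) {
  a <- encode_masks(normalize_sequence(a))
  b <- encode_masks(normalize_sequence(b))
  if (length(a) != length(b)) {
    stop("aligned sequences differ in length", call. = FALSE)
  }
  valid <- a %in% .CONCRETE & b %in% .CONCRETE
  n <- sum(valid)
  if (n == 0L) stop("no valid (unambiguous, ungapped) sites", call. = FALSE)
  av <- a[valid]
  bv <- b[valid]
  diff <- av != bv
  # transitions: A<->G (masks 1,4) and C<->T (masks 2,8); both members of a
  # purine or pyrimidine pair
  purine <- function(m) m %in% c(1L, 4L)
  ti <- diff & (purine(av) == purine(bv))
  P <- sum(ti) / n
  Q <- sum(diff & !ti) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(Inf)
  -0.5 * log(arg1 * sqrt(arg2))
}

#' Pairwise K2P distance matrix of an alignment
#'
#' @param alignment A tibble with columns `id`, `seq` (equal-length aligned
#'   rows), or a named character vector.
#' @return A symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
k2p_matrix <- function(alignment) {
  tab <- .as_templates(alignment)
  n <- nrow(tab)
  D <- matrix(0, n, n, dimnames = list(tab$id, tab$id))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        D[i, j] <- D[j, i] <- k2p_distance(tab$seq[[i]], tab$seq[[j]])
      }
    }
  }
  D
}

#' Write a distance matrix in square PHYLIP-like text
#'
#' @param D A square distance matrix with dimnames.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format(nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(c(rownames(D)[i], formatC(D[i, ], digits = 6,
                                               format = "f")),
                     collapse = "  "), con)
  }
  invisible(path)
}

#' Furthest-neighbour (complete-linkage) OTU clustering at a cutoff
#'
#' Agglomerates clusters while the smallest complete-linkage inter-cluster
#' distance (the maximum pairwise member distance) is at or below the
#' cutoff. Ties at the same linkage distance are broken by the
#' lexicographically smallest pair of smallest member ids, so partitions
#' are bit-reproducible and independent of input order. Saturated pairs
#' (`Inf`) are never merged. Every OTU satisfies max intra-OTU distance
#' <= cutoff; OTU indices are ordered by each OTU's smallest member id.
#'
#' @param D A symmetric distance matrix with dimnames (see [k2p_matrix()]).
#' @param cutoff Distance cutoff; 0.01 corresponds to the conventional 99%
#'   similarity OTU definition.
#' @return An `otu_assignment`: list with `labels` (tibble `id`, `otu`),
#'   `n_otus`, `cutoff`.
#' @export
cluster_furthest_neighbor <- function(D, cutoff = 0.01) {
  ids <- rownames(D)
  stopifnot(!is.null(ids), nrow(D) == ncol(D))
  clusters <- as.list(ids)          # member ids per cluster
  link <- D                         # complete linkage between clusters
  repeat {
    k <- length(clusters)
    if (k < 2L) break
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        d <- link[i, j]
        if (!is.finite(d) || d > cutoff) next
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || d < best$d ||
            (d == best$d && (key[1] < best$key[1] ||
                             (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(d = d, i = i, j = j, key = key)
        }
      }
    }
    if (is.null(best)) break
    i <- best$i; j <- best$j
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    newlink <- pmax(link[i, ], link[j, ])    # Lance-Williams, complete
    clusters[[i]] <- merged
    link[i, ] <- newlink
    link[, i] <- newlink
    link[i, i] <- 0
    clusters <- clusters[-j]
    link <- link[-j, -j, drop = FALSE]
  }
  ord <- order(vapply(clusters, min, character(1)))
  clusters <- clusters[ord]
  labels <- dplyr::bind_rows(lapply(seq_along(clusters), function(g) {
    tibble::tibble(id = clusters[[g]], otu = g)
  }))
  labels <- labels[match(ids, labels$id), ]
  structure(list(labels = labels, n_otus = length(clusters),
                 cutoff = cutoff),
            class = "otu_assignment")
}

#' @export
print.otu_assignment <- function(x, ...) {
  cat("OTU assignment:", nrow(x$labels), "sequences in", x$n_otus,
      "OTUs at distance cutoff", x$cutoff, "\n")
  invisible(x)
}

#' Per-sequence OTU labels
#'
#' @param x An `otu_assignment`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `otu`.
#' @export
tidy.otu_assignment <- function(x, ...) x$labels

#' One-row OTU clustering summary
#'
#' @param x An `otu_assignment`.
#' @param ... Unused.
#' @return A one-row tibble with `n_sequences`, `n_otus`, `cutoff`.
#' @export
glance.otu_assignment <- function(x, ...) {
  tibble::tibble(n_sequences = nrow(x$labels), n_otus = x$n_otus,
                 cutoff = x$cutoff)
}

#' Cross-sample OTU accounting
#'
#' Given a global OTU assignment and a sample membership table, reports the
#' number of distinct OTUs per sample, the number of distinct OTUs overall,
#' and which OTUs occur in two or more samples.
#'
#' @param assignment An `otu_assignment` over all sequences.
#' @param samples A tibble with columns `id` and `sample`; every sequence
#'   must belong to exactly one sample.
#' @return A list with `per_sample` (tibble `sample`, `n_otus`),
#'   `n_unique_global`, and `sharing` (tibble `otu`, `n_samples`,
#'   `samples`), where `sharing` lists OTUs found in >= 2 samples.
#' @export
shared_otus <- function(assignment, samples) {
  stopifnot(inherits(assignment, "otu_assignment"),
            all(c("id", "sample") %in% names(samples)))
  if (anyDuplicated(samples$id)) {
    stop("a sequence appears in more than one sample", call. = FALSE)
  }
  lab <- assignment$labels
  if (!all(lab$id %in% samples$id)) {
    stop("every clustered sequence needs a sample", call. = FALSE)
  }
  joined <- dplyr::inner_join(lab, samples, by = "id")
  per_sample <- joined |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_otus = dplyr::n_distinct(.data$otu), .groups = "drop")
  occupancy <- joined |>
    dplyr::distinct(.data$otu, .data$sample) |>
    dplyr::group_by(.data$otu) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     samples = paste(sort(.data$sample), collapse = ","),
                     .groups = "drop")
  list(per_sample = per_sample,
       n_unique_global = dplyr::n_distinct(joined$otu),
       sharing = dplyr::filter(occupancy, .data$n_samples >= 2L))
}

#' Write an OTU table as delimited text
#'
#' One row per sequence: id, sample (if given), OTU index. Tab-separated.
#'
#' @param assignment An `otu_assignment`.
#' @param path Destination path.
#' @param samples Optional tibble `id`, `sample`.
#' @return `path`, invisibly.
#' @export
export_otus <- function(assignment, path, samples = NULL) {
  tab <- assignment$labels
  if (!is.null(samples)) {
    tab <- dplyr::left_join(tab, samples, by = "id")
    tab <- dplyr::select(tab, "id", "sample", "otu")
  }
  readr::write_tsv(tab, path)
  invisible(path)
}
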