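test_that("K2P distance matches hand evaluation of the closed form", {
  expect_equal(k2p_distance("ACGTACGT", "ACGTACGT"), 0)
  # one transition in four sites: P = 0.25, Q = 0
  expect_equal(k2p_distance("AAAA", "AGAA"), -0.5 * log(0.5),
               tolerance = 1e-9)
  expect_equal(round(k2p_distance("AAAA", "AGAA"), 5), 0.34657)
  # one transversion in four sites: P = 0, Q = 0.25
  expect_equal(k2p_distance("AAAA", "ACAA"),
               -0.5 * log(0.75 * sqrt(0.5)), tolerance = 1e-9)
})

test_that("gapped and ambiguous sites are excluded pairwise", {
  # only the last four sites are valid in both sequences
  expect_equal(k2p_distance("-NRAAAA", "AAAAGAA"),
               k2p_distance("AAAA", "AGAA"))
  expect_error(k2p_distance("----", "AAAA"), "valid")
  expect_error(k2p_distance("AAA", "AAAA"), "length")
})

test_that("saturated pairs return infinity and are never clustered", {
  expect_equal(k2p_distance("AAAAAAAA", "GGGGGGGG"), Inf)
  D <- matrix(c(0, Inf, Inf, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  asg <- cluster_furthest_neighbor(D, cutoff = 100)
  expect_equal(asg$n_otus, 2)
})

test_that("K2P approaches the transition proportion at low divergence", {
  expect_equal(k2p_distance(strrep("A", 1000),
                            paste0("G", strrep("A", 999))),
               0.001, tolerance = 1e-2)
})

test_that("K2P matrix agrees with an independent phylogenetics implementation", {
  skip_if_not_installed("ape")
  set.seed(71)
  # related sequences (mutated copies of one base) so distances are finite;
  # saturated pairs are compared separately (this package returns Inf where
  # ape returns NaN)
  base <- random_dna(1, 300)
  seqs <- vapply(1:6, function(i) {
    ch <- strsplit(base, "")[[1]]
    pos <- sample(300, sample(5:40, 1))
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("s%d", 1:6)
  D <- k2p_matrix(seqs)
  mat <- do.call(rbind, strsplit(tolower(seqs), ""))
  rownames(mat) <- names(seqs)
  Dape <- as.matrix(ape::dist.dna(ape::as.DNAbin(mat), model = "K80",
                                  pairwise.deletion = TRUE))
  expect_equal(D, Dape[rownames(D), colnames(D)], tolerance = 1e-9)
})

test_that("clustering respects the cutoff limit cases", {
  set.seed(41)
  seqs <- random_dna(5, 200)
  names(seqs) <- sprintf("s%d", 1:5)
  D <- k2p_matrix(seqs)
  expect_equal(cluster_furthest_neighbor(D, cutoff = 0.01)$n_otus, 5)
  dup <- c(seqs, s6 = unname(seqs[1]))
  asg <- cluster_furthest_neighbor(k2p_matrix(dup), cutoff = 0)
  lab <- asg$labels
  expect_equal(lab$otu[lab$id == "s1"], lab$otu[lab$id == "s6"])
  expect_equal(asg$n_otus, 5)
})

test_that("furthest-neighbour clustering matches the step-recomputed oracle", {
  set.seed(51)
  for (trial in 1:25) {
    n <- sample(4:8, 1)
    base <- random_dna(1, 150)
    seqs <- vapply(1:n, function(i) {
      k <- sample(0:12, 1)
      ch <- strsplit(base, "")[[1]]
      pos <- sample(length(ch), k)
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      paste(ch, collapse = "")
    }, character(1))
    names(seqs) <- sprintf("s%02d", 1:n)
    D <- k2p_matrix(seqs)
    cutoff <- sample(c(0.01, 0.03, 0.05), 1)
    got <- cluster_furthest_neighbor(D, cutoff)
    want <- oracle_fn_cluster(D, cutoff)
    lab <- stats::setNames(got$labels$otu, got$labels$id)
    expect_equal(partition_key(lab, names(seqs)),
                 partition_key(want, names(seqs)))
  }
})

test_that("clustering agrees with hclust complete linkage on distinct distances", {
  set.seed(61)
  for (trial in 1:10) {
    n <- 12
    D <- matrix(0, n, n, dimnames = list(sprintf("x%02d", 1:n),
                                         sprintf("x%02d", 1:n)))
    v <- stats::runif(n * (n - 1) / 2, 0, 0.08)
    D[lower.tri(D)] <- v
    D <- D + t(D)
    cutoff <- 0.03
    got <- cluster_furthest_neighbor(D, cutoff)
    hc <- stats::hclust(stats::as.dist(D), method = "complete")
    want <- stats::cutree(hc, h = cutoff)
    lab <- stats::setNames(got$labels$otu, got$labels$id)
    expect_equal(partition_key(lab, rownames(D)),
                 partition_key(want, rownames(D)))
  }
})

test_that("the complete-linkage invariant holds and cutoffs are monotone", {
  set.seed(81)
  fam <- generate_family(family_spec(n_target = 12, n_nontarget = 0,
                                     sequence_length = 300,
                                     target_divergence = 0.03, seed = 5))
  D <- k2p_matrix(fam$sequences)
  cuts <- c(0, 0.005, 0.01, 0.02, 0.05, 0.1)
  n_otus <- vapply(cuts, function(cv) {
    asg <- cluster_furthest_neighbor(D, cv)
    lab <- asg$labels
    for (g in unique(lab$otu)) {
      ids <- lab$id[lab$otu == g]
      if (length(ids) > 1) expect_lte(max(D[ids, ids]), cv)
    }
    asg$n_otus
  }, integer(1))
  expect_true(all(diff(n_otus) <= 0))
})

test_that("partitions are invariant under input permutation", {
  set.seed(91)
  seqs <- random_dna(8, 150)
  base <- seqs[1]
  seqs[2:4] <- vapply(2:4, function(i) {
    paste0(substr(base, 1, 148), substr(seqs[i], 149, 150))
  }, character(1))
  names(seqs) <- sprintf("p%d", 1:8)
  a1 <- cluster_furthest_neighbor(k2p_matrix(seqs), 0.02)
  perm <- sample(8)
  a2 <- cluster_furthest_neighbor(k2p_matrix(seqs[perm]), 0.02)
  l1 <- stats::setNames(a1$labels$otu, a1$labels$id)
  l2 <- stats::setNames(a2$labels$otu, a2$labels$id)
  expect_equal(partition_key(l1, names(seqs)), partition_key(l2, names(seqs)))
})

test_that("cross-sample accounting counts per-sample, global and shared OTUs", {
  # 12 sequences in 11 OTUs across 4 samples; OTU 7 occurs in two samples
  labels <- tibble::tibble(
    id = sprintf("c%02d", 1:12),
    otu = c(1, 2, 3, 4, 5, 6, 7, 7, 8, 9, 10, 11))
  asg <- structure(list(labels = labels, n_otus = 11, cutoff = 0.01),
                   class = "otu_assignment")
  samples <- tibble::tibble(
    id = labels$id,
    sample = c(rep("F", 6), "B1", "M", rep("B2", 4)))
  res <- shared_otus(asg, samples)
  per <- stats::setNames(res$per_sample$n_otus, res$per_sample$sample)
  expect_equal(per[c("F", "B1", "B2", "M")],
               c(F = 6L, B1 = 1L, B2 = 4L, M = 1L))
  expect_equal(res$n_unique_global, 11)
  expect_equal(res$sharing$otu, 7)
  expect_equal(res$sharing$samples, "B1,M")
})

test_that("cross-sample accounting handles degenerate partitions", {
  labels <- tibble::tibble(id = c("a", "b", "c"), otu = 1:3)
  asg <- structure(list(labels = labels, n_otus = 3, cutoff = 0.01),
                   class = "otu_assignment")
  res <- shared_otus(asg, tibble::tibble(id = c("a", "b", "c"),
                                         sample = c("s1", "s2", "s3")))
  expect_equal(res$n_unique_global, 3)
  expect_equal(nrow(res$sharing), 0)
  expect_error(
    shared_otus(asg, tibble::tibble(id = c("a", "a", "b", "c"),
                                    sample = c("s1", "s2", "s1", "s1"))),
    "more than one sample")
})

test_that("distance matrices and OTU tables export as text", {
  set.seed(99)
  seqs <- random_dna(4, 100)
  names(seqs) <- sprintf("q%d", 1:4)
  D <- k2p_matrix(seqs)
  pd <- withr::local_tempfile(fileext = ".dist")
  write_distance_matrix(D, pd)
  lines <- readLines(pd)
  expect_equal(as.integer(lines[1]), 4)
  expect_equal(length(lines), 5)
  asg <- cluster_furthest_neighbor(D, 0.05)
  po <- withr::local_tempfile(fileext = ".tsv")
  export_otus(asg, po, samples = tibble::tibble(id = names(seqs),
                                                sample = "s1"))
  back <- readr::read_tsv(po, show_col_types = FALSE)
  expect_equal(names(back), c("id", "sample", "otu"))
  expect_equal(nrow(back), 4)
})
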