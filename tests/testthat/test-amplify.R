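fwd20 <- "GGATCCTAGGCATCGATCGA"
rev20 <- "TTGACGGCATTGCAATGGCA"

make_template <- function(insert = 400, seed = 1) {
  set.seed(seed)
  paste0(random_dna(1, 30), fwd20, random_dna(1, insert),
         reverse_complement(rev20), random_dna(1, 30))
}

test_that("a constructed template yields exactly one product of known size", {
  tpl <- make_template(400)
  amp <- predict_amplicons(tpl, fwd20, rev20, max_mismatches = 0)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$product_length, 20L + 400L + 20L)
  expect_equal(amp$fwd_start, 31L)
  expect_equal(nchar(amp$product_seq), amp$product_length)
})

test_that("templates lacking the reverse site do not amplify", {
  set.seed(2)
  tpl <- paste0(random_dna(1, 30), fwd20, random_dna(1, 300))
  expect_equal(nrow(predict_amplicons(tpl, fwd20, rev20)), 0)
})

test_that("a 3'-terminal mismatch toggles amplification", {
  tpl <- make_template(300, seed = 3)
  # mutate the template base under the forward primer 3' terminus
  pos <- 30L + 20L
  ch <- substr(tpl, pos, pos)
  sub <- setdiff(c("A", "C", "G", "T"), ch)[1]
  tpl_mut <- paste0(substr(tpl, 1, pos - 1), sub,
                    substr(tpl, pos + 1, nchar(tpl)))
  strict <- predict_amplicons(tpl_mut, fwd20, rev20, max_mismatches = 2,
                              forbid_3p_terminal_mismatch = TRUE)
  loose <- predict_amplicons(tpl_mut, fwd20, rev20, max_mismatches = 2,
                             forbid_3p_terminal_mismatch = FALSE)
  expect_equal(nrow(strict), 0)
  expect_equal(nrow(loose), 1)
})

test_that("exact amplicon prediction matches a brute-force oracle", {
  set.seed(8)
  for (i in 1:10) {
    tpl <- random_dna(1, 400)
    f <- substr(tpl, 41, 52)
    r <- reverse_complement(substr(tpl, 301, 312))
    amp <- predict_amplicons(tpl, f, r, max_mismatches = 0,
                             length_bounds = c(1, 1000))
    f_starts <- oracle_scan_plus(tpl, f, 0)
    r_starts <- oracle_scan_plus(tpl, reverse_complement(r), 0)
    pairs <- expand.grid(fs = f_starts, rs = r_starts)
    pairs <- pairs[pairs$rs > pairs$fs + nchar(f) - 1, , drop = FALSE]
    expect_equal(nrow(amp), nrow(pairs))
    if (nrow(amp)) {
      expect_setequal(amp$product_length,
                      pairs$rs + nchar(r) - 1 - pairs$fs + 1)
    }
  }
})

test_that("semi-nested screening requires an outer product around the inner", {
  inner_f <- "CAGGTACCGGTTAACCGGTA"
  tpl_inner_only <- paste0(strrep("A", 40), inner_f, strrep("C", 200),
                           reverse_complement(rev20), strrep("A", 40))
  res <- nested_screen(tpl_inner_only, fwd20, rev20, inner_f, rev20)
  expect_false(res$outer_product)
  expect_false(res$inner_positive)

  set.seed(12)
  tpl_nested <- paste0(random_dna(1, 30), fwd20, random_dna(1, 60), inner_f,
                       random_dna(1, 200), reverse_complement(rev20),
                       random_dna(1, 30))
  res2 <- nested_screen(tpl_nested, fwd20, rev20, inner_f, rev20)
  expect_true(res2$outer_product)
  expect_true(res2$inner_positive)
})

test_that("inner-positives are always a subset of outer-positives", {
  ref <- synthetic_ssu_reference(seed = 31)
  p <- assay_primers()
  s <- stats::setNames(p$seq, p$name)
  pool <- tibble::tibble(
    id = c("clade", "offclade"),
    seq = c(ref$seq, cladeassay:::.scramble_inner_site(ref$seq, 31)))
  lib <- generate_library(library_spec(pool, n_clones = 30,
                                       proportions = c(0.4, 0.6), seed = 2))
  res <- nested_screen(lib$clones, s[["EukA"]], s[["Peri1403R"]],
                       s[["Peri974F"]], s[["Peri1403R"]])
  expect_true(all(res$outer_product[res$inner_positive]))
})

test_that("restriction digestion cuts at recognition sites", {
  expect_equal(digest("AACCGGTT", enzyme_mspi()), c(5L, 3L))
  expect_equal(digest("AAAATTTT", enzyme_mspi()), 8L)
  # two sites, cut after the first C of each: C | CGGAAC | CGGTT
  expect_equal(digest("CCGGAACCGGTT", enzyme_mspi()), c(6L, 5L, 1L))
})

test_that("digest conserves total length on linear and circular molecules", {
  set.seed(14)
  for (i in 1:50) {
    mol <- random_dna(1, sample(200:2000, 1))
    lin <- digest(mol, enzyme_mspi(), topology = "linear")
    circ <- digest(mol, enzyme_mspi(), topology = "circular")
    expect_equal(sum(lin), nchar(mol))
    expect_equal(sum(circ), nchar(mol))
    n_sites <- length(oracle_scan_plus(mol, "CCGG", 0))
    expect_equal(length(lin), n_sites + 1L)
    expect_equal(length(circ), max(n_sites, 1L))
  }
})

test_that("circular digestion with one cut returns one full-length fragment", {
  mol <- paste0("CCGG", strrep("A", 96))
  expect_equal(digest(mol, enzyme_mspi(), topology = "circular"), 100L)
  expect_equal(digest(mol, enzyme_mspi(), topology = "linear"), c(99L, 1L))
})

test_that("enzyme definitions validate and load from delimited text", {
  expect_error(restriction_enzyme("bad", "CCGG", 7), "cut_offset")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tsite\tcut_offset", "MspI\tCCGG\t1", "EcoRI\tGAATTC\t1"),
             path)
  enz <- read_enzymes(path)
  expect_equal(enz$name, c("MspI", "EcoRI"))
  expect_equal(enz$cut_offset, c(1L, 1L))
})

test_that("RFLP typing groups by binned fragment patterns", {
  set.seed(19)
  base <- random_dna(1, 500)
  seqs <- c(a1 = base, a2 = base,
            b1 = paste0(substr(base, 1, 100), "CCGG",
                        substr(base, 105, 500)))
  g <- rflp_group(seqs, enzyme_mspi(), size_tolerance_bp = 0)
  expect_equal(g$rflp_type[g$template_id == "a1"],
               g$rflp_type[g$template_id == "a2"])
  expect_equal(length(unique(g$rflp_type)), 2)

  # planted distinct patterns stay distinct at tolerance 0
  mols <- vapply(c(100, 200, 300), function(k) {
    paste0(strrep("A", k), "CCGG", strrep("T", 400 - k))
  }, character(1))
  names(mols) <- paste0("m", 1:3)
  g0 <- rflp_group(mols, enzyme_mspi(), size_tolerance_bp = 0)
  expect_equal(length(unique(g0$rflp_type)), 3)
  gbig <- rflp_group(mols, enzyme_mspi(), size_tolerance_bp = 500)
  expect_equal(length(unique(gbig$rflp_type)), 1)
})

test_that("RFLP grouping is permutation-invariant and tolerance-monotone", {
  set.seed(23)
  mols <- random_dna(12, 600)
  names(mols) <- sprintf("m%02d", 1:12)
  g1 <- rflp_group(mols, enzyme_mspi(), size_tolerance_bp = 10)
  perm <- sample(12)
  g2 <- rflp_group(mols[perm], enzyme_mspi(), size_tolerance_bp = 10)
  key1 <- stats::setNames(g1$pattern_key, g1$template_id)
  key2 <- stats::setNames(g2$pattern_key, g2$template_id)
  expect_equal(key1[names(key2)], key2)
  counts <- vapply(c(0, 5, 10, 25, 50, 1000), function(tol) {
    length(unique(rflp_group(mols, enzyme_mspi(), tol)$rflp_type))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})
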