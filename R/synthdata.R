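# Seeded generators for every input class the toolkit consumes, with truth
# records sufficient to score the downstream modules. All generators are
# pure functions of their spec (seed included).

.sample_expansion <- function(oligo) {
  masks <- encode_masks(oligo)
  paste(vapply(masks, function(m) {
    opts <- c("A", "C", "G", "T")[as.logical(intToBits(m)[1:4])]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

# substitute exactly k positions of `site` to bases incompatible with the
# corresponding degenerate code of `oligo`
.plant_mismatches <- function(site, oligo, k) {
  ch <- strsplit(site, "", fixed = TRUE)[[1]]
  masks <- encode_masks(oligo)
  pos <- sample(length(ch), k)
  for (p in pos) {
    bad <- c("A", "C", "G", "T")[!as.logical(intToBits(masks[[p]])[1:4])]
    ch[[p]] <- if (length(bad)) sample(bad, 1L) else ch[[p]]
  }
  paste(ch, collapse = "")
}

# two-rate-class substitution process: each site mutates with probability
# `rate`; a mutation is a transition with odds kappa : 2 against the two
# transversions
.mutate_seq <- function(seq, rate, kappa = 2) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  ti <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"),
             T = c("A", "G"))
  for (p in hit) {
    if (stats::runif(1) < kappa / (kappa + 2)) {
      ch[[p]] <- ti[[ch[[p]]]]
    } else {
      ch[[p]] <- sample(tv[[ch[[p]]]], 1L)
    }
  }
  paste(ch, collapse = "")
}

.overwrite <- function(seq, at, piece) {
  paste0(substr(seq, 1L, at - 1L), piece,
         substr(seq, at + nchar(piece), nchar(seq)))
}

#' Specify a synthetic target/non-target sequence family
#'
#' Describes a family of related sequences with planted, group-specific
#' primer sites: targets carry (mostly) exact copies of each planted oligo,
#' non-targets carry a planned number of mismatches inside each site, and
#' background positions diverge from a common ancestor under a
#' two-rate-class (transition/transversion) substitution process.
#'
#' @param n_target,n_nontarget Group sizes.
#' @param sequence_length Sequence length in bp.
#' @param planted_sites A list of site plans, each a list with `position`
#'   (1-based), `oligo` (IUPAC string), and optionally
#'   `nontarget_mismatches` (default 3), `target_exact_count` (default all
#'   targets) and `offplan_mismatches` (mismatch counts available to
#'   non-exact targets, default 2:4). Sites must not overlap.
#' @param target_divergence,nontarget_divergence Per-site background
#'   substitution probabilities from the shared ancestor, in \[0, 0.75\].
#' @param titv_ratio Transition/transversion rate ratio of the
#'   substitution process.
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return A `family_spec` list, validated.
#' @export
family_spec <- function(n_target = 49L, n_nontarget = 56L,
                        sequence_length = 600L,
                        planted_sites = list(),
                        target_divergence = 0.05,
                        nontarget_divergence = 0.15,
                        titv_ratio = 2, seed = 1L) {
  stopifnot(n_target >= 1L, n_nontarget >= 0L, sequence_length >= 50L,
            target_divergence >= 0, target_divergence <= 0.75,
            nontarget_divergence >= 0, nontarget_divergence <= 0.75)
  sites <- lapply(planted_sites, function(s) {
    stopifnot(!is.null(s$position), !is.null(s$oligo))
    s$oligo <- normalize_sequence(s$oligo, allow_gap = FALSE)
    s$nontarget_mismatches <- s$nontarget_mismatches %||% 3L
    s$target_exact_count <- s$target_exact_count %||% n_target
    s$offplan_mismatches <- s$offplan_mismatches %||% 2:4
    stopifnot(s$position >= 1L,
              s$position + nchar(s$oligo) - 1L <= sequence_length,
              s$target_exact_count <= n_target)
    s
  })
  if (length(sites) > 1L) {
    iv <- t(vapply(sites, function(s)
      c(s$position, s$position + nchar(s$oligo) - 1L), numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
      stop("planted sites overlap", call. = FALSE)
    }
  }
  structure(list(n_target = n_target, n_nontarget = n_nontarget,
                 sequence_length = sequence_length, planted_sites = sites,
                 target_divergence = target_divergence,
                 nontarget_divergence = nontarget_divergence,
                 titv_ratio = titv_ratio, seed = as.integer(seed)),
            class = "family_spec")
}

#' Generate a synthetic sequence family with planted primer sites
#'
#' @param spec A [family_spec()].
#' @return A list with `sequences` (tibble `id`, `group`, `seq`) and
#'   `truth` (list with `sites`, a tibble of planted coordinates and the
#'   ids of targets carrying exact sites, and the `spec` itself).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  ancestor <- paste(sample(c("A", "C", "G", "T"), spec$sequence_length,
                           replace = TRUE), collapse = "")
  tgt_ids <- sprintf("target_%02d", seq_len(spec$n_target))
  non_ids <- if (spec$n_nontarget > 0L) {
    sprintf("nontarget_%02d", seq_len(spec$n_nontarget))
  } else character(0)

  exact_ids <- lapply(spec$planted_sites, function(s) {
    sort(sample(tgt_ids, s$target_exact_count))
  })

  make_target <- function(id) {
    s <- .mutate_seq(ancestor, spec$target_divergence, spec$titv_ratio)
    for (k in seq_along(spec$planted_sites)) {
      site <- spec$planted_sites[[k]]
      piece <- .sample_expansion(site$oligo)
      if (!(id %in% exact_ids[[k]])) {
        k_off <- site$offplan_mismatches
        if (length(k_off) > 1L) k_off <- sample(k_off, 1L)
        piece <- .plant_mismatches(piece, site$oligo, k_off)
      }
      s <- .overwrite(s, site$position, piece)
    }
    s
  }
  make_nontarget <- function(id) {
    s <- .mutate_seq(ancestor, spec$nontarget_divergence, spec$titv_ratio)
    for (site in spec$planted_sites) {
      piece <- .plant_mismatches(.sample_expansion(site$oligo), site$oligo,
                                 site$nontarget_mismatches)
      s <- .overwrite(s, site$position, piece)
    }
    s
  }

  sequences <- tibble::tibble(
    id = c(tgt_ids, non_ids),
    group = c(rep("target", spec$n_target),
              rep("nontarget", spec$n_nontarget)),
    seq = c(vapply(tgt_ids, make_target, character(1)),
            vapply(non_ids, make_nontarget, character(1)))
  )
  sites <- if (length(spec$planted_sites)) {
    dplyr::bind_rows(lapply(seq_along(spec$planted_sites), function(k) {
      s <- spec$planted_sites[[k]]
      tibble::tibble(site = k, position = s$position, oligo = s$oligo,
                     length = nchar(s$oligo),
                     nontarget_mismatches = s$nontarget_mismatches,
                     target_exact_count = s$target_exact_count,
                     exact_target_ids = list(exact_ids[[k]]))
    }))
  } else {
    tibble::tibble(site = integer(), position = integer(),
                   oligo = character(), length = integer(),
                   nontarget_mismatches = integer(),
                   target_exact_count = integer(),
                   exact_target_ids = list())
  }
  list(sequences = sequences, truth = list(sites = sites, spec = spec))
}

#' Specify a synthetic clone library
#'
#' A clone library is drawn from a small pool of insert templates, either
#' multinomially (via `proportions`) or with exact per-template `counts`.
#' A fraction of clones can be chimeric: a single uniform crossover between
#' two distinct sampled parents.
#'
#' @param templates A tibble with columns `id`, `seq` (the insert pool).
#' @param n_clones Number of clones to draw.
#' @param proportions Mixing proportions (sum to 1); ignored when `counts`
#'   is given.
#' @param counts Exact per-template clone counts (sums to `n_clones`).
#' @param chimera_fraction Probability a clone is chimeric, in \[0, 1).
#' @param seed Integer seed.
#' @return A `library_spec` list, validated.
#' @export
library_spec <- function(templates, n_clones = 50L, proportions = NULL,
                         counts = NULL, chimera_fraction = 0, seed = 1L) {
  stopifnot(all(c("id", "seq") %in% names(templates)), n_clones >= 1L,
            chimera_fraction >= 0, chimera_fraction < 1)
  if (is.null(counts)) {
    if (is.null(proportions)) {
      proportions <- rep(1 / nrow(templates), nrow(templates))
    }
    stopifnot(length(proportions) == nrow(templates),
              abs(sum(proportions) - 1) < 1e-8)
  } else {
    stopifnot(length(counts) == nrow(templates), sum(counts) == n_clones)
  }
  if (chimera_fraction > 0 && nrow(templates) < 2L) {
    stop("chimeras need a pool of >= 2 templates", call. = FALSE)
  }
  structure(list(templates = tibble::tibble(
    id = templates$id, seq = normalize_sequence(templates$seq)),
    n_clones = as.integer(n_clones), proportions = proportions,
    counts = counts, chimera_fraction = chimera_fraction,
    seed = as.integer(seed)), class = "library_spec")
}

#' Generate a synthetic clone library with truth labels
#'
#' @param spec A [library_spec()].
#' @return A list with `clones` (tibble `id`, `seq`) and `truth` (tibble
#'   `id`, `parent`, `parent2`, `breakpoint`, `is_chimera`).
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  set.seed(spec$seed)
  pool <- spec$templates
  parents <- if (!is.null(spec$counts)) {
    sample(rep(pool$id, spec$counts))
  } else {
    sample(pool$id, spec$n_clones, replace = TRUE, prob = spec$proportions)
  }
  is_chi <- stats::runif(spec$n_clones) < spec$chimera_fraction
  rows <- lapply(seq_len(spec$n_clones), function(i) {
    p1 <- parents[[i]]
    s1 <- pool$seq[[match(p1, pool$id)]]
    if (is_chi[[i]]) {
      p2 <- sample(setdiff(pool$id, p1), 1L)
      s2 <- pool$seq[[match(p2, pool$id)]]
      bp <- sample(min(nchar(s1), nchar(s2)) - 1L, 1L)
      seq <- paste0(substr(s1, 1L, bp), substr(s2, bp + 1L, nchar(s2)))
      tibble::tibble(id = sprintf("clone_%03d", i), seq = seq, parent = p1,
                     parent2 = p2, breakpoint = bp, is_chimera = TRUE)
    } else {
      tibble::tibble(id = sprintf("clone_%03d", i), seq = s1, parent = p1,
                     parent2 = NA_character_, breakpoint = NA_integer_,
                     is_chimera = FALSE)
    }
  })
  tab <- dplyr::bind_rows(rows)
  list(clones = tab[, c("id", "seq")],
       truth = tab[, c("id", "parent", "parent2", "breakpoint",
                       "is_chimera")])
}

#' Generate a noisy qPCR dilution series
#'
#' Tenfold dilution levels with C_T values on a true standard line plus
#' Gaussian noise. The default truth is slope -3.5187 cycles per decade and
#' intercept 32.035 cycles, a realistic published-assay calibration.
#'
#' @param true_slope,true_intercept Standard-line truth.
#' @param levels Number of tenfold dilution levels (>= 3); copies run from
#'   `top_copies` down by decades.
#' @param replicates Replicates per level.
#' @param ct_noise_sd Gaussian C_T noise standard deviation (>= 0).
#' @param top_copies Copies per uL at the least-diluted level.
#' @param seed Integer seed.
#' @return A tibble of dilution points: `level`, `copies_per_ul`,
#'   `replicate`, `ct`.
#' @export
generate_dilution_series <- function(true_slope = -3.5187,
                                     true_intercept = 32.035,
                                     levels = 8L, replicates = 3L,
                                     ct_noise_sd = 0, top_copies = 1e8,
                                     seed = 1L) {
  stopifnot(levels >= 3L, replicates >= 1L)
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  copies <- top_copies / 10^(seq_len(levels) - 1L)
  grid <- tidyr::expand_grid(level = seq_len(levels),
                             replicate = seq_len(replicates))
  grid$copies_per_ul <- copies[grid$level]
  grid$ct <- true_slope * log10(grid$copies_per_ul) + true_intercept +
    stats::rnorm(nrow(grid), sd = ct_noise_sd)
  grid[, c("level", "copies_per_ul", "replicate", "ct")]
}

#' Synthetic SSU rRNA-like reference with canonical primer-site coordinates
#'
#' A synthetic stand-in for an SSU rRNA gene reference: a random background
#' with the universal forward site planted at position 1, the clade forward
#' primer sites planted so the main forward primer's 5' base sits at
#' ungapped position 974 (with the overlapping internal reverse site), and
#' the distal reverse primer site ending at position 1414. The clade
#' forward/distal-reverse pair therefore predicts a single 441-bp product
#' under the inclusive-span convention. This is generated data, not a
#' database record.
#'
#' @param length_bp Total reference length (default 1775).
#' @param seed Integer seed for the background.
#' @return A 1-row tibble `id`, `description`, `seq`.
#' @export
synthetic_ssu_reference <- function(length_bp = 1775L, seed = 7L) {
  stopifnot(length_bp >= 1500L)
  set.seed(seed)
  p <- assay_primers()
  bg <- paste(sample(c("A", "C", "G", "T"), length_bp, replace = TRUE),
              collapse = "")
  seqs <- stats::setNames(p$seq, p$name)
  # region 974..1004 must satisfy the forward primers and the overlapping
  # internal reverse primer simultaneously: intersect their site masks
  region <- as.integer(rep(15L, 31L))  # N over 974..1004
  stack <- list(
    list(at = 1L, masks = encode_masks(seqs[["Peri974F"]])),
    list(at = 6L, masks = encode_masks(seqs[["Peri979F"]])),
    list(at = 8L, masks = .primer_site_masks(encode_masks(seqs[["Peri1004R"]]),
                                             "minus"))
  )
  for (s in stack) {
    idx <- s$at:(s$at + length(s$masks) - 1L)
    region[idx] <- bitwAnd(region[idx], s$masks)
  }
  if (any(region == 0L)) {
    stop("internal: overlapping primer sites are incompatible", call. = FALSE)
  }
  concrete <- vapply(region, function(m) {
    c("A", "C", "G", "T")[which(as.logical(intToBits(m)[1:4]))[1]]
  }, character(1))
  out <- bg
  out <- .overwrite(out, 1L, .sample_expansion(seqs[["EukA"]]))
  out <- .overwrite(out, 974L, paste(concrete, collapse = ""))
  rev_site <- reverse_complement(.sample_expansion(seqs[["Peri1403R"]]))
  out <- .overwrite(out, 1414L - nchar(rev_site) + 1L, rev_site)
  tibble::tibble(
    id = "synthetic_ssu_reference",
    description = "synthetic SSU rRNA-like reference with planted primer sites",
    seq = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
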