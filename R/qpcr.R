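# qPCR standard-curve model and absolute quantitation.
#
# The model is the usual log-linear standard curve C_T = k * log10(copies
# per uL) + b with k < 0: every |k| cycles corresponds to one decade of
# template. Published curves are sometimes printed with the slope's sign
# dropped; fit_standard_curve() always reports the fitted (negative) slope,
# and efficiency() requires a negative slope, which is the only reading
# consistent with E = (10^(-1/k) - 1) * 100%.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of C_T on log10(copies per uL) across a dilution
#' series. By default replicate C_T values are averaged per dilution level
#' before fitting; set `average_replicates = FALSE` to fit all replicate
#' points pooled.
#'
#' @param points A tibble with columns `copies_per_ul` (> 0) and `ct`
#'   (> 0); an optional `replicate` column identifies replicates.
#' @param average_replicates Average replicates per level before fitting?
#' @return A `standard_curve` object with elements `slope` (cycles per
#'   decade, negative for a working assay), `intercept` (C_T at 1 copy/uL),
#'   `r2`, `n_levels`, `n_points`, `efficiency_percent` and the underlying
#'   `lm` fit. Supports [tidy()], [glance()], `autoplot()`.
#' @export
fit_standard_curve <- function(points, average_replicates = TRUE) {
  stopifnot(all(c("copies_per_ul", "ct") %in% names(points)))
  stopifnot(all(points$copies_per_ul > 0), all(points$ct > 0))
  dat <- tibble::tibble(log10_copies = log10(points$copies_per_ul),
                        ct = points$ct)
  n_levels <- dplyr::n_distinct(round(dat$log10_copies, 9))
  if (n_levels < 3L) {
    stop("need >= 3 distinct dilution levels, got ", n_levels, call. = FALSE)
  }
  if (stats::sd(dat$log10_copies) == 0) {
    stop("zero variance in log10 copies: degenerate design", call. = FALSE)
  }
  if (average_replicates) {
    dat <- dat |>
      dplyr::group_by(.data$log10_copies) |>
      dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  }
  fit <- stats::lm(ct ~ log10_copies, data = dat)
  slope <- unname(stats::coef(fit)[["log10_copies"]])
  intercept <- unname(stats::coef(fit)[["(Intercept)"]])
  r2 <- stats::cor(dat$log10_copies, dat$ct)^2
  if (slope >= 0) {
    warning("fitted slope is non-negative; C_T should decrease with ",
            "template amount", call. = FALSE)
  }
  structure(list(
    slope = slope, intercept = intercept, r2 = r2,
    n_levels = n_levels, n_points = nrow(dat),
    efficiency_percent = if (slope < 0) efficiency(slope) else NA_real_,
    fit = fit, data = dat
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: C_T = %.4f * log10(copies/uL) + %.3f\n",
              x$slope, x$intercept))
  cat(sprintf("  R^2 = %.4f over %d levels (%d fitted points); efficiency %.1f%%\n",
              x$r2, x$n_levels, x$n_points, x$efficiency_percent))
  invisible(x)
}

#' Coefficient-level summary of a standard curve
#'
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`,
#'   `std.error`).
#' @export
tidy.standard_curve <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std.error = sm[, 2])
}

#' One-row summary of a standard curve
#'
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @return A one-row tibble with `slope`, `intercept`, `r2`,
#'   `efficiency_percent`, `n_levels`, `n_points`.
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
                 efficiency_percent = x$efficiency_percent,
                 n_levels = x$n_levels, n_points = x$n_points)
}

#' Plot a fitted standard curve
#'
#' @param object A `standard_curve`.
#' @param ... Unused.
#' @return A ggplot of C_T against log10 copies with the fitted line.
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$log10_copies, y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept) +
    ggplot2::labs(
      x = expression(log[10] ~ "(rDNA copies " * mu * L^-1 * ")"),
      y = expression(C[T]),
      title = sprintf("C_T = %.4f log10(copies) + %.3f   (R^2 = %.3f, E = %.1f%%)",
                      object$slope, object$intercept, object$r2,
                      object$efficiency_percent)) +
    ggplot2::theme_minimal()
}

#' Amplification efficiency from the standard-curve slope
#'
#' E = (10^(-1/k) - 1) * 100 with k the (negative) slope in cycles per
#' decade; k = -1/log10(2) (about -3.32) gives 100% (perfect doubling).
#'
#' @param slope Standard-curve slope (cycles per log10 copies), negative.
#' @return Efficiency in percent.
#' @examples
#' efficiency(-3.5187)  # 92.4
#' @export
efficiency <- function(slope) {
  stopifnot(is.numeric(slope))
  if (any(slope == 0)) stop("slope must be non-zero", call. = FALSE)
  if (any(slope > 0)) {
    stop("slope must be negative (C_T decreases with template); a curve ",
         "printed with a positive slope should be read as its negative",
         call. = FALSE)
  }
  (10^(-1 / slope) - 1) * 100
}

#' Copies per microliter of a quantified DNA standard
#'
#' molecules/uL = a / (L * bp_mw) * avogadro, where a is the measured DNA
#' concentration (g/uL), L the fragment length (bp), bp_mw the average
#' molecular weight of a base pair (660 g/mol/bp for double-stranded DNA)
#' and avogadro the molar constant.
#'
#' @param concentration_g_per_ul DNA concentration in g/uL (> 0).
#' @param fragment_length_bp Standard fragment length in bp (> 0).
#' @param bp_mw Average base-pair molecular weight (g/mol/bp).
#' @param avogadro Avogadro constant (1/mol).
#' @return Copies per microliter.
#' @export
molecules_per_ul <- function(concentration_g_per_ul, fragment_length_bp,
                             bp_mw = 660, avogadro = 6.022e23) {
  stopifnot(all(concentration_g_per_ul > 0), all(fragment_length_bp > 0),
            bp_mw > 0, avogadro > 0)
  concentration_g_per_ul / (fragment_length_bp * bp_mw) * avogadro
}

#' Invert a standard curve: C_T to copies per microliter
#'
#' copies = 10^((ct - b) / k); the exact inverse of the fitted line, so a
#' round trip through [fit_standard_curve()] on noiseless data is exact to
#' numerical precision.
#'
#' @param curve A `standard_curve`.
#' @param ct C_T values (vectorized).
#' @return Copies per microliter of template.
#' @export
ct_to_copies <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope >= 0) stop("curve slope must be negative", call. = FALSE)
  10^((ct - curve$intercept) / curve$slope)
}

#' Scale template copies to copies per liter of source water
#'
#' copies/L = copies/uL(template) * (extract volume / template volume) *
#' (1000 / filtered volume in mL). Between-sample ratios are invariant to a
#' common rescaling of extract volumes.
#'
#' @param copies_per_ul_template Copies per uL of template DNA.
#' @param template_vol_ul Template volume per reaction (uL).
#' @param extract_vol_ul Total DNA-extract volume (uL).
#' @param filtered_vol_ml Filtered water volume (mL).
#' @return Copies per liter of source water.
#' @export
copies_per_liter <- function(copies_per_ul_template, template_vol_ul,
                             extract_vol_ul, filtered_vol_ml) {
  stopifnot(all(template_vol_ul > 0), all(extract_vol_ul > 0),
            all(filtered_vol_ml > 0))
  copies_per_ul_template * (extract_vol_ul / template_vol_ul) *
    (1000 / filtered_vol_ml)
}

#' Detection limit in cell equivalents
#'
#' Converts a minimum detectable copy number into cell equivalents given
#' the per-cell rDNA copy number of the calibrating organism.
#'
#' @param min_detectable_copies Copies at the assay detection limit.
#' @param copies_per_cell rDNA copies per cell (> 0).
#' @return Cell equivalents.
#' @examples
#' detection_limit_cells(96, 160000)  # 0.0006
#' @export
detection_limit_cells <- function(min_detectable_copies, copies_per_cell) {
  stopifnot(all(copies_per_cell > 0))
  min_detectable_copies / copies_per_cell
}

#' Quantify environmental samples against a standard curve
#'
#' Converts per-sample C_T values into template copies per uL and copies
#' per liter of source water, averaging replicates per sample. Samples
#' whose mean C_T exceeds `lod_ct` (the C_T at the lowest reliably detected
#' standard) are flagged below detection and their per-liter value set to
#' `NA`.
#'
#' @param samples A tibble with columns `sample`, `ct`, `template_vol_ul`,
#'   `extract_vol_ul`, `filtered_vol_ml` (and optionally `replicate`).
#' @param curve A `standard_curve`.
#' @param lod_ct Optional limit-of-detection C_T.
#' @return A tibble with one row per sample: mean/SD C_T, copies per uL,
#'   copies per liter, `below_detection`.
#' @export
quantify_samples <- function(samples, curve, lod_ct = NULL) {
  need <- c("sample", "ct", "template_vol_ul", "extract_vol_ul",
            "filtered_vol_ml")
  stopifnot(all(need %in% names(samples)))
  out <- samples |>
    dplyr::group_by(.data$sample, .data$template_vol_ul,
                    .data$extract_vol_ul, .data$filtered_vol_ml) |>
    dplyr::summarise(ct_mean = mean(.data$ct),
                     ct_sd = stats::sd(.data$ct),
                     n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      copies_per_ul_template = ct_to_copies(curve, .data$ct_mean),
      below_detection = if (is.null(lod_ct)) FALSE else .data$ct_mean > lod_ct,
      copies_per_liter = ifelse(
        .data$below_detection, NA_real_,
        copies_per_liter(.data$copies_per_ul_template,
                         .data$template_vol_ul, .data$extract_vol_ul,
                         .data$filtered_vol_ml)))
  dplyr::select(out, "sample", "n_replicates", "ct_mean", "ct_sd",
                "copies_per_ul_template", "copies_per_liter",
                "below_detection", "template_vol_ul", "extract_vol_ul",
                "filtered_vol_ml")
}

#' Read a qPCR dilution series or sample C_T table
#'
#' Delimited text with header; a dilution series needs columns
#' `copies_per_ul`, `ct` (optional `replicate`); a sample table needs
#' `sample`, `ct`, `template_vol_ul`, `extract_vol_ul`, `filtered_vol_ml`.
#'
#' @param path Path to the table (TSV, or CSV by extension).
#' @return A tibble.
#' @export
read_qpcr_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  suppressMessages(readr::read_delim(
    path, delim = if (grepl("\\.csv$", path)) "," else "\t",
    show_col_types = FALSE, trim_ws = TRUE))
}
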