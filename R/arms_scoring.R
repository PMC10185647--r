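#' ARMS assay definitions for KRAS codon 12
#'
#' An assay definition bundles everything needed to score one allele-specific
#' PCR + HRM assay: the target allele, the primer pair (the forward primer's
#' 3' base provides allele specificity), the temperature window in which the
#' scoring melting peak is read, the decision threshold on the normalized
#' score, and the melting peaks the assay is expected to produce.
#'
#' Packaged defaults:
#'
#' * `G12V`: forward `CTTGTGGTAGTTGGAGCTTT`, reverse
#'   `CTCTATTGTTGGATCATATTCG`; scoring temperature 79.5 degC (window
#'   +/- 1 degC), expected specific peak at 80.0 degC.
#' * `G12D`: forward `CTTGTGGTAGTTGGAGCTTA`, same reverse; scoring
#'   temperature 79.5 degC; expected peaks at 75.5 degC (genotype-independent
#'   by-product) and 79.5 degC (G12D-specific).
#' * `WT`: control assay for the wild-type allele; expected peak 78.5 degC.
#'   The published study describes the assay but its forward primer sequence
#'   is not in the main text, so the field is `NA` here.
#'
#' @param assay_id `"G12V"`, `"G12D"` or `"WT"`.
#' @param scoring_temp Centre of the scoring window, degC.
#' @param scoring_halfwidth Half-width of the scoring window, degC
#'   (default 1.0; absorbs up to +/- 0.5 degC Tm drift plus grid resolution).
#' @param threshold Normalized-score decision threshold in (0, 1);
#'   default 0.5.
#' @return An object of class `assay_definition`.
#' @export
#' @examples
#' assay_definition("G12D")$expected_peaks
assay_definition <- function(assay_id = c("G12V", "G12D", "WT"),
                             scoring_temp = NULL,
                             scoring_halfwidth = 1.0,
                             threshold = 0.5) {
  assay_id <- match.arg(assay_id)
  defaults <- list(
    G12V = list(target_allele = "G12V",
                forward_primer = "CTTGTGGTAGTTGGAGCTTT",
                reverse_primer = "CTCTATTGTTGGATCATATTCG",
                scoring_temp = 79.5, expected_peaks = 80.0),
    G12D = list(target_allele = "G12D",
                forward_primer = "CTTGTGGTAGTTGGAGCTTA",
                reverse_primer = "CTCTATTGTTGGATCATATTCG",
                scoring_temp = 79.5, expected_peaks = c(75.5, 79.5)),
    WT = list(target_allele = "wt",
              forward_primer = NA_character_,
              reverse_primer = "CTCTATTGTTGGATCATATTCG",
              scoring_temp = 78.5, expected_peaks = 78.5)
  )[[assay_id]]
  if (is.null(scoring_temp)) scoring_temp <- defaults$scoring_temp
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must lie strictly between 0 and 1")
  stopifnot(scoring_halfwidth > 0)
  window <- c(scoring_temp - scoring_halfwidth, scoring_temp + scoring_halfwidth)
  structure(
    list(assay_id = assay_id,
         target_allele = defaults$target_allele,
         forward_primer = defaults$forward_primer,
         reverse_primer = defaults$reverse_primer,
         scoring_temp = scoring_temp,
         scoring_window = window,
         threshold = threshold,
         expected_peaks = defaults$expected_peaks),
    class = "assay_definition")
}

#' @export
print.assay_definition <- function(x, ...) {
  cat(sprintf("<assay_definition> %s (target %s): score window %.1f-%.1f degC, threshold %.2f\n",
              x$assay_id, x$target_allele, x$scoring_window[1L],
              x$scoring_window[2L], x$threshold))
  invisible(x)
}

#' Melting-peak intensity inside the assay's scoring window
#'
#' The raw scoring signal: by default the maximum of -dF/dT inside the
#' assay's scoring window (robust to small Tm drift between runs), clipped
#' at zero.  `mode = "at_temp"` instead reads the -dF/dT value at the grid
#' point nearest the assay's scoring temperature, mirroring a fixed-readout
#' instrument export.
#'
#' @param dcurve A `derivative_curve`.
#' @param assay An [assay_definition].
#' @param mode `"window_max"` (default) or `"at_temp"`.
#' @return Non-negative scalar, a.u. per degC.
#' @export
peak_intensity <- function(dcurve, assay, mode = c("window_max", "at_temp")) {
  stopifnot(inherits(dcurve, "derivative_curve"),
            inherits(assay, "assay_definition"))
  mode <- match.arg(mode)
  tt <- dcurve$temperatures
  win <- assay$scoring_window
  if (win[1L] < tt[1L] - .grid_tol || win[2L] > tt[length(tt)] + .grid_tol)
    stop("scoring window ", win[1L], "-", win[2L],
         " degC lies outside the temperature grid")
  val <- if (mode == "window_max") {
    sel <- tt >= win[1L] & tt <= win[2L]
    max(dcurve$neg_dfdt[sel])
  } else {
    dcurve$neg_dfdt[which.min(abs(tt - assay$scoring_temp))]
  }
  max(val, 0)
}

#' Two-control normalization of a peak intensity
#'
#' Linear rescaling of a sample's scoring-peak intensity so that the run's
#' wild-type (negative) control maps to 0 and its mutant (positive) control
#' maps to 1: `(f_sample - f_neg) / (f_pos - f_neg)`.  Scores are reported
#' as-is — values above 1 (stronger than the positive control) or below 0
#' are informative and are not clipped.
#'
#' @param f_sample,f_neg,f_pos Peak intensities (a.u./degC) of the sample,
#'   the wild-type control and the mutant control.
#' @return Unitless normalized score.
#' @export
normalize_score <- function(f_sample, f_neg, f_pos) {
  if (any(f_neg < 0)) stop("negative control intensity must be >= 0")
  if (any(f_pos <= f_neg))
    stop("control failure: mutant-control intensity (", f_pos,
         ") does not exceed wt-control intensity (", f_neg,
         "); run invalid")
  (f_sample - f_neg) / (f_pos - f_neg)
}

#' Threshold classification of a mean normalized score
#'
#' `MUT` iff the score is strictly above the threshold; a score exactly at
#' the threshold is `NEG` (mutation calls require evidence above the
#' threshold, not at it).
#'
#' @param mean_score Unitless normalized score (replicate mean).
#' @param threshold Decision threshold in (0, 1); default 0.5.
#' @return `"MUT"` or `"NEG"` (vectorised over `mean_score`).
#' @export
classify_call <- function(mean_score, threshold = 0.5) {
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must lie strictly between 0 and 1")
  ifelse(mean_score > threshold, "MUT", "NEG")
}

#' Score a full ARMS-HRMA run
#'
#' The complete scoring pipeline for one assay's plate: each well's curve is
#' smoothed, differentiated, and its scoring-peak intensity extracted; the
#' run's control intensities are averaged across control replicates
#' (negative raw intensities are already clipped to zero); every well is
#' normalized against the control means; replicate wells of one sample are
#' averaged; and the mean score is thresholded into a MUT/NEG call.
#'
#' Run validity: the sheet must provide at least one `wt_control` and one
#' `mut_control` well for the assay, and the mutant-control mean intensity
#' must exceed the wild-type-control mean (otherwise the run is invalid and
#' an error is thrown).  Any NTC well whose scoring-peak intensity exceeds
#' 10% of the mutant-control mean raises a contamination QC flag on every
#' sample of the run.
#'
#' @param curves Named list of [melt_curve] objects (names = well IDs), or
#'   the `curves` element of [read_melt_run()].
#' @param sheet A `sample_sheet`; only rows with the assay's `assay_id` are
#'   used.
#' @param assay An [assay_definition].
#' @param smooth_window,smooth_order Savitzky-Golay parameters passed to
#'   [smooth_curve()].
#' @param mode Peak-intensity readout mode, see [peak_intensity()].
#' @return An object of class `score_run` wrapping:
#'   * `scores`: data.frame with one row per sample/control
#'     (`sample_id`, `role`, `n_replicates`, `mean_raw`, `mean_score`,
#'     `call`, `qc_flags`),
#'   * `replicates`: per-well data.frame (`well_id`, `sample_id`, `role`,
#'     `raw_intensity`, `score`),
#'   * `controls`: list with `f_neg`, `f_pos` (run control means),
#'   * `assay`: the assay definition used.
#' @export
score_run <- function(curves, sheet, assay,
                      smooth_window = 11L, smooth_order = 3L,
                      mode = c("window_max", "at_temp")) {
  stopifnot(inherits(assay, "assay_definition"))
  mode <- match.arg(mode)
  sheet <- validate_sample_sheet(as.data.frame(sheet))
  sub <- sheet[sheet$assay_id == assay$assay_id, , drop = FALSE]
  if (!nrow(sub))
    stop("sample sheet has no wells for assay ", assay$assay_id)
  if (!any(sub$role == "wt_control"))
    stop("run invalid: no wt_control wells for assay ", assay$assay_id)
  if (!any(sub$role == "mut_control"))
    stop("run invalid: no mut_control wells for assay ", assay$assay_id)
  missing_wells <- setdiff(sub$well_id, names(curves))
  if (length(missing_wells))
    stop("no melt curve for well(s): ", paste(missing_wells, collapse = ", "))

  raw <- vapply(sub$well_id, function(w) {
    dc <- negative_derivative(smooth_curve(curves[[w]], smooth_window,
                                           smooth_order))
    peak_intensity(dc, assay, mode = mode)
  }, numeric(1))

  f_neg <- mean(raw[sub$role == "wt_control"])
  f_pos <- mean(raw[sub$role == "mut_control"])
  if (f_pos <= f_neg)
    stop("control failure for assay ", assay$assay_id,
         ": mutant-control mean intensity (", signif(f_pos, 4),
         ") does not exceed wt-control mean (", signif(f_neg, 4),
         "); run invalid")

  scores <- normalize_score(raw, f_neg, f_pos)
  reps <- data.frame(well_id = sub$well_id, sample_id = sub$sample_id,
                     role = sub$role, raw_intensity = unname(raw),
                     score = unname(scores), stringsAsFactors = FALSE,
                     row.names = NULL)

  ntc_flag <- character(0)
  ntc_raw <- raw[sub$role == "ntc"]
  if (length(ntc_raw) && any(ntc_raw > 0.1 * f_pos))
    ntc_flag <- "NTC_SIGNAL"

  grp <- reps[reps$role != "ntc", , drop = FALSE]
  agg <- lapply(split(grp, grp$sample_id), function(g) {
    data.frame(sample_id = g$sample_id[1L], role = g$role[1L],
               n_replicates = nrow(g),
               mean_raw = mean(g$raw_intensity),
               mean_score = mean(g$score),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(match(out$sample_id, sub$sample_id)), , drop = FALSE]
  out$call <- classify_call(out$mean_score, assay$threshold)
  out$qc_flags <- if (length(ntc_flag)) ntc_flag else ""
  row.names(out) <- NULL

  structure(list(scores = out, replicates = reps,
                 controls = list(f_neg = unname(f_neg), f_pos = unname(f_pos)),
                 assay = assay),
            class = "score_run")
}

#' @export
print.score_run <- function(x, ...) {
  cat(sprintf("<score_run> assay %s: %d samples, controls f_neg=%.4g f_pos=%.4g\n",
              x$assay$assay_id, sum(x$scores$role == "sample"),
              x$controls$f_neg, x$controls$f_pos))
  print(utils::head(x$scores, 10))
  if (nrow(x$scores) > 10) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.score_run <- function(x, ...) x$scores
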