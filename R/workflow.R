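#' Plot derivative curves
#'
#' Overlaid -dF/dT traces for a set of wells, the standard instrument-style
#' derivative plot.
#'
#' @param dcurves List of `derivative_curve` objects.
#' @param main Plot title.
#' @param col Line colours (recycled).
#' @return Invisibly, `NULL`.
#' @export
plot_derivative <- function(dcurves, main = "Derivative plot",
                            col = seq_along(dcurves)) {
  stopifnot(length(dcurves) >= 1L)
  ylim <- range(vapply(dcurves, function(d) range(d$neg_dfdt), numeric(2)))
  graphics::plot(dcurves[[1L]]$temperatures, dcurves[[1L]]$neg_dfdt,
                 type = "n", ylim = ylim,
                 xlab = "Temperature (°C)", ylab = "-dF/dT (a.u./°C)",
                 main = main)
  col <- rep_len(col, length(dcurves))
  for (i in seq_along(dcurves))
    graphics::lines(dcurves[[i]]$temperatures, dcurves[[i]]$neg_dfdt,
                    col = col[i])
  invisible(NULL)
}

#' Plot difference curves against a wild-type reference
#'
#' @param dcurves List of [melt_curve] objects as returned by
#'   [difference_curve()].
#' @inheritParams plot_derivative
#' @return Invisibly, `NULL`.
#' @export
plot_difference <- function(dcurves, main = "Difference plot",
                            col = seq_along(dcurves)) {
  stopifnot(length(dcurves) >= 1L)
  ylim <- range(vapply(dcurves, function(d) range(d$fluorescence), numeric(2)))
  graphics::plot(dcurves[[1L]]$temperatures, dcurves[[1L]]$fluorescence,
                 type = "n", ylim = ylim,
                 xlab = "Temperature (°C)",
                 ylab = "Δ Fluorescence (a.u.)", main = main)
  graphics::abline(h = 0, col = "grey60", lty = 2)
  col <- rep_len(col, length(dcurves))
  for (i in seq_along(dcurves))
    graphics::lines(dcurves[[i]]$temperatures, dcurves[[i]]$fluorescence,
                    col = col[i])
  invisible(NULL)
}

#' Score one or more assays end to end and write result files
#'
#' Orchestrates the full scoring pipeline for a melt run: read (or accept)
#' curves and sample sheet, score every requested assay with [score_run()],
#' and write per-assay score tables, replicate tables, derivative/difference
#' plots and a run log to an output directory.  Invalid runs (missing
#' controls, mutant control not exceeding the wild-type control) raise an
#' error after being recorded in the log.
#'
#' @param curves,sheet A named list of [melt_curve] and a `sample_sheet`
#'   (e.g. from [read_melt_run()] or [simulate_run()]); alternatively give
#'   `curve_file`/`sheet_file`.
#' @param curve_file,sheet_file Paths read via [read_melt_run()] when
#'   `curves` is `NULL`.
#' @param assays List of [assay_definition()] objects, or character assay
#'   IDs (default: every assay present in the sheet).
#' @param out_dir Output directory (created if needed).
#' @param smooth_window,smooth_order Savitzky-Golay parameters.
#' @param plots Write PNG derivative/difference plots (default `TRUE`).
#' @return Invisibly, a named list of `score_run` objects.
#' @export
run_scoring <- function(curves = NULL, sheet = NULL,
                        curve_file = NULL, sheet_file = NULL,
                        assays = NULL, out_dir = ".",
                        smooth_window = 11L, smooth_order = 3L,
                        plots = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_line <- function(...) cat(..., "\n", sep = "", file = log_path,
                                append = TRUE)
  cat("", file = log_path)  # truncate
  log_line("armshrma scoring run")
  if (is.null(curves)) {
    if (is.null(curve_file) || is.null(sheet_file))
      stop("give either curves+sheet or curve_file+sheet_file")
    run <- tryCatch(read_melt_run(curve_file, sheet_file), error = function(e) {
      log_line("INVALID RUN - ", conditionMessage(e)); stop(e)
    })
    curves <- run$curves
    sheet <- run$sheet
  }
  sheet <- tryCatch(validate_sample_sheet(as.data.frame(sheet)),
                    error = function(e) {
                      log_line("INVALID RUN - ", conditionMessage(e)); stop(e)
                    })
  if (is.null(assays)) assays <- unique(sheet$assay_id)
  if (is.character(assays)) assays <- lapply(assays, assay_definition)
  names(assays) <- vapply(assays, `[[`, "", "assay_id")
  log_line("wells: ", length(curves), "; assays: ",
           paste(names(assays), collapse = ", "))

  results <- list()
  for (assay in assays) {
    aid <- assay$assay_id
    res <- tryCatch(
      score_run(curves, sheet, assay, smooth_window = smooth_window,
                smooth_order = smooth_order),
      error = function(e) {
        log_line("assay ", aid, ": INVALID RUN - ", conditionMessage(e))
        stop(e)
      })
    log_line(sprintf("assay %s: f_neg=%.6g f_pos=%.6g, %d samples, %d MUT",
                     aid, res$controls$f_neg, res$controls$f_pos,
                     sum(res$scores$role == "sample"),
                     sum(res$scores$call == "MUT" & res$scores$role == "sample")))
    if (any(res$scores$qc_flags != ""))
      log_line("assay ", aid, ": QC flags present (NTC signal)")
    utils::write.csv(res$scores,
                     file.path(out_dir, paste0("scores_", aid, ".csv")),
                     row.names = FALSE)
    utils::write.csv(res$replicates,
                     file.path(out_dir, paste0("replicates_", aid, ".csv")),
                     row.names = FALSE)
    if (plots) write_assay_plots(curves, sheet, assay, res, out_dir,
                                 smooth_window, smooth_order)
    results[[aid]] <- res
  }
  invisible(results)
}

#' @noRd
write_assay_plots <- function(curves, sheet, assay, res, out_dir,
                              smooth_window, smooth_order) {
  aid <- assay$assay_id
  sub <- sheet[sheet$assay_id == aid, , drop = FALSE]
  smoothed <- lapply(sub$well_id, function(w)
    smooth_curve(curves[[w]], smooth_window, smooth_order))
  names(smoothed) <- sub$well_id
  dcurves <- lapply(smoothed, negative_derivative)
  grDevices::png(file.path(out_dir, paste0("derivative_", aid, ".png")),
                 width = 900, height = 600)
  plot_derivative(dcurves, main = paste("Derivative plot -", aid))
  grDevices::dev.off()
  wt_wells <- sub$well_id[sub$role == "wt_control"]
  ref <- smoothed[[wt_wells[1L]]]
  diffs <- lapply(smoothed[sub$well_id[sub$role == "sample"]],
                  function(s) difference_curve(s, ref))
  if (length(diffs)) {
    grDevices::png(file.path(out_dir, paste0("difference_", aid, ".png")),
                   width = 900, height = 600)
    plot_difference(diffs, main = paste("Difference plot -", aid,
                                        "(sample - wt control)"))
    grDevices::dev.off()
  }
  invisible(NULL)
}

#' Cross-method concordance reports for a call table
#'
#' Runs [pairwise_concordance()] for every requested combination of
#' specimen, assay and method pair, and writes a tidy CSV report plus
#' per-method positive-call counts.  An empty call table produces an empty
#' (header-only) report without error.
#'
#' @param table A `call_table` (e.g. [load_call_table()]), or a score table
#'   merged into one.
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @param specimens,assay_ids Subsets to report (defaults: those present /
#'   both assays).
#' @param pairs List of 2-element character vectors of methods (default:
#'   ARMS vs ddPCR and ARMS vs Sanger).
#' @param scopes Concordance scopes to include.
#' @return A data.frame with one row per report (discordant patient IDs
#'   collapsed with `;`), invisibly written to
#'   `file.path(out_dir, "concordance.csv")`.
#' @export
run_concordance <- function(table, out_dir = NULL,
                            specimens = NULL,
                            assay_ids = c("G12V", "G12D"),
                            pairs = list(c("arms", "ddpcr"), c("arms", "ss")),
                            scopes = c("positives_of_a", "all")) {
  table <- validate_call_table(as.data.frame(table))
  if (is.null(specimens)) specimens <- unique(table$specimen)
  rows <- list()
  for (sp in specimens) for (aid in assay_ids) for (pr in pairs)
    for (sc in scopes) {
      rep <- pairwise_concordance(table, sp, aid, pr[1L], pr[2L], scope = sc)
      rows[[length(rows) + 1L]] <- data.frame(
        specimen = sp, assay_id = aid,
        method_a = pr[1L], method_b = pr[2L], scope = sc,
        n_total = rep$n_total, n_co_assessed = rep$n_co_assessed,
        n_concordant = rep$n_concordant,
        concordance_pct = rep$concordance_pct,
        discordant_ids = paste(rep$discordant_ids, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(specimen = character(0), assay_id = character(0),
               method_a = character(0), method_b = character(0),
               scope = character(0), n_total = integer(0),
               n_co_assessed = integer(0), n_concordant = integer(0),
               concordance_pct = numeric(0), discordant_ids = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "concordance.csv"),
                     row.names = FALSE)
  }
  out
}
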