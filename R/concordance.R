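#' Count calls of a given state in a call table
#'
#' Counts rows of one specimen type whose call for `method` equals `state`.
#' Missing assessments (`NA`) and, for Sanger, `UNREADABLE` chromatograms are
#' only counted when explicitly requested as the `state` (use `state = NA`
#' to count not-assessed rows).
#'
#' @param table A `call_table` (see [load_call_table()]).
#' @param specimen `"tumor"` or `"plasma"`.
#' @param method One of `"arms_g12v"`, `"arms_g12d"`, `"ss"`, `"ddpcr"`.
#' @param state A call value from the method's vocabulary, or `NA`.
#' @return Integer count.
#' @export
#' @examples
#' count_calls(load_call_table("tumor"), "tumor", "arms_g12v", "G12V")
count_calls <- function(table, specimen, method, state) {
  table <- validate_call_table(as.data.frame(table))
  specimen <- match.arg(specimen, c("tumor", "plasma"))
  if (!method %in% call_methods)
    stop("unknown method: ", method)
  if (!is.na(state) && !state %in% call_vocab[[method]])
    stop("unknown state '", state, "' for method ", method)
  vals <- table[[method]][table$specimen == specimen]
  if (is.na(state)) sum(is.na(vals)) else sum(!is.na(vals) & vals == state)
}

#' Number of specimens actually assessed by a method
#'
#' Non-`NA` rows for the method; for Sanger sequencing this includes
#' `UNREADABLE` rows (the reaction was attempted, only the chromatogram
#' failed).
#'
#' @inheritParams count_calls
#' @return Integer count.
#' @export
n_assessed <- function(table, specimen, method) {
  table <- validate_call_table(as.data.frame(table))
  specimen <- match.arg(specimen, c("tumor", "plasma"))
  if (!method %in% call_methods)
    stop("unknown method: ", method)
  sum(!is.na(table[[method]][table$specimen == specimen]))
}

#' Per-assay positive/negative status of each method
#'
#' Maps a method's raw call vocabulary onto the binary question "does this
#' method call the assay's target allele?": `"pos"`, `"neg"`, or `NA`
#' (missing — for Sanger, `UNREADABLE` counts as missing here).  A
#' heterozygous Sanger call (`wt_G12V`) is positive for the G12V assay;
#' `wt` and non-target variants (e.g. `wt_G12R`, ddPCR `G12R`) are negative
#' for both target assays.
#'
#' @param table A `call_table`.
#' @param method `"arms"`, `"ss"` or `"ddpcr"` (`"arms"` resolves to the
#'   assay's ARMS column).
#' @param assay_id `"G12V"` or `"G12D"`.
#' @return Character vector (`"pos"`/`"neg"`/`NA`), one element per row of
#'   `table`.
#' @export
method_status <- function(table, method, assay_id) {
  method <- match.arg(method, c("arms", "ss", "ddpcr"))
  assay_id <- match.arg(assay_id, c("G12V", "G12D"))
  if (method == "arms") {
    col <- if (assay_id == "G12V") table$arms_g12v else table$arms_g12d
    ifelse(is.na(col), NA_character_,
           ifelse(col == assay_id, "pos", "neg"))
  } else if (method == "ss") {
    col <- table$ss
    ifelse(is.na(col) | col == "UNREADABLE", NA_character_,
           ifelse(col == paste0("wt_", assay_id), "pos", "neg"))
  } else {
    col <- table$ddpcr
    ifelse(is.na(col), NA_character_,
           ifelse(col == assay_id, "pos", "neg"))
  }
}

#' Pairwise concordance between two genotyping methods
#'
#' Restricts a call table to one specimen type, maps both methods to
#' positive/negative status for one assay, and compares them on the rows
#' where both are non-missing (co-assessed).
#'
#' Two denominators are offered.  `scope = "positives_of_a"` reproduces the
#' study-style comparison: among samples called positive by `method_a` and
#' co-assessed by `method_b`, what fraction does `method_b` also call
#' positive?  `scope = "all"` is the symmetric agreement rate over all
#' co-assessed rows.
#'
#' @param table A `call_table`.
#' @param specimen `"tumor"` or `"plasma"`.
#' @param assay_id `"G12V"` or `"G12D"`.
#' @param method_a,method_b `"arms"`, `"ss"` or `"ddpcr"`.
#' @param scope `"positives_of_a"` (default) or `"all"`.
#' @return An object of class `concordance_report`: a list with
#'   `assay_id`, `specimen`, `method_a`, `method_b`, `scope`, `n_total`,
#'   `n_co_assessed`, `positives` (named counts per method over co-assessed
#'   rows), `n_concordant`, `concordance_pct` (`NA` with `degenerate = TRUE`
#'   when nothing is co-assessed), and `discordant_ids`.
#' @export
#' @examples
#' pairwise_concordance(load_call_table("tumor"), "tumor", "G12V",
#'                      "arms", "ddpcr")
pairwise_concordance <- function(table, specimen, assay_id,
                                 method_a, method_b,
                                 scope = c("positives_of_a", "all")) {
  table <- validate_call_table(as.data.frame(table))
  specimen <- match.arg(specimen, c("tumor", "plasma"))
  scope <- match.arg(scope)
  sub <- table[table$specimen == specimen, , drop = FALSE]
  sa <- method_status(sub, method_a, assay_id)
  sb <- method_status(sub, method_b, assay_id)
  keep <- if (scope == "positives_of_a") {
    !is.na(sa) & sa == "pos" & !is.na(sb)
  } else {
    !is.na(sa) & !is.na(sb)
  }
  n_co <- sum(keep)
  concord <- keep & (sa == sb)
  discordant <- sub$patient_id[keep & (sa != sb)]
  report <- list(
    assay_id = assay_id, specimen = specimen,
    method_a = method_a, method_b = method_b, scope = scope,
    n_total = nrow(sub), n_co_assessed = n_co,
    positives = c(
      stats::setNames(sum(keep & sa == "pos"), method_a),
      stats::setNames(sum(keep & sb == "pos"), method_b)),
    n_concordant = sum(concord),
    concordance_pct = if (n_co > 0) 100 * sum(concord) / n_co else NA_real_,
    degenerate = n_co == 0,
    discordant_ids = discordant)
  class(report) <- "concordance_report"
  report
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %s %s: %s vs %s (%s)\n",
              x$specimen, x$assay_id, x$method_a, x$method_b, x$scope))
  if (x$degenerate) {
    cat("  no co-assessed samples; concordance undefined\n")
  } else {
    cat(sprintf("  co-assessed %d/%d, concordance %.1f%%",
                x$n_co_assessed, x$n_total, x$concordance_pct))
    if (length(x$discordant_ids))
      cat(", discordant patient(s): ",
          paste(x$discordant_ids, collapse = ", "), sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Sensitivity and specificity against a reference method
#'
#' Treats one method (default ddPCR) as the reference and reports the test
#' method's sensitivity, specificity and 2x2 counts over co-assessed rows.
#' Provided as a supplementary summary; the headline study comparison is
#' [pairwise_concordance()].
#'
#' @inheritParams pairwise_concordance
#' @param method Test method (`"arms"`, `"ss"` or `"ddpcr"`).
#' @param reference Reference method; default `"ddpcr"`.
#' @return A list with `tp`, `fp`, `fn`, `tn`, `sensitivity`, `specificity`
#'   (proportions, `NA` when the denominator is empty), and `n_co_assessed`.
#' @export
sensitivity_specificity <- function(table, specimen, assay_id,
                                    method = "arms", reference = "ddpcr") {
  table <- validate_call_table(as.data.frame(table))
  specimen <- match.arg(specimen, c("tumor", "plasma"))
  sub <- table[table$specimen == specimen, , drop = FALSE]
  st <- method_status(sub, method, assay_id)
  sr <- method_status(sub, reference, assay_id)
  keep <- !is.na(st) & !is.na(sr)
  st <- st[keep]; sr <- sr[keep]
  tp <- sum(st == "pos" & sr == "pos")
  fp <- sum(st == "pos" & sr == "neg")
  fn <- sum(st == "neg" & sr == "pos")
  tn <- sum(st == "neg" & sr == "neg")
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       n_co_assessed = sum(keep))
}
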