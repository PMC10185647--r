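#' Multi-method genotype call tables
#'
#' A call table records, per patient and specimen (tumor or plasma), the
#' KRAS codon-12 calls produced by three methods: the two ARMS-HRMA assays
#' (`arms_g12v`, `arms_g12d`), Sanger sequencing (`ss`) and droplet digital
#' PCR (`ddpcr`).  Vocabulary is closed:
#'
#' * `arms_g12v`: `G12V`, `NEG`, or `NA` (assay not performed)
#' * `arms_g12d`: `G12D`, `NEG`, or `NA`
#' * `ss`: `wt`, `wt_G12V`, `wt_G12D`, `wt_G12R`, `UNREADABLE`
#'   (sequencing attempted, chromatogram unreadable), or `NA` (not attempted)
#' * `ddpcr`: `wt`, `G12V`, `G12D`, `G12R`, or `NA`
#'
#' `UNREADABLE` is kept distinct from `NA` because the two are counted
#' separately when reporting how many specimens could be sequenced at all
#' versus how many yielded a readable chromatogram.
#'
#' @name call_table
NULL

call_vocab <- list(
  arms_g12v = c("G12V", "NEG"),
  arms_g12d = c("G12D", "NEG"),
  ss = c("wt", "wt_G12V", "wt_G12D", "wt_G12R", "UNREADABLE"),
  ddpcr = c("wt", "G12V", "G12D", "G12R")
)

call_methods <- names(call_vocab)

#' Validate a call table
#'
#' Checks column presence, the closed call vocabulary (NA allowed
#' everywhere), and patient-ID uniqueness within specimen.
#'
#' @param tab A data.frame with columns `patient_id`, `specimen`,
#'   `arms_g12v`, `arms_g12d`, `ss`, `ddpcr`.
#' @return `tab` with class `call_table`, invisibly validated.
#' @export
validate_call_table <- function(tab) {
  req <- c("patient_id", "specimen", call_methods)
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("call table missing column(s): ", paste(missing_cols, collapse = ", "))
  bad_spec <- setdiff(unique(tab$specimen), c("tumor", "plasma"))
  if (length(bad_spec))
    stop("unknown specimen value(s): ", paste(bad_spec, collapse = ", "))
  for (m in call_methods) {
    vals <- tab[[m]]
    bad <- setdiff(unique(vals[!is.na(vals)]), call_vocab[[m]])
    if (length(bad))
      stop("invalid ", m, " call value(s): ", paste(bad, collapse = ", "))
  }
  for (sp in unique(tab$specimen)) {
    ids <- tab$patient_id[tab$specimen == sp]
    if (anyDuplicated(ids))
      stop("duplicated patient_id within specimen ", sp)
  }
  class(tab) <- c("call_table", "data.frame")
  tab
}

#' Load a packaged multi-method call table
#'
#' The package ships machine-readable transcriptions of the study's two
#' published call tables: 30 tumor specimens and 30 plasma specimens from the
#' same pancreatic-cancer patients, each with ARMS-HRMA (G12V and G12D
#' assays), Sanger sequencing and ddPCR calls.  Missing assessments are `NA`;
#' Sanger reactions that ran but gave no readable chromatogram are
#' `UNREADABLE`.
#'
#' @param which `"tumor"` or `"plasma"`.
#' @return A validated `call_table` data.frame with 30 rows.
#' @export
#' @examples
#' tab <- load_call_table("tumor")
#' table(tab$arms_g12v, useNA = "ifany")
load_call_table <- function(which = c("tumor", "plasma")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("call_table_", which, ".csv"),
                      package = "armshrma", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "NA", colClasses = "character")
  tab$patient_id <- as.integer(tab$patient_id)
  validate_call_table(tab)
}
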