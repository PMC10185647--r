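#' Construct a melt curve
#'
#' A melt curve is one well's raw HRM fluorescence trace over a strictly
#' increasing temperature grid (degrees Celsius).  The canonical instrument
#' ramp is 45--95 degrees C at 0.2 degree steps (251 points), but any strictly
#' increasing grid of length >= 3 is accepted.
#'
#' @param well_id Well identifier (single string).
#' @param sample_id Sample identifier (single string); replicate wells of one
#'   sample share a `sample_id`.
#' @param temperatures Numeric vector of temperatures in degrees C, strictly
#'   increasing, length >= 3.
#' @param fluorescence Numeric vector of fluorescence readings (arbitrary
#'   units), same length as `temperatures`, all finite.
#' @return An object of class `melt_curve`.
#' @export
#' @examples
#' tg <- melt_grid()
#' mc <- melt_curve("A1", "S1", tg, 1 / (1 + exp((tg - 80) / 0.8)))
melt_curve <- function(well_id, sample_id, temperatures, fluorescence) {
  stopifnot(is.character(well_id), length(well_id) == 1L,
            is.character(sample_id), length(sample_id) == 1L)
  temperatures <- as.numeric(temperatures)
  fluorescence <- as.numeric(fluorescence)
  if (length(temperatures) < 3L)
    stop("melt curve needs at least 3 temperature points")
  if (length(temperatures) != length(fluorescence))
    stop("temperatures and fluorescence must have the same length")
  if (any(diff(temperatures) <= 0))
    stop("non-monotonic temperature grid: temperatures must be strictly increasing")
  if (!all(is.finite(fluorescence)))
    stop("fluorescence values must all be finite")
  structure(
    list(well_id = well_id, sample_id = sample_id,
         temperatures = temperatures, fluorescence = fluorescence),
    class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve> well %s, sample %s: %d points, %.1f-%.1f degC\n",
              x$well_id, x$sample_id, length(x$temperatures),
              min(x$temperatures), max(x$temperatures)))
  invisible(x)
}

#' Canonical HRM temperature grid
#'
#' The instrument ramp: `from` to `to` degrees C rising `by` per step.
#' Defaults give the 45--95 degC / 0.2 degC grid (251 points).
#'
#' @param from,to,by Ramp limits and step in degrees C.
#' @return Numeric vector of temperatures.
#' @export
melt_grid <- function(from = 45, to = 95, by = 0.2) {
  seq(from, to, by = by)
}

# Grids equal within this tolerance are treated as shared; no resampling here.
.grid_tol <- 1e-6

#' Check that two temperature grids are shared
#' @noRd
same_grid <- function(a, b) {
  length(a) == length(b) && all(abs(a - b) < .grid_tol)
}

#' Construct a sample sheet
#'
#' Maps wells to sample IDs, roles and assays.  Roles follow the plate layout
#' of an ARMS-HRMA run: patient wells (`sample`), the wild-type cell-line
#' control (`wt_control`, e.g. SW48), the mutant cell-line control
#' (`mut_control`, e.g. SW480 for G12V or LS174T for G12D) and optional
#' non-template controls (`ntc`).
#'
#' @param well_id,sample_id Character vectors (one entry per well).
#' @param role Character vector; each entry one of `"sample"`, `"wt_control"`,
#'   `"mut_control"`, `"ntc"`.
#' @param assay_id Character vector; each entry one of `"G12V"`, `"G12D"`,
#'   `"WT"`.
#' @param replicate_index Integer vector (>= 1); replicate number within
#'   sample and assay.
#' @return A `data.frame` with class `sample_sheet`.
#' @export
sample_sheet <- function(well_id, sample_id, role, assay_id,
                         replicate_index = 1L) {
  sheet <- data.frame(well_id = as.character(well_id),
                      sample_id = as.character(sample_id),
                      role = as.character(role),
                      assay_id = as.character(assay_id),
                      replicate_index = as.integer(replicate_index),
                      stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

valid_roles <- c("sample", "wt_control", "mut_control", "ntc")
valid_assays <- c("G12V", "G12D", "WT")

validate_sample_sheet <- function(sheet) {
  req <- c("well_id", "sample_id", "role", "assay_id", "replicate_index")
  missing_cols <- setdiff(req, names(sheet))
  if (length(missing_cols))
    stop("sample sheet missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sheet$well_id))
    stop("duplicated well_id in sample sheet: ",
         paste(unique(sheet$well_id[duplicated(sheet$well_id)]), collapse = ", "))
  bad_role <- setdiff(unique(sheet$role), valid_roles)
  if (length(bad_role))
    stop("unknown role(s) in sample sheet: ", paste(bad_role, collapse = ", "))
  bad_assay <- setdiff(unique(sheet$assay_id), valid_assays)
  if (length(bad_assay))
    stop("unknown assay_id(s) in sample sheet: ", paste(bad_assay, collapse = ", "))
  if (any(sheet$replicate_index < 1L))
    stop("replicate_index must be >= 1")
  for (aid in unique(sheet$assay_id)) {
    roles <- sheet$role[sheet$assay_id == aid]
    if (!any(roles == "wt_control"))
      stop("assay ", aid, " has no wt_control well in the sample sheet")
    if (!any(roles == "mut_control"))
      stop("assay ", aid, " has no mut_control well in the sample sheet")
  }
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Read a melt run (curves + sample sheet)
#'
#' The melt file is a wide CSV in the package's canonical dialect: header row,
#' first column `temperature` (degrees C, dot decimal), one column per well
#' named by its well ID.  The sheet file is a CSV with columns `well_id`,
#' `sample_id`, `role`, `assay_id`, `replicate_index`.
#'
#' Every well column in the melt file must appear in the sheet; the
#' temperature column must be strictly increasing.
#'
#' @param curve_file Path to the wide melt CSV.
#' @param sheet_file Path to the sample-sheet CSV.
#' @return A list with elements `curves` (named list of [melt_curve] objects,
#'   one per well column) and `sheet` (a `sample_sheet`).
#' @seealso [write_melt_run()]
#' @export
read_melt_run <- function(curve_file, sheet_file) {
  if (!file.exists(curve_file)) stop("melt file not found: ", curve_file)
  if (!file.exists(sheet_file)) stop("sample sheet not found: ", sheet_file)
  wide <- utils::read.csv(curve_file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(wide) < 2L)
    stop("melt file must have a temperature column plus at least one well column")
  temps <- as.numeric(wide[[1L]])
  if (any(diff(temps) <= 0))
    stop("non-monotonic temperature column in ", curve_file)
  sheet <- utils::read.csv(sheet_file, stringsAsFactors = FALSE)
  sheet <- validate_sample_sheet(sheet)
  wells <- names(wide)[-1L]
  unknown <- setdiff(wells, sheet$well_id)
  if (length(unknown))
    stop("well(s) in melt file missing from sample sheet: ",
         paste(unknown, collapse = ", "))
  curves <- lapply(wells, function(w) {
    sid <- sheet$sample_id[match(w, sheet$well_id)]
    melt_curve(w, sid, temps, wide[[w]])
  })
  names(curves) <- wells
  list(curves = curves, sheet = sheet)
}

#' Write a melt run in the canonical wide-CSV dialect
#'
#' All curves must share one temperature grid (within 1e-6 degrees C).
#'
#' @param curves List of [melt_curve] objects.
#' @param sheet A `sample_sheet` covering every curve's well.
#' @param curve_file,sheet_file Output CSV paths.
#' @return Invisibly, `c(curve_file, sheet_file)`.
#' @export
write_melt_run <- function(curves, sheet, curve_file, sheet_file) {
  stopifnot(length(curves) >= 1L)
  sheet <- validate_sample_sheet(as.data.frame(sheet))
  grid <- curves[[1L]]$temperatures
  for (cu in curves) {
    if (!same_grid(grid, cu$temperatures))
      stop("curves do not share a temperature grid (well ", cu$well_id, ")")
    if (!cu$well_id %in% sheet$well_id)
      stop("curve well ", cu$well_id, " missing from sample sheet")
  }
  wide <- data.frame(temperature = grid, check.names = FALSE)
  for (cu in curves) wide[[cu$well_id]] <- cu$fluorescence
  utils::write.csv(wide, curve_file, row.names = FALSE)
  utils::write.csv(as.data.frame(sheet)[, c("well_id", "sample_id", "role",
                                            "assay_id", "replicate_index")],
                   sheet_file, row.names = FALSE)
  invisible(c(curve_file, sheet_file))
}
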