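#' Read a long-format qPCR plate export
#'
#' Reads the delimited table exported from a real-time PCR instrument (or
#' written by [simulate_plate()]): one row per well per cycle, with the
#' columns `sample`, `locus`, `assay`, `well`, `cycle`, `fluorescence`.
#' The `assay` column labels whether the reaction targets the occupied
#' (`"presence"`) or empty (`"absence"`) insertion site.
#'
#' @param file Path to a CSV file.
#' @returns A tibble with the six required columns, validated by
#'   [validate_plate()].
#' @seealso [simulate_plate()], [estimate_reactions()]
#' @export
#' @examples
#' plate <- simulate_plate(plate_scenario(dosage = c(S1 = 6), seed = 1))
#' tmp <- tempfile(fileext = ".csv")
#' readr::write_csv(plate, tmp)
#' read_plate(tmp)
read_plate <- function(file) {
  x <- readr::read_csv(
    file,
    col_types = readr::cols(
      sample = readr::col_character(),
      locus = readr::col_character(),
      assay = readr::col_character(),
      well = readr::col_character(),
      cycle = readr::col_integer(),
      fluorescence = readr::col_double()
    )
  )
  validate_plate(x)
}

#' Validate a plate of amplification curves
#'
#' Checks the invariants every downstream step relies on: required columns
#' present, assay labels in `{presence, absence}`, and for every well a
#' complete run of cycles `1..C` (strictly increasing, no gaps) with finite
#' fluorescence readings and at least 12 cycles.
#'
#' @param plate A data frame of per-cycle fluorescence readings.
#' @returns The input as a tibble, invisibly checked; errors describe the
#'   offending wells.
#' @export
validate_plate <- function(plate) {
  required <- c("sample", "locus", "assay", "well", "cycle", "fluorescence")
  missing <- setdiff(required, names(plate))
  if (length(missing) > 0) {
    abort(paste0("plate is missing column(s): ", paste(missing, collapse = ", ")),
          class = "tedose_malformed_input")
  }
  bad_assay <- setdiff(unique(plate$assay), c("presence", "absence"))
  if (length(bad_assay) > 0) {
    abort(paste0("assay must be 'presence' or 'absence'; found: ",
                 paste(bad_assay, collapse = ", ")),
          class = "tedose_malformed_input")
  }
  if (!all(is.finite(plate$fluorescence))) {
    abort("non-finite fluorescence readings", class = "tedose_malformed_input")
  }
  chk <- plate |>
    dplyr::group_by(.data$sample, .data$locus, .data$assay, .data$well) |>
    dplyr::summarise(
      n = dplyr::n(),
      complete = identical(as.integer(.data$cycle), seq_len(dplyr::n())),
      .groups = "drop"
    )
  bad <- chk |> dplyr::filter(!.data$complete | .data$n < 12L)
  if (nrow(bad) > 0) {
    abort(paste0("wells with incomplete or short cycle runs: ",
                 paste(utils::head(bad$well, 5), collapse = ", ")),
          class = "tedose_malformed_input")
  }
  out <- as_tibble(plate)
  if (!inherits(out, "tedose_plate")) {
    class(out) <- c("tedose_plate", class(out))
  }
  out
}
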