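#' Registry of coded fetal facial movements
#'
#' The coding scheme distinguishes 19 elementary facial movements derived from
#' the Facial Action Coding System that are observable and reliably codable on
#' fetal 4-D ultrasound. Six of them -- Brow Lowerer, Nose Wrinkle, Upper-Lip
#' Raiser, Nasolabial Furrow, Lips Parting and Mouth Stretch -- jointly make up
#' the "pain/distress" facial gestalt: a configuration an observer would read
#' as a pain or distress face, with no claim about felt experience.
#'
#' @return A tibble with one row per movement code and columns
#'   \describe{
#'     \item{code_id}{integer 1--19}
#'     \item{label}{movement name}
#'     \item{in_pain_gestalt}{logical, membership of the pain/distress gestalt}
#'   }
#' @examples
#' movement_codes()
#' dplyr::filter(movement_codes(), in_pain_gestalt)
#' @export
movement_codes <- function() {
  labels <- c(
    "Inner-Brow Raiser", "Outer Brow Raiser", "Brow Lowerer", "Cheek Raiser",
    "Nose Wrinkle", "Upper-Lip Raiser", "Nasolabial Furrow", "Lip Pull",
    "Dimpler", "Lip-Corner Depressor", "Lower-Lip Depressor", "Chin Raiser",
    "Lip Pucker", "Tongue Show", "Lip Stretch", "Lip Presser",
    "Lips Parting", "Mouth Stretch", "Lip Suck"
  )
  tibble::tibble(
    code_id = 1:19,
    label = labels,
    in_pain_gestalt = 1:19 %in% gestalt_code_ids()
  )
}

#' @rdname movement_codes
#' @export
gestalt_code_ids <- function() c(3L, 5L, 6L, 7L, 17L, 18L)

# nominal observation ages of the longitudinal design, in gestational weeks
nominal_ages <- function() c(24, 28, 32, 36)
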