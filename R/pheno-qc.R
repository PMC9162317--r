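#' Clean longitudinal height measurements into one height per person
#'
#' Applies the EHR height-cleaning rule: compute a provisional per-person mean
#' over all measurements (inches), drop measurements deviating strictly more
#' than 3 inches from it, recompute the mean once, and exclude persons whose
#' final mean is at or below 50 inches or at or above 100 inches. The
#' deviation pass runs exactly once (no iteration to a fixed point). The
#' result is converted to centimetres at the end so rounding is not
#' compounded.
#'
#' @param measurements Data frame with columns `person_id`, `value` (height in
#'   inches); a `date` column may be present but the rule does not use it.
#' @return A tibble with one row per person: `person_id`, `height_cm` (`NA`
#'   when excluded), `n_measurements`, `n_dropped`, `excluded`,
#'   `exclusion_reason`.
#' @export
#' @examples
#' clean_height(data.frame(person_id = "a", value = 70))
clean_height <- function(measurements) {
  measurements <- tibble::as_tibble(measurements)
  stopifnot(all(c("person_id", "value") %in% names(measurements)))
  if (any(measurements$value <= 0)) abort("Height measurements must be positive.")
  prov <- measurements |>
    dplyr::group_by(person_id = .data$person_id) |>
    dplyr::summarise(n_measurements = dplyr::n(),
                     prov_mean = mean(.data$value), .groups = "drop")
  final <- measurements |>
    dplyr::left_join(prov, by = "person_id") |>
    dplyr::filter(abs(.data$value - .data$prov_mean) <= 3) |>
    dplyr::group_by(person_id = .data$person_id) |>
    dplyr::summarise(height_in = mean(.data$value),
                     n_kept = dplyr::n(), .groups = "drop")
  prov |>
    dplyr::left_join(final, by = "person_id") |>
    dplyr::mutate(
      n_dropped = .data$n_measurements - dplyr::coalesce(.data$n_kept, 0L),
      exclusion_reason = dplyr::case_when(
        is.na(.data$height_in) ~ "all measurements dropped by deviation rule",
        .data$height_in <= 50 ~ "extreme average height (<= 50 inches)",
        .data$height_in >= 100 ~ "extreme average height (>= 100 inches)",
        TRUE ~ NA_character_
      ),
      excluded = !is.na(.data$exclusion_reason),
      height_cm = dplyr::if_else(.data$excluded, NA_real_,
                                 .data$height_in * 2.54)
    ) |>
    dplyr::select("person_id", "height_cm", "n_measurements", "n_dropped",
                  "excluded", "exclusion_reason")
}

#' Average BMI around enrollment from weight measurements
#'
#' Restricts each person's weights (pounds) to a window from 1.5 years before
#' to 1.5 years after enrollment, drops weights deviating strictly more than
#' 60 pounds from the person's in-window mean (one pass, mean recomputed
#' once), and returns BMI = mean weight (kg) / height (m) squared. Persons
#' with no in-window weights get `NA` BMI but are retained for analyses that
#' do not adjust for BMI.
#'
#' @param weights Data frame with columns `person_id`, `date`, `value`
#'   (pounds).
#' @param heights Data frame with `person_id`, `height_cm`, e.g. the output of
#'   [clean_height()]; rows with `NA` height yield `NA` BMI.
#' @param enrollment Data frame with `person_id`, `enrollment_date`.
#' @param window_days Half-width of the enrollment window in days
#'   (default 1.5 years).
#' @return A tibble `person_id`, `bmi`, `n_weights_used`.
#' @export
clean_bmi <- function(weights, heights, enrollment,
                      window_days = round(1.5 * 365.25)) {
  weights <- tibble::as_tibble(weights)
  stopifnot(all(c("person_id", "date", "value") %in% names(weights)),
            all(c("person_id", "height_cm") %in% names(heights)),
            all(c("person_id", "enrollment_date") %in% names(enrollment)))
  if (any(weights$value <= 0)) abort("Weight measurements must be positive.")
  win <- weights |>
    dplyr::inner_join(
      dplyr::select(tibble::as_tibble(enrollment), "person_id", "enrollment_date"),
      by = "person_id"
    ) |>
    dplyr::filter(abs(as.numeric(as.Date(.data$date) -
                                   as.Date(.data$enrollment_date))) <= window_days)
  prov <- win |>
    dplyr::group_by(person_id = .data$person_id) |>
    dplyr::summarise(prov_mean = mean(.data$value), .groups = "drop")
  means <- win |>
    dplyr::left_join(prov, by = "person_id") |>
    dplyr::filter(abs(.data$value - .data$prov_mean) <= 60) |>
    dplyr::group_by(person_id = .data$person_id) |>
    dplyr::summarise(weight_lb = mean(.data$value),
                     n_weights_used = dplyr::n(), .groups = "drop")
  tibble::as_tibble(heights) |>
    dplyr::select("person_id", "height_cm") |>
    dplyr::left_join(means, by = "person_id") |>
    dplyr::mutate(
      bmi = (.data$weight_lb * 0.45359237) / (.data$height_cm / 100)^2,
      n_weights_used = dplyr::coalesce(.data$n_weights_used, 0L)
    ) |>
    dplyr::select("person_id", "bmi", "n_weights_used")
}
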