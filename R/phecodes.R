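#' Assign phecode case/control status from ICD diagnosis events
#'
#' Maps long-format ICD events onto phecodes by exact string match on
#' (vocabulary, code) and applies the standard PheWAS case rule: a person is
#' a *case* for a phecode when they carry at least `min_code_count` mapped
#' diagnosis events, a *control* when they carry none, and *missing*
#' (excluded from that phecode's model) when they carry some but fewer than
#' `min_code_count`. Duplicate (person, date, code) events are de-duplicated
#' with a warning; event codes absent from the map are counted and reported
#' but are not an error.
#'
#' @param icd_events Data frame: `person_id`, `date`, `vocabulary`
#'   (`"ICD9"`/`"ICD10"`), `code`.
#' @param phecode_map Data frame: `vocabulary`, `code`, `phecode`.
#' @param persons Character vector of the person universe; persons with no
#'   mapped events are controls for every phecode. Defaults to the persons
#'   present in `icd_events`.
#' @param min_code_count Minimum number of qualifying codes for case status
#'   (default 2).
#' @return A `phecode_matrix` object: sparse long representation of statuses
#'   plus per-phecode case/control/missing counts.
#' @export
assign_phecodes <- function(icd_events, phecode_map, persons = NULL,
                            min_code_count = 2) {
  icd_events <- tibble::as_tibble(icd_events)
  phecode_map <- tibble::as_tibble(phecode_map)
  stopifnot(all(c("person_id", "vocabulary", "code") %in% names(icd_events)),
            all(c("vocabulary", "code", "phecode") %in% names(phecode_map)))
  if (is.null(persons)) persons <- unique(icd_events$person_id)
  persons <- as.character(persons)

  if ("date" %in% names(icd_events)) {
    n0 <- nrow(icd_events)
    icd_events <- dplyr::distinct(icd_events, .data$person_id, .data$date,
                                  .data$code, .keep_all = TRUE)
    if (nrow(icd_events) < n0) {
      warn(sprintf("De-duplicated %d repeated (person, date, code) events.",
                   n0 - nrow(icd_events)))
    }
  }

  mapped <- dplyr::inner_join(icd_events, phecode_map,
                              by = c("vocabulary", "code"),
                              relationship = "many-to-many")
  n_unmapped <- nrow(icd_events) - nrow(dplyr::semi_join(
    icd_events, phecode_map, by = c("vocabulary", "code")))
  if (nrow(mapped) == 0 && nrow(icd_events) > 0) {
    abort("The phecode map covers none of the event codes.")
  }
  if (n_unmapped > 0) {
    inform(sprintf("%d ICD events did not map to any phecode.", n_unmapped))
  }
  mapped <- dplyr::filter(mapped, .data$person_id %in% persons)

  calls <- mapped |>
    dplyr::count(person_id = .data$person_id,
                 phecode = as.character(.data$phecode), name = "n_codes") |>
    dplyr::mutate(status = dplyr::if_else(.data$n_codes >= min_code_count,
                                          "case", "missing"))

  phecodes <- sort(unique(as.character(phecode_map$phecode)))
  counts <- calls |>
    dplyr::count(phecode = .data$phecode, status = .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  if (!"case" %in% names(counts)) counts$case <- 0L
  if (!"missing" %in% names(counts)) counts$missing <- 0L
  counts <- tibble::tibble(phecode = phecodes) |>
    dplyr::left_join(counts, by = "phecode") |>
    dplyr::mutate(
      n_case = dplyr::coalesce(.data$case, 0L),
      n_missing = dplyr::coalesce(.data$missing, 0L),
      n_control = length(persons) - .data$n_case - .data$n_missing
    ) |>
    dplyr::select("phecode", "n_case", "n_control", "n_missing")

  structure(list(
    calls = calls,
    persons = persons,
    counts = counts,
    min_code_count = min_code_count,
    n_unmapped_events = n_unmapped
  ), class = "phecode_matrix")
}

#' @export
print.phecode_matrix <- function(x, ...) {
  cat("<phecode_matrix> ", length(x$persons), " persons x ",
      nrow(x$counts), " phecodes (case rule: >= ", x$min_code_count,
      " codes)\n", sep = "")
  print(head(x$counts, 5))
  invisible(x)
}

#' Restrict a phecode matrix to phecodes with enough cases and controls
#'
#' Retains exactly the phecodes with at least `min_cases` cases and
#' `min_controls` controls. Re-applying the filter is idempotent. An empty
#' result is permitted (with a warning) so phenome sweeps can no-op.
#'
#' @param pm A `phecode_matrix`.
#' @param min_cases,min_controls Inclusive thresholds (default 200/200).
#' @return A filtered `phecode_matrix`.
#' @export
filter_phecodes <- function(pm, min_cases = 200, min_controls = 200) {
  stopifnot(inherits(pm, "phecode_matrix"))
  keep <- pm$counts$phecode[pm$counts$n_case >= min_cases &
                              pm$counts$n_control >= min_controls]
  if (length(keep) == 0) {
    warn("No phecodes satisfy the case/control minimums; downstream sweeps will no-op.")
  }
  pm$counts <- dplyr::filter(pm$counts, .data$phecode %in% keep)
  pm$calls <- dplyr::filter(pm$calls, .data$phecode %in% keep)
  pm
}

#' Restrict a phecode matrix to a subset of persons
#'
#' Recomputes statuses and counts within the subset; used by stratified
#' analyses.
#'
#' @param pm A `phecode_matrix`.
#' @param persons Character vector of person ids to keep.
#' @return A `phecode_matrix` over the subset.
#' @export
subset_persons <- function(pm, persons) {
  stopifnot(inherits(pm, "phecode_matrix"))
  persons <- intersect(as.character(persons), pm$persons)
  pm$calls <- dplyr::filter(pm$calls, .data$person_id %in% persons)
  pm$persons <- persons
  pm$counts <- pm$calls |>
    dplyr::count(phecode = .data$phecode, status = .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      if (!"case" %in% names(d)) d$case <- 0L
      if (!"missing" %in% names(d)) d$missing <- 0L
      d
    })() |>
    dplyr::right_join(tibble::tibble(phecode = pm$counts$phecode), by = "phecode") |>
    dplyr::mutate(
      n_case = dplyr::coalesce(.data$case, 0L),
      n_missing = dplyr::coalesce(.data$missing, 0L),
      n_control = length(persons) - .data$n_case - .data$n_missing
    ) |>
    dplyr::select("phecode", "n_case", "n_control", "n_missing")
  pm
}

#' Case/control outcome vector for one phecode
#'
#' @param pm A `phecode_matrix`.
#' @param phecode Phecode id (character or numeric).
#' @return Named integer vector over `pm$persons`: 1 = case, 0 = control,
#'   `NA` = missing (fewer qualifying codes than the case rule requires).
#' @export
phecode_outcome <- function(pm, phecode) {
  stopifnot(inherits(pm, "phecode_matrix"))
  phecode <- as.character(phecode)
  y <- setNames(rep(0L, length(pm$persons)), pm$persons)
  rows <- pm$calls[pm$calls$phecode == phecode, ]
  y[rows$person_id[rows$status == "case"]] <- 1L
  y[rows$person_id[rows$status == "missing"]] <- NA_integer_
  y
}

#' Phecode group (body system) for numeric-style phecodes
#'
#' Assigns each phecode to a clinical group by its integer range, following
#' the conventional phecode chapter layout. Unknown or non-numeric phecodes
#' fall in group `"other"`.
#'
#' @param phecode Character or numeric vector of phecodes.
#' @return Character vector of group names.
#' @export
phecode_group <- function(phecode) {
  x <- suppressWarnings(as.numeric(phecode))
  breaks <- c(0, 140, 240, 280, 290, 320, 390, 460, 520, 580, 630, 680, 710,
              740, 760, 780, 1000)
  labels <- c("infectious diseases", "neoplasms", "endocrine/metabolic",
              "hematopoietic", "mental disorders", "neurological",
              "circulatory system", "respiratory", "digestive",
              "genitourinary", "pregnancy complications", "dermatologic",
              "musculoskeletal", "congenital anomalies", "symptoms",
              "injuries & poisonings")
  out <- as.character(cut(x, breaks = breaks, labels = labels, right = FALSE))
  out[is.na(out)] <- "other"
  out
}
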