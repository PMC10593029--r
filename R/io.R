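#' Write simulated populations and study samples to disk
#'
#' Populations are written as plain CSV (one row per individual, including
#' both potential-outcome vectors). Study samples are written as CSV of the
#' visible rows plus a JSON sidecar (`<path>.json`) recording the design,
#' ascertainment event, selection rule and seed, so every sample is
#' traceable to its scenario.
#'
#' @param pop A population from [sample_population()].
#' @param sample A `study_sample`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
write_study_sample <- function(sample, path) {
  utils::write.csv(as.data.frame(sample), path, row.names = FALSE)
  prov <- attr(sample, "provenance")
  jsonlite::write_json(
    list(design = attr(sample, "design"),
         ascertainment_event = attr(sample, "ascertainment_event"),
         selection = prov$selection,
         seed = prov$seed,
         n = nrow(sample)),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_population
#' @export
read_study_sample <- function(path) {
  rows <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(rows, "design") <- meta$design
    attr(rows, "ascertainment_event") <- meta$ascertainment_event
    attr(rows, "provenance") <- list(seed = meta$seed,
                                     selection = meta$selection)
  }
  assert_masked(rows)
  class(rows) <- c("study_sample", class(rows))
  rows
}
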