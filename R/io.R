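#' Write a simulated cohort to a portable container
#'
#' One directory per participant holding a raw float32 array file
#' (`epochs.f32`, C order: samples fastest, then channels, then epochs)
#' plus a JSON sidecar (`meta.json`) with dimensions, sampling rate,
#' channel names/positions, the trial schedule and, when present, the
#' planted ground truth.  The stimulus table is stored once at the top
#' level as `ratings.csv`.
#'
#' @param cohort an `eeg_cohort`.
#' @param dir target directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ratings_csv(cohort$stimuli, file.path(dir, "ratings.csv"))
  hm <- cohort$head_model
  jsonlite::write_json(list(radius_mm = hm$radius, conductivity = hm$sigma,
                            channel_names = hm$channel_names,
                            positions = hm$positions),
                       file.path(dir, "head_model.json"), digits = NA)
  for (rec in cohort$participants) {
    pd <- file.path(dir, sprintf("participant_%02d", rec$participant_id))
    dir.create(pd, showWarnings = FALSE)
    d <- dim(rec$epochs)
    con <- file(file.path(pd, "epochs.f32"), "wb")
    # write sample-fastest: epoch-major blocks of channels x samples
    writeBin(as.numeric(aperm(rec$epochs, c(3L, 2L, 1L))), con, size = 4L)
    close(con)
    meta <- list(participant_id = rec$participant_id,
                 dims = d, sampling_rate = rec$sampling_rate,
                 channel_names = rec$channel_names,
                 epoch_stimulus = rec$epoch_stimulus,
                 schedule = rec$schedule)
    if (!is.null(rec$ground_truth)) {
      gt <- rec$ground_truth
      meta$ground_truth <- list(source_locations = gt$source_locations,
                                is_artifact = gt$is_artifact,
                                slope_mult = gt$slope_mult)
    }
    jsonlite::write_json(meta, file.path(pd, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort container written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return an `eeg_cohort` (without the full planted ground truth).
#' @export
read_cohort <- function(dir) {
  stim <- read_ratings_csv(file.path(dir, "ratings.csv"))
  hmj <- jsonlite::read_json(file.path(dir, "head_model.json"),
                             simplifyVector = TRUE)
  hm <- make_head_model(length(hmj$channel_names), hmj$radius_mm,
                        hmj$conductivity)
  pdirs <- sort(list.dirs(dir, recursive = FALSE))
  participants <- lapply(pdirs, function(pd) {
    meta <- jsonlite::read_json(file.path(pd, "meta.json"),
                                simplifyVector = TRUE)
    d <- as.integer(meta$dims)
    con <- file(file.path(pd, "epochs.f32"), "rb")
    raw <- readBin(con, numeric(), n = prod(d), size = 4L)
    close(con)
    ep <- aperm(array(raw, d[c(3L, 2L, 1L)]), c(3L, 2L, 1L))
    structure(list(participant_id = meta$participant_id, epochs = ep,
                   sampling_rate = meta$sampling_rate,
                   schedule = meta$schedule,
                   epoch_stimulus = meta$epoch_stimulus,
                   channel_names = meta$channel_names,
                   channel_positions = hm$positions,
                   ground_truth = meta$ground_truth),
              class = "participant_recording")
  })
  structure(list(stimuli = stim, head_model = hm, config = NULL,
                 participants = participants),
            class = "eeg_cohort")
}
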