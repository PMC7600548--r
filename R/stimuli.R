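#' Generate a quadrant-balanced affective stimulus set
#'
#' Draws normative valence and arousal ratings for a set of picture-like
#' stimuli on the standard 1-9 scales of the circumplex model of affect
#' (5 = neutral on both axes).  Stimuli are balanced across the four
#' quadrants HVHA, HVLA, LVHA and LVLA (high/low valence x high/low
#' arousal); within a quadrant, ratings are drawn uniformly over the
#' quadrant's rectangle, excluding a guard band of 0.1 around the neutral
#' value 5 so that every stimulus belongs unambiguously to a high (>5) or
#' low (<5) state on both axes.
#'
#' @param n_per_quadrant stimuli per quadrant (default 40, giving the
#'   160-stimulus design).
#' @param seed integer seed; the same seed reproduces the same table.
#' @param guard half-width of the excluded band around 5 (default 0.1).
#' @return a data.frame with columns `stimulus_id`, `valence`, `arousal`,
#'   `quadrant`.
#' @examples
#' stim <- generate_stimulus_set(40, seed = 1)
#' table(stim$quadrant)
#' @export
generate_stimulus_set <- function(n_per_quadrant = 40L, seed = 1L,
                                  guard = 0.1) {
  n_per_quadrant <- check_count(n_per_quadrant, "n_per_quadrant")
  guard <- check_scalar(guard, "guard", lower = 0, upper = 1)
  quadrants <- c("HVHA", "HVLA", "LVHA", "LVLA")
  n <- 4L * n_per_quadrant

  rng <- local_rng(derive_seed(seed, 1L))
  draw <- function(high) {
    # uniform on [1, 5 - guard] (low) or [5 + guard, 9] (high)
    if (high) stats::runif(n_per_quadrant, 5 + guard, 9)
    else stats::runif(n_per_quadrant, 1, 5 - guard)
  }
  val <- aro <- numeric(0)
  for (q in quadrants) {
    val <- c(val, draw(substr(q, 1L, 1L) == "H"))
    aro <- c(aro, draw(substr(q, 3L, 3L) == "H"))
  }
  rng$restore()

  out <- data.frame(
    stimulus_id = seq_len(n),
    valence = val,
    arousal = aro,
    quadrant = rep(quadrants, each = n_per_quadrant),
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$quadrant == rating_quadrant(out$valence, out$arousal)))
  out
}

#' Quadrant label from valence and arousal ratings
#'
#' @param valence,arousal numeric ratings on [1, 9], none exactly 5.
#' @return character vector of quadrant labels.
#' @export
rating_quadrant <- function(valence, arousal) {
  if (any(valence == 5) || any(arousal == 5)) {
    stop_invalid("ratings exactly at the neutral value 5 have no quadrant")
  }
  paste0(ifelse(valence > 5, "HV", "LV"), ifelse(arousal > 5, "HA", "LA"))
}

#' Schedule stimuli into quadrant-balanced sessions
#'
#' Assigns every stimulus to exactly one trial, split across sessions so
#' that each session presents the same number of stimuli from each
#' quadrant, in pseudo-random order within session (the 160-stimulus
#' default yields 8 sessions of 20 trials, 5 per quadrant per session).
#'
#' @param stimuli a stimulus table from [generate_stimulus_set()].
#' @param n_sessions number of sessions; must divide the per-quadrant
#'   count.
#' @param seed integer seed.
#' @return a data.frame with columns `session`, `trial`, `stimulus_id`.
#' @export
generate_schedule <- function(stimuli, n_sessions = 8L, seed = 1L) {
  n_sessions <- check_count(n_sessions, "n_sessions")
  counts <- table(stimuli$quadrant)
  if (any(counts %% n_sessions != 0)) {
    stop_invalid("per-quadrant stimulus count (%s) must be divisible by n_sessions (%d)",
                 paste(counts, collapse = ", "), n_sessions)
  }
  per_sess <- counts[1L] / n_sessions

  rng <- local_rng(derive_seed(seed, 2L))
  # deal each quadrant's stimuli into sessions, then shuffle within session
  by_q <- split(stimuli$stimulus_id, stimuli$quadrant)
  sess_ids <- vector("list", n_sessions)
  for (q in names(by_q)) {
    ids <- sample(by_q[[q]])
    for (s in seq_len(n_sessions)) {
      take <- ids[((s - 1L) * per_sess + 1L):(s * per_sess)]
      sess_ids[[s]] <- c(sess_ids[[s]], take)
    }
  }
  out <- do.call(rbind, lapply(seq_len(n_sessions), function(s) {
    ids <- sample(sess_ids[[s]])
    data.frame(session = s, trial = seq_along(ids), stimulus_id = ids)
  }))
  rng$restore()
  rownames(out) <- NULL
  out
}

#' Read or write a ratings table as CSV
#'
#' The on-disk interchange format for stimulus ratings: columns
#' `stimulus_id`, `valence`, `arousal`, `quadrant`.
#'
#' @param stimuli a stimulus table.
#' @param path file path.
#' @return `read_ratings_csv` returns the validated table.
#' @export
write_ratings_csv <- function(stimuli, path) {
  utils::write.csv(stimuli, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings_csv
#' @export
read_ratings_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stimulus_id", "valence", "arousal")
  if (!all(need %in% names(x))) {
    stop_invalid("ratings CSV must have columns %s", paste(need, collapse = ", "))
  }
  if (is.null(x$quadrant)) {
    x$quadrant <- rating_quadrant(x$valence, x$arousal)
  }
  x
}

# Scoped RNG: seed without disturbing the caller's RNG state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}
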