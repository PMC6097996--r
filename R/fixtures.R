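#' Seeded synthetic tap takes
#'
#' Generates drummer tapping recordings with the structure the consensus
#' beat-annotation procedure expects: true beats (isochronous or with
#' linear tempo drift) plus a per-drummer constant motor offset and
#' per-tap Gaussian jitter. The true beats are returned alongside for
#' oracle comparisons.
#'
#' @param n_drummers Number of drummers.
#' @param takes_per_drummer Takes per drummer (`>= 2`).
#' @param n_beats Beats per take.
#' @param period Mean inter-beat interval in seconds.
#' @param drift Linear tempo drift: total fractional change of the
#'   period across the excerpt (0 = isochronous).
#' @param jitter_sd Per-tap jitter SD in seconds.
#' @param offsets Constant motor offset per drummer, seconds (recycled).
#' @param latency Equipment latency in seconds, added to every recorded
#'   onset and declared as each take's `latency_correction`.
#' @param seed Integer seed.
#' @return A list with `takes` (list of tap takes: lists with
#'   `drummer_id`, `take_id`, `onsets`, `latency_correction`) and
#'   `true_beats` (numeric vector).
#' @export
make_tap_takes <- function(n_drummers = 3, takes_per_drummer = 3,
                           n_beats = 12, period = 0.5, drift = 0,
                           jitter_sd = 0.01, offsets = 0,
                           latency = 0.02, seed = 1L) {
  stopifnot(takes_per_drummer >= 2, n_beats >= 3, period > 0,
            jitter_sd >= 0)
  rng <- local_rng(seed)
  periods <- period * (1 + drift * seq(0, 1, length.out = n_beats - 1L))
  true_beats <- cumsum(c(1, periods))  # start 1 s into the excerpt
  offsets <- rep_len(offsets, n_drummers)
  takes <- list()
  for (d in seq_len(n_drummers)) {
    for (t in seq_len(takes_per_drummer)) {
      onsets <- true_beats + offsets[d] +
        rng$norm(n_beats) * jitter_sd + latency
      takes[[length(takes) + 1L]] <- list(
        drummer_id = sprintf("drummer%02d", d),
        take_id = sprintf("drummer%02d_take%02d", d, t),
        onsets = sort(onsets),
        latency_correction = latency)
    }
  }
  list(takes = takes, true_beats = true_beats)
}

#' Seeded synthetic response matrices
#'
#' Draws Bernoulli responses under the constrained 2-AFC model with
#' abilities from the standard normal (or supplied), for a given item
#' set. Supports the balanced-assignment design in which each
#' participant answers one item per track and one item per accuracy
#' level, realised as a seeded random bijection of tracks onto accuracy
#' levels per participant (items outside the participant's assignment
#' are missing).
#'
#' @param n_persons Number of persons.
#' @param items Data frame with columns `item_id`, `difficulty`, and,
#'   for the balanced design, `track_id` and `accuracy` (an
#'   `"item_bank"` works directly).
#' @param coefficients A [difficulty_coefficients()] object (supplies
#'   the discrimination).
#' @param abilities Optional vector of true abilities (default: drawn
#'   from N(0,1)).
#' @param design `"complete"` (every person answers every item) or
#'   `"balanced"` (one item per track x one per accuracy level).
#' @param seed Integer seed.
#' @return A list with `matrix` (a [response_matrix()]) and `truth`
#'   (list with `abilities` and `coefficients`).
#' @export
make_response_matrix <- function(n_persons, items,
                                 coefficients = difficulty_coefficients(),
                                 abilities = NULL,
                                 design = c("complete", "balanced"),
                                 seed = 1L) {
  design <- match.arg(design)
  items <- as.data.frame(items)
  stopifnot(n_persons >= 1, nrow(items) >= 1,
            all(c("item_id", "difficulty") %in% names(items)))
  rng <- local_rng(seed)
  if (is.null(abilities)) abilities <- rng$norm(n_persons)
  stopifnot(length(abilities) == n_persons)
  a <- coefficients$discrimination
  n_items <- nrow(items)
  scores <- matrix(NA_integer_, n_persons, n_items,
                   dimnames = list(sprintf("p%04d", seq_len(n_persons)),
                                   items$item_id))
  if (design == "complete") {
    for (i in seq_len(n_persons)) {
      p <- prob_correct_2afc(abilities[i], items$difficulty, a)
      scores[i, ] <- rng$bern(p)
    }
  } else {
    stopifnot(all(c("track_id", "accuracy") %in% names(items)))
    tracks <- sort(unique(items$track_id))
    accs <- sort(unique(items$accuracy))
    if (length(tracks) != length(accs))
      stop("balanced design requires equal numbers of tracks and ",
           "accuracy levels", call. = FALSE)
    m <- length(tracks)
    for (i in seq_len(n_persons)) {
      pairing <- accs[rng$permutation(m)]  # track k -> accuracy pairing[k]
      for (k in seq_len(m)) {
        cand <- which(items$track_id == tracks[k] &
                        abs(items$accuracy - pairing[k]) < 1e-12)
        if (length(cand) == 0L)
          stop("infeasible balanced assignment: no item for track ",
               tracks[k], call. = FALSE)
        j <- if (length(cand) == 1L) cand else cand[rng$choose(length(cand), 1L)]
        p <- prob_correct_2afc(abilities[i], items$difficulty[j], a)
        scores[i, j] <- rng$bern(p)
      }
    }
  }
  keep <- c("item_id", intersect(c("track_id", "accuracy", "direction",
                                   "order", "difficulty"), names(items)))
  list(matrix = response_matrix(scores, items[, keep, drop = FALSE]),
       truth = list(abilities = abilities, coefficients = coefficients))
}
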