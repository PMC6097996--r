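#' Beep-track accuracy from beep-track offset
#'
#' Transforms a lure's beep-track offset `P` (displacement as a fraction of
#' one beat, `0 < P <= 0.5`) into beep-track accuracy `cos^4(pi * P)`, the
#' structural feature that drives item difficulty approximately linearly.
#' Because the beat is periodic, half a beat is the largest meaningful
#' displacement.
#'
#' @param offset Beep-track offset(s) in `(0, 0.5]`, fraction of a beat.
#' @return Accuracy value(s) in `[0, 1)`; strictly decreasing in `offset`.
#' @examples
#' accuracy_from_offset(0.25)  # exactly 0.25
#' accuracy_from_offset(0.5)   # 0: maximal displacement
#' @export
accuracy_from_offset <- function(offset) {
  if (any(!is.finite(offset)) || any(offset <= 0 | offset > 0.5))
    stop("`offset` must lie in (0, 0.5] (fraction of a beat)",
         call. = FALSE)
  cos(pi * offset)^4
}

#' Beep-track offset realising a target accuracy
#'
#' Inverse of [accuracy_from_offset()]: `arccos(accuracy^(1/4)) / pi`.
#' Used to turn an accuracy grid into concrete stimulus displacements.
#'
#' @param accuracy Accuracy value(s) in `[0, 1)`.
#' @return Offset(s) in `(0, 0.5]`, fraction of a beat.
#' @export
offset_from_accuracy <- function(accuracy) {
  if (any(!is.finite(accuracy)) || any(accuracy < 0 | accuracy >= 1))
    stop("`accuracy` must lie in [0, 1)", call. = FALSE)
  acos(accuracy^0.25) / pi
}

#' Equally spaced accuracy levels
#'
#' `n_levels` values starting at `low` with step
#' `(high_exclusive - low) / n_levels`; the upper endpoint is excluded,
#' matching an accuracy range such as `0.5 <= d < 1`.
#'
#' @param n_levels Number of levels, `>= 1`.
#' @param low First level (included).
#' @param high_exclusive Upper bound (excluded).
#' @return Numeric vector of length `n_levels`, all `< high_exclusive`.
#' @examples
#' accuracy_grid(100, 0.5, 1)  # 0.500, 0.505, ..., 0.995
#' @export
accuracy_grid <- function(n_levels, low = 0.5, high_exclusive = 1) {
  if (!is.numeric(n_levels) || length(n_levels) != 1L || n_levels < 1)
    stop("`n_levels` must be a positive count", call. = FALSE)
  if (low >= high_exclusive)
    stop("`low` must be < `high_exclusive`", call. = FALSE)
  n_levels <- as.integer(n_levels)
  low + (seq_len(n_levels) - 1L) * (high_exclusive - low) / n_levels
}

#' Difficulty coefficients of the explanatory item response model
#'
#' The linear model mapping item features to item difficulty:
#' `difficulty = intercept + accuracy_effect * accuracy +
#' direction_effect * [direction == "behind"]`, together with the shared
#' discrimination. Defaults are the published calibration (intercept
#' -5.393, accuracy effect 7.247, behind-the-beat effect -0.576,
#' discrimination 1.166). Track-level random-effect estimates from the
#' calibration study (intercept SD 2.121, accuracy-slope SD 1.477,
#' correlation -1) are carried as metadata only; they do not enter
#' difficulty prediction because including them was found to reduce test
#' reliability.
#'
#' @param intercept,accuracy_effect,direction_effect Fixed effects on the
#'   difficulty (latent) scale; the direction effect applies when the lure
#'   is displaced behind the beat.
#' @param discrimination Shared discrimination `a > 0`.
#' @param track_random_effects Optional named list of track-level
#'   random-effect metadata (not used in prediction).
#' @return An object of class `"difficulty_coefficients"`.
#' @examples
#' difficulty_coefficients()  # published calibration
#' @export
difficulty_coefficients <- function(intercept = -5.393,
                                    accuracy_effect = 7.247,
                                    direction_effect = -0.576,
                                    discrimination = 1.166,
                                    track_random_effects = list(
                                      intercept_sd = 2.121,
                                      accuracy_slope_sd = 1.477,
                                      correlation = -1)) {
  if (discrimination <= 0)
    stop("`discrimination` must be > 0", call. = FALSE)
  structure(list(intercept = intercept,
                 accuracy_effect = accuracy_effect,
                 direction_effect = direction_effect,
                 discrimination = discrimination,
                 track_random_effects = track_random_effects),
            class = "difficulty_coefficients")
}

#' @export
print.difficulty_coefficients <- function(x, ...) {
  cat("Explanatory difficulty model: intercept + accuracy + direction\n")
  cat(sprintf("  intercept        %8.3f\n", x$intercept))
  cat(sprintf("  accuracy effect  %8.3f\n", x$accuracy_effect))
  cat(sprintf("  behind effect    %8.3f\n", x$direction_effect))
  cat(sprintf("  discrimination   %8.3f\n", x$discrimination))
  invisible(x)
}

#' @export
coef.difficulty_coefficients <- function(object, ...) {
  c(intercept = object$intercept,
    accuracy = object$accuracy_effect,
    direction_behind = object$direction_effect)
}

#' Predict item difficulty from structural features
#'
#' Applies the explanatory difficulty model: only beep-track accuracy and
#' displacement direction enter; the musical track and the stimulus order
#' are incidentals for difficulty prediction. Direction is dummy-coded 1
#' for "behind" (the beat), 0 for "ahead".
#'
#' @param accuracy Beep-track accuracy in `[0, 1)` (vectorised).
#' @param direction Character vector, `"ahead"` or `"behind"` (recycled).
#' @param coefficients A [difficulty_coefficients()] object.
#' @return Predicted difficulty on the latent ability scale.
#' @examples
#' predict_difficulty(0.995, "ahead")   # ~1.818, near the bank ceiling
#' predict_difficulty(0.5, "behind")    # ~-2.35, near the bank floor
#' @export
predict_difficulty <- function(accuracy, direction,
                               coefficients = difficulty_coefficients()) {
  if (any(accuracy < 0 | accuracy >= 1))
    stop("`accuracy` must lie in [0, 1)", call. = FALSE)
  direction <- match.arg2(direction, c("ahead", "behind"))
  coefficients$intercept +
    coefficients$accuracy_effect * accuracy +
    coefficients$direction_effect * (direction == "behind")
}

## vectorised match.arg
match.arg2 <- function(x, choices) {
  x <- as.character(x)
  if (any(!x %in% choices))
    stop(sprintf("values must be one of: %s",
                 paste(choices, collapse = ", ")), call. = FALSE)
  x
}

#' Convert raw mixed-model effects to the item-response-theory metric
#'
#' When the constrained 2-AFC model is estimated as a logistic mixed
#' model with a Gaussian person intercept, the IRT discrimination equals
#' the person-intercept standard deviation and each item-feature effect on
#' the difficulty scale equals the raw fixed effect multiplied by
#' `-1 / discrimination`.
#'
#' @param raw_effects Numeric vector of raw (logit-scale) fixed effects;
#'   names are preserved.
#' @param person_sd Standard deviation of the person intercept, `> 0`.
#' @return A [difficulty_coefficients()] object when `raw_effects` has
#'   length 3 (intercept, accuracy, direction); otherwise a numeric vector
#'   of converted effects with attribute `discrimination`.
#' @examples
#' glmm_to_irt(c(6.287, -8.448, 0.671), person_sd = 1.166)
#' @export
glmm_to_irt <- function(raw_effects, person_sd) {
  if (!is.numeric(person_sd) || length(person_sd) != 1L || person_sd <= 0)
    stop("`person_sd` must be a positive scalar", call. = FALSE)
  eff <- -raw_effects / person_sd
  if (length(raw_effects) == 3L) {
    difficulty_coefficients(intercept = eff[[1L]],
                            accuracy_effect = eff[[2L]],
                            direction_effect = eff[[3L]],
                            discrimination = person_sd)
  } else {
    structure(eff, discrimination = person_sd)
  }
}

item_id_from_features <- function(track_id, accuracy, direction, order) {
  sprintf("%s_a%.6f_%s_%s", track_id, accuracy,
          substr(direction, 1, 2), substr(order, 1, 2))
}

#' Build an item bank from structural feature grids
#'
#' Automatic item generation. In `"factorial"` mode every combination of
#' track, accuracy level, displacement direction, and stimulus order
#' becomes one item (e.g. 27 tracks x 27 accuracies x 2 x 2 = 2916 items;
#' 25 x 100 x 2 x 2 = 10000 items). In `"paired"` mode tracks and
#' accuracy levels (equal counts) are randomly paired one-to-one and one
#' random half of the items is displaced ahead / presented target-first,
#' the other half behind / lure-first. Every item carries its predicted
#' difficulty and the offset realising its accuracy.
#'
#' @param tracks Character vector of distinct track identifiers.
#' @param accuracies Numeric vector of accuracy levels in `[0, 1)`.
#' @param directions Subset of `c("ahead", "behind")` (factorial mode).
#' @param orders Subset of `c("target_first", "lure_first")` (factorial
#'   mode).
#' @param coefficients A [difficulty_coefficients()] object.
#' @param mode `"factorial"` or `"paired"`.
#' @param seed Integer seed recorded in the bank's provenance and used
#'   for the random pairing in `"paired"` mode.
#' @return An object of class `"item_bank"`: a data frame with columns
#'   `item_id`, `track_id`, `offset`, `accuracy`, `direction`, `order`,
#'   `difficulty`, plus attributes `coefficients` and `provenance`.
#' @examples
#' bank <- build_bank(sprintf("t%02d", 1:27), accuracy_grid(27, 0.5, 1))
#' nrow(bank)  # 2916
#' @export
build_bank <- function(tracks, accuracies,
                       directions = c("ahead", "behind"),
                       orders = c("target_first", "lure_first"),
                       coefficients = difficulty_coefficients(),
                       mode = c("factorial", "paired"),
                       seed = 1L) {
  mode <- match.arg(mode)
  tracks <- as.character(tracks)
  if (length(tracks) == 0L || length(accuracies) == 0L)
    stop("`tracks` and `accuracies` must be nonempty", call. = FALSE)
  if (anyDuplicated(tracks))
    stop("duplicate track ids", call. = FALSE)
  directions <- match.arg2(directions, c("ahead", "behind"))
  orders <- match.arg2(orders, c("target_first", "lure_first"))

  if (mode == "factorial") {
    grid <- expand.grid(track_id = tracks, accuracy = accuracies,
                        direction = directions, order = orders,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    if (length(tracks) != length(accuracies))
      stop("paired mode requires equal numbers of tracks and accuracies",
           call. = FALSE)
    n <- length(tracks)
    rng <- local_rng(seed)
    acc <- accuracies[rng$permutation(n)]
    dir <- rep("behind", n)
    dir[rng$choose(n, floor(n / 2))] <- "ahead"
    ord <- rep("lure_first", n)
    ord[rng$choose(n, floor(n / 2))] <- "target_first"
    grid <- data.frame(track_id = tracks, accuracy = acc,
                       direction = dir, order = ord,
                       stringsAsFactors = FALSE)
  }
  grid$offset <- offset_from_accuracy(grid$accuracy)
  grid$difficulty <- predict_difficulty(grid$accuracy, grid$direction,
                                        coefficients)
  grid$item_id <- item_id_from_features(grid$track_id, grid$accuracy,
                                        grid$direction, grid$order)
  if (anyDuplicated(grid$item_id))
    stop("internal error: duplicate item ids", call. = FALSE)
  bank <- grid[, c("item_id", "track_id", "offset", "accuracy",
                   "direction", "order", "difficulty")]
  rownames(bank) <- NULL
  structure(bank,
            coefficients = coefficients,
            provenance = list(mode = mode, seed = seed,
                              n_tracks = length(tracks),
                              n_accuracies = length(unique(accuracies))),
            class = c("item_bank", "data.frame"))
}

#' The standard adaptive-test item bank
#'
#' Convenience constructor for the full adaptive bank: 25 tracks crossed
#' with 100 equally spaced accuracy levels on `[0.5, 1)`, both
#' displacement directions and both stimulus orders (10000 items), with
#' the published difficulty coefficients.
#'
#' @param n_tracks,n_accuracies Factor cardinalities.
#' @param coefficients A [difficulty_coefficients()] object.
#' @return An `"item_bank"` object.
#' @export
standard_bank <- function(n_tracks = 25, n_accuracies = 100,
                          coefficients = difficulty_coefficients()) {
  build_bank(sprintf("track%03d", seq_len(n_tracks)),
             accuracy_grid(n_accuracies, 0.5, 1),
             coefficients = coefficients)
}

#' @export
print.item_bank <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("Item bank: %d items (%s mode), %d tracks, %d accuracy levels\n",
              nrow(x), prov$mode, prov$n_tracks, prov$n_accuracies))
  cat(sprintf("  difficulty range: [%.3f, %.3f]\n",
              min(x$difficulty), max(x$difficulty)))
  invisible(x)
}

#' @export
summary.item_bank <- function(object, ...) {
  cat("Item bank summary\n")
  print(attr(object, "coefficients"))
  print(summary(object$difficulty))
  invisible(object)
}

#' Write / read an item bank as CSV
#'
#' The CSV carries one row per item with columns `item_id`, `track_id`,
#' `offset`, `accuracy`, `direction`, `order`, `difficulty` (at least six
#' significant digits). The reader re-validates the bank: unique item
#' ids, `accuracy = cos^4(pi * offset)` and stored difficulty matching the
#' supplied coefficients, both to `1e-6`.
#'
#' @param bank An `"item_bank"` object.
#' @param path File path.
#' @param coefficients Coefficients used for re-validation on read.
#' @return `write_bank()` returns `path` invisibly; `read_bank()` returns
#'   an `"item_bank"` object.
#' @export
write_bank <- function(bank, path) {
  df <- as.data.frame(bank)
  for (col in c("offset", "accuracy", "difficulty"))
    df[[col]] <- formatC(df[[col]], digits = 9, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bank
#' @export
read_bank <- function(path, coefficients = difficulty_coefficients()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("item_id", "track_id", "offset", "accuracy", "direction",
                "order", "difficulty")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("bank file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop("bank file contains no items", call. = FALSE)
  dup <- which(duplicated(df$item_id))
  if (length(dup))
    stop(sprintf("duplicate item_id at row %d", dup[1L]), call. = FALSE)
  bad_acc <- which(abs(accuracy_from_offset(df$offset) - df$accuracy) > 1e-6)
  if (length(bad_acc))
    stop(sprintf("row %d: accuracy inconsistent with offset", bad_acc[1L]),
         call. = FALSE)
  pred <- predict_difficulty(df$accuracy, df$direction, coefficients)
  bad_diff <- which(abs(pred - df$difficulty) > 1e-6)
  if (length(bad_diff))
    stop(sprintf("row %d: difficulty inconsistent with features",
                 bad_diff[1L]), call. = FALSE)
  structure(df[, required],
            coefficients = coefficients,
            provenance = list(mode = "file", seed = NA_integer_,
                              n_tracks = length(unique(df$track_id)),
                              n_accuracies = length(unique(df$accuracy))),
            class = c("item_bank", "data.frame"))
}
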