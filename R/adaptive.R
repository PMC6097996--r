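#' Configuration for an adaptive test session
#'
#' @param test_length Number of items to administer (default 25). Must
#'   not exceed the number of distinct tracks in the bank, since a track
#'   is never heard twice within a session.
#' @param first_item_difficulty Difficulty targeted by the first item
#'   (default -0.01, an average-ability start; 0 is also natural).
#' @param randomesque Size of the candidate set for item selection: the
#'   eligible items nearest in difficulty to the current ability estimate
#'   (ties always included), from which one is drawn at random. Default 1
#'   plus ties, i.e. pure nearest-difficulty selection.
#' @param prior_mean,prior_sd Gaussian prior for interim Bayes modal
#'   scoring.
#' @param seed Integer seed driving all of the session's randomness
#'   (stimulus-order choice for the first item, tie-breaks).
#' @return An object of class `"session_config"`.
#' @export
session_config <- function(test_length = 25,
                           first_item_difficulty = -0.01,
                           randomesque = 1,
                           prior_mean = 0, prior_sd = 1,
                           seed = 1L) {
  stopifnot(test_length >= 1, randomesque >= 1, prior_sd > 0)
  structure(list(test_length = as.integer(test_length),
                 first_item_difficulty = first_item_difficulty,
                 randomesque = as.integer(randomesque),
                 prior_mean = prior_mean, prior_sd = prior_sd,
                 seed = as.integer(seed)),
            class = "session_config")
}

#' First item of an adaptive session
#'
#' Returns the bank item whose difficulty is nearest the configured
#' first-item target. All structural features except stimulus order are
#' fixed by that choice; the order (and any exact difficulty tie) is
#' resolved by the session's seeded generator.
#'
#' @param bank An `"item_bank"` object.
#' @param config A [session_config()] object.
#' @param rng Internal RNG stream (defaults to one seeded from `config`).
#' @return A one-row data frame: the selected item.
#' @export
select_first_item <- function(bank, config = session_config(),
                              rng = local_rng(config$seed)) {
  if (nrow(bank) == 0L) stop("empty item bank", call. = FALSE)
  d <- abs(bank$difficulty - config$first_item_difficulty)
  nearest <- which(d <= min(d) + 1e-12)
  ## the difficulty is fixed; stimulus order (and any tie) varies randomly
  bank[rng$pick(nearest), , drop = FALSE]
}

#' Next item under the nearest-difficulty (Urry) criterion
#'
#' Among items whose track has not been used, those minimally distant in
#' difficulty from the current ability estimate form the candidate set
#' (expanded to `config$randomesque` members by next-nearest difficulty;
#' exact ties are always kept together); one candidate is drawn uniformly
#' with the session's seeded generator.
#'
#' @param bank An `"item_bank"` object.
#' @param theta_hat Current ability estimate.
#' @param used_tracks Character vector of track ids already administered.
#' @param config A [session_config()] object.
#' @param rng Internal RNG stream.
#' @return A one-row data frame: the selected item.
#' @export
select_next_item <- function(bank, theta_hat, used_tracks,
                             config = session_config(),
                             rng = local_rng(config$seed)) {
  eligible <- which(!(bank$track_id %in% used_tracks))
  if (length(eligible) == 0L)
    stop("item bank exhausted: no unused tracks remain", call. = FALSE)
  d <- abs(bank$difficulty[eligible] - theta_hat)
  ord <- order(d)
  k <- config$randomesque
  if (k < length(ord)) {
    cutoff <- d[ord[k]] + 1e-12   # keep exact ties with the k-th nearest
    cand <- eligible[d <= cutoff]
  } else {
    cand <- eligible
  }
  bank[rng$pick(cand), , drop = FALSE]
}

#' Run one adaptive test session
#'
#' The session loop: administer the first item at the configured target
#' difficulty, then repeatedly re-estimate ability by Bayes modal
#' estimation (Gaussian prior) and administer the unused-track item
#' nearest in difficulty to the estimate, stopping after
#' `config$test_length` items. The final score is a weighted likelihood
#' (Warm) estimate over the full pattern.
#'
#' @param bank An `"item_bank"` object.
#' @param responder A function `function(item) -> 0/1` scoring the
#'   simulated or scripted response to a one-row item data frame (see
#'   [simulate_responder()]).
#' @param config A [session_config()] object.
#' @return An object of class `"cat_session"`: list with `items` (the
#'   administered items, in order), `responses`, `trajectory` (one
#'   interim `"ability_estimate"` per response), `final` (the weighted
#'   likelihood estimate), and `config`. If the responder fails, the
#'   error is re-signalled with the partial log attached in the
#'   condition's `data`.
#' @examples
#' bank <- standard_bank()
#' resp <- simulate_responder(0.5, seed = 7)
#' s <- run_session(bank, resp, session_config(seed = 7))
#' s$final$theta
#' @export
run_session <- function(bank, responder, config = session_config()) {
  if (config$test_length > length(unique(bank$track_id)))
    stop("test_length exceeds the number of distinct tracks",
         call. = FALSE)
  params <- bank_params(bank)
  rng <- local_rng(config$seed)
  items <- vector("list", config$test_length)
  responses <- integer(config$test_length)
  trajectory <- vector("list", config$test_length)
  used <- character(0)
  theta_hat <- config$prior_mean
  for (k in seq_len(config$test_length)) {
    item <- if (k == 1L) select_first_item(bank, config, rng)
            else select_next_item(bank, theta_hat, used, config, rng)
    resp <- tryCatch(responder(item), error = function(e) e)
    if (inherits(resp, "error")) {
      partial <- finish_session(items[seq_len(k - 1L)],
                                responses[seq_len(k - 1L)],
                                trajectory[seq_len(k - 1L)],
                                config, params, final = FALSE)
      cond <- simpleError(
        sprintf("responder failed at item %d: %s", k,
                conditionMessage(resp)))
      cond$data <- partial
      stop(cond)
    }
    resp <- as.integer(resp)
    if (!resp %in% c(0L, 1L))
      stop("responder must return 0 or 1", call. = FALSE)
    items[[k]] <- item
    responses[k] <- resp
    used <- c(used, item$track_id)
    est <- estimate_bayes_modal(
      responses[seq_len(k)],
      vapply(items[seq_len(k)], function(i) i$difficulty, numeric(1)),
      params, config$prior_mean, config$prior_sd)
    trajectory[[k]] <- est
    theta_hat <- est$theta
  }
  finish_session(items, responses, trajectory, config, params,
                 final = TRUE)
}

bank_params <- function(bank) {
  coefs <- attr(bank, "coefficients")
  a <- if (!is.null(coefs)) coefs$discrimination else 1.166
  response_model_params(discrimination = a)
}

finish_session <- function(items, responses, trajectory, config, params,
                           final = TRUE) {
  items_df <- do.call(rbind, items)
  final_est <- if (final && length(responses))
    estimate_weighted_likelihood(responses, items_df$difficulty, params)
  else NULL
  structure(list(items = items_df, responses = responses,
                 trajectory = trajectory, final = final_est,
                 config = config, params = params),
            class = "cat_session")
}

#' @export
print.cat_session <- function(x, ...) {
  n <- length(x$responses)
  cat(sprintf("Adaptive session: %d items, %d correct (%.0f%%)\n",
              n, sum(x$responses), 100 * mean(x$responses)))
  if (!is.null(x$final))
    cat(sprintf("  final (weighted likelihood): theta = %.3f, SE = %.3f\n",
                x$final$theta, x$final$se))
  invisible(x)
}

#' @export
summary.cat_session <- function(object, ...) {
  df <- data.frame(
    item = seq_along(object$responses),
    item_id = object$items$item_id,
    difficulty = object$items$difficulty,
    response = object$responses,
    theta_interim = vapply(object$trajectory, `[[`, numeric(1), "theta"),
    se_interim = vapply(object$trajectory, `[[`, numeric(1), "se"))
  print(object)
  df
}

#' @export
coef.cat_session <- function(object, ...) {
  c(theta = object$final$theta, se = object$final$se)
}

#' Plot the ability trajectory of a session
#'
#' Interim Bayes modal estimates with +-1 SE bands and the administered
#' item difficulties, as a function of item number.
#'
#' @param x A `"cat_session"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cat_session <- function(x, ...) {
  th <- vapply(x$trajectory, `[[`, numeric(1), "theta")
  se <- vapply(x$trajectory, `[[`, numeric(1), "se")
  k <- seq_along(th)
  graphics::plot(k, th, type = "b", pch = 16,
                 ylim = range(th - se, th + se, x$items$difficulty),
                 xlab = "item number", ylab = "ability estimate", ...)
  graphics::arrows(k, th - se, k, th + se, angle = 90, code = 3,
                   length = 0.03, col = "grey50")
  graphics::points(k, x$items$difficulty, pch = 4, col = "firebrick")
  graphics::legend("bottomright", pch = c(16, 4),
                   col = c("black", "firebrick"),
                   legend = c("interim estimate", "item difficulty"),
                   bty = "n")
  invisible(x)
}

#' Recompute the weighted likelihood score after the first k items
#'
#' Used for standard-error-versus-length curves: a full-length session is
#' rescored as if it had stopped after `k` items.
#'
#' @param session A `"cat_session"` object.
#' @param k Number of leading responses to use.
#' @return An `"ability_estimate"` (weighted likelihood).
#' @export
rescore_at_length <- function(session, k) {
  stopifnot(k >= 1, k <= length(session$responses))
  estimate_weighted_likelihood(session$responses[seq_len(k)],
                               session$items$difficulty[seq_len(k)],
                               session$params)
}

#' Write / read a session log as JSON lines
#'
#' One JSON record per administered item (`item_id`, features, response,
#' interim estimate and SE), followed by a final record with the weighted
#' likelihood score. `read_session_log()` returns the parsed records; the
#' trajectory can be reproduced exactly by rescoring the logged
#' responses.
#'
#' @param session A `"cat_session"` object.
#' @param path File path.
#' @return `write_session_log()` returns `path` invisibly;
#'   `read_session_log()` a list with `items` (data frame) and `final`.
#' @export
write_session_log <- function(session, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in seq_along(session$responses)) {
    it <- session$items[k, ]
    rec <- list(type = "item", k = k, item_id = it$item_id,
                track_id = it$track_id, accuracy = it$accuracy,
                direction = it$direction, order = it$order,
                difficulty = it$difficulty,
                response = session$responses[k],
                theta_interim = session$trajectory[[k]]$theta,
                se_interim = session$trajectory[[k]]$se)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  if (!is.null(session$final)) {
    fin <- list(type = "final", method = session$final$method,
                theta = session$final$theta, se = session$final$se)
    writeLines(jsonlite::toJSON(fin, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  recs <- lapply(lines, jsonlite::fromJSON)
  types <- vapply(recs, `[[`, character(1), "type")
  items <- do.call(rbind, lapply(recs[types == "item"], function(r)
    data.frame(k = r$k, item_id = r$item_id, track_id = r$track_id,
               accuracy = r$accuracy, direction = r$direction,
               order = r$order, difficulty = r$difficulty,
               response = r$response, theta_interim = r$theta_interim,
               se_interim = r$se_interim, stringsAsFactors = FALSE)))
  final <- recs[types == "final"]
  list(items = items,
       final = if (length(final)) final[[1L]] else NULL)
}
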