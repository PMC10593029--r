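#' Joint outcome distributions
#'
#' A joint outcome distribution assigns a probability to every feasible
#' outcome vector of an event chain, within one stratum (covariate level,
#' vaccination arm, variant). This is the parameterization an
#' individual-based model consumes when it draws a complete post-exposure
#' fate in one step; [joint_to_conditional()] converts it to the
#' step-by-step progression probabilities used when the model draws events
#' sequentially.
#'
#' @param mass A data frame with one 0/1 column per chain event plus a
#'   `prob` column. Vectors absent from `mass` carry probability 0.
#' @param chain An [event_chain()].
#' @param stratum Optional named list tagging the stratum (e.g.
#'   `list(l = "65+", a = 1, e = "omicron")`).
#' @return A tibble of class `joint_outcome_dist` with the event columns in
#'   chain order and a `prob` column, one row per feasible vector
#'   (unlisted vectors filled with probability 0).
#' @export
joint_outcome_distribution <- function(mass, chain = event_chain(),
                                       stratum = NULL) {
  stopifnot(is.data.frame(mass), "prob" %in% names(mass),
            all(chain$events %in% names(mass)))
  if (any(mass$prob < 0)) {
    abort("probabilities must be non-negative",
          class = "vesimlab_domain_error")
  }
  if (abs(sum(mass$prob) - 1) > 1e-12) {
    abort(sprintf("probabilities sum to %.15f, not 1", sum(mass$prob)),
          class = "vesimlab_domain_error")
  }
  if (!all(is_feasible(mass, chain))) {
    abort("mass assigned to vectors violating the precedence relation",
          class = "vesimlab_constraint_error")
  }
  full <- enumerate_feasible(chain)
  out <- dplyr::left_join(full,
                          dplyr::select(tibble::as_tibble(mass),
                                        dplyr::all_of(c(chain$events, "prob"))),
                          by = chain$events) |>
    dplyr::mutate(prob = dplyr::coalesce(.data$prob, 0))
  attr(out, "chain") <- chain
  attr(out, "stratum") <- stratum
  class(out) <- c("joint_outcome_dist", class(out))
  out
}

history_key <- function(m, events) {
  if (!length(events)) return(rep("", nrow(m)))
  keys <- apply(m[, events, drop = FALSE], 1L,
                function(r) paste0(events, "=", r, collapse = ","))
  as.character(keys)
}

#' Convert a joint outcome distribution to progression probabilities
#'
#' For each event and each reachable history of prior events, computes the
#' conditional probability that the event occurs given that history, by
#' summing joint mass. Histories with zero marginal mass yield an explicit
#' undefined entry (`defined = FALSE`, `prob = NA`) — "never reached" is
#' deliberately distinct from "never progresses" (probability 0), because a
#' sequential-draw model must treat them differently.
#'
#' @param j A [joint_outcome_distribution()].
#' @return A tibble of class `progression_table`: columns `event`,
#'   `history` (e.g. `"I=1,S=0"`, empty for the first event), `prob`,
#'   `defined`.
#' @export
joint_to_conditional <- function(j) {
  chain <- attr(j, "chain")
  ev <- chain$events
  m <- as.matrix(j[, ev, drop = FALSE])
  prob <- j$prob
  rows <- purrr::map(seq_along(ev), function(k) {
    prior <- ev[seq_len(k - 1L)]
    key <- history_key(m, prior)
    den <- tapply(prob, key, sum)
    num <- tapply(prob * (m[, k] == 1), key, sum)
    tibble::tibble(
      event = ev[k],
      history = names(den),
      prob = as.numeric(ifelse(den > 0, num / den, NA_real_)),
      defined = as.numeric(den) > 0
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "chain") <- chain
  class(out) <- c("progression_table", class(out))
  out
}

#' Convert progression probabilities to a joint outcome distribution
#'
#' Multiplies conditional probabilities along each feasible outcome vector
#' (chain rule over full histories). A missing entry for a history that is
#' reached with positive probability is an error; undefined entries are
#' tolerated only on histories whose running probability is already zero.
#'
#' @param t A [progression_table][joint_to_conditional()].
#' @param chain The [event_chain()]; defaults to the one attached to `t`.
#' @return A [joint_outcome_distribution()].
#' @export
conditional_to_joint <- function(t, chain = attr(t, "chain")) {
  stopifnot(is.data.frame(t),
            all(c("event", "history", "prob") %in% names(t)))
  ev <- chain$events
  full <- enumerate_feasible(chain)
  m <- as.matrix(full)
  lookup <- setNames(t$prob, paste(t$event, t$history, sep = "|"))
  mass <- vapply(seq_len(nrow(m)), function(r) {
    p <- 1
    for (k in seq_along(ev)) {
      if (p == 0) break
      key <- paste(ev[k], history_key(m[r, , drop = FALSE],
                                      ev[seq_len(k - 1L)]), sep = "|")
      if (!key %in% names(lookup)) {
        abort(sprintf("no progression entry for event %s given history '%s'",
                      ev[k], sub("^[^|]*\\|", "", key)),
              class = "vesimlab_incomplete_table_error")
      }
      pk <- lookup[[key]]
      if (is.na(pk)) {
        abort(sprintf(
          "undefined progression entry reached with positive probability: event %s, history '%s'",
          ev[k], sub("^[^|]*\\|", "", key)),
          class = "vesimlab_incomplete_table_error")
      }
      p <- p * if (m[r, k] == 1) pk else 1 - pk
    }
    p
  }, numeric(1))
  out <- full
  out$prob <- mass
  joint_outcome_distribution(out, chain)
}

#' Read or write joint and progression tables
#'
#' Joint distributions are stored as one row per outcome vector (one 0/1
#' column per event plus `prob`); progression tables as rows of
#' `(event, history, prob, defined)`. Format follows the file extension:
#' `.csv` or `.json`.
#'
#' @param x The table to write.
#' @param path File path ending in `.csv` or `.json`.
#' @param chain The [event_chain()] the stored table refers to.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_outcome_table <- function(x, path) {
  df <- as.data.frame(x)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA, na = "null")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_outcome_table
#' @export
read_joint_distribution <- function(path, chain = event_chain()) {
  df <- read_table_file(path)
  joint_outcome_distribution(df, chain)
}

#' @rdname write_outcome_table
#' @export
read_progression_table <- function(path, chain = event_chain()) {
  df <- read_table_file(path)
  stopifnot(all(c("event", "history", "prob") %in% names(df)))
  df$history[is.na(df$history)] <- ""
  if (!"defined" %in% names(df)) df$defined <- !is.na(df$prob)
  out <- tibble::as_tibble(df)
  attr(out, "chain") <- chain
  class(out) <- c("progression_table", class(out))
  out
}

read_table_file <- function(path) {
  if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}
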