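#' Post-exposure event chains
#'
#' An event chain lists the binary events that can occur after an exposure,
#' in approximate temporal order, together with a precedence relation:
#' `requires` is a set of ordered pairs `(a, b)` meaning event `b` can occur
#' only if event `a` has occurred. Precedence is a relation over pairs rather
#' than a strict linear chain because some events may skip predecessors
#' (a patient can die without ever being admitted to the ICU).
#'
#' The default chain holds the six post-exposure events of an acute
#' respiratory infection: infection (`I`), symptoms (`S`), diagnosis (`D`),
#' hospitalization (`H`), ICU admission (`C`) and death (`M`), with
#' S and D requiring I, H requiring D, C requiring H, and M requiring H
#' (so death may skip the ICU).
#'
#' @param events Character vector of unique event labels, in chain order.
#' @param requires A list of length-2 character vectors (or a 2-column
#'   matrix), each `c(a, b)` meaning `b` requires `a`. May be empty.
#'
#' @return An object of class `event_chain`.
#' @examples
#' chain <- event_chain()
#' enumerate_feasible(chain)
#' @export
event_chain <- function(events = c("I", "S", "D", "H", "C", "M"),
                        requires = list(
                          c("I", "S"), c("I", "D"), c("D", "H"),
                          c("H", "C"), c("H", "M")
                        )) {
  if (is.matrix(requires)) {
    requires <- lapply(seq_len(nrow(requires)), function(i) requires[i, ])
  }
  req <- if (length(requires)) {
    do.call(rbind, lapply(requires, function(p) {
      if (length(p) != 2L) {
        abort("each `requires` entry must be a pair c(prerequisite, event)",
              class = "vesimlab_constraint_error")
      }
      as.character(p)
    }))
  } else {
    matrix(character(), ncol = 2)
  }
  colnames(req) <- c("prerequisite", "event")
  chain <- structure(
    list(events = as.character(events), requires = req),
    class = "event_chain"
  )
  validate_event_chain(chain)
  chain
}

#' Validate an event chain
#'
#' Checks label uniqueness, that every precedence pair references known
#' events, and that the `requires` relation is acyclic.
#'
#' @param chain An [event_chain()].
#' @return The chain, invisibly, if valid; otherwise an error of class
#'   `vesimlab_constraint_error`.
#' @export
validate_event_chain <- function(chain) {
  ev <- chain$events
  if (anyDuplicated(ev)) {
    abort("event labels must be unique", class = "vesimlab_constraint_error")
  }
  req <- chain$requires
  if (nrow(req) && !all(req %in% ev)) {
    bad <- setdiff(unique(as.vector(req)), ev)
    abort(paste0("`requires` references unknown events: ",
                 paste(bad, collapse = ", ")),
          class = "vesimlab_constraint_error")
  }
  # cycle check: repeatedly peel events with no remaining prerequisites
  remaining <- ev
  edges <- req
  repeat {
    if (!length(remaining)) break
    has_prereq <- remaining %in% edges[, "event"]
    if (all(has_prereq)) {
      abort("`requires` relation is cyclic",
            class = "vesimlab_constraint_error")
    }
    removable <- remaining[!has_prereq]
    remaining <- setdiff(remaining, removable)
    edges <- edges[!(edges[, "prerequisite"] %in% removable), , drop = FALSE]
  }
  invisible(chain)
}

#' @export
print.event_chain <- function(x, ...) {
  cat("<event_chain> ", paste(x$events, collapse = " -> "), "\n", sep = "")
  if (nrow(x$requires)) {
    cat("requires:",
        paste(x$requires[, "event"], "<=", x$requires[, "prerequisite"],
              collapse = ", "), "\n")
  } else {
    cat("requires: (none)\n")
  }
  invisible(x)
}

#' Test outcome vectors for feasibility under a chain's precedence relation
#'
#' A binary outcome vector is feasible when, for every precedence pair
#' `(a, b)` of the chain, event `b` occurring implies event `a` occurred.
#'
#' @param v A numeric/integer 0-1 vector with one entry per chain event (in
#'   chain order), or a data frame / matrix of such rows.
#' @param chain An [event_chain()].
#' @return A logical, one value per outcome vector supplied.
#' @examples
#' is_feasible(c(0, 0, 0, 0, 0, 0), event_chain())
#' is_feasible(c(0, 0, 0, 0, 0, 1), event_chain())
#' @export
is_feasible <- function(v, chain) {
  m <- if (is.data.frame(v)) {
    as.matrix(v[, chain$events, drop = FALSE])
  } else if (is.matrix(v)) {
    v
  } else {
    matrix(v, nrow = 1)
  }
  if (ncol(m) != length(chain$events)) {
    abort(sprintf("outcome vector has %d entries but the chain has %d events",
                  ncol(m), length(chain$events)),
          class = "vesimlab_shape_error")
  }
  ok <- rep(TRUE, nrow(m))
  req <- chain$requires
  if (nrow(req)) {
    ia <- match(req[, "prerequisite"], chain$events)
    ib <- match(req[, "event"], chain$events)
    for (k in seq_len(nrow(req))) {
      ok <- ok & (m[, ib[k]] == 0 | m[, ia[k]] == 1)
    }
  }
  ok
}

#' Enumerate all feasible outcome vectors of an event chain
#'
#' Constructs, by depth-first assignment in chain order (pruning branches as
#' soon as a precedence pair is violated), every binary outcome vector that
#' satisfies the chain's precedence relation. With no constraints an n-event
#' chain has 2^n feasible vectors; a strict linear chain has n + 1 (the
#' prefix-of-ones patterns); any intermediate relation gives a count in
#' between.
#'
#' @param chain An [event_chain()].
#' @return A tibble with one 0/1 integer column per event and one row per
#'   feasible vector, in lexicographic order (first event most significant).
#' @examples
#' nrow(enumerate_feasible(event_chain(letters[1:6], requires = list()))) # 64
#' @export
enumerate_feasible <- function(chain) {
  validate_event_chain(chain)
  ev <- chain$events
  n <- length(ev)
  req <- chain$requires
  # prerequisites indices per event position
  prereq <- lapply(seq_len(n), function(i) {
    match(req[req[, "event"] == ev[i], "prerequisite"], ev)
  })
  acc <- vector("list", 0)
  walk <- function(prefix) {
    i <- length(prefix) + 1L
    if (i > n) {
      acc[[length(acc) + 1L]] <<- prefix
      return(invisible())
    }
    walk(c(prefix, 0L))
    # assign 1 only when every already-assigned prerequisite is 1;
    # forward-pointing prerequisites (unusual) are handled by the post-filter
    if (all(prefix[prereq[[i]][prereq[[i]] < i]] == 1L)) {
      walk(c(prefix, 1L))
    }
  }
  walk(integer(0))
  m <- do.call(rbind, acc)
  colnames(m) <- ev
  # post-filter covers precedence pairs that point forward in chain order
  m <- m[is_feasible(m, chain), , drop = FALSE]
  tibble::as_tibble(m)
}

#' Read or write an event chain as JSON
#'
#' The on-disk form is `{"events": [...], "requires": [["I","S"], ...]}`.
#'
#' @param chain An [event_chain()].
#' @param path File path.
#' @return `read_event_chain()` returns an [event_chain()];
#'   `write_event_chain()` returns `path` invisibly.
#' @export
write_event_chain <- function(chain, path) {
  req <- lapply(seq_len(nrow(chain$requires)),
                function(i) unname(chain$requires[i, ]))
  jsonlite::write_json(list(events = chain$events, requires = req), path,
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_event_chain
#' @export
read_event_chain <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  event_chain(
    events = vapply(x$events, as.character, character(1)),
    requires = lapply(x$requires, function(p) {
      vapply(p, as.character, character(1))
    })
  )
}
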