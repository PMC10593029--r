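#' Convert between marginal, composite and conditional vaccine effectiveness
#'
#' Vaccine effectiveness (VE) is one minus a risk ratio. Writing `VE_S` for
#' effectiveness against symptomatic infection and `VE_SH` for effectiveness
#' against hospitalization (unconditional on symptoms), the effectiveness
#' against hospitalization *among the symptomatically infected* is
#'
#' \deqn{VE_{H|S} = 1 - \frac{1 - VE_{SH}}{1 - VE_S}}
#'
#' `ve_conditional()` evaluates this conversion; `ve_compose()` inverts it,
#' recovering `VE_SH = 1 - (1 - VE_S)(1 - VE_{H|S})`. The two are exact
#' inverses whenever `ve_s < 1`. Because `VE_H|S` is a ratio of two
#' quantities that may wane at different rates, it need not itself wane:
#' it can increase with time since vaccination even while both inputs
#' decrease.
#'
#' All values are proportions in `(-Inf, 1]`; negative values represent harm.
#' Percent formatting belongs to the reporting layer (see
#' [format_percent()]).
#'
#' @param ve_s VE against symptomatic infection; must be `< 1` for
#'   `ve_conditional()` (at `ve_s = 1` no vaccinated case ever occurs and
#'   the conditional quotient is undefined).
#' @param ve_sh VE against hospitalization, unconditional on symptoms
#'   (`<= 1`).
#' @param ve_h_given_s VE against hospitalization among the symptomatic
#'   (`<= 1`).
#' @return A numeric proportion, vectorized over its inputs.
#' @examples
#' ve_conditional(0.90, 0.97) # 0.70
#' ve_compose(0.90, 0.70)     # 0.97
#' @export
ve_conditional <- function(ve_s, ve_sh) {
  check_ve(ve_sh, "ve_sh")
  check_ve(ve_s, "ve_s")
  if (any(ve_s == 1)) {
    abort("ve_conditional() is undefined at ve_s = 1 (no vaccinated cases occur, so the conditional risk ratio has no denominator)",
          class = "vesimlab_domain_error")
  }
  1 - (1 - ve_sh) / (1 - ve_s)
}

#' @rdname ve_conditional
#' @export
ve_compose <- function(ve_s, ve_h_given_s) {
  check_ve(ve_s, "ve_s")
  check_ve(ve_h_given_s, "ve_h_given_s")
  1 - (1 - ve_s) * (1 - ve_h_given_s)
}

check_ve <- function(x, name) {
  if (any(!is.finite(x)) || any(x > 1)) {
    abort(sprintf("`%s` must be a finite proportion <= 1", name),
          class = "vesimlab_domain_error")
  }
  invisible(x)
}

#' Compose the symptomatic case-fatality ratio from pyramid levels
#'
#' Under the severity-pyramid decomposition the symptomatic case-fatality
#' ratio is the product of per-level conditional risks,
#' `sCFR = r_D|H * r_H|S` (probability of death given hospitalization times
#' probability of hospitalization given symptomatic infection). The product
#' equals `Pr(death | symptomatic)` only when every death passes through
#' hospitalization, so the operation takes the event chain and refuses when
#' the chain permits death without hospitalization.
#'
#' @param r_d_given_h Probability of death given hospitalization, in `[0,1]`.
#' @param r_h_given_s Probability of hospitalization given symptomatic
#'   infection, in `[0,1]`.
#' @param chain An [event_chain()] containing events `H` and `M`; used to
#'   verify that death requires hospitalization. The default chain does.
#' @return The composed sCFR, a proportion.
#' @examples
#' scfr_compose(0.15, 0.10)
#' @export
scfr_compose <- function(r_d_given_h, r_h_given_s, chain = event_chain()) {
  stopifnot(all(r_d_given_h >= 0 & r_d_given_h <= 1),
            all(r_h_given_s >= 0 & r_h_given_s <= 1))
  req <- chain$requires
  death_req <- req[req[, "event"] == "M", "prerequisite"]
  # H must be a (possibly transitive) prerequisite of M
  anc <- death_req
  repeat {
    more <- req[req[, "event"] %in% anc, "prerequisite"]
    new_anc <- union(anc, more)
    if (setequal(new_anc, anc)) break
    anc <- new_anc
  }
  if (!"H" %in% anc) {
    abort("the chain permits death without hospitalization, so r_D|H * r_H|S is not the sCFR",
          class = "vesimlab_decomposition_error")
  }
  r_d_given_h * r_h_given_s
}

#' Tabulate conditional VE across waning strata
#'
#' Takes a data frame of VE profiles, one row per time-since-vaccination
#' stratum, and fills in the conditional effectiveness against
#' hospitalization among the symptomatic via [ve_conditional()]. Input row
#' order is preserved so non-monotone trends across strata remain visible:
#' when protection against infection wanes faster than protection against
#' hospitalization, the conditional measure *increases* with time since
#' vaccination.
#'
#' @param profiles A data frame with columns `stratum_label`, `ve_s`,
#'   `ve_sh` (proportions; `ve_s < 1`).
#' @return A tibble of class `ve_waning_tbl` with columns `stratum_label`,
#'   `ve_s`, `ve_h_given_s`, `ve_sh`, in input order.
#' @examples
#' ve_waning_table(data.frame(
#'   stratum_label = c("Recent", "Longer ago"),
#'   ve_s = c(0.90, 0.65), ve_sh = c(0.97, 0.80)
#' ))
#' @export
ve_waning_table <- function(profiles) {
  stopifnot(is.data.frame(profiles),
            all(c("stratum_label", "ve_s", "ve_sh") %in% names(profiles)))
  out <- tibble::as_tibble(profiles) |>
    dplyr::mutate(ve_h_given_s = ve_conditional(.data$ve_s, .data$ve_sh)) |>
    dplyr::select(dplyr::any_of(c("example", "stratum_label")),
                  "ve_s", "ve_h_given_s", "ve_sh")
  class(out) <- c("ve_waning_tbl", class(out))
  out
}

#' Format a proportion as a nearest-integer percent, rounding half up
#'
#' Reporting layer for VE tables: `0.42857 -> "43%"`, `0.705 -> "71%"`.
#' Round-half-up (not banker's rounding) so that printed tables match the
#' usual epidemiologic reporting convention.
#'
#' @param x Numeric proportions.
#' @param digits Decimal places of the percent (default 0).
#' @return Character vector like `"70%"`.
#' @export
format_percent <- function(x, digits = 0) {
  p <- round_half_up(100 * x, digits)
  paste0(formatC(p, format = "f", digits = digits), "%")
}

#' @rdname format_percent
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5 + 1e-12) / scale
}
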