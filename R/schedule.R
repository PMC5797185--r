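# Reinforcement schedules: fixed ratio (FR) and progressive ratio (PR).

#' Fixed-ratio reinforcement schedule
#'
#' Under a fixed-ratio schedule FRn, every `n` counted active-well responses
#' earn one reinforcement. FR1 delivers a reward for every active poke; FR5
#' requires five.
#'
#' @param n Positive integer, the response requirement per reinforcement.
#' @return An object of class `schedule_spec`.
#' @seealso [pr_schedule()], [requirement_for()]
#' @examples
#' requirement_for(fr_schedule(5), 0:3)  # always 5
#' @export
fr_schedule <- function(n = 1L) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("fixed ratio `n` must be a single integer >= 1", call. = FALSE)
  structure(list(kind = "FR", fixed_ratio = n), class = "schedule_spec")
}

#' Progressive-ratio reinforcement schedule
#'
#' Under a progressive-ratio schedule the response requirement grows
#' exponentially with each reinforcement earned:
#' \deqn{R_N = \mathrm{round}(s\, e^{N r} - s), \quad N = \text{rewards earned} + 1,}
#' clamped below at 1, where `s` is `scale` and `r` is `rate`. With the
#' default constants (`scale = 5`, `rate = 0.2`) the requirement series is
#' 1, 2, 4, 6, 9, 12, 15, 20, 25, 32, ... Rounding is to the nearest
#' integer, half away from zero.
#'
#' @param scale Positive real, the scale constant `s` (default 5).
#' @param rate Positive real, the exponential growth rate `r` (default 0.2).
#' @return An object of class `schedule_spec`.
#' @seealso [fr_schedule()], [requirement_for()], [pr_sequence()]
#' @examples
#' pr_sequence(pr_schedule(), 6)  # 1 2 4 6 9 12
#' @export
pr_schedule <- function(scale = 5, rate = 0.2) {
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0)
    stop("`scale` must be a single positive number", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= 0)
    stop("`rate` must be a single positive number", call. = FALSE)
  structure(list(kind = "PR", pr_scale = as.numeric(scale),
                 pr_rate = as.numeric(rate)),
            class = "schedule_spec")
}

#' @export
print.schedule_spec <- function(x, ...) {
  if (x$kind == "FR") {
    cat(sprintf("<fixed-ratio schedule FR%d>\n", x$fixed_ratio))
  } else {
    cat(sprintf("<progressive-ratio schedule: round(%g * exp(N * %g) - %g)>\n",
                x$pr_scale, x$pr_rate, x$pr_scale))
  }
  invisible(x)
}

is_schedule <- function(x) inherits(x, "schedule_spec")

# round half away from zero (for positive arguments this is floor(x + 0.5));
# base round() rounds half to even, which would be wrong for requirement
# values landing exactly on .5 under nonstandard constants
round_half_up <- function(x) floor(x + 0.5)

#' Response requirement for the next reinforcement
#'
#' Computes how many counted active-well responses are required to earn the
#' next reinforcement, given how many have been earned so far. For a
#' fixed-ratio schedule this is constant; for a progressive-ratio schedule it
#' follows the exponential requirement formula (see [pr_schedule()]) with
#' `N = rewards_earned + 1`, rounded to the nearest integer and clamped to a
#' minimum of 1.
#'
#' @param spec A `schedule_spec` from [fr_schedule()] or [pr_schedule()].
#' @param rewards_earned Non-negative integer (vectorised): reinforcements
#'   already earned in the session.
#' @return Integer vector of response requirements, each >= 1.
#' @examples
#' requirement_for(pr_schedule(), 0:5)  # 1 2 4 6 9 12
#' @export
requirement_for <- function(spec, rewards_earned) {
  stopifnot(is_schedule(spec))
  if (length(rewards_earned) == 0L) return(integer(0))
  if (any(is.na(rewards_earned)) || any(rewards_earned < 0))
    stop("`rewards_earned` must be non-negative", call. = FALSE)
  if (spec$kind == "FR")
    return(rep.int(spec$fixed_ratio, length(rewards_earned)))
  n_next <- rewards_earned + 1
  req <- round_half_up(spec$pr_scale * exp(n_next * spec$pr_rate) - spec$pr_scale)
  as.integer(pmax(req, 1))
}

#' Progressive-ratio requirement series
#'
#' The first `k` response requirements of a schedule, i.e. the number of
#' counted active pokes needed for reinforcement 1, 2, ..., `k`.
#'
#' @inheritParams requirement_for
#' @param k Positive integer, the number of reinforcements.
#' @return Integer vector of length `k`; non-decreasing for progressive-ratio
#'   schedules.
#' @examples
#' pr_sequence(pr_schedule(), 10)
#' @export
pr_sequence <- function(spec, k) {
  stopifnot(is_schedule(spec))
  if (length(k) != 1L || is.na(k) || k < 1)
    stop("`k` must be a single integer >= 1", call. = FALSE)
  requirement_for(spec, seq_len(k) - 1L)
}

#' Cumulative pokes needed for k reinforcements
#'
#' Total counted active-well responses required to earn the first `k`
#' reinforcements: the running sum of the requirement series. Useful for
#' feasibility checks (e.g. whether a given poke throughput can reach a
#' target breakpoint within a session).
#'
#' @inheritParams pr_sequence
#' @return Integer scalar, strictly increasing in `k`.
#' @examples
#' cumulative_pokes(pr_schedule(), 6)   # 34 = 1+2+4+6+9+12
#' cumulative_pokes(fr_schedule(5), 3)  # 15
#' @export
cumulative_pokes <- function(spec, k) {
  sum(pr_sequence(spec, k))
}

# Build a schedule from a plain list, e.g. parsed YAML:
#   {kind: FR, n: 5}  or  {kind: PR, scale: 5, rate: 0.2}
#' Coerce a configuration list to a schedule
#'
#' Accepts the configuration-file representation of a schedule, either
#' `list(kind = "FR", n = 5)` or `list(kind = "PR", scale = 5, rate = 0.2)`
#' (scale/rate optional, defaulting to the standard constants).
#'
#' @param x A `schedule_spec` (returned unchanged) or a named list.
#' @return A `schedule_spec`.
#' @export
as_schedule <- function(x) {
  if (is_schedule(x)) return(x)
  if (!is.list(x) || is.null(x$kind))
    stop("cannot interpret `x` as a schedule; need a list with a `kind` field",
         call. = FALSE)
  kind <- toupper(as.character(x$kind))
  if (kind %in% c("FR", "FIXED_RATIO")) {
    # a bare `n:` key in YAML 1.1 parses as the boolean FALSE, so accept
    # that spelling of the key as well
    n <- x$n
    if (is.null(n)) n <- x$fixed_ratio
    if (is.null(n)) n <- x[["FALSE"]]
    fr_schedule(n)
  } else if (kind %in% c("PR", "PROGRESSIVE_RATIO")) {
    pr_schedule(scale = if (!is.null(x$scale)) x$scale else 5,
                rate  = if (!is.null(x$rate)) x$rate else 0.2)
  } else {
    stop(sprintf("unknown schedule kind '%s' (expected FR or PR)", kind),
         call. = FALSE)
  }
}
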