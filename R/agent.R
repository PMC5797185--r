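# Virtual-mouse behavioral parameters and their between-mouse distributions.

AGENT_PARAM_NAMES <- c("poke_rate_hz", "p_active_floor", "p_active_ceiling",
                       "learning_midpoint_day", "learning_slope_days",
                       "persistence", "disengaged_rate_hz",
                       "disengaged_p_active")

# which parameters are probabilities (logit-normal between-mouse variation)
# vs positive reals (lognormal)
AGENT_PROB_PARAMS <- c("p_active_floor", "p_active_ceiling",
                       "disengaged_p_active")

#' Behavioral parameters of one virtual mouse
#'
#' The agent model has three mechanisms, each carrying one or two
#' parameters:
#' \describe{
#'   \item{Poking}{While engaged, inter-poke intervals are exponential with
#'     rate `poke_rate_hz` (a Poisson poke process).}
#'   \item{Learning}{Each poke targets the active well with probability
#'     `p_active(day) = floor + (ceiling - floor) *
#'     plogis((day - midpoint) / slope)` — a logistic acquisition curve from
#'     chance-level discrimination (`p_active_floor`, default 0.5) to an
#'     asymptote (`p_active_ceiling`), centred on `learning_midpoint_day`
#'     with time-scale `learning_slope_days`.}
#'   \item{Motivation}{In progressive-ratio sessions only, immediately after
#'     earning reward `k` the agent stays engaged with probability
#'     `exp(-r / persistence)` where `r` is the upcoming response
#'     requirement; otherwise it permanently disengages for the session and
#'     thereafter pokes at `disengaged_rate_hz` with active-well probability
#'     `disengaged_p_active`. `persistence` is an effort scale in units of
#'     pokes: the requirement at which the per-reward survival probability
#'     drops to 1/e.}
#' }
#'
#' @param poke_rate_hz Positive real; engaged poke rate (Hz).
#' @param p_active_floor,p_active_ceiling Probabilities, floor <= ceiling.
#' @param learning_midpoint_day,learning_slope_days Positive reals (days).
#' @param persistence Positive real (pokes); use `Inf` for an agent that
#'   never disengages.
#' @param disengaged_rate_hz Non-negative real (Hz).
#' @param disengaged_p_active Probability.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(poke_rate_hz, p_active_floor = 0.5, p_active_ceiling,
                         learning_midpoint_day, learning_slope_days,
                         persistence, disengaged_rate_hz = 0.01,
                         disengaged_p_active = 0.5) {
  probs <- c(p_active_floor, p_active_ceiling, disengaged_p_active)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (p_active_floor > p_active_ceiling)
    stop("`p_active_floor` must not exceed `p_active_ceiling`", call. = FALSE)
  if (poke_rate_hz <= 0 || learning_midpoint_day <= 0 ||
      learning_slope_days <= 0 || persistence <= 0)
    stop("rates, time-scales and persistence must be positive", call. = FALSE)
  if (disengaged_rate_hz < 0)
    stop("`disengaged_rate_hz` must be non-negative", call. = FALSE)
  structure(list(poke_rate_hz = poke_rate_hz,
                 p_active_floor = p_active_floor,
                 p_active_ceiling = p_active_ceiling,
                 learning_midpoint_day = learning_midpoint_day,
                 learning_slope_days = learning_slope_days,
                 persistence = persistence,
                 disengaged_rate_hz = disengaged_rate_hz,
                 disengaged_p_active = disengaged_p_active),
            class = "agent_params")
}

#' Active-well probability on a given day
#'
#' The logistic learning curve of the agent model (see [agent_params()]).
#'
#' @param agent An `agent_params`.
#' @param day Positive numeric (vectorised); the global session-day counter,
#'   accumulating across phases.
#' @return Probability vector.
#' @export
p_active_on_day <- function(agent, day) {
  agent$p_active_floor + (agent$p_active_ceiling - agent$p_active_floor) *
    stats::plogis((day - agent$learning_midpoint_day) / agent$learning_slope_days)
}

#' Between-mouse distribution of agent parameters for one genotype
#'
#' Each behavioral parameter varies between mice: positive parameters are
#' lognormal (parameterised by their mean and the log-scale SD `dispersion`),
#' probabilities are logit-normal (location at `qlogis(mean)`, SD
#' `dispersion` on the logit scale). A dispersion of 0 fixes the parameter
#' at its mean.
#'
#' @param label Genotype label, e.g. `"wild-type"`.
#' @param means Named list/vector of parameter means (all of
#'   [agent_params()]'s arguments).
#' @param dispersions Named list/vector of non-negative dispersions; missing
#'   names default to 0.
#' @return An object of class `genotype_profile`.
#' @seealso [default_profiles()], [sample_agent()]
#' @export
genotype_profile <- function(label, means, dispersions = list()) {
  means <- as.list(means)
  dispersions <- as.list(dispersions)
  missing <- setdiff(AGENT_PARAM_NAMES, names(means))
  if (length(missing))
    stop("missing parameter means: ", paste(missing, collapse = ", "),
         call. = FALSE)
  disp <- stats::setNames(rep(0, length(AGENT_PARAM_NAMES)), AGENT_PARAM_NAMES)
  disp[names(dispersions)] <- unlist(dispersions)
  if (any(disp < 0))
    stop("dispersions must be non-negative", call. = FALSE)
  structure(list(label = label,
                 means = means[AGENT_PARAM_NAMES],
                 dispersions = as.list(disp)),
            class = "genotype_profile")
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat(sprintf("<genotype_profile '%s'>\n", x$label))
  for (p in AGENT_PARAM_NAMES)
    cat(sprintf("  %-22s mean %-8.4g dispersion %.3g\n",
                p, x$means[[p]], x$dispersions[[p]]))
  invisible(x)
}

#' Draw one virtual mouse from a genotype profile
#'
#' One draw per parameter from the profile's between-mouse distributions
#' (lognormal for positive parameters, logit-normal for probabilities),
#' using the current RNG state. With all dispersions zero the draw equals
#' the profile means exactly.
#'
#' @param profile A [genotype_profile()].
#' @return An [agent_params()] object.
#' @export
sample_agent <- function(profile) {
  stopifnot(inherits(profile, "genotype_profile"))
  draw <- function(name) {
    m <- profile$means[[name]]
    s <- profile$dispersions[[name]]
    if (s == 0) return(m)
    if (name %in% AGENT_PROB_PARAMS) {
      stats::plogis(stats::rnorm(1, stats::qlogis(m), s))
    } else {
      if (m == 0) return(0)
      if (!is.finite(m)) return(m)
      # meanlog chosen so the distribution mean equals m
      stats::rlnorm(1, meanlog = log(m) - s^2 / 2, sdlog = s)
    }
  }
  vals <- lapply(AGENT_PARAM_NAMES, draw)
  names(vals) <- AGENT_PARAM_NAMES
  do.call(agent_params, vals)
}

#' Frozen default genotype profiles
#'
#' The package's calibrated defaults for a two-genotype motivation study:
#' a wild-type profile and a mutant profile that differs only in
#' `persistence` (a motivation-specific deficit; learning and throughput
#' parameters are shared). The calibration reproduces, under the default
#' protocol, FR1 acquisition in roughly 7.5 +/- 2.4 days with ~5% of mice
#' excluded, ~273 total pokes per 60-minute FR5 session, and a 35-45%
#' reduction in the mutant's stabilized progressive-ratio breakpoint with a
#' large (d > 1.5) effect size. See the package vignette for how these
#' values were chosen.
#'
#' @param wt_label,mut_label Genotype labels used in logs and reports.
#' @return A list of two [genotype_profile()]s, named `wt` and `mut`.
#' @export
default_profiles <- function(wt_label = "wild-type", mut_label = "mutant") {
  means <- list(poke_rate_hz = 0.0759,
                p_active_floor = 0.5,
                p_active_ceiling = 0.88,
                learning_midpoint_day = 4.25,
                learning_slope_days = 1.0,
                persistence = 170,
                disengaged_rate_hz = 0.01,
                disengaged_p_active = 0.5)
  dispersions <- list(poke_rate_hz = 0.15,
                      p_active_ceiling = 0.45,
                      learning_midpoint_day = 0.45,
                      learning_slope_days = 0.20,
                      persistence = 0.55)
  wt <- genotype_profile(wt_label, means, dispersions)
  mut_means <- means
  mut_means$persistence <- 34
  mut <- genotype_profile(mut_label, mut_means, dispersions)
  list(wt = wt, mut = mut)
}
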