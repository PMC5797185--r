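# YAML experiment configuration.

config_to_session <- function(x) {
  if (is.null(x)) return(NULL)
  session_config(schedule = as_schedule(x$schedule),
                 max_duration_s = x$max_duration_s %||% 3600,
                 max_rewards = x$max_rewards %||% Inf,
                 timeout_s = x$timeout_s %||% 1,
                 reward_volume_ul = x$reward_volume_ul %||% 10,
                 sucrose_pct = x$sucrose_pct %||% 20)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an experiment configuration from YAML
#'
#' Builds a [cohort_spec()] from a YAML file of the form:
#' \preformatted{
#' seed: 1
#' n_per_genotype: [12, 12]
#' profiles:
#'   - label: wild-type
#'     means: {poke_rate_hz: 0.0759, p_active_floor: 0.5, ...}
#'     dispersions: {poke_rate_hz: 0.15, ...}
#'   - label: mutant
#'     ...
#' protocol:
#'   fr1: {schedule: {kind: FR, n: 1}, max_rewards: 50}
#'   fr5: {schedule: {kind: FR, n: 5}}
#'   pr:  {schedule: {kind: PR, scale: 5, rate: 0.2}}
#'   criteria: {fr1_ratio_min: 3, fr1_rewards_min: 20, ...}
#'   pr_max_days: 30
#' }
#' Omitted fields take the package defaults; omitted `profiles` use
#' [default_profiles()].
#'
#' @param path Path to a YAML file.
#' @return A [cohort_spec()].
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  profiles <- if (is.null(x$profiles)) default_profiles() else
    lapply(x$profiles, function(p)
      genotype_profile(p$label, p$means, p$dispersions %||% list()))
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, `[[`, character(1), "label")
  proto <- x$protocol
  crit_args <- proto$criteria %||% list()
  protocol <- protocol_config(
    fr1 = config_to_session(proto$fr1) %||%
      session_config(fr_schedule(1), max_rewards = 50),
    fr5 = config_to_session(proto$fr5) %||% session_config(fr_schedule(5)),
    pr = config_to_session(proto$pr) %||% session_config(pr_schedule()),
    criteria = do.call(criteria_config, crit_args),
    pr_max_days = proto$pr_max_days %||% 30)
  cohort_spec(n_per_genotype = x$n_per_genotype %||% 12,
              profiles = profiles, protocol = protocol,
              seed = x$seed %||% 1L)
}
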