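# round half away from zero; base::round() rounds half to even, which would
# bias discretized Likert scores at the .5 boundary
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

default_authority_profile <- function() {
  list(
    theory = c(large = 0.5, medium = 0.4, small = 0.1),
    practice = c(large = 0.5, medium = 0.4, small = 0.1),
    reference = c(large = 0.3, medium = 0.5, small = 0.2),
    intuition = c(large = 0.2, medium = 0.5, small = 0.3),
    familiarity = c(0, 0.05, 0.25, 0.40, 0.30)  # Likert 1..5
  )
}

#' Configuration of the synthetic expert panel generator
#'
#' The generator emulates a 15-expert consultation on a 5-point importance
#' scale: each indicator has a latent importance `mu` (score units,
#' typically 3.5-5.0), every expert's score is `mu` plus homoscedastic
#' normal noise, rounded half-away-from-zero and clamped to 1..5.
#' "Not necessary" votes occur with probability `p_not_necessary` only for
#' indicators with `mu` below 3.5 (experts do not flag indicators they
#' consider important). Authority survey answers are drawn from
#' `authority_profile`, a list of category probabilities per judgment
#' dimension plus familiarity.
#'
#' @param mu named numeric vector of latent importances; defaults to the
#'   packaged framework's per-indicator panel means.
#' @param n_experts panel size (default 15, the consultation size the
#'   generator emulates).
#' @param sigma expert noise SD in score units; the default 0.5 matches the
#'   middle of the packaged framework's per-indicator score SDs (0.0-0.8).
#' @param round2_shrink multiplicative factor on `sigma` in round 2,
#'   modeling between-round convergence of opinions (default 0.5).
#' @param p_not_necessary per-expert, per-indicator vote probability for
#'   low-`mu` indicators.
#' @param authority_profile category-probability list shaped like
#'   `default_authority_profile()`.
#' @param seed master seed; per-round substreams are derived from it so a
#'   round regenerates identically on its own.
#' @return list of class `panel_sim_config`.
#' @export
panel_sim_config <- function(mu = NULL, n_experts = 15L, sigma = 0.5,
                             round2_shrink = 0.5, p_not_necessary = 0.2,
                             authority_profile = default_authority_profile(),
                             seed = 1L) {
  if (is.null(mu)) {
    panel <- packaged_panel()
    mu <- stats::setNames(colMeans(panel$scores), panel$indicator_ids)
  }
  stopifnot(is.numeric(mu), !is.null(names(mu)), all(is.finite(mu)),
            n_experts >= 1, sigma >= 0,
            round2_shrink >= 0, round2_shrink <= 1,
            p_not_necessary >= 0, p_not_necessary <= 1)
  structure(list(mu = mu, n_experts = as.integer(n_experts), sigma = sigma,
                 round2_shrink = round2_shrink,
                 p_not_necessary = p_not_necessary,
                 authority_profile = authority_profile,
                 seed = as.integer(seed)),
            class = "panel_sim_config")
}

# deterministic per-round substream seed, kept inside 32-bit range
round_seed <- function(seed, round) {
  (as.double(seed) * 48271 + round * 104729) %% 2147483647
}

#' Simulate one Delphi round's score panel
#'
#' score(e, i) = clamp(round(mu_i + eps), 1, 5) with eps ~ N(0, sigma);
#' round 2 uses sigma * round2_shrink. Identical seeds give identical
#' panels.
#'
#' @param config a [panel_sim_config()].
#' @param round round number (1 or 2; round 2 shrinks the noise).
#' @return a `score_panel` with necessity votes and authority answers.
#' @export
simulate_panel <- function(config, round = 1L) {
  stopifnot(inherits(config, "panel_sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(round_seed(config$seed, round))
  m <- config$n_experts
  n <- length(config$mu)
  sigma <- config$sigma * if (round >= 2) config$round2_shrink else 1
  eps <- matrix(rnorm(m * n, 0, sigma), m, n)
  scores <- pmin(pmax(round_half_away(sweep(eps, 2, config$mu, "+")), 1), 5)
  colnames(scores) <- names(config$mu)
  rownames(scores) <- paste0("E", seq_len(m))
  low <- config$mu < 3.5
  votes <- matrix(runif(m * n) < config$p_not_necessary, m, n)
  votes <- sweep(votes, 2, low, "&")
  prof <- config$authority_profile
  draw <- function(p) sample(names(p), m, replace = TRUE, prob = p)
  judgment <- data.frame(theory = draw(prof$theory),
                         practice = draw(prof$practice),
                         reference = draw(prof$reference),
                         intuition = draw(prof$intuition),
                         stringsAsFactors = FALSE)
  familiarity <- sample(seq_along(prof$familiarity), m, replace = TRUE,
                        prob = prof$familiarity)
  score_panel(scores, necessity = votes, judgment = judgment,
              familiarity = familiarity, round_id = round)
}

#' Simulate a two-round Delphi study
#'
#' Round 2 replays the same latent importances with noise shrunk by
#' `round2_shrink`, so concordance W is expected to rise between rounds
#' (and equals the round-1 distribution when the shrink factor is 1).
#'
#' @param config a [panel_sim_config()].
#' @return list with elements `round1` and `round2`, both `score_panel`s.
#' @export
simulate_study <- function(config) {
  list(round1 = simulate_panel(config, round = 1L),
       round2 = simulate_panel(config, round = 2L))
}

#' Packaged reconstructed score panel
#'
#' A synthetic 15-expert score panel whose per-indicator score multisets
#' reproduce the packaged framework's published round-2 mean, population
#' SD and CV for all 31 indicators. The raw panels behind the published
#' table are not public, so the assignment of scores to individual experts
#' is arbitrary; only the per-indicator score multisets are meaningful.
#'
#' @param authority include the synthetic authority survey companion file.
#' @return a `score_panel`.
#' @export
packaged_panel <- function(authority = TRUE) {
  read_score_panel(
    system.file("extdata", "score_panel_synthetic.csv",
                package = "delphiAHP", mustWork = TRUE),
    authority_path = if (authority)
      system.file("extdata", "authority_synthetic.csv",
                  package = "delphiAHP", mustWork = TRUE),
    round_id = 2L)
}
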