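#' @importFrom stats pchisq rnorm runif
NULL

GRADE_LEVELS <- c("large", "medium", "small")

# judgment-basis score tables: theory and practice vary by grade, the
# reference-material and intuition dimensions contribute 0.1 regardless
CA_TABLE <- list(
  theory = c(large = 0.3, medium = 0.2, small = 0.1),
  practice = c(large = 0.5, medium = 0.4, small = 0.3),
  reference = c(large = 0.1, medium = 0.1, small = 0.1),
  intuition = c(large = 0.1, medium = 0.1, small = 0.1)
)

FAMILIARITY_VALUES <- c("very unfamiliar" = 0.2, "unfamiliar" = 0.4,
                        "neutral" = 0.6, "familiar" = 0.8,
                        "very familiar" = 1.0)

#' Construct a Delphi score panel
#'
#' One consultation round's raw data: a matrix of integer importance scores
#' (5-point Likert, 1 = very unimportant .. 5 = very important), experts in
#' rows and indicators in columns, plus optional "not necessary" votes and
#' the expert-authority survey answers.
#'
#' @param scores integer matrix, experts x indicators, entries in 1..5;
#'   needs column names (indicator ids); row names default to `E1..Em`.
#' @param necessity optional logical/0-1 matrix of the same shape; `TRUE`
#'   means the expert voted the indicator "not necessary".
#' @param judgment optional data frame of judgment-basis grades, one row per
#'   expert with columns `theory`, `practice`, `reference`, `intuition`,
#'   each in `c("large", "medium", "small")`.
#' @param familiarity optional per-expert familiarity, either labels
#'   (`"very unfamiliar"` .. `"very familiar"`) or Likert integers 1..5.
#' @param round_id integer round identifier.
#' @return An object of class `score_panel`.
#' @export
score_panel <- function(scores, necessity = NULL, judgment = NULL,
                        familiarity = NULL, round_id = 1L) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) stop("score matrix needs indicator ids as column names")
  if (is.null(rownames(scores)) && nrow(scores)) {
    rownames(scores) <- paste0("E", seq_len(nrow(scores)))
  }
  storage.mode(scores) <- "double"
  bad <- which(!is.finite(scores) | scores != round(scores) | scores < 1 | scores > 5)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(scores))
    stop(sprintf("score for expert '%s', indicator '%s' is not an integer in 1..5",
                 rownames(scores)[rc[1]], colnames(scores)[rc[2]]))
  }
  if (!is.null(necessity)) {
    necessity <- as.matrix(necessity)
    storage.mode(necessity) <- "logical"
    if (!identical(dim(necessity), dim(scores))) {
      stop("necessity-vote matrix must match the score matrix dimensions")
    }
    dimnames(necessity) <- dimnames(scores)
  }
  if (!is.null(judgment)) {
    judgment <- as.data.frame(judgment)
    need <- c("theory", "practice", "reference", "intuition")
    if (!all(need %in% names(judgment))) {
      stop("judgment grades need columns theory, practice, reference, intuition")
    }
    if (nrow(judgment) != nrow(scores)) stop("one judgment-grade row per expert required")
    for (d in need) {
      if (any(!judgment[[d]] %in% GRADE_LEVELS)) {
        stop(sprintf("judgment grade for dimension '%s' must be large/medium/small", d))
      }
    }
  }
  if (!is.null(familiarity)) {
    familiarity <- as_familiarity(familiarity)
    if (length(familiarity) != nrow(scores)) stop("one familiarity value per expert required")
  }
  structure(list(round_id = as.integer(round_id),
                 expert_ids = rownames(scores),
                 indicator_ids = colnames(scores),
                 scores = scores, necessity = necessity,
                 judgment = judgment, familiarity = familiarity),
            class = "score_panel")
}

as_familiarity <- function(x) {
  if (is.numeric(x)) {
    if (all(x %in% 1:5)) return(unname(FAMILIARITY_VALUES[x]))
    if (all(x %in% FAMILIARITY_VALUES)) return(as.numeric(x))
    stop("familiarity must be Likert 1..5 or values in {0.2,0.4,0.6,0.8,1.0}")
  }
  x <- tolower(as.character(x))
  if (any(!x %in% names(FAMILIARITY_VALUES))) {
    stop(sprintf("unknown familiarity label '%s'", x[!x %in% names(FAMILIARITY_VALUES)][1]))
  }
  unname(FAMILIARITY_VALUES[x])
}

#' @export
print.score_panel <- function(x, ...) {
  cat(sprintf("Delphi score panel (round %d): %d experts x %d indicators\n",
              x$round_id, length(x$expert_ids), length(x$indicator_ids)))
  if (!is.null(x$necessity)) cat(sprintf("  %d 'not necessary' votes\n", sum(x$necessity)))
  if (!is.null(x$judgment)) cat("  authority survey attached\n")
  invisible(x)
}

#' Read a score panel from CSV files
#'
#' The score file has `expert_id` in the first column and one column per
#' indicator id with integer cells. Necessity votes are a parallel 0/1 CSV
#' of the same shape. Authority answers are a CSV with columns `expert_id`,
#' `theory`, `practice`, `reference`, `intuition`, `familiarity`.
#'
#' @param path score CSV path.
#' @param necessity_path,authority_path optional companion CSV paths.
#' @param round_id integer round identifier.
#' @return A `score_panel`.
#' @export
read_score_panel <- function(path, necessity_path = NULL, authority_path = NULL,
                             round_id = 1L) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  scores <- as.matrix(raw[, -1, drop = FALSE])
  rownames(scores) <- as.character(raw[[1]])
  necessity <- NULL
  if (!is.null(necessity_path)) {
    nv <- utils::read.csv(necessity_path, check.names = FALSE, stringsAsFactors = FALSE)
    necessity <- as.matrix(nv[, -1, drop = FALSE]) != 0
    rownames(necessity) <- as.character(nv[[1]])
    necessity <- necessity[rownames(scores), colnames(scores), drop = FALSE]
  }
  judgment <- familiarity <- NULL
  if (!is.null(authority_path)) {
    au <- utils::read.csv(authority_path, check.names = FALSE, stringsAsFactors = FALSE)
    au <- au[match(rownames(scores), as.character(au$expert_id)), , drop = FALSE]
    if (anyNA(au$expert_id)) stop("authority file is missing rows for some experts")
    judgment <- au[, c("theory", "practice", "reference", "intuition")]
    familiarity <- au$familiarity
  }
  score_panel(scores, necessity = necessity, judgment = judgment,
              familiarity = familiarity, round_id = round_id)
}

#' Per-indicator descriptive statistics
#'
#' For each indicator: arithmetic mean, population standard deviation
#' (divisor N — the convention of the consensus literature this package
#' follows), coefficient of variation sd/mean, and the fraction of experts
#' voting "not necessary" (0 when no vote matrix is attached). Full
#' precision is returned; reports round to 2 decimals at the formatting
#' stage only.
#'
#' @param panel a `score_panel`.
#' @return data frame with columns `indicator_id`, `n`, `mean`, `sd`, `cv`,
#'   `pct_not_necessary`.
#' @export
indicator_stats <- function(panel) {
  stopifnot(inherits(panel, "score_panel"))
  s <- panel$scores
  if (!nrow(s) || !ncol(s)) stop("empty score panel")
  m <- colMeans(s)
  sd <- sqrt(colMeans(sweep(s, 2, m)^2))
  nn <- if (is.null(panel$necessity)) rep(0, ncol(s)) else colMeans(panel$necessity)
  data.frame(indicator_id = colnames(s), n = nrow(s), mean = m, sd = sd,
             cv = ifelse(m > 0, sd / m, 0), pct_not_necessary = nn,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Effective questionnaire recovery rate
#'
#' Expert motivation measure: valid returned questionnaires (complete score
#' matrices) over questionnaires sent.
#'
#' @param sent number of questionnaires sent (> 0).
#' @param returned_valid number returned with complete score matrices.
#' @return fraction in \[0, 1\].
#' @export
response_rate <- function(sent, returned_valid) {
  if (sent <= 0) stop("sent must be positive")
  if (returned_valid < 0 || returned_valid > sent) {
    stop("returned_valid must lie in [0, sent]")
  }
  returned_valid / sent
}

#' Expert authority coefficients
#'
#' Cr = (Ca + Cs) / 2 per expert. Ca (judgment basis) sums four graded
#' dimensions: theoretical analysis (large/medium/small = 0.3/0.2/0.1),
#' practical foundation (0.5/0.4/0.3), with reference materials and
#' intuitive judgment fixed at 0.1 each. Cs (familiarity) maps the 5-point
#' self-rating to 0.2..1.0. The panel is conventionally deemed credible
#' when the mean Cr is at least 0.7.
#'
#' @param panel a `score_panel` with judgment grades and familiarity.
#' @param ca_table optional replacement grade table shaped like the default.
#' @param credible_min panel-mean Cr credibility threshold.
#' @return list with `experts` (data frame expert_id/Ca/Cs/Cr), `panel_cr`
#'   and `credible`.
#' @export
authority_coefficient <- function(panel, ca_table = CA_TABLE, credible_min = 0.7) {
  stopifnot(inherits(panel, "score_panel"))
  if (is.null(panel$judgment) || is.null(panel$familiarity)) {
    stop("panel lacks judgment grades or familiarity ratings")
  }
  j <- panel$judgment
  ca <- ca_table$theory[j$theory] + ca_table$practice[j$practice] +
    ca_table$reference[j$reference] + ca_table$intuition[j$intuition]
  cs <- panel$familiarity
  cr <- (ca + cs) / 2
  list(experts = data.frame(expert_id = panel$expert_ids, Ca = unname(ca),
                            Cs = cs, Cr = unname(cr), row.names = NULL,
                            stringsAsFactors = FALSE),
       panel_cr = mean(cr), credible = mean(cr) >= credible_min)
}

#' Kendall's coefficient of concordance with tie correction
#'
#' Scores are converted to within-expert ranks (mid-ranks for ties; 5-point
#' scales tie heavily) and
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n) - m \sum_j T_j}}
#' where `S` is the sum of squared deviations of the indicator rank sums,
#' `m` the number of experts, `n` the number of indicators and
#' \eqn{T_j = \sum (t^3 - t)} over expert j's tie groups. Significance uses
#' the chi-square approximation \eqn{\chi^2 = m (n - 1) W} on `n - 1`
#' degrees of freedom (exact in the tie-free case by construction).
#'
#' @param panel a `score_panel`, or a bare experts-x-items score matrix.
#' @return list with `W`, `chi2`, `df`, `p`, `m`, `n`.
#' @export
kendalls_w <- function(panel) {
  s <- if (inherits(panel, "score_panel")) panel$scores else as.matrix(panel)
  m <- nrow(s); n <- ncol(s)
  if (m < 2 || n < 2) stop("Kendall's W needs at least 2 experts and 2 indicators")
  ranks <- t(apply(s, 1, rank))
  rs <- colSums(ranks)
  S <- sum((rs - mean(rs))^2)
  Tj <- apply(s, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  })
  denom <- m^2 * (n^3 - n) - m * sum(Tj)
  if (denom <= 0) stop("degenerate panel: every expert rated all indicators identically")
  W <- 12 * S / denom
  chi2 <- m * (n - 1) * W
  list(W = W, chi2 = chi2, df = n - 1L,
       p = pchisq(chi2, df = n - 1, lower.tail = FALSE), m = m, n = n)
}

#' Screening thresholds
#'
#' Defaults encode the retention band (mean >= 4 and CV < 0.25), the
#' deletion band (over 30% "not necessary" votes, mean < 3.5, or CV > 0.3)
#' and leave everything in between flagged for expert re-argument.
#'
#' @param retain_mean,retain_cv retention band: mean at least `retain_mean`
#'   and CV strictly below `retain_cv`.
#' @param delete_mean,delete_cv deletion band: mean strictly below
#'   `delete_mean` or CV strictly above `delete_cv`.
#' @param max_not_necessary vote fraction strictly above which an indicator
#'   is censored regardless of its scores.
#' @return list of class `screening_config`.
#' @export
screening_config <- function(retain_mean = 4.0, retain_cv = 0.25,
                             delete_mean = 3.5, delete_cv = 0.30,
                             max_not_necessary = 0.30) {
  stopifnot(delete_mean <= retain_mean, retain_cv <= delete_cv,
            max_not_necessary >= 0, max_not_necessary <= 1)
  structure(list(retain_mean = retain_mean, retain_cv = retain_cv,
                 delete_mean = delete_mean, delete_cv = delete_cv,
                 max_not_necessary = max_not_necessary),
            class = "screening_config")
}

#' Screen indicators on mean, CV and necessity votes
#'
#' Pure function of the statistics and thresholds. Verdicts: `delete` when
#' any deletion rule fires (votes > 30%, mean below the deletion floor, CV
#' above the deletion ceiling); `retain` when the retention band is met and
#' nothing fired; otherwise `review` (kept pending expert argumentation).
#' Each decision lists the rule ids that fired.
#'
#' @param stats data frame from [indicator_stats()].
#' @param config a [screening_config()].
#' @return data frame `indicator_id`, `verdict`, `rules` (comma-separated).
#' @export
screen_indicators <- function(stats, config = screening_config()) {
  stopifnot(all(c("indicator_id", "mean", "cv") %in% names(stats)))
  nn <- if ("pct_not_necessary" %in% names(stats)) stats$pct_not_necessary else 0
  out <- lapply(seq_len(nrow(stats)), function(i) {
    fired <- character()
    if (nn[i] > config$max_not_necessary) fired <- c(fired, "votes_gt_30pct")
    if (stats$mean[i] < config$delete_mean) fired <- c(fired, "mean_below_delete")
    if (stats$cv[i] > config$delete_cv) fired <- c(fired, "cv_above_delete")
    if (length(fired)) {
      verdict <- "delete"
    } else if (stats$mean[i] >= config$retain_mean && stats$cv[i] < config$retain_cv) {
      verdict <- "retain"
      fired <- "retain_band"
    } else {
      verdict <- "review"
      fired <- "outside_retain_band"
    }
    data.frame(indicator_id = stats$indicator_id[i], verdict = verdict,
               rules = paste(fired, collapse = ","), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run one full Delphi round
#'
#' Aggregates descriptives, authority, concordance and screening into one
#' auditable round report, and exposes the stop-criterion flag used to end
#' the correspondence: opinions are considered converged when W >= 0.5 and
#' every indicator's CV is below the retention CV threshold.
#'
#' @param h an `indicator_hierarchy`; the panel may score indicators at any
#'   level, but every scored id must be active in `h`.
#' @param panel a `score_panel`.
#' @param config a [screening_config()].
#' @return list of class `delphi_round_report`.
#' @export
run_round <- function(h, panel, config = screening_config()) {
  stopifnot(inherits(h, "indicator_hierarchy"), inherits(panel, "score_panel"))
  act <- active_indicators(h)$id
  unknown <- setdiff(panel$indicator_ids, act)
  if (length(unknown)) {
    stop(sprintf("panel scores inactive or unknown indicator '%s'", unknown[1]))
  }
  stats <- indicator_stats(panel)
  authority <- if (!is.null(panel$judgment) && !is.null(panel$familiarity)) {
    authority_coefficient(panel)
  }
  concordance <- kendalls_w(panel)
  decisions <- screen_indicators(stats, config)
  structure(list(round_id = panel$round_id, stats = stats,
                 authority = authority, concordance = concordance,
                 decisions = decisions,
                 converged = concordance$W >= 0.5 && all(stats$cv < config$retain_cv)),
            class = "delphi_round_report")
}

#' @export
print.delphi_round_report <- function(x, ...) {
  cat(sprintf("Delphi round %d: %d indicators, %d experts\n", x$round_id,
              nrow(x$stats), x$concordance$m))
  cat(sprintf("  Kendall W = %.3f (chi2 = %.3f, df = %d, p = %.3g)\n",
              x$concordance$W, x$concordance$chi2, x$concordance$df, x$concordance$p))
  if (!is.null(x$authority)) {
    cat(sprintf("  panel authority Cr = %.3f (%s)\n", x$authority$panel_cr,
                if (x$authority$credible) "credible" else "below 0.7"))
  }
  cat(sprintf("  verdicts: %s\n",
              paste(names(table(x$decisions$verdict)), table(x$decisions$verdict),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  converged: %s\n", x$converged))
  invisible(x)
}
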