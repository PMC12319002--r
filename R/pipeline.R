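fmt2 <- function(x) sprintf("%.2f", round(x + 1e-12, 2))
fmt4 <- function(x) sprintf("%.4f", round(x + 1e-12, 4))

#' Table-style weight report
#'
#' Joins descriptive statistics and AHP weights into the standard report
#' layout — id, name, mean +/- SD, CV, combination weight, leaf rank —
#' with statistics shown at 2 decimals and weights at 4, ordered by id.
#'
#' @param weights data frame from [full_ahp()]'s `weights` element (or
#'   [combine_weights()]).
#' @param stats data frame from [indicator_stats()].
#' @param h an `indicator_hierarchy` supplying display names.
#' @return data frame with character columns ready for serialization.
#' @export
weight_report <- function(weights, stats, h) {
  ids <- weights$indicator_id
  mismatch <- union(setdiff(ids, stats$indicator_id), setdiff(stats$indicator_id, ids))
  if (length(mismatch)) {
    stop(sprintf("id mismatch between stats and weights: '%s'", mismatch[1]))
  }
  act <- active_indicators(h)
  st <- stats[match(ids, stats$indicator_id), ]
  data.frame(
    id = ids,
    name = act$name[match(ids, act$id)],
    mean_sd = paste0(fmt2(st$mean), " ± ", fmt2(st$sd)),
    cv = fmt2(st$cv),
    weight = fmt4(weights$combination_weight),
    rank = weights$rank,
    stringsAsFactors = FALSE
  )
}

#' Write a weight report to disk
#'
#' @param report data frame from [weight_report()] (an empty frame writes a
#'   header-only file).
#' @param path output path without extension.
#' @param formats subset of `c("tsv", "json")`.
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(report, path, formats = c("tsv", "json")) {
  formats <- match.arg(formats, several.ok = TRUE)
  written <- character()
  if ("tsv" %in% formats) {
    f <- paste0(path, ".tsv")
    utils::write.table(report, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    written <- c(written, f)
  }
  if ("json" %in% formats) {
    f <- paste0(path, ".json")
    jsonlite::write_json(report, f, auto_unbox = TRUE, pretty = TRUE,
                         na = "null", digits = NA)
    written <- c(written, f)
  }
  invisible(written)
}

#' Read a pipeline configuration
#'
#' JSON with blocks `paths` (hierarchy, per-round score/necessity/authority
#' CSVs, revisions file, output_dir), `screening` (thresholds for
#' [screening_config()]), `saaty_mapping` (`upper`, `scale`),
#' `random_index`, and `seed`. Missing blocks fall back to package
#' defaults.
#'
#' @param path JSON config path, or an already-parsed list.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg$screening <- do.call(screening_config, as.list(cfg$screening %||% list()))
  cfg$saaty_mapping <- if (is.null(cfg$saaty_mapping)) saaty_mapping()
    else saaty_mapping(upper = cfg$saaty_mapping$upper, scale = cfg$saaty_mapping$scale)
  cfg$random_index <- if (is.null(cfg$random_index)) random_index()
    else unlist(cfg$random_index)
  structure(cfg, class = "pipeline_config")
}

load_panel_from_paths <- function(paths, round) {
  key <- sprintf("round%d_scores", round)
  if (is.null(paths[[key]])) stop(sprintf("round %d panel not found", round))
  if (!file.exists(paths[[key]])) stop(sprintf("round %d panel not found: %s",
                                               round, paths[[key]]))
  maybe <- function(k) if (!is.null(paths[[k]]) && file.exists(paths[[k]])) paths[[k]]
  read_score_panel(paths[[key]],
                   necessity_path = maybe(sprintf("round%d_necessity", round)),
                   authority_path = maybe(sprintf("round%d_authority", round)),
                   round_id = round)
}

#' Run the full two-round Delphi-AHP pipeline
#'
#' round-1 statistics and screening -> replay of the recorded framework
#' revisions -> round-2 statistics and convergence check -> AHP weighting
#' from the round-2 means -> report. Revisions are replayed from the
#' recorded actions file (framework revision is an expert decision informed
#' by, not mechanically derived from, the screening verdicts; the verdicts
#' are logged alongside for audit). Every screening decision and every
#' matrix consistency check lands in a machine-readable audit log.
#'
#' @param config a `pipeline_config`, raw list, or JSON path.
#' @param force pass the consistency gate override to [full_ahp()].
#' @return list of class `pipeline_result`: `round1`, `round2` (round
#'   reports), `hierarchy` (post-revision), `ahp`, `report`, `audit`,
#'   `files`.
#' @export
run_pipeline <- function(config, force = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else read_pipeline_config(config)
  paths <- cfg$paths
  if (is.null(paths$hierarchy)) stop("config lacks paths$hierarchy")
  audit <- list()
  note <- function(stage, ...) {
    audit[[length(audit) + 1]] <<- c(list(stage = stage), list(...))
  }

  h <- load_hierarchy(paths$hierarchy)
  note("load_hierarchy", counts = as.list(level_counts(h)))

  p1 <- load_panel_from_paths(paths, 1L)
  r1 <- run_round(h, p1, cfg$screening)
  for (i in seq_len(nrow(r1$decisions))) {
    note("screening", round = 1, indicator = r1$decisions$indicator_id[i],
         verdict = r1$decisions$verdict[i], rules = r1$decisions$rules[i])
  }
  note("concordance", round = 1, W = r1$concordance$W, chi2 = r1$concordance$chi2,
       p = r1$concordance$p)

  revisions <- if (!is.null(paths$revisions)) {
    jsonlite::fromJSON(paths$revisions, simplifyDataFrame = FALSE)$rounds
  } else list()
  for (rv in revisions) {
    h <- apply_revision(h, rv$round, rv$actions)
    note("revision", round = rv$round, n_actions = length(rv$actions))
  }

  p2 <- load_panel_from_paths(paths, 2L)
  r2 <- run_round(h, p2, cfg$screening)
  for (i in seq_len(nrow(r2$decisions))) {
    note("screening", round = 2, indicator = r2$decisions$indicator_id[i],
         verdict = r2$decisions$verdict[i], rules = r2$decisions$rules[i])
  }
  note("concordance", round = 2, W = r2$concordance$W, chi2 = r2$concordance$chi2,
       p = r2$concordance$p, converged = r2$converged)

  means <- stats::setNames(r2$stats$mean, r2$stats$indicator_id)
  ahp <- full_ahp(h, means, mapping = cfg$saaty_mapping, ri = cfg$random_index,
                  force = force)
  for (i in seq_len(nrow(ahp$consistency))) {
    note("consistency", parent = ahp$consistency$parent[i],
         lambda_max = ahp$consistency$lambda_max[i],
         cr = ahp$consistency$cr[i], pass = ahp$consistency$pass[i])
  }

  report <- weight_report(ahp$weights, r2$stats, h)
  files <- character()
  if (!is.null(paths$output_dir)) {
    dir.create(paths$output_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_report(report, file.path(paths$output_dir, "weight_report"))
    audit_file <- file.path(paths$output_dir, "audit.jsonl")
    writeLines(vapply(audit, function(e) jsonlite::toJSON(e, auto_unbox = TRUE),
                      character(1)), audit_file)
    files <- c(files, audit_file)
  }
  structure(list(round1 = r1, round2 = r2, hierarchy = h, ahp = ahp,
                 report = report, audit = audit, files = files),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Two-round Delphi-AHP pipeline\n")
  cat(sprintf("  round 1: W = %.3f; round 2: W = %.3f (converged: %s)\n",
              x$round1$concordance$W, x$round2$concordance$W, x$round2$converged))
  print(x$hierarchy)
  cat(sprintf("  max CR = %.4f over %d matrices\n",
              max(x$ahp$consistency$cr), nrow(x$ahp$consistency)))
  invisible(x)
}
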