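#' @importFrom stats setNames
NULL

# split a dotted code into integer components; "2.2.1" -> c(2, 2, 1)
id_components <- function(id) {
  lapply(strsplit(id, ".", fixed = TRUE), function(x) suppressWarnings(as.integer(x)))
}

id_level <- function(id) lengths(id_components(id))

# parent code implied by the id itself; NA for level-1 codes
id_parent <- function(id) {
  parts <- strsplit(id, ".", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) <= 1L) NA_character_ else paste(p[-length(p)], collapse = ".")
  }, character(1))
}

# order dotted codes component-wise and numerically ("1.10" after "1.9")
order_ids <- function(ids) {
  comp <- id_components(ids)
  k <- max(lengths(comp))
  keys <- vapply(comp, function(x) {
    x <- c(x, rep(-1L, k - length(x)))
    paste(sprintf("%06d", x + 1L), collapse = "")
  }, character(1))
  order(keys)
}

ACTIVE_STATUSES <- c("active", "revised")

#' Construct an indicator hierarchy
#'
#' An indicator hierarchy is a rooted three-level tree of evaluation
#' indicators identified by dotted codes (`"1"`, `"1.2"`, `"1.2.1"`). The
#' dotted code is canonical: an indicator's level is the number of code
#' components and its parent is the code with the last component removed.
#' Names are display-only, so renaming never breaks references.
#'
#' @param indicators data frame with columns `id`, `name`, and optionally
#'   `interpretation` and `status` (default `"active"`). `level` and `parent`
#'   are derived from `id` and validated if supplied.
#' @param round_log data frame of recorded revision actions
#'   (`round`, `action`, `id`, `note`); usually left empty and grown by
#'   [apply_revision()].
#' @param meta optional named list of free-form metadata.
#' @return An object of class `indicator_hierarchy`.
#' @seealso [load_hierarchy()], [apply_revision()], [children_of()]
#' @export
indicator_hierarchy <- function(indicators, round_log = NULL, meta = list()) {
  stopifnot(is.data.frame(indicators), all(c("id", "name") %in% names(indicators)))
  ind <- data.frame(
    id = as.character(indicators$id),
    name = as.character(indicators$name),
    level = id_level(as.character(indicators$id)),
    parent = id_parent(as.character(indicators$id)),
    interpretation = if ("interpretation" %in% names(indicators))
      as.character(indicators$interpretation) else "",
    status = if ("status" %in% names(indicators))
      as.character(indicators$status) else "active",
    stringsAsFactors = FALSE
  )
  if ("level" %in% names(indicators)) {
    bad <- which(as.integer(indicators$level) != ind$level)
    if (length(bad)) {
      stop(sprintf("level/id mismatch for indicator '%s': id implies level %d, file says %s",
                   ind$id[bad[1]], ind$level[bad[1]], indicators$level[bad[1]]))
    }
  }
  if ("parent" %in% names(indicators)) {
    declared <- as.character(indicators$parent)
    declared[declared %in% c("", "NA")] <- NA_character_
    bad <- which(!is.na(declared) & declared != ind$parent |
                   (is.na(declared) != is.na(ind$parent)))
    if (length(bad)) {
      stop(sprintf("parent/id mismatch for indicator '%s'", ind$id[bad[1]]))
    }
  }
  ind <- ind[order_ids(ind$id), , drop = FALSE]
  rownames(ind) <- NULL
  if (is.null(round_log)) {
    round_log <- data.frame(round = integer(), action = character(),
                            id = character(), note = character(),
                            stringsAsFactors = FALSE)
  }
  h <- structure(list(indicators = ind, round_log = round_log, meta = meta),
                 class = "indicator_hierarchy")
  validate_hierarchy(h)
  h
}

#' Validate an indicator hierarchy
#'
#' Checks id uniqueness, well-formed dotted codes, level/id agreement and
#' that every active level-2/3 indicator has an active parent. Violations
#' raise an error naming the offending id; nothing is silently repaired.
#'
#' @param h an `indicator_hierarchy`.
#' @return `h`, invisibly.
#' @export
validate_hierarchy <- function(h) {
  ind <- h$indicators
  dup <- ind$id[duplicated(ind$id)]
  if (length(dup)) stop(sprintf("duplicate indicator id '%s'", dup[1]))
  comp <- id_components(ind$id)
  badid <- ind$id[vapply(comp, function(x) any(is.na(x)) || !length(x), logical(1))]
  if (length(badid)) stop(sprintf("malformed indicator id '%s'", badid[1]))
  if (any(ind$level > 3L)) {
    stop(sprintf("indicator '%s' is deeper than three levels",
                 ind$id[which(ind$level > 3L)[1]]))
  }
  if (!all(ind$status %in% c(ACTIVE_STATUSES, "deleted", "merged"))) {
    bad <- ind$id[!ind$status %in% c(ACTIVE_STATUSES, "deleted", "merged")]
    stop(sprintf("indicator '%s' has unknown status", bad[1]))
  }
  act <- ind[ind$status %in% ACTIVE_STATUSES, , drop = FALSE]
  kids <- act[act$level > 1L, , drop = FALSE]
  if (nrow(kids)) {
    ok <- kids$parent %in% act$id
    if (!all(ok)) {
      stop(sprintf("orphan child '%s': parent '%s' missing or inactive",
                   kids$id[!ok][1], kids$parent[!ok][1]))
    }
  }
  invisible(h)
}

#' Load an indicator hierarchy from a JSON file
#'
#' The file holds one record per indicator: `{id, name, level, parent,
#' interpretation}` (UTF-8), either as a bare array or under an
#' `"indicators"` key with optional `"meta"`. `level` and `parent` are
#' redundant with the dotted `id` and are cross-checked when present.
#'
#' @param path path to the JSON hierarchy file.
#' @return A validated `indicator_hierarchy`.
#' @export
load_hierarchy <- function(path) {
  if (!file.exists(path)) stop(sprintf("hierarchy file not found: %s", path))
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.data.frame(x)) {
    indicator_hierarchy(x)
  } else {
    indicator_hierarchy(x$indicators, meta = x$meta %||% list())
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an indicator hierarchy to JSON
#'
#' Inverse of [load_hierarchy()]: `load_hierarchy(write_hierarchy(h, f))`
#' round-trips the indicator table (the round log is metadata and is
#' serialized alongside).
#'
#' @param h an `indicator_hierarchy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(h, path) {
  jsonlite::write_json(
    list(meta = h$meta, indicators = h$indicators, round_log = h$round_log),
    path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}

#' Active indicators, optionally restricted to one level
#'
#' @param h an `indicator_hierarchy`.
#' @param level optional level filter (1, 2 or 3).
#' @return data frame of active (including renamed) indicators ordered by id.
#' @export
active_indicators <- function(h, level = NULL) {
  ind <- h$indicators[h$indicators$status %in% ACTIVE_STATUSES, , drop = FALSE]
  if (!is.null(level)) ind <- ind[ind$level %in% level, , drop = FALSE]
  rownames(ind) <- NULL
  ind
}

#' Count active indicators per level
#'
#' @param h an `indicator_hierarchy`.
#' @return named integer vector over levels 1..3.
#' @export
level_counts <- function(h) {
  act <- active_indicators(h)
  vapply(1:3, function(l) sum(act$level == l), integer(1)) |>
    setNames(c("primary", "secondary", "tertiary"))
}

#' Active leaves (indicators with no active children)
#'
#' @param h an `indicator_hierarchy`.
#' @param level leaf level to count; defaults to 3, the scoring level of a
#'   three-tier indicator system.
#' @return character vector of ids.
#' @export
active_leaves <- function(h, level = 3L) {
  active_indicators(h, level = level)$id
}

#' Active children of an indicator
#'
#' @param h an `indicator_hierarchy`.
#' @param id dotted code of an active indicator.
#' @return data frame of active children ordered by id; zero rows for a leaf.
#' @export
children_of <- function(h, id) {
  act <- active_indicators(h)
  if (!id %in% act$id) stop(sprintf("unknown or inactive indicator id '%s'", id))
  kids <- act[!is.na(act$parent) & act$parent == id, , drop = FALSE]
  rownames(kids) <- NULL
  kids
}

#' Apply one round of revision actions
#'
#' Actions record the expert-driven evolution of the framework between
#' consultation rounds: deletions, renames (status becomes `"revised"`,
#' id unchanged) and additions. A merge of two indicators is expressed as
#' deletions plus an addition carrying a merge note. Every action is
#' appended to the round log; deleted indicators keep their records with
#' `status = "deleted"` so the audit trail is complete.
#'
#' @param h an `indicator_hierarchy`.
#' @param round integer round number.
#' @param actions list of actions; each a list with `action` in
#'   `c("delete", "rename", "add")`, `id`, and for renames `name`, for adds
#'   `name`/`interpretation`, plus an optional `note`.
#' @return A new `indicator_hierarchy`; the input is not modified.
#' @export
apply_revision <- function(h, round, actions = list()) {
  ind <- h$indicators
  log <- h$round_log
  log <- rbind(log, data.frame(round = round, action = "round", id = "",
                               note = sprintf("round %d revision", round),
                               stringsAsFactors = FALSE))
  for (a in actions) {
    stopifnot(is.list(a), !is.null(a$action), !is.null(a$id))
    note <- a$note %||% ""
    i <- match(a$id, ind$id)
    if (a$action %in% c("delete", "rename")) {
      if (is.na(i)) stop(sprintf("revision action on unknown id '%s'", a$id))
      if (!ind$status[i] %in% ACTIVE_STATUSES) {
        stop(sprintf("revision action on deleted indicator '%s'", a$id))
      }
    }
    if (a$action == "delete") {
      desc <- ind$id[!is.na(ind$parent) &
                       startsWith(ind$id, paste0(a$id, ".")) &
                       ind$status %in% ACTIVE_STATUSES]
      if (length(desc)) {
        stop(sprintf("cannot delete '%s': active children remain (%s)",
                     a$id, desc[1]))
      }
      ind$status[i] <- if (nzchar(note) && grepl("merge", note)) "merged" else "deleted"
    } else if (a$action == "rename") {
      stopifnot(!is.null(a$name))
      ind$name[i] <- a$name
      ind$status[i] <- "revised"
    } else if (a$action == "add") {
      if (!is.na(i)) stop(sprintf("id collision on add: '%s' already exists", a$id))
      ind <- rbind(ind, data.frame(
        id = a$id, name = a$name %||% a$id, level = id_level(a$id),
        parent = id_parent(a$id), interpretation = a$interpretation %||% "",
        status = "active", stringsAsFactors = FALSE))
    } else {
      stop(sprintf("unknown revision action '%s'", a$action))
    }
    log <- rbind(log, data.frame(round = round, action = a$action, id = a$id,
                                 note = note, stringsAsFactors = FALSE))
  }
  indicator_hierarchy(ind, round_log = log, meta = h$meta)
}

#' @export
print.indicator_hierarchy <- function(x, ...) {
  n <- level_counts(x)
  cat(sprintf("Indicator hierarchy: %d primary, %d secondary, %d tertiary active indicators\n",
              n[1], n[2], n[3]))
  dropped <- sum(!x$indicators$status %in% ACTIVE_STATUSES)
  if (dropped) cat(sprintf("  (%d removed across %d logged rounds)\n",
                           dropped, length(unique(x$round_log$round))))
  invisible(x)
}

#' Packaged hierarchy fixtures
#'
#' `final_hierarchy()` loads the packaged 3/9/19 digital-health-competency
#' framework. `round1_hierarchy()` loads the reconstructed pre-screening
#' framework (a synthetic stand-in: the published source does not include
#' the pre-screening wording, see the file's `meta`). `packaged_revisions()`
#' returns the two rounds of replayable revision actions connecting them.
#'
#' @return An `indicator_hierarchy`, or for `packaged_revisions()` a list of
#'   per-round action lists.
#' @export
final_hierarchy <- function() {
  load_hierarchy(system.file("extdata", "hierarchy_final.json",
                             package = "delphiAHP", mustWork = TRUE))
}

#' @rdname final_hierarchy
#' @export
round1_hierarchy <- function() {
  load_hierarchy(system.file("extdata", "hierarchy_round1_synthetic.json",
                             package = "delphiAHP", mustWork = TRUE))
}

#' @rdname final_hierarchy
#' @export
packaged_revisions <- function() {
  x <- jsonlite::fromJSON(system.file("extdata", "revisions.json",
                                      package = "delphiAHP", mustWork = TRUE),
                          simplifyDataFrame = FALSE)
  x$rounds
}
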