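#' Difference-to-Saaty mapping
#'
#' Judgment matrices are built from differences of panel mean scores: the
#' absolute difference |d| between two sibling indicators' means falls into
#' a bin, the bin fixes the Saaty scale value, and the sign of d decides
#' which side gets the value and which its reciprocal. The default bins are
#' calibrated so that the packaged framework's mean scores reproduce its
#' published weight table: d = 0 maps to 1 and the upper bounds 0.15, 0.35,
#' 0.50, 0.75, 0.85 (inclusive) map to scales 2..6, everything larger to 7.
#'
#' @param upper numeric vector of inclusive upper bounds, strictly
#'   increasing, first element 0 (the equal-importance bin); the last bin is
#'   open-ended.
#' @param scale Saaty scale values (1..9), one per bin, non-decreasing,
#'   starting at 1.
#' @return object of class `saaty_mapping`.
#' @export
saaty_mapping <- function(upper = c(0, 0.15, 0.35, 0.50, 0.75, 0.85),
                          scale = 1:6) {
  # the final open-ended bin takes scale max+1 by default construction below
  if (length(scale) == length(upper)) scale <- c(scale, min(scale[length(scale)] + 1, 9))
  stopifnot(length(scale) == length(upper) + 1,
            upper[1] == 0, !is.unsorted(upper, strictly = TRUE),
            !is.unsorted(scale), scale[1] == 1,
            all(scale %in% 1:9))
  structure(list(upper = upper, scale = scale), class = "saaty_mapping")
}

#' @export
print.saaty_mapping <- function(x, ...) {
  lo <- c(format(x$upper), "")
  cat("difference-to-Saaty mapping (inclusive upper bounds):\n")
  cat(sprintf("  |d| = 0 -> %d\n", x$scale[1]))
  for (i in seq_along(x$upper)[-1]) {
    cat(sprintf("  (%s, %s] -> %d\n", format(x$upper[i - 1]), format(x$upper[i]),
                x$scale[i]))
  }
  cat(sprintf("  (%s, Inf) -> %d\n", format(x$upper[length(x$upper)]),
              x$scale[length(x$scale)]))
  invisible(x)
}

#' Saaty scale value for a mean difference
#'
#' @param d signed mean difference(s).
#' @param mapping a [saaty_mapping()].
#' @return a_ij values: the scale for d >= 0, its reciprocal for d < 0.
#' @export
saaty_value <- function(d, mapping = saaty_mapping()) {
  vapply(d, function(di) {
    a <- abs(di)
    k <- if (a <= mapping$upper[1] + 1e-12) 1L
         else {
           hit <- which(a <= mapping$upper + 1e-12)
           if (length(hit)) hit[1] else length(mapping$scale)
         }
    s <- mapping$scale[k]
    if (di >= 0) s else 1 / s
  }, numeric(1))
}

#' Build a pairwise judgment matrix from mean scores
#'
#' For sibling indicators under one parent, a_ij = scale(|mean_i - mean_j|)
#' when indicator i scored at least as high as j, and the reciprocal
#' otherwise; the diagonal is 1. The result is a positive reciprocal matrix
#' for any mapping.
#'
#' @param means named numeric vector of mean scores (names = indicator ids).
#' @param mapping a [saaty_mapping()].
#' @return square matrix with the indicator ids as dimnames.
#' @export
build_judgment_matrix <- function(means, mapping = saaty_mapping()) {
  if (!length(means)) stop("cannot build a judgment matrix from zero items")
  stopifnot(all(is.finite(means)))
  n <- length(means)
  M <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) M[i, j] <- saaty_value(means[i] - means[j], mapping)
    }
  }
  dimnames(M) <- list(names(means), names(means))
  M
}

check_reciprocal <- function(M, tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("judgment matrix must be square")
  if (any(M <= 0)) stop("judgment matrix must be strictly positive")
  if (any(abs(diag(M) - 1) > tol)) stop("judgment matrix diagonal must be 1")
  if (any(abs(M * t(M) - 1) > tol)) stop("judgment matrix is not reciprocal")
  invisible(TRUE)
}

#' Principal-eigenvector priority weights
#'
#' Power iteration from the uniform vector, renormalized to sum 1 each
#' step, stopping when successive iterates differ by less than `tol` in the
#' max norm. The dominant eigenvalue is the Rayleigh quotient at
#' convergence (for a sum-1 weight vector, lambda = sum(M w)).
#'
#' @param M positive reciprocal judgment matrix.
#' @param tol convergence tolerance (max-norm on the weight iterate).
#' @param max_iter iteration cap; exceeding it signals a malformed matrix.
#' @return list with `weights` (named, sum 1) and `lambda_max`.
#' @export
principal_weights <- function(M, tol = 1e-12, max_iter = 10000L) {
  check_reciprocal(M)
  n <- nrow(M)
  w <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    w_new <- as.numeric(M %*% w)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) {
      lambda <- sum(M %*% w_new)
      return(list(weights = stats::setNames(w_new, rownames(M)), lambda_max = lambda))
    }
    w <- w_new
  }
  stop("power iteration failed to converge; malformed judgment matrix?")
}

#' Row-geometric-mean priority weights
#'
#' The logarithmic least-squares alternative to the eigenvector method;
#' identical to it on perfectly consistent matrices, which makes it the
#' independent oracle in this package's tests.
#'
#' @param M positive reciprocal judgment matrix.
#' @return named weights summing to 1.
#' @export
geometric_mean_weights <- function(M) {
  check_reciprocal(M)
  g <- apply(M, 1, function(r) exp(mean(log(r))))
  stats::setNames(g / sum(g), rownames(M))
}

#' Random-index table
#'
#' Expected consistency index of random reciprocal matrices by order n.
#' RI(3) = 0.52 here (the value used by contemporary AHP desktop software;
#' the older 0.58 is not compatible with the packaged framework's published
#' consistency ratios).
#'
#' @return named numeric vector for n = 1..9.
#' @export
random_index <- function() {
  c("1" = 0, "2" = 0, "3" = 0.52, "4" = 0.89, "5" = 1.12, "6" = 1.26,
    "7" = 1.36, "8" = 1.41, "9" = 1.46)
}

#' Consistency test of a judgment matrix
#'
#' CI = (lambda_max - n)/(n - 1), CR = CI / RI(n), with CR defined as 0 for
#' n <= 2; the matrix passes when CR < 0.1. By default lambda_max is
#' computed with the classical sum-product approximation (weights =
#' row means of the column-normalized matrix; lambda_max = mean of
#' (M w)_i / w_i), the convention of the desktop AHP tools this package's
#' reference results come from; `lambda_method = "power"` uses the exact
#' dominant eigenvalue instead. The two agree to ~1e-3 on near-consistent
#' matrices and exactly on consistent ones.
#'
#' @param M positive reciprocal judgment matrix.
#' @param lambda_max optionally a precomputed dominant eigenvalue, e.g. from
#'   [principal_weights()]; overrides `lambda_method`.
#' @param ri random-index table, as [random_index()].
#' @param lambda_method `"column-sum"` (default) or `"power"`.
#' @return list with `n`, `lambda_max`, `ci`, `ri`, `cr`, `pass`.
#' @export
ahp_consistency <- function(M, lambda_max = NULL, ri = random_index(),
                            lambda_method = c("column-sum", "power")) {
  check_reciprocal(M)
  n <- nrow(M)
  lambda_method <- match.arg(lambda_method)
  if (is.null(lambda_max)) {
    lambda_max <- if (n == 1) 1
    else if (lambda_method == "power") principal_weights(M)$lambda_max
    else {
      w <- rowMeans(sweep(M, 2, colSums(M), "/"))
      mean(as.numeric(M %*% w) / w)
    }
  }
  if (n <= 2) {
    ci <- 0; cr <- 0; rin <- 0
  } else {
    ci <- (lambda_max - n) / (n - 1)
    rin <- ri[as.character(n)]
    if (is.na(rin)) stop(sprintf("no random index for matrix order %d", n))
    cr <- ci / rin
  }
  list(n = n, lambda_max = lambda_max, ci = unname(ci), ri = unname(rin),
       cr = unname(cr), pass = cr < 0.1)
}

#' Combine local weights down the hierarchy
#'
#' The combination (global) weight of an indicator is the product of local
#' weights along its root path; the top level's local weights are already
#' global. Children's combination weights therefore sum to their parent's,
#' and the leaves' sum to 1.
#'
#' @param h an `indicator_hierarchy`.
#' @param locals named list: parent id (or `"root"` for the top level) ->
#'   named local weight vector over its children.
#' @return data frame `indicator_id`, `level`, `local_weight`,
#'   `combination_weight`, `rank` (dense rank over leaves, NA elsewhere).
#' @export
combine_weights <- function(h, locals) {
  act <- active_indicators(h)
  if (is.null(locals$root)) stop("missing local weight vector for parent 'root'")
  comb <- local <- stats::setNames(numeric(nrow(act)), act$id)
  for (id in names(locals$root)) {
    local[id] <- comb[id] <- locals$root[[id]]
  }
  for (lev in 2:3) {
    for (id in act$id[act$level == lev]) {
      p <- id_parent(id)
      lv <- locals[[p]]
      if (is.null(lv) || is.null(lv[[id]])) {
        stop(sprintf("missing local weight vector for parent '%s'", p))
      }
      local[id] <- lv[[id]]
      comb[id] <- comb[p] * lv[[id]]
    }
  }
  leaves <- active_leaves(h)
  out <- data.frame(indicator_id = act$id, level = act$level,
                    local_weight = unname(local[act$id]),
                    combination_weight = unname(comb[act$id]),
                    rank = NA_integer_, stringsAsFactors = FALSE)
  out$rank[match(leaves, out$indicator_id)] <-
    rank(-out$combination_weight[match(leaves, out$indicator_id)],
         ties.method = "min")
  out
}

#' Full AHP over a hierarchy
#'
#' Builds one judgment matrix per active non-leaf parent (and one over the
#' top-level indicators), derives local weights by the principal-eigenvector
#' method, runs the consistency test on every matrix, and combines local
#' weights into global ones. Any matrix with CR >= 0.1 aborts the run
#' unless `force = TRUE`.
#'
#' @param h an `indicator_hierarchy`.
#' @param means named numeric vector of mean scores covering every active
#'   indicator.
#' @param mapping a [saaty_mapping()].
#' @param ri random-index table.
#' @param force emit weights even when a matrix fails the consistency gate.
#' @param lambda_method lambda convention for [ahp_consistency()].
#' @return list of class `ahp_result`: `matrices` (named list),
#'   `consistency` (data frame per parent), `weights` (from
#'   [combine_weights()]).
#' @export
full_ahp <- function(h, means, mapping = saaty_mapping(), ri = random_index(),
                     force = FALSE, lambda_method = "column-sum") {
  act <- active_indicators(h)
  missing <- setdiff(act$id, names(means))
  if (length(missing)) {
    stop(sprintf("no mean score for active indicator '%s'", missing[1]))
  }
  parents <- c("root", act$id[act$level < 3])
  matrices <- list()
  locals <- list()
  cons <- list()
  for (p in parents) {
    ids <- if (p == "root") active_indicators(h, level = 1)$id else children_of(h, p)$id
    if (!length(ids)) next  # childless non-leaf contributes no matrix
    M <- build_judgment_matrix(means[ids], mapping)
    pw <- principal_weights(M)
    cc <- ahp_consistency(M, ri = ri, lambda_method = lambda_method)
    matrices[[p]] <- M
    locals[[p]] <- pw$weights
    cons[[p]] <- data.frame(parent = p, n = cc$n, lambda_max = cc$lambda_max,
                            ci = cc$ci, cr = cc$cr, pass = cc$pass,
                            stringsAsFactors = FALSE)
  }
  cons <- do.call(rbind, c(cons, list(make.row.names = FALSE)))
  if (!force && any(!cons$pass)) {
    stop(sprintf("consistency gate failed (CR >= 0.1) for parent '%s'; use force = TRUE to override",
                 cons$parent[!cons$pass][1]))
  }
  structure(list(matrices = matrices, consistency = cons,
                 weights = combine_weights(h, locals)),
            class = "ahp_result")
}

#' @export
print.ahp_result <- function(x, ...) {
  cat(sprintf("AHP result: %d judgment matrices, max CR = %.4f\n",
              nrow(x$consistency), max(x$consistency$cr)))
  lf <- x$weights[!is.na(x$weights$rank), ]
  lf <- lf[order(lf$rank), ]
  cat("top leaves by combination weight:\n")
  utils::head(lf[, c("indicator_id", "combination_weight", "rank")], 5) |>
    print(row.names = FALSE)
  invisible(x)
}

#' Calibrate a difference-to-Saaty mapping from examples
#'
#' Given observed |mean difference| -> Saaty scale pairs (for instance read
#' off a published weight table), finds inclusive bin upper bounds placed
#' midway between the largest difference of each scale group and the
#' smallest of the next, erroring if any groups overlap.
#'
#' @param diffs absolute mean differences.
#' @param scales the Saaty scale value each difference maps to.
#' @return a [saaty_mapping()].
#' @export
calibrate_mapping <- function(diffs, scales) {
  stopifnot(length(diffs) == length(scales), all(diffs >= 0),
            all(scales %in% 1:9))
  if (any(scales == 1 & diffs > 0)) {
    stop("scale 1 (equal importance) must correspond to zero difference")
  }
  sc <- sort(unique(c(1L, scales)))  # the equal-importance bin always exists
  hi <- vapply(sc, function(s) if (any(scales == s)) max(diffs[scales == s]) else NA_real_,
               numeric(1))
  lo <- vapply(sc, function(s) if (any(scales == s)) min(diffs[scales == s]) else NA_real_,
               numeric(1))
  # upper[1] = 0 closes the equal-importance bin; for k = 2..K-1 the bound
  # between group k and k+1 sits midway between them; group K is open-ended
  upper <- 0
  if (length(sc) > 1 && !is.na(lo[2]) && lo[2] <= 0) {
    stop(sprintf("difference groups for scales 1 and %d overlap", sc[2]))
  }
  if (length(sc) > 2) {
    for (k in 2:(length(sc) - 1)) {
      a <- hi[k]; b <- lo[k + 1]
      if (is.na(a)) a <- upper[length(upper)]
      if (is.na(b)) b <- a + 0.1
      if (b <= a) stop(sprintf("difference groups for scales %d and %d overlap",
                               sc[k], sc[k + 1]))
      upper <- c(upper, (a + b) / 2)
    }
  }
  saaty_mapping(upper = upper, scale = sc)
}
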