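#' AMA ("All Marker Alleles") core selection
#'
#' Deterministic greedy covering of all marker/allele combinations. The
#' accession with the highest coefficient of rareness seeds the set; each
#' following step adds the accession contributing the largest number of not
#' yet covered combinations, breaking ties first by higher rareness, then by
#' lexicographically smaller accession id. Selection stops when every
#' coverable combination (present in at least one accession) is covered.
#' Given the same input, the algorithm returns the same core set every time.
#'
#' @param a an [accession_matrix()]; a combination is present in an
#'   accession when `z >= presence_threshold`.
#' @param r rareness result from [rareness_coefficients()], aligned with
#'   `a`; computed from `a` when omitted.
#' @param presence_threshold minimum z that witnesses an allele (default 1:
#'   detection in a single bulk suffices).
#' @return A `core_set`: list with `selected` (ordered accession ids),
#'   `step_log` (per step: accession, gain in newly covered columns, R at
#'   selection, cumulative coverage), `covered_columns`, `uncoverable`
#'   (columns absent from every accession, excluded from the target with a
#'   warning), `coverage` (fraction of coverable columns covered) and
#'   `mean_R`.
#' @seealso [brute_force_min_cover()], [core_metrics()]
#' @export
ama_select <- function(a, r = NULL, presence_threshold = 1L) {
  stopifnot(inherits(a, "accession_matrix"))
  if (is.null(r)) r <- rareness_coefficients(a)
  if (!inherits(r, "rareness") || !identical(r$accession, rownames(a$z)))
    stop("'r' is not aligned with 'a' (accession ids differ)")

  presence <- a$z >= presence_threshold
  coverable <- colSums(presence) > 0L
  uncoverable <- colnames(a$z)[!coverable]
  if (length(uncoverable))
    warning(sprintf("%d column(s) present in no accession excluded from the coverage target: %s",
                    length(uncoverable), paste(uncoverable, collapse = ", ")))

  ids <- r$accession
  R <- r$R
  covered <- !coverable           # uncoverable columns count as done
  selected <- character(0)
  log <- list()
  remaining <- rep(TRUE, length(ids))
  n_target <- sum(coverable)

  step <- 0L
  repeat {
    step <- step + 1L
    cand <- which(remaining)
    if (!length(cand)) break
    if (step == 1L) {
      # seed: highest rareness, ties to the lexicographically smallest id
      pick <- cand[order(-R[cand], ids[cand])[1L]]
    } else {
      gain <- rowSums(presence[cand, !covered, drop = FALSE])
      if (max(gain) == 0L) break
      pick <- cand[order(-gain, -R[cand], ids[cand])[1L]]
    }
    newly <- presence[pick, ] & !covered
    covered <- covered | presence[pick, ]
    selected <- c(selected, ids[pick])
    remaining[pick] <- FALSE
    log[[step]] <- data.frame(
      step = step, accession = ids[pick], gain = sum(newly), R = R[pick],
      cum_covered = sum(covered & coverable),
      cum_coverage = if (n_target) sum(covered & coverable) / n_target else 1,
      stringsAsFactors = FALSE)
    if (all(covered)) break
  }

  structure(list(
    selected = selected,
    step_log = do.call(rbind, log),
    covered_columns = colnames(a$z)[covered & coverable],
    uncoverable = uncoverable,
    coverage = if (n_target) sum(covered & coverable) / n_target else 1,
    mean_R = mean(R[match(selected, ids)]),
    method = "ama",
    presence_threshold = as.integer(presence_threshold)
  ), class = "core_set")
}

#' Exact minimum cover by exhaustive search
#'
#' Enumerates accession subsets in increasing size (and, within a size, in
#' lexicographic id order) until one covers every coverable marker/allele
#' combination; the first hit is a minimum-cardinality cover and the
#' lexicographically smallest among covers of that size. Intended as an
#' optimality oracle for [ama_select()]; refuses more than `max_n`
#' accessions.
#'
#' @inheritParams ama_select
#' @param max_n exhaustive-search guard (default 20 accessions).
#' @return A `core_set` (with `method = "brute_force"`; `step_log` reports
#'   the selected accessions without greedy gains).
#' @export
brute_force_min_cover <- function(a, presence_threshold = 1L, max_n = 20L) {
  stopifnot(inherits(a, "accession_matrix"))
  n <- nrow(a$z)
  if (n > max_n)
    stop(sprintf("exhaustive search is limited to %d accessions (got %d); use ama_select()",
                 max_n, n))
  presence <- a$z >= presence_threshold
  coverable <- colSums(presence) > 0L
  uncoverable <- colnames(a$z)[!coverable]
  ids_sorted <- sort(rownames(a$z))
  P <- presence[ids_sorted, coverable, drop = FALSE]
  m <- ncol(P)

  best <- character(0)
  if (m > 0L) {
    found <- FALSE
    for (k in seq_len(n)) {
      combos <- utils::combn(n, k)
      for (ci in seq_len(ncol(combos))) {
        rows <- combos[, ci]
        if (all(colSums(P[rows, , drop = FALSE]) > 0L)) {
          best <- ids_sorted[rows]
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }

  structure(list(
    selected = best,
    step_log = data.frame(step = seq_along(best), accession = best,
                          gain = rep(NA_integer_, length(best)),
                          R = rep(NA_real_, length(best)),
                          cum_covered = rep(NA_integer_, length(best)),
                          cum_coverage = rep(NA_real_, length(best)),
                          stringsAsFactors = FALSE),
    covered_columns = colnames(a$z)[coverable],
    uncoverable = uncoverable,
    coverage = 1,
    mean_R = NA_real_,
    method = "brute_force",
    presence_threshold = as.integer(presence_threshold)
  ), class = "core_set")
}

#' Core-set quality metrics
#'
#' Coverage, mean rareness and per-column redundancy of a candidate core set
#' (from [ama_select()], [brute_force_min_cover()], or any external
#' selection given as a character vector of accession ids).
#'
#' @param core a `core_set` or character vector of accession ids.
#' @inheritParams ama_select
#' @return List with `size`, `coverage` (covered / coverable columns),
#'   `mean_R` (`NA` for an empty set), and `redundancy` (named integer
#'   vector: number of selected accessions presenting each column).
#' @export
core_metrics <- function(core, a, r = NULL, presence_threshold = 1L) {
  stopifnot(inherits(a, "accession_matrix"))
  selected <- if (inherits(core, "core_set")) core$selected else as.character(core)
  unknown <- setdiff(selected, rownames(a$z))
  if (length(unknown))
    stop(sprintf("unknown accession(s) in core set: %s",
                 paste(unknown, collapse = ", ")))
  if (is.null(r)) r <- rareness_coefficients(a)
  presence <- a$z >= presence_threshold
  coverable <- colSums(presence) > 0L
  sub <- presence[selected, , drop = FALSE]
  redundancy <- colSums(sub)
  covered <- redundancy > 0L & coverable
  list(
    size = length(selected),
    coverage = if (any(coverable)) sum(covered) / sum(coverable)
               else if (length(selected)) 1 else 0,
    mean_R = if (length(selected))
      mean(r$R[match(selected, r$accession)]) else NA_real_,
    redundancy = redundancy
  )
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("Core set (%s): %d accessions, coverage %.3f\n",
              x$method, length(x$selected), x$coverage))
  if (!is.na(x$mean_R)) cat(sprintf("  mean rareness of selected: %.4g\n", x$mean_R))
  if (length(x$uncoverable))
    cat(sprintf("  %d uncoverable column(s) excluded\n", length(x$uncoverable)))
  show <- utils::head(x$selected, 10L)
  cat("  selected:", paste(show, collapse = ", "),
      if (length(x$selected) > 10L) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.core_set <- function(object, ...) {
  cat(sprintf("Core set selected by %s\n", object$method))
  print(object$step_log, row.names = FALSE)
  invisible(object)
}
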