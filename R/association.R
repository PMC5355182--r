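#' Per-race Welch t-tests of marker/allele z-scores
#'
#' For each group (race, kernel colour, ...) with at least `min_size`
#' members, every marker/allele column is tested by a Welch two-sample
#' t-test of z in the group against z in all other accessions.
#' Benjamini-Hochberg q-values are computed over the whole group x column
#' family of one run; a column that is constant over all accessions is not
#' tested (p fixed at 1, flagged in `note`).
#'
#' @param a an [accession_matrix()].
#' @param groups group label per accession of `a` (character or factor;
#'   `NA` labels are left out of every group but kept in the "others" side).
#' @param fdr_level declare significance at BH q <= this level (default
#'   0.001, i.e. FDR <= 0.1%).
#' @param min_size smallest group analysed (default 10 accessions).
#' @return An `association_table` data frame, one row per group x column:
#'   `group`, `column`, `n_group`, `mean_in_group`, `mean_in_others`,
#'   `direction` (`"+"` iff the group mean is larger), `t_statistic`,
#'   `p_value`, `fdr_q`, `significant`, `note`.
#' @export
group_allele_ttests <- function(a, groups, fdr_level = 0.001, min_size = 10L) {
  stopifnot(inherits(a, "accession_matrix"))
  z <- a$z
  groups <- as.character(groups)
  if (length(groups) != nrow(z))
    stop("'groups' must have one label per accession")
  use <- table(groups[!is.na(groups)])
  use <- names(use)[use >= min_size & use <= nrow(z) - 2L]
  if (!length(use)) stop(sprintf("no group with >= %d members", min_size))

  rows <- list()
  for (g in sort(use)) {
    ing <- !is.na(groups) & groups == g
    for (j in seq_len(ncol(z))) {
      x <- z[ing, j]; y <- z[!ing, j]
      rec <- list(group = g, column = colnames(z)[j], n_group = sum(ing),
                  mean_in_group = mean(x), mean_in_others = mean(y),
                  direction = if (mean(x) > mean(y)) "+" else "-",
                  t_statistic = NA_real_, p_value = NA_real_,
                  tested = TRUE, note = "")
      if (stats::sd(z[, j]) == 0) {
        rec$p_value <- 1
        rec$tested <- FALSE
        rec$note <- "column constant across all accessions; not tested"
      } else if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        # both sides constant but at different levels: zero standard error
        rec$t_statistic <- sign(mean(x) - mean(y)) * Inf
        rec$p_value <- 0
        rec$note <- "zero variance on both sides; degenerate Welch limit"
      } else {
        tt <- stats::t.test(x, y, var.equal = FALSE)
        rec$t_statistic <- unname(tt$statistic)
        rec$p_value <- tt$p.value
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out$fdr_q <- NA_real_
  fam <- out$tested
  out$fdr_q[fam] <- stats::p.adjust(out$p_value[fam], method = "BH")
  out$fdr_q[!fam] <- 1
  out$significant <- out$tested & out$fdr_q <= fdr_level
  attr(out, "fdr_level") <- fdr_level
  attr(out, "test") <- "welch_t"
  class(out) <- c("association_table", "data.frame")
  out
}

# G-statistic (likelihood-ratio chi-square) of a contingency table.
g_statistic <- function(tab) {
  tab <- as.matrix(tab)
  N <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / N
  nz <- tab > 0
  2 * sum(tab[nz] * log(tab[nz] / E[nz]))
}

#' Per-race G-statistic contingency tests of marker/allele presence
#'
#' For each sufficiently large group and each marker/allele column, a
#' contingency table of group membership against allele presence is tested
#' with the likelihood-ratio G-statistic, \eqn{G = 2\sum O \ln(O/E)}
#' (chi-square reference with (k-1) degrees of freedom for a 2 x k table).
#' By default presence is dichotomized at z >= `presence_threshold`;
#' `levels = "z"` instead uses the full 2 x (B+1) table of z levels.
#' Benjamini-Hochberg q-values are computed over the family of all tests in
#' the run; degenerate tables (a margin with a single level) are skipped
#' with a note.
#'
#' @inheritParams group_allele_ttests
#' @param m an [accession_matrix()] (units = accessions) or [bulk_matrix()]
#'   (units = bulks, inheriting their accession's group label).
#' @param presence_threshold z at or above which an allele counts as present
#'   (default 1).
#' @param levels `"binary"` (default) or `"z"` for multi-level z tables.
#' @return An `association_table` data frame with `G_statistic`, `df`,
#'   `p_value`, `fdr_q`, `significant`, `direction` (sign of the
#'   presence-rate difference), `note`.
#' @export
group_allele_gtests <- function(m, groups, fdr_level = 0.001, min_size = 10L,
                                presence_threshold = 1L,
                                levels = c("binary", "z")) {
  levels <- match.arg(levels)
  if (inherits(m, "bulk_matrix")) {
    if (length(groups) == length(unique(m$accession)))
      groups <- as.character(groups)[match(m$accession, unique(m$accession))]
    x <- m$scores
    presence_threshold <- 1L
  } else if (inherits(m, "accession_matrix")) {
    x <- m$z
  } else stop("'m' must be a bulk_matrix or accession_matrix")
  groups <- as.character(groups)
  if (length(groups) != nrow(x))
    stop("'groups' must have one label per row unit")
  counts <- table(groups[!is.na(groups)])
  use <- names(counts)[counts >= min_size & counts <= nrow(x) - 2L]
  if (!length(use)) stop(sprintf("no group with >= %d members", min_size))

  rows <- list()
  for (g in sort(use)) {
    ing <- factor(ifelse(!is.na(groups) & groups == g, "in", "out"),
                  levels = c("in", "out"))
    for (j in seq_len(ncol(x))) {
      val <- if (levels == "binary")
        factor(ifelse(x[, j] >= presence_threshold, "present", "absent"),
               levels = c("absent", "present"))
      else factor(x[, j], levels = sort(unique(x[, j])))
      rate_in <- mean(x[ing == "in", j] >= presence_threshold)
      rate_out <- mean(x[ing == "out", j] >= presence_threshold)
      rec <- list(group = g, column = colnames(x)[j],
                  n_group = sum(ing == "in"),
                  rate_in_group = rate_in, rate_in_others = rate_out,
                  direction = if (rate_in > rate_out) "+" else "-",
                  G_statistic = NA_real_, df = NA_integer_,
                  p_value = NA_real_, tested = TRUE, note = "")
      tab <- table(ing, val)
      if (any(dim(tab) < 2L) || any(colSums(tab) == 0L)) {
        rec$tested <- FALSE
        rec$note <- "degenerate margin (all units share one level); skipped"
      } else {
        G <- g_statistic(tab)
        rec$G_statistic <- G
        rec$df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
        rec$p_value <- stats::pchisq(G, df = rec$df, lower.tail = FALSE)
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out$fdr_q <- NA_real_
  fam <- out$tested
  out$fdr_q[fam] <- stats::p.adjust(out$p_value[fam], method = "BH")
  out$significant <- out$tested & !is.na(out$fdr_q) & out$fdr_q <= fdr_level
  attr(out, "fdr_level") <- fdr_level
  attr(out, "test") <- "g_contingency"
  class(out) <- c("association_table", "data.frame")
  out
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("Association tests (%s): %d group x column tests, %d significant at FDR <= %g\n",
              attr(x, "test"), nrow(x), sum(x$significant),
              attr(x, "fdr_level")))
  sig <- x[x$significant, , drop = FALSE]
  if (nrow(sig)) {
    sig <- sig[order(sig$fdr_q), , drop = FALSE]
    print(utils::head(as.data.frame(sig), 10L), row.names = FALSE)
    if (nrow(sig) > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' Forward-selection regression of altitude on marker/allele scores
#'
#' Ordinary least squares of meters above sea level (MASL) on accession
#' z-scores, built by forward stepwise selection: starting from the
#' intercept-only model, the column whose addition most improves the
#' criterion (BIC by default) is added until no candidate improves it or
#' `max_terms` is reached. Candidate columns that are collinear with the
#' selected ones (rank-deficient fit) are skipped with a note.
#'
#' @param a an [accession_matrix()].
#' @param masl numeric altitude (m) per accession of `a`.
#' @param criterion `"bic"` (default) or `"aic"`.
#' @param max_terms maximum number of selected columns (default unlimited).
#' @return A `masl_model`: list with the final `lm` fit (`fit`), `terms`
#'   (selected column labels in selection order), `coefficients` (estimate,
#'   std. error, t-value, p), `r_squared`, `selection_path` (per step:
#'   column, criterion before/after, action) and `skipped` (collinear
#'   candidates). Methods: `print`, `summary`, `coef`, `predict`,
#'   `residuals`.
#' @export
masl_regression <- function(a, masl, criterion = c("bic", "aic"),
                            max_terms = Inf) {
  stopifnot(inherits(a, "accession_matrix"))
  criterion <- match.arg(criterion)
  masl <- as.numeric(masl)
  if (length(masl) != nrow(a$z))
    stop("'masl' must have one value per accession")
  if (anyNA(masl)) stop("'masl' must be present for all accessions used")
  crit_fun <- if (criterion == "bic") stats::BIC else stats::AIC

  labels <- colnames(a$z)
  dat <- as.data.frame(a$z)
  names(dat) <- paste0("x", seq_along(labels))   # syntactic stand-ins
  dat$.masl <- masl
  candidates <- which(apply(a$z, 2L, stats::sd) > 0)

  fit <- stats::lm(.masl ~ 1, data = dat)
  selected <- integer(0)
  skipped <- character(0)
  path <- list()
  current <- crit_fun(fit)

  while (length(selected) < max_terms && length(candidates)) {
    if (nrow(dat) <= length(selected) + 2L) break
    scores <- rep(NA_real_, length(candidates))
    fits <- vector("list", length(candidates))
    for (k in seq_along(candidates)) {
      j <- candidates[k]
      f <- stats::as.formula(paste(".masl ~",
                                   paste(names(dat)[c(selected, j)],
                                         collapse = " + ")))
      cand_fit <- stats::lm(f, data = dat)
      if (anyNA(stats::coef(cand_fit))) next       # collinear with selected
      scores[k] <- crit_fun(cand_fit)
      fits[[k]] <- cand_fit
    }
    if (all(is.na(scores))) break
    best <- which.min(scores)
    if (scores[best] >= current) break
    j <- candidates[best]
    path[[length(path) + 1L]] <- data.frame(
      step = length(selected) + 1L, column = labels[j],
      criterion_before = current, criterion_after = scores[best],
      stringsAsFactors = FALSE)
    collinear <- candidates[is.na(scores) & seq_along(candidates) != best]
    fit <- fits[[best]]
    current <- scores[best]
    selected <- c(selected, j)
    candidates <- setdiff(candidates, j)
  }

  # record candidates that were collinear with the final selection
  for (j in candidates) {
    f <- stats::as.formula(paste(".masl ~",
                                 paste(names(dat)[c(selected, j)],
                                       collapse = " + ")))
    if (anyNA(stats::coef(stats::lm(f, data = dat))))
      skipped <- c(skipped, labels[j])
  }

  ct <- summary(fit)$coefficients
  if (length(selected)) {
    rn <- rownames(ct)
    rn[match(paste0("x", selected), rn)] <- labels[selected]
    rownames(ct) <- rn
  }
  structure(list(
    fit = fit, terms = labels[selected], coefficients = ct,
    r_squared = summary(fit)$r.squared,
    selection_path = if (length(path)) do.call(rbind, path) else
      data.frame(step = integer(0), column = character(0),
                 criterion_before = numeric(0), criterion_after = numeric(0)),
    skipped = skipped, criterion = criterion,
    column_map = stats::setNames(paste0("x", seq_along(labels)), labels)
  ), class = "masl_model")
}

#' @export
print.masl_model <- function(x, ...) {
  cat(sprintf("MASL ~ marker/allele forward selection (%s): %d term(s), R^2 = %.3f\n",
              toupper(x$criterion), length(x$terms), x$r_squared))
  print(round(x$coefficients, 4))
  if (length(x$skipped))
    cat("  skipped (collinear):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.masl_model <- function(object, ...) {
  cat("Selection path:\n")
  print(object$selection_path, row.names = FALSE)
  print(object)
  invisible(object)
}

#' @export
coef.masl_model <- function(object, ...) {
  cf <- object$coefficients[, "Estimate"]
  names(cf) <- rownames(object$coefficients)
  cf
}

#' @export
predict.masl_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$fit))
  z <- if (inherits(newdata, "accession_matrix")) newdata$z else as.matrix(newdata)
  dat <- as.data.frame(z[, names(object$column_map)[
    match(object$terms, names(object$column_map))], drop = FALSE])
  names(dat) <- unname(object$column_map[object$terms])
  stats::predict(object$fit, newdata = dat)
}

#' @export
residuals.masl_model <- function(object, ...) stats::residuals(object$fit)
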