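#' Coefficient of rareness per accession
#'
#' For accession `i` with z-scores `z[i, j]` the coefficient of rareness is
#' the mean squared deviation of its marker/allele scores from the
#' collection-wide column means:
#'
#' \deqn{R_i = \frac{1}{M} \sum_{j=1}^{M} (z_{ij} - \bar z_j)^2}
#'
#' where \eqn{\bar z_j} is the mean score of column `j` over the whole
#' collection, focal accession included. Accessions carrying uncommon
#' marker/allele combinations score high; an accession whose profile matches
#' the collection averages scores near zero.
#'
#' @param a an [accession_matrix()] (bulk matrices work too and are treated
#'   as B = 1 profiles after collapsing; rareness is conventionally computed
#'   on z-scores).
#' @param exclude_self if `TRUE`, each accession's own row is removed from
#'   the column means it is compared against. Default `FALSE` (whole
#'   collection, the conventional definition).
#' @return A data frame of class `rareness` with columns `accession`, `R`
#'   and (until [classify_rareness()] is applied) an all-`NA` ordered factor
#'   `class`. Row order matches the input.
#' @seealso [classify_rareness()], [ama_select()]
#' @export
rareness_coefficients <- function(a, exclude_self = FALSE) {
  if (inherits(a, "bulk_matrix")) a <- collapse_bulks(a)
  stopifnot(inherits(a, "accession_matrix"))
  z <- a$z
  n <- nrow(z)
  if (n < 2L) stop("need at least 2 accessions")
  if (ncol(z) == 0L) stop("no marker/allele columns")
  zbar <- colMeans(z)
  if (exclude_self) {
    # leave-one-out mean: (n * zbar - z_i) / (n - 1), per accession
    dev <- z - (matrix(zbar, n, ncol(z), byrow = TRUE) * n -
                  z) / (n - 1)
  } else {
    dev <- sweep(z, 2L, zbar)
  }
  out <- data.frame(accession = rownames(z), R = rowMeans(dev^2),
                    stringsAsFactors = FALSE)
  out$class <- factor(rep(NA_character_, n), levels = rareness_classes(),
                      ordered = TRUE)
  rownames(out) <- NULL
  attr(out, "B") <- a$B
  attr(out, "exclude_self") <- exclude_self
  attr(out, "n_accessions") <- n
  class(out) <- c("rareness", "data.frame")
  out
}

#' The five ordered rareness class labels
#'
#' @return Character vector, most common first.
#' @export
rareness_classes <- function() {
  c("very_common", "common", "average", "rare", "very_rare")
}

#' Assign five-class rareness labels
#'
#' Cuts the empirical distribution of `R` at four quantile levels into five
#' ordered classes (very common, common, average, rare, very rare). A value
#' that ties a class boundary is assigned to the rarer class, so a
#' degenerate distribution (all `R` equal) yields a single deterministic
#' label.
#'
#' @param r a `rareness` data frame from [rareness_coefficients()].
#' @param breaks four strictly increasing quantile levels in (0, 1). The
#'   defaults put roughly 40/20/17/20/3 percent of accessions in the five
#'   classes.
#' @return `r` with the `class` column filled; attribute `class_breaks`
#'   records the cut points used.
#' @export
classify_rareness <- function(r, breaks = c(0.40, 0.60, 0.77, 0.97)) {
  stopifnot(inherits(r, "rareness"))
  if (length(breaks) != 4L || any(diff(breaks) <= 0) ||
      any(breaks <= 0) || any(breaks >= 1))
    stop("'breaks' must be four strictly increasing quantile levels in (0, 1)")
  q <- stats::quantile(r$R, probs = breaks, names = FALSE, type = 7)
  idx <- 1L + rowSums(outer(r$R, q, ">="))
  r$class <- factor(rareness_classes()[idx], levels = rareness_classes(),
                    ordered = TRUE)
  attr(r, "class_breaks") <- q
  attr(r, "break_levels") <- breaks
  r
}

#' @export
print.rareness <- function(x, ...) {
  cat(sprintf("Rareness coefficients for %d accessions\n", nrow(x)))
  cat(sprintf("  R: min %.4g, median %.4g, max %.4g\n",
              min(x$R), stats::median(x$R), max(x$R)))
  if (!all(is.na(x$class))) {
    tab <- table(x$class)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.rareness <- function(object, ...) {
  out <- list(R = summary(object$R),
              class = if (all(is.na(object$class))) NULL else table(object$class),
              class_breaks = attr(object, "class_breaks"))
  class(out) <- "summary.rareness"
  out
}

#' @export
print.summary.rareness <- function(x, ...) {
  cat("Rareness coefficient summary\n")
  print(x$R)
  if (!is.null(x$class)) {
    cat("Class counts:\n")
    print(x$class)
  }
  invisible(x)
}
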