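#' Euclidean distances between bulks or accessions
#'
#' Pairwise Euclidean distances between the binary bulk profiles (bulk
#' level, entities labelled `"accession.bulk"`) or between the z-score
#' profiles (accession level).
#'
#' @param m a [bulk_matrix()] or [accession_matrix()].
#' @return A `stats::dist` object with attribute `level` set to `"bulk"` or
#'   `"accession"`.
#' @export
pairwise_distances <- function(m) {
  if (inherits(m, "bulk_matrix")) {
    x <- m$scores
    level <- "bulk"
  } else if (inherits(m, "accession_matrix")) {
    x <- m$z
    level <- "accession"
  } else stop("'m' must be a bulk_matrix or accession_matrix")
  if (nrow(x) < 2L) stop("need at least 2 entities for pairwise distances")
  d <- stats::dist(x, method = "euclidean")
  attr(d, "level") <- level
  d
}

#' Within- versus between-accession distance statistics
#'
#' Splits the bulk-level pairwise distances into pairs of bulks from the
#' same accession (within) and pairs from different accessions (between) and
#' compares the two populations with a Welch two-sample t-test. Pair
#' distances are not mutually independent, so the t-test p-value is an
#' approximation; an optional permutation test (accession labels permuted
#' over bulks) is available via `permutations`.
#'
#' @param d bulk-level `dist` from [pairwise_distances()], or a
#'   [bulk_matrix()] (distances computed internally).
#' @param accession accession id per entity of `d`; derived from the
#'   `"accession.bulk"` labels when omitted.
#' @param permutations optional number of label permutations for a
#'   permutation p-value (0 = none).
#' @param seed RNG seed for the permutation test.
#' @return A `wb_stats` list: `mean_within`, `mean_between`,
#'   `median_within`, `median_between`, `ratio_between_over_within`,
#'   `t_statistic`, `p_value`, `n_within_pairs`, `n_between_pairs`,
#'   `range_all`, `mean_all`, `median_all`, and `perm_p_value` if requested.
#'   Degenerate inputs (all distances equal) report `NA` statistics with a
#'   `note`.
#' @export
within_between_stats <- function(d, accession = NULL, permutations = 0L,
                                 seed = NULL) {
  if (inherits(d, "bulk_matrix")) {
    accession <- d$accession
    d <- pairwise_distances(d)
  }
  stopifnot(inherits(d, "dist"))
  labs <- attr(d, "Labels")
  if (is.null(accession)) {
    if (is.null(labs)) stop("no labels on 'd'; supply 'accession'")
    accession <- sub("\\.[^.]*$", "", labs)
  }
  n <- attr(d, "Size")
  if (length(accession) != n)
    stop("'accession' must have one entry per entity of 'd'")

  dm <- as.matrix(d)
  same <- outer(accession, accession, "==")
  ut <- upper.tri(dm)
  within <- dm[ut & same]
  between <- dm[ut & !same]
  if (!length(within))
    stop("no within-accession pairs (need >= 2 bulks for some accession)")
  if (!length(between))
    stop("no between-accession pairs (need >= 2 accessions)")

  all_d <- dm[ut]
  out <- list(
    mean_within = mean(within), mean_between = mean(between),
    median_within = stats::median(within),
    median_between = stats::median(between),
    ratio_between_over_within = mean(between) / mean(within),
    n_within_pairs = length(within), n_between_pairs = length(between),
    mean_all = mean(all_d), median_all = stats::median(all_d),
    range_all = range(all_d))

  sw <- stats::sd(within); sb <- stats::sd(between)
  if (length(within) < 2L || length(between) < 2L || (sw == 0 && sb == 0)) {
    out$t_statistic <- NA_real_
    out$p_value <- NA_real_
    out$note <- "pair-distance populations too small or constant; t-test undefined"
  } else {
    tt <- stats::t.test(between, within, var.equal = FALSE)
    out$t_statistic <- unname(tt$statistic)
    out$p_value <- tt$p.value
  }

  if (permutations > 0L) {
    if (!is.null(seed)) set.seed(seed)
    obs <- out$mean_between - out$mean_within
    perm <- replicate(permutations, {
      g <- sample(accession)
      sg <- outer(g, g, "==")
      mean(dm[ut & !sg]) - mean(dm[ut & sg])
    })
    out$perm_p_value <- (sum(perm >= obs) + 1) / (permutations + 1)
  }
  structure(out, class = "wb_stats")
}

#' @export
print.wb_stats <- function(x, ...) {
  cat("Within/between-accession bulk distances\n")
  cat(sprintf("  all pairs:  mean %.2f, median %.2f, range %.2f-%.2f\n",
              x$mean_all, x$median_all, x$range_all[1], x$range_all[2]))
  cat(sprintf("  within:  mean %.2f (median %.2f, n = %d)\n",
              x$mean_within, x$median_within, x$n_within_pairs))
  cat(sprintf("  between: mean %.2f (median %.2f, n = %d)\n",
              x$mean_between, x$median_between, x$n_between_pairs))
  cat(sprintf("  between/within ratio: %.3f\n", x$ratio_between_over_within))
  if (is.na(x$t_statistic)) cat("  t-test: undefined -", x$note, "\n")
  else cat(sprintf("  Welch t = %.3f, p = %.3g\n", x$t_statistic, x$p_value))
  if (!is.null(x$perm_p_value))
    cat(sprintf("  permutation p = %.3g\n", x$perm_p_value))
  invisible(x)
}

#' UPGMA clustering
#'
#' Average-linkage agglomerative clustering producing a rooted ultrametric
#' tree. Cluster distances are arithmetic averages weighted by cluster
#' sizes; each merge sits at half the merged distance so cophenetic
#' distances between leaves equal the merge distance of their lowest common
#' ancestor. Ties among minimal distances are broken by the
#' lexicographically smallest pair of cluster representative labels, making
#' the output reproducible and invariant to input ordering.
#'
#' @param d a symmetric `dist` object (or symmetric matrix) with entity
#'   labels.
#' @return An [ape::read.tree()] `phylo` object with branch lengths.
#' @export
upgma <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d))) stop("distance input must be symmetric")
    d <- stats::as.dist(d)
  }
  dm <- as.matrix(d)
  if (is.null(rownames(dm)))
    rownames(dm) <- colnames(dm) <- paste0("L", seq_len(nrow(dm)))
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 entities")

  newick <- rownames(dm)           # growing subtree strings
  height <- rep(0, n)              # height of each active cluster
  size <- rep(1L, n)
  rep_lab <- rownames(dm)          # representative (min) label per cluster
  active <- rep(TRUE, n)
  D <- dm

  for (merge in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    diag(sub) <- Inf
    dmin <- min(sub)
    hits <- which(sub == dmin, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # deterministic tie-break: smallest sorted pair of representative labels
    keys <- apply(hits, 1L, function(h) {
      p <- sort(c(rep_lab[idx[h[1]]], rep_lab[idx[h[2]]]))
      paste(p, collapse = "\r")
    })
    h <- hits[order(keys)[1L], ]
    i <- idx[h[1]]; j <- idx[h[2]]
    hnew <- dmin / 2
    part <- c(
      sprintf("%s:%.12g", newick[i], hnew - height[i]),
      sprintf("%s:%.12g", newick[j], hnew - height[j]))
    ord <- order(c(rep_lab[i], rep_lab[j]))
    merged <- paste0("(", paste(part[ord], collapse = ","), ")")

    # weighted average linkage to every other active cluster
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      dnew <- (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j])
      D[i, others] <- dnew
      D[others, i] <- dnew
    }
    newick[i] <- merged
    height[i] <- hnew
    size[i] <- size[i] + size[j]
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    active[j] <- FALSE
  }
  ape::read.tree(text = paste0(newick[which(active)], ";"))
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` object, e.g. from [upgma()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Jackknife column-exclusion sensitivity of the dendrogram
#'
#' Rebuilds the accession-level distances and UPGMA tree with each
#' marker/allele column left out in turn; the sensitivity of column `j` is
#' `1 - r` where `r` is the Pearson correlation between the cophenetic
#' distance vectors of the full and the reduced tree. Excluding an
#' uninformative (constant or duplicated) column leaves the distances
#' unchanged and scores 0.
#'
#' @param a an [accession_matrix()] with at least 2 columns.
#' @return Data frame with columns `column` and `sensitivity` (NA when a
#'   reduced tree's cophenetic distances are constant).
#' @export
jackknife_columns <- function(a) {
  stopifnot(inherits(a, "accession_matrix"))
  if (ncol(a$z) < 2L) stop("need at least 2 marker/allele columns")
  full <- stats::cophenetic(upgma(pairwise_distances(a)))
  ord <- rownames(full)
  v_full <- full[lower.tri(full)]
  sens <- vapply(seq_len(ncol(a$z)), function(j) {
    red <- accession_matrix(a$z[, -j, drop = FALSE], a$B)
    cop <- stats::cophenetic(upgma(pairwise_distances(red)))[ord, ord]
    v <- cop[lower.tri(cop)]
    if (stats::sd(v) == 0 || stats::sd(v_full) == 0) return(NA_real_)
    1 - stats::cor(v_full, v)
  }, numeric(1))
  data.frame(column = colnames(a$z), sensitivity = sens,
             stringsAsFactors = FALSE)
}

#' Geographic versus genetic distance correlation
#'
#' Great-circle (haversine, Earth radius 6371 km) distances between
#' collection sites are correlated with the accession-level genetic
#' distances: Pearson r between the two condensed distance vectors, with a
#' Mantel permutation p-value (via [vegan::mantel()]) when `permutations >
#' 0`.
#'
#' @param meta metadata data frame (see [read_metadata()]) with `accession`,
#'   `lat`, `lon` for every accession in `d`.
#' @param d accession-level `dist` from [pairwise_distances()].
#' @param permutations Mantel permutations (0 = correlation only).
#' @param seed RNG seed for the permutation test.
#' @return List of class `geo_correlation`: `r`, `mantel_p` (NULL if no
#'   permutations), `n`, `permutations`; `r` is `NA` with a `note` when one
#'   of the distance sets is constant.
#' @export
geo_genetic_correlation <- function(meta, d, permutations = 999L,
                                    seed = NULL) {
  stopifnot(inherits(d, "dist"))
  labs <- attr(d, "Labels")
  if (is.null(labs)) stop("'d' must carry accession labels")
  idx <- match(labs, meta$accession)
  missing_meta <- labs[is.na(idx)]
  if (length(missing_meta))
    stop(sprintf("no metadata for accession(s): %s",
                 paste(missing_meta, collapse = ", ")))
  lat <- meta$lat[idx]; lon <- meta$lon[idx]
  if (anyNA(lat) || anyNA(lon))
    stop(sprintf("missing coordinates for accession(s): %s",
                 paste(labs[is.na(lat) | is.na(lon)], collapse = ", ")))

  gm <- geosphere::distm(cbind(lon, lat),
                         fun = function(p1, p2)
                           geosphere::distHaversine(p1, p2, r = 6371000))
  gkm <- stats::as.dist(gm / 1000)

  out <- list(n = length(labs), permutations = as.integer(permutations))
  gsd <- stats::sd(as.vector(gkm)); dsd <- stats::sd(as.vector(d))
  if (is.na(gsd) || is.na(dsd) || gsd == 0 || dsd == 0) {
    out$r <- NA_real_
    out$mantel_p <- NULL
    out$note <- "a distance set is constant (or a single pair); correlation undefined"
  } else {
    out$r <- stats::cor(as.vector(gkm), as.vector(d))
    if (permutations > 0L) {
      if (!is.null(seed)) set.seed(seed)
      mt <- vegan::mantel(gkm, d, method = "pearson",
                          permutations = permutations)
      out$r <- unname(mt$statistic)
      out$mantel_p <- mt$signif
    } else out$mantel_p <- NULL
  }
  class(out) <- "geo_correlation"
  out
}

#' @export
print.geo_correlation <- function(x, ...) {
  cat(sprintf("Geographic vs genetic distance (n = %d accessions)\n", x$n))
  if (is.na(x$r)) cat("  r undefined -", x$note, "\n")
  else {
    cat(sprintf("  Pearson r = %.4f\n", x$r))
    if (!is.null(x$mantel_p))
      cat(sprintf("  Mantel p = %.4g (%d permutations)\n",
                  x$mantel_p, x$permutations))
  }
  invisible(x)
}
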