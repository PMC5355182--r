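#' Bulk-level binary marker/allele matrix
#'
#' Container for bulked SSR genotyping data scored as presence (1) or absence
#' (0) of each marker/allele combination in each DNA bulk. Rows are bulks
#' (`B` consecutive rows per accession, in accession order), columns are
#' marker/allele combinations labelled `"MARKER_allele"` (e.g. `"PHI015_80"`;
#' the allele part is kept as a string so null alleles can be labelled
#' `"null"`).
#'
#' @param scores numeric or integer matrix of 0/1 scores; one row per
#'   (accession, bulk), one column per marker/allele combination, with column
#'   names in `"MARKER_allele"` format.
#' @param accession character vector, one entry per row of `scores`, giving
#'   the accession each bulk belongs to.
#' @param bulk integer vector, one entry per row, giving the bulk index
#'   (1..B) within its accession.
#' @param bulks_per_accession number of bulks per accession (B, default 3).
#'
#' @return An object of class `bulk_matrix` with fields `scores`,
#'   `accession`, `bulk` and `B`.
#' @seealso [read_bulk_calls()], [collapse_bulks()], [validate()]
#' @export
bulk_matrix <- function(scores, accession, bulk, bulks_per_accession = 3L) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  accession <- as.character(accession)
  bulk <- as.integer(bulk)
  if (nrow(scores) != length(accession) || nrow(scores) != length(bulk))
    stop("'accession' and 'bulk' must each have one entry per row of 'scores'")
  if (is.null(colnames(scores)) && ncol(scores) > 0L)
    stop("'scores' must have marker/allele column names")
  rownames(scores) <- paste(accession, bulk, sep = ".")
  structure(
    list(scores = scores, accession = accession, bulk = bulk,
         B = as.integer(bulks_per_accession)),
    class = "bulk_matrix"
  )
}

#' Accession-level z-score matrix
#'
#' Container for accession-level scores: `z[i, j]` counts in how many of the
#' B bulks of accession `i` the marker/allele combination `j` was detected,
#' so every entry lies in 0..B.
#'
#' @param z integer matrix, accessions x marker/allele combinations, with
#'   accession row names and `"MARKER_allele"` column names.
#' @param bulks_per_accession number of bulks each accession was genotyped
#'   as (B, default 3).
#'
#' @return An object of class `accession_matrix` with fields `z` and `B`.
#' @export
accession_matrix <- function(z, bulks_per_accession = 3L) {
  z <- as.matrix(z)
  storage.mode(z) <- "integer"
  if (is.null(rownames(z)))
    stop("'z' must have accession row names")
  if (is.null(colnames(z)) && ncol(z) > 0L)
    stop("'z' must have marker/allele column names")
  structure(list(z = z, B = as.integer(bulks_per_accession)),
            class = "accession_matrix")
}

#' @export
print.bulk_matrix <- function(x, ...) {
  cat(sprintf("Bulk-level marker/allele matrix: %d accessions x %d bulks, %d columns\n",
              length(unique(x$accession)), x$B, ncol(x$scores)))
  cat(sprintf("  %d rows (bulks), %.1f%% presence calls\n",
              nrow(x$scores),
              if (length(x$scores)) 100 * mean(x$scores) else 0))
  invisible(x)
}

#' @export
print.accession_matrix <- function(x, ...) {
  cat(sprintf("Accession-level z matrix: %d accessions x %d columns (B = %d)\n",
              nrow(x$z), ncol(x$z), x$B))
  invisible(x)
}

#' @export
dim.bulk_matrix <- function(x) dim(x$scores)

#' @export
dim.accession_matrix <- function(x) dim(x$z)

# Split "MARKER_allele" labels at the last underscore.
parse_column_labels <- function(labels) {
  marker <- sub("_[^_]*$", "", labels)
  allele <- sub("^.*_", "", labels)
  ok <- grepl("_", labels, fixed = TRUE) & nzchar(marker) & nzchar(allele)
  data.frame(label = labels, marker = marker, allele = allele, ok = ok,
             stringsAsFactors = FALSE)
}

#' Read long-format bulk allele calls
#'
#' Reads a CSV of per-bulk allele detections (one row per detected allele per
#' bulk, columns `accession,bulk,marker,allele`) into a [bulk_matrix()]. The
#' matrix columns are the union of observed (marker, allele) pairs, sorted
#' lexicographically by marker then allele label; pairs absent from a bulk
#' are scored 0 and duplicate rows collapse to a single presence.
#'
#' @param path CSV file with header `accession,bulk,marker,allele`.
#' @param bulks_per_accession bulks per accession B (default 3); bulk indices
#'   in the file must lie in 1..B.
#' @param accessions optional character vector declaring the accession set
#'   (and order). Needed to represent accessions with no detected alleles,
#'   e.g. for an empty call file.
#'
#' @return A [bulk_matrix()] with `length(accessions)` (or the number of
#'   distinct accessions observed) times B rows.
#' @export
read_bulk_calls <- function(path, bulks_per_accession = 3L, accessions = NULL) {
  B <- as.integer(bulks_per_accession)
  calls <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("accession", "bulk", "marker", "allele")
  if (!all(required %in% names(calls)))
    stop("call file must have header columns accession,bulk,marker,allele")
  calls <- calls[required]

  if (nrow(calls)) {
    bad <- which(!stats::complete.cases(calls) |
                   apply(calls == "", 1L, any) |
                   is.na(suppressWarnings(as.integer(calls$bulk))))
    if (length(bad))
      stop(sprintf("malformed call row(s) at line(s): %s",
                   paste(bad + 1L, collapse = ", ")))
    calls$bulk <- as.integer(calls$bulk)
    off <- unique(calls$accession[calls$bulk < 1L | calls$bulk > B])
    if (length(off))
      stop(sprintf("bulk index outside 1..%d for accession(s): %s",
                   B, paste(sort(off), collapse = ", ")))
  } else {
    calls$bulk <- integer(0)
  }

  acc <- if (!is.null(accessions)) as.character(accessions)
         else unique(calls$accession)
  if (!length(acc))
    stop("no accessions: empty call file and no 'accessions' declared")
  unknown <- setdiff(unique(calls$accession), acc)
  if (length(unknown))
    stop(sprintf("call rows for undeclared accession(s): %s",
                 paste(sort(unknown), collapse = ", ")))

  pairs <- unique(calls[c("marker", "allele")])
  pairs <- pairs[order(pairs$marker, pairs$allele), , drop = FALSE]
  labels <- if (nrow(pairs)) paste(pairs$marker, pairs$allele, sep = "_")
            else character(0)

  scores <- matrix(0L, nrow = length(acc) * B, ncol = length(labels),
                   dimnames = list(NULL, labels))
  row_acc <- rep(acc, each = B)
  row_bulk <- rep(seq_len(B), times = length(acc))
  if (nrow(calls)) {
    i <- match(calls$accession, acc) * B - B + calls$bulk
    j <- match(paste(calls$marker, calls$allele, sep = "_"), labels)
    scores[cbind(i, j)] <- 1L
  }
  bulk_matrix(scores, row_acc, row_bulk, B)
}

#' Collapse bulks to accession-level z-scores
#'
#' Sums the binary presence scores over the B bulks of each accession,
#' yielding the z-score matrix: `z[i, j]` is the number of bulks of accession
#' `i` presenting combination `j` (0..B).
#'
#' @param m a [bulk_matrix()].
#' @return An [accession_matrix()] with accessions in their original order.
#' @export
collapse_bulks <- function(m) {
  stopifnot(inherits(m, "bulk_matrix"))
  acc <- unique(m$accession)
  z <- rowsum(m$scores, group = factor(m$accession, levels = acc))
  storage.mode(z) <- "integer"
  accession_matrix(z[acc, , drop = FALSE], m$B)
}

#' Validate a marker/allele matrix
#'
#' Checks the structural invariants of a matrix and reports violations
#' rather than erroring: binary values and exactly B bulk rows per accession
#' (bulk level), z in 0..B (accession level), unique parseable
#' `"MARKER_allele"` column labels, and no accession with an all-zero
#' profile (unless `allow_empty_accessions = TRUE`).
#'
#' @param x a [bulk_matrix()] or [accession_matrix()].
#' @param allow_empty_accessions if `TRUE`, accessions with no detected
#'   alleles are not reported.
#' @param ... unused.
#' @return A data frame with columns `code`, `entity`, `message`; zero rows
#'   iff all invariants hold.
#' @export
validate <- function(x, ...) UseMethod("validate")

violation <- function(code, entity, message) {
  data.frame(code = code, entity = entity, message = message,
             stringsAsFactors = FALSE)
}

validate_labels <- function(labels) {
  out <- violation(character(0), character(0), character(0))
  dup <- unique(labels[duplicated(labels)])
  for (d in dup)
    out <- rbind(out, violation("duplicate_column", d, "duplicate column label"))
  parsed <- parse_column_labels(labels)
  for (b in parsed$label[!parsed$ok])
    out <- rbind(out, violation("bad_label", b,
                                "label does not parse as MARKER_allele"))
  out
}

#' @rdname validate
#' @export
validate.bulk_matrix <- function(x, allow_empty_accessions = FALSE, ...) {
  out <- validate_labels(colnames(x$scores))
  bad <- !(x$scores %in% c(0L, 1L))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(x$scores)), arr.ind = TRUE)
    for (k in seq_len(nrow(idx)))
      out <- rbind(out, violation(
        "non_binary_value",
        sprintf("%s[,%s]", rownames(x$scores)[idx[k, 1]],
                colnames(x$scores)[idx[k, 2]]),
        sprintf("non-binary value %s", x$scores[idx[k, 1], idx[k, 2]])))
  }
  counts <- table(factor(x$accession, levels = unique(x$accession)))
  for (a in names(counts)[counts != x$B])
    out <- rbind(out, violation(
      "bulk_count_mismatch", a,
      sprintf("bulk count mismatch: %d bulks, expected %d", counts[[a]], x$B)))
  for (a in unique(x$accession)) {
    rows <- x$accession == a
    b <- sort(x$bulk[rows])
    if (length(b) == x$B && !identical(b, seq_len(x$B)))
      out <- rbind(out, violation("bad_bulk_index", a,
                                  "bulk indices are not 1..B"))
    if (!allow_empty_accessions && sum(x$scores[rows, , drop = FALSE]) == 0L)
      out <- rbind(out, violation("empty_accession", a,
                                  "accession has no detected alleles"))
  }
  out
}

#' @rdname validate
#' @export
validate.accession_matrix <- function(x, allow_empty_accessions = FALSE, ...) {
  out <- validate_labels(colnames(x$z))
  bad <- x$z < 0L | x$z > x$B
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    for (k in seq_len(nrow(idx)))
      out <- rbind(out, violation(
        "z_out_of_range",
        sprintf("%s[,%s]", rownames(x$z)[idx[k, 1]], colnames(x$z)[idx[k, 2]]),
        sprintf("z value %d outside 0..%d", x$z[idx[k, 1], idx[k, 2]], x$B)))
  }
  dup <- unique(rownames(x$z)[duplicated(rownames(x$z))])
  for (d in dup)
    out <- rbind(out, violation("duplicate_accession", d,
                                "duplicate accession id"))
  if (!allow_empty_accessions && ncol(x$z) > 0L)
    for (a in rownames(x$z)[rowSums(x$z) == 0L])
      out <- rbind(out, violation("empty_accession", a,
                                  "accession has no detected alleles"))
  out
}

#' Write a matrix to wide-format CSV
#'
#' Bulk matrices are written with identifier columns `accession,bulk` and
#' accession matrices with `accession`, followed by one column per
#' marker/allele label, preserving column order verbatim. The matching
#' [read_matrix()] round-trips bit-exactly.
#'
#' @param m a [bulk_matrix()] or [accession_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  if (inherits(m, "bulk_matrix")) {
    df <- data.frame(accession = m$accession, bulk = m$bulk,
                     check.names = FALSE, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(m$scores, check.names = FALSE))
  } else if (inherits(m, "accession_matrix")) {
    df <- data.frame(accession = rownames(m$z),
                     check.names = FALSE, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(m$z, check.names = FALSE))
  } else stop("'m' must be a bulk_matrix or accession_matrix")
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a wide-format matrix CSV
#'
#' Detects the dialect from the header: a `bulk` column marks bulk-level
#' binary scores, otherwise the file is read as accession-level z-scores.
#'
#' @param path CSV written by [write_matrix()] (or equivalent).
#' @param bulks_per_accession B to record on the result (default 3; for a
#'   bulk-level file the observed per-accession row count must agree).
#' @return A [bulk_matrix()] or [accession_matrix()].
#' @export
read_matrix <- function(path, bulks_per_accession = 3L) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if ("bulk" %in% names(df)) {
    labels <- setdiff(names(df), c("accession", "bulk"))
    scores <- as.matrix(df[labels])
    bulk_matrix(scores, df$accession, df$bulk, bulks_per_accession)
  } else {
    labels <- setdiff(names(df), "accession")
    z <- as.matrix(df[labels])
    rownames(z) <- df$accession
    accession_matrix(z, bulks_per_accession)
  }
}

#' Read accession metadata
#'
#' Reads the passport/phenotype CSV with columns
#' `accession,race1,race2,kernel_color,lat,lon,masl`. Empty `race2` entries
#' (accessions with a single race classification) become `NA`.
#'
#' @param path metadata CSV path.
#' @return A data frame, one row per accession, with numeric `lat`, `lon`
#'   and `masl`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("accession", "race1", "race2", "kernel_color",
                "lat", "lon", "masl")
  if (!all(required %in% names(df)))
    stop("metadata must have columns accession,race1,race2,kernel_color,lat,lon,masl")
  df$race2[!is.na(df$race2) & df$race2 == ""] <- NA
  for (col in c("lat", "lon", "masl")) df[[col]] <- as.numeric(df[[col]])
  bad <- df$accession[!is.na(df$lat) & abs(df$lat) > 90 |
                        !is.na(df$lon) & abs(df$lon) > 180 |
                        !is.na(df$masl) & df$masl < 0]
  if (length(bad))
    stop(sprintf("out-of-range coordinates or altitude for: %s",
                 paste(bad, collapse = ", ")))
  df
}
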