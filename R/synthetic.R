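#' Probability of detecting an allele in a DNA bulk
#'
#' A bulk of `n` diploid plants pools `n * ploidy` haplotypes; an allele at
#' within-accession frequency `p` is scored present when at least one
#' pooled haplotype carries it:
#'
#' \deqn{P(\mathrm{detect}) = 1 - (1 - p)^{n \cdot \mathrm{ploidy}}}
#'
#' A bulk of 10 diploid plants therefore detects an allele at frequency 0.1
#' with probability \eqn{1 - 0.9^{20} \approx 0.878}; bulk scoring yields
#' presence, not a direct allele-frequency estimate.
#'
#' @param p allele frequency within the accession, in \[0, 1\] (vectorized).
#' @param plants_per_bulk number of plants pooled per bulk (default 10).
#' @param ploidy haplotypes per plant (default 2).
#' @return Detection probability in \[0, 1\].
#' @export
detection_probability <- function(p, plants_per_bulk = 10L, ploidy = 2L) {
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
  if (any(plants_per_bulk < 1L)) stop("'plants_per_bulk' must be >= 1")
  1 - (1 - p)^(plants_per_bulk * ploidy)
}

# Dirichlet draw (one vector) via normalized gammas.
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulation configuration for bulked SSR genotyping
#'
#' Defines a landrace-like collection design: races with diverged SSR
#' allele frequencies, accessions drawn around their race, and per-accession
#' DNA bulks of pooled plants scored for allele presence. The defaults
#' mirror a 185-accession collection genotyped at 14 SSR loci as 3 bulks of
#' 10 diploid plants per accession with 16 races.
#'
#' @param n_accessions number of accessions (default 185).
#' @param n_markers number of SSR loci (default 14).
#' @param alleles_per_marker integer vector of allele counts per marker
#'   (recycled), or `NULL` to draw uniformly from `allele_range`.
#' @param allele_range inclusive range alleles-per-marker are drawn from
#'   when `alleles_per_marker` is `NULL` (default 9..25, the span observed
#'   for maize SSRs of this panel).
#' @param n_races number of race labels (default 16).
#' @param race_concentration total Dirichlet concentration of race base
#'   frequencies around the collection base; smaller = more divergence
#'   between races (default 10, i.e. race-level F_ST around 0.09).
#' @param accession_concentration total concentration of accession
#'   frequencies around their race base (default 150: accessions of one
#'   race stay related but distinct, and between-accession bulk distances
#'   exceed within-accession ones by the 20-40% seen in real landrace
#'   collections).
#' @param bulks_per_accession bulks per accession B (default 3).
#' @param plants_per_bulk plants pooled per bulk (default 10).
#' @param ploidy haplotypes per plant (default 2).
#' @param planted_rare optional data frame `accession` (index or id),
#'   `marker` (index), `allele` (new private allele label), `freq`
#'   (within-accession frequency): plants a private allele in that
#'   accession, scaling its other allele frequencies by `1 - freq`.
#' @param masl_effects optional data frame `marker`, `allele` (index within
#'   marker), `slope`: the allele's per-bulk detection probability follows
#'   a logistic curve in standardized altitude (log-odds slope = `slope`),
#'   with its sibling alleles sharing the complementary frequency
#'   proportionally - an altitude-correlated allele.
#' @param false_negative_rate per bulk-allele probability that a true
#'   presence is scored absent, emulating occasional PCR failure / null
#'   alleles (default 0.005, i.e. ~0.5% of calls).
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_accessions = 185L, n_markers = 14L,
                       alleles_per_marker = NULL, allele_range = c(9L, 25L),
                       n_races = 16L, race_concentration = 10,
                       accession_concentration = 150,
                       bulks_per_accession = 3L, plants_per_bulk = 10L,
                       ploidy = 2L, planted_rare = NULL, masl_effects = NULL,
                       false_negative_rate = 0.005, seed = NULL) {
  cfg <- list(n_accessions = as.integer(n_accessions),
              n_markers = as.integer(n_markers),
              alleles_per_marker = alleles_per_marker,
              allele_range = as.integer(allele_range),
              n_races = as.integer(n_races),
              race_concentration = race_concentration,
              accession_concentration = accession_concentration,
              bulks_per_accession = as.integer(bulks_per_accession),
              plants_per_bulk = as.integer(plants_per_bulk),
              ploidy = as.integer(ploidy),
              planted_rare = planted_rare, masl_effects = masl_effects,
              false_negative_rate = false_negative_rate, seed = seed)
  stopifnot(cfg$n_accessions >= 1L, cfg$n_markers >= 1L, cfg$n_races >= 1L,
            cfg$bulks_per_accession >= 1L, cfg$plants_per_bulk >= 1L,
            cfg$ploidy >= 1L,
            cfg$false_negative_rate >= 0, cfg$false_negative_rate < 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a bulked SSR genotyping study
#'
#' Draws a landrace-like collection under a [sim_config()]: per marker a
#' collection-wide base allele-frequency vector, per race a Dirichlet
#' perturbation of it, per accession a perturbation of its race; each bulk
#' then draws `plants_per_bulk * ploidy` haplotypes per marker from the
#' accession frequencies and scores each allele present when drawn at least
#' once (optionally dropped by the false-negative rate). Accession altitude
#' (MASL) and coordinates are race-clustered so altitude and geography carry
#' signal; planted private alleles and altitude effects from the config are
#' applied to the frequency vectors before sampling. Matrix columns span
#' the full configured allele universe, so the column set is deterministic
#' even when an allele happens never to be drawn.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_collection`: `bulks` ([bulk_matrix()]),
#'   `metadata` (accession, race1, race2, kernel_color, lat, lon, masl) and
#'   `truth` (per-accession allele frequencies, race assignment, planted
#'   rare accessions, masl effects, config).
#' @export
simulate_collection <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nA <- cfg$n_accessions; nM <- cfg$n_markers; B <- cfg$bulks_per_accession
  H <- cfg$plants_per_bulk * cfg$ploidy

  n_alleles <- if (!is.null(cfg$alleles_per_marker))
    rep_len(as.integer(cfg$alleles_per_marker), nM)
  else sample(cfg$allele_range[1]:cfg$allele_range[2], nM, replace = TRUE)
  markers <- sprintf("SSR%02d", seq_len(nM))
  # zero-padded fragment-size labels keep lexicographic = numeric order
  allele_labels <- lapply(seq_len(nM), function(k)
    sprintf("%03d", sort(sample(60:320, n_alleles[k]))))

  acc_ids <- sprintf("A%03d", seq_len(nA))
  race_of <- sort(rep_len(seq_len(cfg$n_races), nA))
  race_ids <- sprintf("R%02d", race_of)

  # race-clustered altitude and coordinates (Puebla-like bounding box)
  race_masl <- stats::runif(cfg$n_races, 1200, 2900)
  race_lat <- stats::runif(cfg$n_races, 18.1, 20.7)
  race_lon <- stats::runif(cfg$n_races, -98.7, -97.1)
  masl <- pmax(0, race_masl[race_of] + stats::rnorm(nA, 0, 180))
  lat <- pmin(20.8, pmax(18.0, race_lat[race_of] + stats::rnorm(nA, 0, 0.15)))
  lon <- pmin(-97.0, pmax(-98.8, race_lon[race_of] + stats::rnorm(nA, 0, 0.15)))
  masl_std <- if (stats::sd(masl) > 0) (masl - mean(masl)) / stats::sd(masl)
              else rep(0, nA)

  # frequency hierarchy: base -> race -> accession
  base <- lapply(n_alleles, function(A) rdirichlet1(rep(0.8, A)))
  race_freq <- lapply(seq_len(nM), function(k)
    t(vapply(seq_len(cfg$n_races), function(r)
      rdirichlet1(base[[k]] * cfg$race_concentration),
      numeric(n_alleles[k]))))
  freqs <- lapply(seq_len(nA), function(i)
    lapply(seq_len(nM), function(k)
      rdirichlet1(race_freq[[k]][race_of[i], ] *
                    cfg$accession_concentration)))

  # altitude effects: the slope acts on the log-odds of per-bulk detection,
  # so the allele's presence score sweeps its full range across altitudes
  # (a logistic directly on the frequency would saturate: pooling n*ploidy
  # haplotypes detects any frequency above ~0.2 almost surely). The allele
  # frequency is the detection probability inverted through
  # 1 - (1 - p)^H; siblings share the complement proportionally.
  if (!is.null(cfg$masl_effects)) {
    eff <- cfg$masl_effects
    for (e in seq_len(nrow(eff))) {
      k <- eff$marker[e]; al <- eff$allele[e]; s <- eff$slope[e]
      for (i in seq_len(nA)) {
        f <- freqs[[i]][[k]]
        detect <- stats::plogis(s * masl_std[i])
        target <- 1 - (1 - detect)^(1 / H)
        rest <- sum(f[-al])
        f[-al] <- if (rest > 0) f[-al] * (1 - target) / rest
                  else (1 - target) / (length(f) - 1)
        f[al] <- target
        freqs[[i]][[k]] <- f
      }
    }
  }

  # planted private rare alleles (extra column per planting)
  planted <- cfg$planted_rare
  if (!is.null(planted)) {
    planted$accession_id <- if (is.numeric(planted$accession))
      acc_ids[planted$accession] else as.character(planted$accession)
    # extend each affected marker's allele universe, then re-sort
    for (k in unique(planted$marker)) {
      labs <- unique(as.character(planted$allele[planted$marker == k]))
      clash <- labs[labs %in% allele_labels[[k]]]
      if (length(clash))
        stop(sprintf("planted allele '%s' collides with an existing allele of %s",
                     clash[1], markers[k]))
      allele_labels[[k]] <- c(allele_labels[[k]], labs)
      for (i in seq_len(nA))
        freqs[[i]][[k]] <- c(freqs[[i]][[k]], numeric(length(labs)))
      ord <- order(allele_labels[[k]])
      allele_labels[[k]] <- allele_labels[[k]][ord]
      for (i in seq_len(nA)) freqs[[i]][[k]] <- freqs[[i]][[k]][ord]
    }
    for (e in seq_len(nrow(planted))) {
      i <- match(planted$accession_id[e], acc_ids)
      k <- planted$marker[e]
      slot <- match(as.character(planted$allele[e]), allele_labels[[k]])
      f <- freqs[[i]][[k]] * (1 - planted$freq[e])
      f[slot] <- planted$freq[e]
      freqs[[i]][[k]] <- f
    }
  }

  columns <- unlist(lapply(seq_len(nM), function(k)
    paste(markers[k], allele_labels[[k]], sep = "_")))
  col_offset <- c(0L, cumsum(vapply(allele_labels, length, 1L)))

  scores <- matrix(0L, nrow = nA * B, ncol = length(columns),
                   dimnames = list(NULL, columns))
  for (i in seq_len(nA)) {
    for (b in seq_len(B)) {
      row <- (i - 1L) * B + b
      for (k in seq_len(nM)) {
        counts <- stats::rmultinom(1L, H, freqs[[i]][[k]])[, 1L]
        present <- counts > 0L
        if (cfg$false_negative_rate > 0 && any(present)) {
          drop <- stats::runif(sum(present)) < cfg$false_negative_rate
          present[present][drop] <- FALSE
        }
        scores[row, col_offset[k] + which(present)] <- 1L
      }
    }
  }

  bulks <- bulk_matrix(scores, rep(acc_ids, each = B),
                       rep(seq_len(B), nA), B)
  kernel_colors <- c("white", "yellow", "blue", "red", "purple", "mixed")
  race2 <- ifelse(stats::runif(nA) < 0.3,
                  sprintf("R%02d", sample(cfg$n_races, nA, replace = TRUE)),
                  NA_character_)
  metadata <- data.frame(
    accession = acc_ids, race1 = race_ids, race2 = race2,
    kernel_color = sample(kernel_colors, nA, replace = TRUE,
                          prob = c(0.35, 0.3, 0.12, 0.1, 0.08, 0.05)),
    lat = lat, lon = lon, masl = masl, stringsAsFactors = FALSE)

  truth <- list(freqs = freqs, markers = markers,
                allele_labels = allele_labels, race = race_ids,
                planted_rare = planted, masl_effects = cfg$masl_effects,
                masl = masl, config = cfg)
  structure(list(bulks = bulks, metadata = metadata, truth = truth),
            class = "sim_collection")
}

#' @export
print.sim_collection <- function(x, ...) {
  cat(sprintf("Simulated bulked SSR collection: %d accessions x %d bulks, %d marker/allele columns\n",
              length(unique(x$bulks$accession)), x$bulks$B,
              ncol(x$bulks$scores)))
  if (!is.null(x$truth$planted_rare))
    cat(sprintf("  %d planted rare accession(s)\n",
                length(unique(x$truth$planted_rare$accession_id))))
  invisible(x)
}

#' Built-in fixtures
#'
#' Small deterministic datasets used throughout the documentation and
#' tests:
#' \describe{
#'   \item{`"F1"`}{the 3-accession, 3-column hand example (B = 1) whose
#'     rareness coefficients are 1/3, 1/9 and 2/9 and whose AMA core is
#'     `A, C`.}
#'   \item{`"F2"`}{a seeded 5-accession x 3-bulk collection at 3 SSR loci.}
#'   \item{`"study_shape"`}{a seeded 240-accession x 3-bulk collection with
#'     36 race labels and exactly 278 marker/allele columns (720 x 278 at
#'     bulk level), matching the shape of a full landrace study.}
#' }
#'
#' @param name one of `"F1"`, `"F2"`, `"study_shape"`.
#' @return A list with elements `bulks` ([bulk_matrix()]; `NULL` for the
#'   accession-level `"F1"`), `accessions` ([accession_matrix()]) and
#'   `metadata` (where applicable).
#' @export
make_fixture <- function(name = c("F1", "F2", "study_shape")) {
  name <- match.arg(name)
  if (name == "F1") {
    z <- matrix(c(1L, 1L, 0L,
                  0L, 1L, 1L,
                  0L, 0L, 1L), nrow = 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"),
                                c("SSR01_080", "SSR01_083", "SSR02_120")))
    b <- bulk_matrix(z, c("A", "B", "C"), c(1L, 1L, 1L),
                     bulks_per_accession = 1L)
    return(list(bulks = b, accessions = accession_matrix(z, 1L),
                metadata = NULL))
  }
  if (name == "F2") {
    cfg <- sim_config(n_accessions = 5L, n_markers = 3L,
                      alleles_per_marker = c(3L, 4L, 2L), n_races = 2L,
                      false_negative_rate = 0, seed = 20202L)
  } else {
    # 14 markers whose allele counts sum to 278 columns
    cfg <- sim_config(n_accessions = 240L, n_markers = 14L,
                      alleles_per_marker = c(rep(20L, 12L), 19L, 19L),
                      n_races = 36L, seed = 27817L)
  }
  sim <- simulate_collection(cfg)
  list(bulks = sim$bulks, accessions = collapse_bulks(sim$bulks),
       metadata = sim$metadata)
}
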