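power_law_shares <- function(k, exponent = 1) {
  w <- (seq_len(k))^(-exponent)
  w / sum(w)
}

#' Configuration for a synthetic cohort
#'
#' Defines the statistical structure of a simulated two-group cohort from
#' one mucosal habitat.  Two habitat profiles are available:
#' `"lactobacillus_dominant"` - a low-diversity community in which the
#' first species holds `dominance_fraction` of the expected mass (the
#' 90-95% lactobacilli share typical of the vagina; default 0.92) and the
#' remainder follows a 1/rank power law - and `"polymicrobial"`, where
#' all species follow the power law (a more complex, higher-diversity
#' spectrum).
#'
#' Latent dependence is a Gaussian copula: within each listed block the
#' latent normals share a constant correlation `rho >= 0` (always
#' positive semi-definite); biomarkers add a `log2_effect` shift to the
#' log-abundance of one species in one outcome group.  Structural zeros
#' are drawn per sample x species with probability `dropout` (the
#' dominant species is exempt in the lactobacillus profile - it is
#' structurally present).  Sequencing depth is log-normal around
#' `depth_mean` with CV 0.3, mimicking uneven library sizes.
#'
#' @param n_samples_per_group samples per outcome group; a single integer
#'   or a length-2 vector `(pregnant, non_pregnant)`.
#' @param n_species number of species (default 40).
#' @param habitat_profile `"lactobacillus_dominant"` or `"polymicrobial"`.
#' @param dominance_fraction expected share of species 1 in the
#'   lactobacillus profile, in (0, 1) (default 0.92).
#' @param depth_mean mean reads per sample (default 18000).
#' @param dropout per-species structural-zero probability in \[0, 1);
#'   scalar or length `n_species`.  The default (`NULL`) is a linear
#'   gradient from 0.25 for the most abundant rank to 0.9 for the
#'   rarest: even common minor taxa are missing from a sizeable share of
#'   real 16S samples, and the gradient makes a 20% prevalence filter
#'   non-trivial.
#' @param sigma baseline log-scale noise standard deviation (default
#'   0.6).  Minor taxa are overdispersed, as in real communities: every
#'   non-dominant species gets 1.5-2x `sigma` (growing with rarity
#'   rank).  In the lactobacillus profile the dominant species is
#'   tightly regulated at 0.5x `sigma`, which is what confines its
#'   per-sample share to the narrow 90-95% band and makes it the
#'   habitat's most reliable discriminant, as in real vaginal
#'   communities.
#' @param power_exponent exponent of the 1/rank^a power-law baseline
#'   (default 1).  Use 0 for an even community, e.g. when benchmarking
#'   copula-driven correlation structure without compositional-closure
#'   coupling.
#' @param blocks list of `list(species = <indices>, rho = <0..1>)`;
#'   species sets must be disjoint.
#' @param biomarkers list of `list(species = <index>, log2_effect = <real>,
#'   group = "pregnant"|"non_pregnant")`.
#' @param seed integer RNG seed.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_samples_per_group = 17,
                         n_species = 40,
                         habitat_profile = c("lactobacillus_dominant",
                                             "polymicrobial"),
                         dominance_fraction = 0.92,
                         depth_mean = 18000,
                         dropout = NULL,
                         sigma = 0.6,
                         power_exponent = 1,
                         blocks = list(),
                         biomarkers = list(),
                         seed = 1) {
  habitat_profile <- match.arg(habitat_profile)
  if (length(n_samples_per_group) == 1L)
    n_samples_per_group <- rep(n_samples_per_group, 2L)
  if (length(n_samples_per_group) != 2L || any(n_samples_per_group < 1) ||
      any(n_samples_per_group != round(n_samples_per_group)))
    abort("n_samples_per_group must be one or two positive integers")
  if (n_species < 2L) abort("need at least 2 species")
  if (dominance_fraction <= 0 || dominance_fraction >= 1)
    abort("dominance_fraction must lie in (0, 1): the remaining species mass would be infeasible")
  if (depth_mean < 1) abort("depth_mean must be positive")
  if (is.null(dropout))
    dropout <- 0.25 + 0.65 * (seq_len(n_species) - 1L) / (n_species - 1L)
  if (length(dropout) == 1L) dropout <- rep(dropout, n_species)
  if (length(dropout) != n_species || any(dropout < 0) || any(dropout >= 1))
    abort("dropout must be per-species probabilities in [0, 1)")
  seen <- integer()
  for (b in blocks) {
    if (is.null(b$species) || is.null(b$rho))
      abort("each block needs $species and $rho")
    if (any(b$species < 1) || any(b$species > n_species))
      abort("block species indices out of range")
    if (any(b$species %in% seen)) abort("block species sets must be disjoint")
    seen <- c(seen, b$species)
    if (b$rho < 0 || b$rho >= 1)
      abort("block correlation rho = %g gives a non positive semi-definite latent correlation; need 0 <= rho < 1",
            b$rho)
  }
  for (bm in biomarkers) {
    if (is.null(bm$species) || is.null(bm$log2_effect) || is.null(bm$group))
      abort("each biomarker needs $species, $log2_effect and $group")
    if (bm$species < 1 || bm$species > n_species)
      abort("biomarker species index out of range")
    if (!bm$group %in% OUTCOMES)
      abort("biomarker group must be one of %s", paste(OUTCOMES, collapse = ", "))
  }
  structure(list(n_samples_per_group = as.integer(n_samples_per_group),
                 n_species = as.integer(n_species),
                 habitat_profile = habitat_profile,
                 dominance_fraction = dominance_fraction,
                 depth_mean = depth_mean,
                 dropout = dropout,
                 sigma = sigma,
                 power_exponent = power_exponent,
                 blocks = blocks,
                 biomarkers = biomarkers,
                 seed = as.integer(seed)),
            class = "synth_config")
}

profile_targets <- function(config) {
  S <- config$n_species
  a <- config$power_exponent %||% 1
  if (config$habitat_profile == "lactobacillus_dominant") {
    d <- config$dominance_fraction
    c(d, (1 - d) * power_law_shares(S - 1L, a))
  } else {
    power_law_shares(S, a)
  }
}

auto_taxonomy <- function(species) {
  j <- seq_along(species)
  taxonomy_map(data.frame(
    species_id = species,
    phylum = sprintf("Phylum_%02d", (j - 1L) %/% 32L + 1L),
    class = sprintf("Class_%02d", (j - 1L) %/% 16L + 1L),
    order = sprintf("Order_%02d", (j - 1L) %/% 8L + 1L),
    family = sprintf("Family_%02d", (j - 1L) %/% 4L + 1L),
    genus = sprintf("Genus_%02d", (j - 1L) %/% 2L + 1L),
    species = species,
    stringsAsFactors = FALSE))
}

#' Generate a synthetic cohort
#'
#' Draws a seeded cohort with the structure described in
#' [synth_config()]: a latent Gaussian vector with block-structured
#' correlation gives each sample x species cell its noise quantile; the
#' log abundance is the profile baseline (chosen so expected shares match
#' the profile targets) plus any biomarker shift plus `sigma` times the
#' latent normal; structural zeros are applied; the row is closed to a
#' composition; and integer counts are drawn multinomially at a
#' log-normal depth.  Counts in each sample sum exactly to its drawn
#' depth.  Deterministic given the seed.
#'
#' @param config a [synth_config()].
#' @return An object of class `synthetic_cohort`: list with `abundance`
#'   (counts [abundance_table()]), `metadata` ([sample_metadata()]),
#'   `taxonomy` ([taxonomy_map()]), `truth` (planted biomarkers/blocks)
#'   and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  S <- config$n_species
  npg <- config$n_samples_per_group
  n <- sum(npg)
  outcome <- rep(OUTCOMES, times = npg)
  habitat <- if (config$habitat_profile == "lactobacillus_dominant")
    "vagina" else "endometrium"
  targets <- profile_targets(config)
  # per-species dispersion: minor taxa are overdispersed (1.5-2x sigma,
  # growing with rarity); a dominant lactobacillus is tightly regulated
  mult <- 1.5 + 0.5 * (seq_len(S) - 1L) / (S - 1L)
  if (config$habitat_profile == "lactobacillus_dominant") mult[1L] <- 0.5
  sigma <- config$sigma * mult
  dropout <- config$dropout
  if (config$habitat_profile == "lactobacillus_dominant")
    dropout[1L] <- 0
  # targets describe the realized (post-dropout) expected composition, so
  # the pre-dropout weights are inflated by the survival probability
  baseline <- log(targets / (1 - dropout)) - sigma^2 / 2
  shift <- matrix(0, n, S)
  for (bm in config$biomarkers)
    shift[outcome == bm$group, bm$species] <-
      shift[outcome == bm$group, bm$species] + log(2) * bm$log2_effect
  counts <- run_seeded(config$seed, {
    Z <- matrix(stats::rnorm(n * S), n, S)
    for (b in config$blocks) {
      G <- stats::rnorm(n)
      Z[, b$species] <- sqrt(b$rho) * G +
        sqrt(1 - b$rho) * Z[, b$species, drop = FALSE]
    }
    A <- exp(sweep(shift + sweep(Z, 2L, sigma, `*`), 2L, baseline, `+`))
    zero <- matrix(stats::runif(n * S), n, S) <
      matrix(dropout, n, S, byrow = TRUE)
    A[zero] <- 0
    # a fully dropped row carries no community; keep its most abundant cell
    dead <- rowSums(A) == 0
    if (any(dead))
      for (i in which(dead)) A[i, which.max(baseline)] <- exp(max(baseline))
    comp <- A / rowSums(A)
    sdlog <- sqrt(log(1 + 0.3^2))
    depth <- pmax(1, round(stats::rlnorm(n, log(config$depth_mean) -
                                           sdlog^2 / 2, sdlog)))
    t(vapply(seq_len(n), function(i)
      stats::rmultinom(1L, depth[i], comp[i, ])[, 1L], numeric(S)))
  })
  species <- sprintf("sp%03d", seq_len(S))
  samples <- sprintf("%s_%s_%02d", substr(habitat, 1L, 3L), outcome,
                     seq_len(n))
  dimnames(counts) <- list(samples, species)
  meta <- sample_metadata(data.frame(sample_id = samples,
                                     habitat = habitat,
                                     outcome = outcome,
                                     stringsAsFactors = FALSE))
  truth <- list(biomarkers = config$biomarkers, blocks = config$blocks)
  structure(list(abundance = abundance_table(counts, "counts"),
                 metadata = meta,
                 taxonomy = auto_taxonomy(species),
                 truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples x %d species (%s; seed %d)\n",
              nrow(abund_values(x$abundance)), x$config$n_species,
              x$config$habitat_profile, x$config$seed))
  invisible(x)
}

#' Planted ground truth of a synthetic cohort
#'
#' Round-trip identity: returns exactly the biomarker and block lists the
#' cohort was generated with.
#'
#' @param cohort a [generate_cohort()] result.
#' @return List with `biomarkers` and `blocks`.
#' @export
planted_truth <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cohort$truth
}

#' Generate a two-habitat synthetic study
#'
#' Builds the study-shaped dataset: a Lactobacillus-dominant vaginal
#' cohort and a polymicrobial endometrial cohort over the same species
#' panel, concatenated, with outcome groups inside each habitat.  The
#' endometrial cohort uses `seed + 1`.
#'
#' @param n_per_habitat samples per habitat (split as evenly as possible
#'   between the outcome groups), or a length-2 outcome split.
#' @param n_species species panel size shared by both habitats.
#' @param seed RNG seed.
#' @param ... further arguments passed to both [synth_config()] calls
#'   (e.g. `biomarkers`, `blocks`, `dropout`).
#' @return A `synthetic_cohort` covering both habitats; `truth` holds the
#'   per-habitat planted structure.
#' @export
generate_study <- function(n_per_habitat = 17, n_species = 40, seed = 1,
                           ...) {
  npg <- if (length(n_per_habitat) == 2L) n_per_habitat
  else c(floor(n_per_habitat / 2), ceiling(n_per_habitat / 2))
  vag <- generate_cohort(synth_config(
    n_samples_per_group = npg, n_species = n_species,
    habitat_profile = "lactobacillus_dominant", seed = seed, ...))
  end <- generate_cohort(synth_config(
    n_samples_per_group = npg, n_species = n_species,
    habitat_profile = "polymicrobial", seed = seed + 1L, ...))
  counts <- rbind(abund_values(vag$abundance), abund_values(end$abundance))
  meta <- sample_metadata(rbind(as.data.frame(vag$metadata),
                                as.data.frame(end$metadata)))
  structure(list(abundance = abundance_table(counts, "counts"),
                 metadata = meta,
                 taxonomy = vag$taxonomy,
                 truth = list(vagina = vag$truth, endometrium = end$truth),
                 config = list(vagina = vag$config, endometrium = end$config)),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits `abundance.tsv`, `abundance.shared` (mothur dialect),
#' `metadata.tsv`, `taxonomy.tsv` and `truth.json` under `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_abundance(cohort$abundance, file.path(dir, "abundance.tsv"))
  write_mothur_shared(cohort$abundance, file.path(dir, "abundance.shared"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  write_taxonomy(cohort$taxonomy, file.path(dir, "taxonomy.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
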