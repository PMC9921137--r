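#' Configuration for the clonal population simulator
#'
#' Defines a synthetic clonal population: a single founder genotype shared by
#' all clones, rare somatic changes accumulating independently per clone
#' (stepwise microsatellite mutation; dominant band gain/loss), and replicated
#' quantitative traits with clone-level effects plus replicate noise. The
#' defaults emulate a varietal clone panel of the kind used in intra-varietal
#' diversity studies: 17 clones typed at 10 SSR loci and 26 polymorphic
#' bands, with five replicated bunch/berry measurements per clone.
#'
#' @param n_clones number of clones.
#' @param n_ssr_loci number of microsatellite loci.
#' @param founder_alleles_per_locus integer range (length 2) giving the size
#'   of the per-locus allele pool the founder's two distinct alleles are
#'   drawn from.
#' @param ssr_motif_bp repeat-unit size in bp; somatic mutations step allele
#'   sizes by one motif unit.
#' @param ssr_mutation_rate probability that an allele copy mutates, per
#'   allele per clone.
#' @param n_bands number of dominant marker bands.
#' @param band_loss_rate probability a present band is lost, per band per
#'   clone.
#' @param band_gain_rate probability an absent band is gained, per band per
#'   clone.
#' @param founder_band_prob probability a band is present in the founder.
#' @param n_traits number of quantitative traits.
#' @param trait_means trait grand means (length `n_traits`).
#' @param clone_effect_sd s.d. of the zero-mean normal clone effects, per
#'   trait.
#' @param replicate_noise_sd s.d. of the replicate noise, per trait.
#' @param n_replicates replicates per clone.
#' @param seed integer seed; identical seeds reproduce outputs exactly.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(n_clones = 17,
                              n_ssr_loci = 10,
                              founder_alleles_per_locus = c(2L, 4L),
                              ssr_motif_bp = 2,
                              ssr_mutation_rate = 0.05,
                              n_bands = 26,
                              band_loss_rate = 0.12,
                              band_gain_rate = 0.08,
                              founder_band_prob = 0.45,
                              n_traits = 3,
                              trait_means = c(berries_per_bunch = 110,
                                rachis_length_cm = 16.3, tss_brix = 22.3),
                              clone_effect_sd = c(22, 2.7, 1.2),
                              replicate_noise_sd = c(25, 2.5, 0.6),
                              n_replicates = 5,
                              seed = 1L) {
  cfg <- list(n_clones = n_clones, n_ssr_loci = n_ssr_loci,
    founder_alleles_per_locus = founder_alleles_per_locus,
    ssr_motif_bp = ssr_motif_bp, ssr_mutation_rate = ssr_mutation_rate,
    n_bands = n_bands, band_loss_rate = band_loss_rate,
    band_gain_rate = band_gain_rate, founder_band_prob = founder_band_prob,
    n_traits = n_traits, trait_means = trait_means,
    clone_effect_sd = clone_effect_sd,
    replicate_noise_sd = replicate_noise_sd,
    n_replicates = n_replicates, seed = seed)
  check_count <- function(field, min = 1) {
    v <- cfg[[field]]
    if (length(v) != 1 || is.na(v) || v < min || v != round(v)) {
      stop(sprintf("invalid configuration: '%s' must be an integer >= %d",
        field, min), call. = FALSE)
    }
  }
  check_rate <- function(field) {
    v <- cfg[[field]]
    if (any(is.na(v)) || any(v < 0) || any(v > 1)) {
      stop(sprintf("invalid configuration: '%s' must be in [0, 1]", field),
        call. = FALSE)
    }
  }
  for (f in c("n_clones", "n_ssr_loci", "n_bands", "n_traits",
    "n_replicates")) check_count(f)
  check_count("ssr_motif_bp")
  check_count("seed", min = 0)
  for (f in c("ssr_mutation_rate", "band_loss_rate", "band_gain_rate",
    "founder_band_prob")) check_rate(f)
  if (length(founder_alleles_per_locus) != 2 ||
      any(founder_alleles_per_locus < 2) ||
      founder_alleles_per_locus[1] > founder_alleles_per_locus[2]) {
    stop("invalid configuration: 'founder_alleles_per_locus' must be a range with min >= 2",
      call. = FALSE)
  }
  for (f in c("trait_means", "clone_effect_sd", "replicate_noise_sd")) {
    if (length(cfg[[f]]) != n_traits) {
      stop(sprintf(
        "invalid configuration: '%s' must have length n_traits (%d), got %d",
        f, n_traits, length(cfg[[f]])), call. = FALSE)
    }
  }
  if (any(cfg$clone_effect_sd < 0) || any(cfg$replicate_noise_sd < 0)) {
    stop("invalid configuration: standard deviations must be >= 0",
      call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# deterministic sub-seed per simulation stage, kept below 2^31 - 1
stage_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483629)
}

#' Apply somatic stepwise mutation to one SSR genotype
#'
#' Each of the two allele copies independently mutates with probability
#' `rate`; a mutation shifts the size by one repeat motif up or down with
#' equal probability (symmetric single-step stepwise mutation model). Draws
#' come from the current R random stream.
#'
#' @param alleles integer vector of length 2, positive allele sizes (bp).
#' @param rate per-allele mutation probability.
#' @param motif_bp repeat-unit size (bp).
#' @return sorted integer vector of length 2.
#' @export
mutate_ssr_genotype <- function(alleles, rate, motif_bp = 2) {
  if (length(alleles) != 2 || any(is.na(alleles)) || any(alleles <= 0)) {
    stop("alleles must be two positive integer sizes", call. = FALSE)
  }
  hit <- stats::runif(2) < rate
  step <- ifelse(stats::runif(2) < 0.5, -1L, 1L) * as.integer(motif_bp)
  out <- as.integer(alleles) + ifelse(hit, step, 0L)
  if (any(out <= 0)) {
    stop("mutation produced a nonpositive allele size", call. = FALSE)
  }
  sort(out)
}

#' Apply somatic band gain/loss to one dominant marker profile
#'
#' Each present band (1) is lost with probability `loss_rate`; each absent
#' band (0) is gained with probability `gain_rate`. Gain and loss rates are
#' separate because insertion and excision of mobile elements are
#' mechanistically asymmetric.
#'
#' @param bands 0/1 vector.
#' @param loss_rate,gain_rate flip probabilities.
#' @return 0/1 integer vector of the same length.
#' @export
mutate_band_profile <- function(bands, loss_rate, gain_rate) {
  if (any(is.na(bands)) || !all(bands %in% c(0, 1))) {
    stop("bands must be a 0/1 vector", call. = FALSE)
  }
  u <- stats::runif(length(bands))
  out <- as.integer(bands)
  out[bands == 1 & u < loss_rate] <- 0L
  out[bands == 0 & u < gain_rate] <- 1L
  out
}

#' Simulate replicated quantitative traits for a clone panel
#'
#' value(clone c, replicate r, trait t) =
#' `trait_means[t]` + clone effect(c, t) + noise(c, r, t), with clone effects
#' drawn from N(0, `clone_effect_sd[t]`) once per clone and noise from
#' N(0, `replicate_noise_sd[t]`) per observation. Draws come from the current
#' R random stream.
#'
#' @param config a [simulation_config].
#' @param clone_ids optional character vector of sample ids.
#' @return a [trait_table] with `n_clones * n_replicates` rows.
#' @export
simulate_traits <- function(config, clone_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_clones
  if (is.null(clone_ids)) clone_ids <- paste0("G", seq_len(n))
  tnames <- names(config$trait_means)
  if (is.null(tnames)) tnames <- paste0("trait", seq_len(config$n_traits))
  effects <- matrix(stats::rnorm(n * config$n_traits, 0,
    rep(config$clone_effect_sd, each = n)), nrow = n)
  rows <- expand.grid(replicate = seq_len(config$n_replicates),
    clone = seq_len(n))
  vals <- matrix(NA_real_, nrow(rows), config$n_traits)
  for (t in seq_len(config$n_traits)) {
    vals[, t] <- config$trait_means[t] + effects[rows$clone, t] +
      stats::rnorm(nrow(rows), 0, config$replicate_noise_sd[t])
  }
  colnames(vals) <- tnames
  df <- data.frame(sample = clone_ids[rows$clone],
    replicate = rows$replicate, vals, check.names = FALSE,
    stringsAsFactors = FALSE)
  df <- df[order(match(df$sample, clone_ids), df$replicate), ]
  rownames(df) <- NULL
  trait_table(df)
}

#' Simulate a clonal population (SSR genotypes, bands, traits)
#'
#' A founder genotype is drawn once: heterozygous at every SSR locus (two
#' distinct allele sizes from a small per-locus pool spaced by the repeat
#' motif) and with each dominant band present with probability
#' `founder_band_prob`. Every clone is the founder plus independent somatic
#' changes: stepwise SSR mutation ([mutate_ssr_genotype]) and band gain/loss
#' ([mutate_band_profile]). Traits come from [simulate_traits]. Each stage
#' uses its own sub-seed derived from `config$seed`, so outputs are
#' bit-reproducible and stages are independent.
#'
#' @param config a [simulation_config].
#' @return list with `ssr` (an [ssr_table]), `bands` (a [band_matrix]),
#'   `traits` (a [trait_table]) and `founder` (list with the founder SSR
#'   genotype matrix and band profile).
#' @examples
#' pop <- simulate_clonal_population(simulation_config(seed = 42))
#' dim(pop$ssr)
#' @export
simulate_clonal_population <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_clones
  L <- config$n_ssr_loci
  clone_ids <- paste0("G", seq_len(n))
  locus_ids <- sprintf("L%02d", seq_len(L))

  # stage 1: founder
  set.seed(stage_seed(config$seed, 1L))
  size_range <- seq(config$founder_alleles_per_locus[1],
    config$founder_alleles_per_locus[2])
  pool_sizes <- size_range[sample.int(length(size_range), L, replace = TRUE)]
  founder <- matrix(NA_integer_, 2, L, dimnames = list(NULL, locus_ids))
  for (l in seq_len(L)) {
    base <- sample(90:320, 1)
    pool <- base + config$ssr_motif_bp * sort(sample(0:7, pool_sizes[l]))
    founder[, l] <- sort(sample(pool, 2))  # heterozygous: pool values distinct
  }
  founder_bands <- as.integer(stats::runif(config$n_bands) <
    config$founder_band_prob)

  # stage 2: somatic SSR mutation per clone
  set.seed(stage_seed(config$seed, 2L))
  a1 <- matrix(NA_integer_, n, L, dimnames = list(clone_ids, locus_ids))
  a2 <- a1
  for (c in seq_len(n)) {
    for (l in seq_len(L)) {
      g <- mutate_ssr_genotype(founder[, l], config$ssr_mutation_rate,
        config$ssr_motif_bp)
      a1[c, l] <- g[1]
      a2[c, l] <- g[2]
    }
  }

  # stage 3: band gain/loss per clone
  set.seed(stage_seed(config$seed, 3L))
  bands <- matrix(NA_integer_, n, config$n_bands,
    dimnames = list(clone_ids, sprintf("B%02d", seq_len(config$n_bands))))
  for (c in seq_len(n)) {
    bands[c, ] <- mutate_band_profile(founder_bands, config$band_loss_rate,
      config$band_gain_rate)
  }

  # stage 4: traits
  set.seed(stage_seed(config$seed, 4L))
  traits <- simulate_traits(config, clone_ids)

  list(ssr = ssr_table(a1, a2), bands = band_matrix(bands), traits = traits,
    founder = list(ssr = founder, bands = founder_bands))
}
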