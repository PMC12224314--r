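# Synthetic proteome + microbiome generator with full ground truth.
#
# The generator emulates the data shapes the analysis assumes:
#   * proteome: log10 LFQ intensity ~ Normal(mu_p + delta_{p,s}, sigma) per
#     reading, left-censored at a detection limit L (censored cells become
#     the missing marker, so missingness is below-detection by construction);
#   * microbiome: zero-inflated negative-binomial counts whose log-mean is
#     baseline + substrate effect + sum of signed couplings
#     gamma * z_{p,s}, with z the standardized substrate-mean (latent)
#     level of the coupled protein. Couplings also shift the
#     structural-presence logit by +gamma * z, so a protein that promotes
#     adhesion raises both the abundance and the prevalence of its microbe;
#   * 24h profiles mix the 2h per-substrate profile with a fresh one under
#     a persistence weight rho_t.

#' Configuration for the synthetic generator
#'
#' Defaults state the emulated world: ~300 proteins and ~300 ASVs on three
#' substrates, three proteomic readings and three microbial replicates per
#' substrate, two timepoints.
#'
#' @param n_proteins,n_asvs feature counts.
#' @param substrates substrate labels.
#' @param readings_per_substrate proteomic readings per substrate.
#' @param replicates_per_substrate microbial replicates per substrate per
#'   timepoint. The default (5) is the smallest group size at which the
#'   Kruskal-Wallis chi-square tail can fall below the microbial screening
#'   threshold of 0.01 with three groups (3 replicates cap H at 7.2, i.e.
#'   p = 0.027).
#' @param base_log10_intensity_mean,base_log10_intensity_sd distribution of
#'   per-protein baseline log10 intensity.
#' @param reading_log10_sd within-protein reading noise (log10 scale).
#' @param substrate_effect_sd sd of planted per-substrate protein effects
#'   (log10 scale).
#' @param n_discriminant_proteins number of proteins given substrate effects.
#' @param detection_limit intensity threshold L; latent intensities below L
#'   are emitted as missing.
#' @param baseline_log_abundance_mean,baseline_log_abundance_sd distribution
#'   of per-ASV baseline log (natural) mean count.
#' @param asv_effect_sd sd of planted per-substrate ASV effects (natural log).
#' @param n_discriminant_asvs number of ASVs given substrate effects.
#' @param count_dispersion negative-binomial size parameter kappa (smaller =
#'   more overdispersed).
#' @param zero_inflation structural zero probability pi.
#' @param n_couplings number of planted protein-to-microbe couplings.
#' @param coupling_strength |gamma|, the coupling magnitude on the natural-log
#'   mean (the default is the generator's "strong" setting).
#' @param persistence rho_t in `[0, 1]`: weight of the 2h per-substrate
#'   profile in the 24h profile (1 = identical profiles).
#' @param seed RNG seed (keep below 2^31 - 2; the microbiome stage derives
#'   seed + 1).
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 300L, n_asvs = 300L,
                             substrates = default_substrates(),
                             readings_per_substrate = 3L,
                             replicates_per_substrate = 5L,
                             base_log10_intensity_mean = 7,
                             base_log10_intensity_sd = 1,
                             reading_log10_sd = 0.2,
                             substrate_effect_sd = 0.8,
                             n_discriminant_proteins = 60L,
                             detection_limit = 5e5,
                             baseline_log_abundance_mean = log(20),
                             baseline_log_abundance_sd = 1.5,
                             asv_effect_sd = 1,
                             n_discriminant_asvs = 20L,
                             count_dispersion = 1,
                             zero_inflation = 0.3,
                             n_couplings = 10L,
                             coupling_strength = 5,
                             persistence = 0.7,
                             seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins), n_asvs = as.integer(n_asvs),
              substrates = canonical_label(substrates),
              readings_per_substrate = as.integer(readings_per_substrate),
              replicates_per_substrate = as.integer(replicates_per_substrate),
              base_log10_intensity_mean = base_log10_intensity_mean,
              base_log10_intensity_sd = base_log10_intensity_sd,
              reading_log10_sd = reading_log10_sd,
              substrate_effect_sd = substrate_effect_sd,
              n_discriminant_proteins = as.integer(n_discriminant_proteins),
              detection_limit = detection_limit,
              baseline_log_abundance_mean = baseline_log_abundance_mean,
              baseline_log_abundance_sd = baseline_log_abundance_sd,
              asv_effect_sd = asv_effect_sd,
              n_discriminant_asvs = as.integer(n_discriminant_asvs),
              count_dispersion = count_dispersion,
              zero_inflation = zero_inflation,
              n_couplings = as.integer(n_couplings),
              coupling_strength = coupling_strength,
              persistence = persistence, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (!is_count(n_proteins) || !is_count(n_asvs)) stopf("feature counts must be >= 1")
    if (length(substrates) < 1L || anyDuplicated(substrates)) stopf("substrates must be unique, >= 1")
    if (!is_count(readings_per_substrate) || !is_count(replicates_per_substrate))
      stopf("per-substrate counts must be >= 1")
    if (!is_pos(detection_limit) && detection_limit != 0) stopf("detection_limit L must be >= 0")
    if (!is_pos(count_dispersion)) stopf("count_dispersion kappa must be > 0")
    if (!is_prob(zero_inflation) || zero_inflation >= 1) stopf("zero_inflation pi must be in [0, 1)")
    if (!is_prob(persistence)) stopf("persistence rho_t must be in [0, 1]")
    if (substrate_effect_sd < 0 || asv_effect_sd < 0) stopf("effect sds must be >= 0")
    if (reading_log10_sd <= 0) stopf("reading_log10_sd must be > 0")
    if (n_discriminant_proteins > n_proteins) stopf("more discriminant proteins than proteins")
    if (n_discriminant_asvs > n_asvs) stopf("more discriminant ASVs than ASVs")
    if (n_couplings > n_asvs) stopf("more couplings than ASVs")
    if (n_couplings > 0L && n_discriminant_proteins == 0L)
      stopf("couplings need at least one discriminant protein to act through")
    if (!is_count(seed, min = 0L) || seed > 2^31 - 1000) stopf("seed must be a small nonnegative integer")
  })
  invisible(cfg)
}

#' Simulate a salivary-pellicle proteome table
#'
#' @param config a [synthetic_config()].
#' @return list with elements `table` (a [protein_table()]) and `truth`
#'   (latent pre-censoring log10 matrix, detection limit, planted
#'   discriminant effects, standardized per-substrate latent means used by
#'   the coupling mechanism, and ids of proteins dropped because every
#'   reading fell below the detection limit).
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    S <- length(cfg$substrates)
    n_exp <- S * cfg$readings_per_substrate
    prot_ids <- sprintf("P%05d", seq_len(cfg$n_proteins))
    design <- experiment_design(
      experiment_id = paste0("prot_", rep(cfg$substrates, each = cfg$readings_per_substrate),
                             "_r", rep(seq_len(cfg$readings_per_substrate), times = S)),
      substrate = rep(cfg$substrates, each = cfg$readings_per_substrate),
      replicate = rep(seq_len(cfg$readings_per_substrate), times = S),
      vocabulary = cfg$substrates)

    mu <- stats::rnorm(cfg$n_proteins, cfg$base_log10_intensity_mean,
                       cfg$base_log10_intensity_sd)
    names(mu) <- prot_ids

    # plant discriminant proteins among those whose baseline sits safely
    # above the detection limit, so planted ids survive censoring
    log10L <- if (cfg$detection_limit > 0) log10(cfg$detection_limit) else -Inf
    eligible <- prot_ids[mu > log10L + 0.5]
    disc <- if (length(eligible) >= cfg$n_discriminant_proteins)
      sort(sample(eligible, cfg$n_discriminant_proteins))
    else  # degenerate censoring: fall back to the highest-baseline proteins
      sort(names(sort(mu, decreasing = TRUE))[seq_len(cfg$n_discriminant_proteins)])
    effects <- matrix(0, cfg$n_proteins, S, dimnames = list(prot_ids, cfg$substrates))
    effects[disc, ] <- stats::rnorm(length(disc) * S, 0, cfg$substrate_effect_sd)

    latent <- matrix(stats::rnorm(cfg$n_proteins * n_exp, 0, cfg$reading_log10_sd),
                     cfg$n_proteins, n_exp,
                     dimnames = list(prot_ids, design$experiment_id))
    latent <- latent + mu + effects[, match(design$substrate, cfg$substrates)]

    values <- 10^latent
    values[latent < log10L] <- NA_real_
    if (all(is.na(values))) stopf("empty table: detection limit censors every entry")
    dropped <- rownames(values)[rowSums(!is.na(values)) == 0L]
    keep <- setdiff(rownames(values), dropped)
    table <- protein_table(values[keep, , drop = FALSE], design)

    # standardized per-substrate latent means (coupling input): latent means
    # averaged over readings within substrate, standardized per protein
    sub_means <- vapply(cfg$substrates, function(s)
      rowMeans(latent[, design$substrate == s, drop = FALSE]),
      numeric(cfg$n_proteins))
    z <- t(scale(t(sub_means)))  # per-protein: mean 0, sd 1 across substrates
    z[is.nan(z)] <- 0

    # planted ids must exist in the emitted table: a fully censored protein
    # is not part of the emitted world
    disc <- setdiff(disc, dropped)
    truth <- list(config = cfg,
                  latent_log10 = latent, detection_limit = cfg$detection_limit,
                  discriminant_proteins = disc,
                  protein_effects = effects[disc, , drop = FALSE],
                  protein_substrate_z = z,
                  dropped_proteins = dropped)
    list(table = table, truth = truth)
  })
}

#' Simulate adherent-microbiome ASV tables at 2h and 24h
#'
#' @param config the [synthetic_config()] used for the proteome.
#' @param proteome_truth the `truth` element returned by
#'   [simulate_proteome()] under the same config/seed.
#' @param couplings optional data.frame (`protein`, `asv`, `sign`) naming
#'   the planted couplings; by default `n_couplings` are sampled, each
#'   linking one discriminant protein to one otherwise-neutral ASV.
#' @return list with elements `table_2h`, `table_24h` (both [asv_table()])
#'   and `truth` (planted ASV effects, couplings with signs and strength,
#'   per-substrate log-mean and structural-zero matrices per timepoint).
#' @export
simulate_microbiome <- function(config, proteome_truth, couplings = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  z <- proteome_truth$protein_substrate_z
  with_seed(cfg$seed + 1L, {
    S <- length(cfg$substrates)
    asv_ids <- sprintf("ASV%04d", seq_len(cfg$n_asvs))
    taxonomy <- paste0("Taxon_sp_HMT-", sprintf("%03d", seq_len(cfg$n_asvs)))

    base <- stats::rnorm(cfg$n_asvs, cfg$baseline_log_abundance_mean,
                         cfg$baseline_log_abundance_sd)
    names(base) <- asv_ids

    disc_asvs <- sort(sample(asv_ids, cfg$n_discriminant_asvs))
    asv_eff <- matrix(0, cfg$n_asvs, S, dimnames = list(asv_ids, cfg$substrates))
    asv_eff[disc_asvs, ] <- stats::rnorm(length(disc_asvs) * S, 0, cfg$asv_effect_sd)

    if (is.null(couplings)) {
      if (cfg$n_couplings > 0L) {
        free_asvs <- setdiff(asv_ids, disc_asvs)
        if (length(free_asvs) < cfg$n_couplings)
          stopf("not enough non-discriminant ASVs to host %d couplings", cfg$n_couplings)
        couplings <- data.frame(
          protein = sample(proteome_truth$discriminant_proteins, cfg$n_couplings,
                           replace = cfg$n_couplings > length(proteome_truth$discriminant_proteins)),
          asv = sort(sample(free_asvs, cfg$n_couplings)),
          sign = sample(c(-1, 1), cfg$n_couplings, replace = TRUE),
          stringsAsFactors = FALSE)
      } else {
        couplings <- data.frame(protein = character(), asv = character(), sign = numeric())
      }
    }
    unknown <- setdiff(couplings$protein, rownames(z))
    if (length(unknown) > 0L)
      stopf("coupling references unknown protein(s): %s", paste(unknown, collapse = ", "))
    if (length(setdiff(couplings$asv, asv_ids)) > 0L)
      stopf("coupling references unknown ASV(s)")
    couplings$gamma <- couplings$sign * cfg$coupling_strength

    # per-(asv, substrate) coupling term on the natural-log mean
    coup_term <- matrix(0, cfg$n_asvs, S, dimnames = list(asv_ids, cfg$substrates))
    for (k in seq_len(nrow(couplings)))
      coup_term[couplings$asv[k], ] <- coup_term[couplings$asv[k], ] +
        couplings$gamma[k] * z[couplings$protein[k], ]

    logmean_2h <- base + asv_eff + coup_term

    # 24h profile: persistence-weighted mix of the 2h profile with a fresh
    # substrate-effect draw (same baseline); rho_t = 1 reproduces 2h exactly
    asv_eff_fresh <- matrix(0, cfg$n_asvs, S, dimnames = list(asv_ids, cfg$substrates))
    asv_eff_fresh[disc_asvs, ] <- stats::rnorm(length(disc_asvs) * S, 0, cfg$asv_effect_sd)
    logmean_24h <- base + cfg$persistence * (asv_eff + coup_term) +
      (1 - cfg$persistence) * asv_eff_fresh

    # structural-zero probability: baseline pi on the logit scale, shifted
    # by the coupling term (adhesion-promoting protein -> higher prevalence)
    pi_mat <- function(coup_scaled) {
      if (cfg$zero_inflation <= 0) return(matrix(0, cfg$n_asvs, S,
                                                 dimnames = list(asv_ids, cfg$substrates)))
      stats::plogis(stats::qlogis(cfg$zero_inflation) - coup_scaled)
    }
    pi_2h <- pi_mat(coup_term)
    pi_24h <- pi_mat(cfg$persistence * coup_term)

    draw_counts <- function(logmean, pim, tp) {
      n_exp <- S * cfg$replicates_per_substrate
      design <- experiment_design(
        experiment_id = paste0("mic_", tp, "_",
                               rep(cfg$substrates, each = cfg$replicates_per_substrate),
                               "_r", rep(seq_len(cfg$replicates_per_substrate), times = S)),
        substrate = rep(cfg$substrates, each = cfg$replicates_per_substrate),
        timepoint = tp,
        replicate = rep(seq_len(cfg$replicates_per_substrate), times = S),
        vocabulary = cfg$substrates)
      sidx <- match(design$substrate, cfg$substrates)
      mu <- exp(logmean[, sidx, drop = FALSE])
      # cap the NB mean: keeps counts in a realistic sequencing range and
      # protects rnbinom's internal rpois from integer overflow
      counts <- matrix(stats::rnbinom(cfg$n_asvs * n_exp, size = cfg$count_dispersion,
                                      mu = pmin(mu, 1e7)),
                       cfg$n_asvs, n_exp, dimnames = list(asv_ids, design$experiment_id))
      if (cfg$zero_inflation > 0) {
        zmask <- matrix(stats::runif(cfg$n_asvs * n_exp) <
                          pim[, sidx, drop = FALSE], cfg$n_asvs, n_exp)
        counts[zmask] <- 0L
      }
      asv_table(counts, design, taxonomy)
    }
    table_2h <- draw_counts(logmean_2h, pi_2h, "2h")
    table_24h <- draw_counts(logmean_24h, pi_24h, "24h")

    truth <- list(config = cfg,
                  discriminant_asvs = disc_asvs,
                  asv_effects = asv_eff[disc_asvs, , drop = FALSE],
                  couplings = couplings,
                  logmean_2h = logmean_2h, logmean_24h = logmean_24h,
                  pi_2h = pi_2h, pi_24h = pi_24h)
    list(table_2h = table_2h, table_24h = table_24h, truth = truth)
  })
}

#' Simulate a sparse random annotation map
#'
#' Assigns each protein 0-3 molecular functions and 0-2 biological
#' processes from small random label pools.
#'
#' @param protein_ids proteins to annotate.
#' @param seed RNG seed.
#' @return an [annotation_map()].
#' @export
simulate_annotation <- function(protein_ids, seed = 1L) {
  with_seed(seed, {
    mf_pool <- sprintf("molecular_function_%02d", 1:15)
    bp_pool <- sprintf("biological_process_%02d", 1:10)
    rows <- lapply(protein_ids, function(p) {
      mf <- sample(mf_pool, stats::rbinom(1L, 3L, 0.4))
      bp <- sample(bp_pool, stats::rbinom(1L, 2L, 0.4))
      if (length(mf) + length(bp) == 0L) return(NULL)
      data.frame(protein_id = p,
                 category = c(rep("molecular_function", length(mf)),
                              rep("biological_process", length(bp))),
                 label = c(mf, bp), stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows)) return(annotation_map())
    annotation_map(rows$protein_id, rows$category, rows$label)
  })
}
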