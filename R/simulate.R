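#' Simulation configuration
#'
#' Describes a multi-cohort CSF proteomics study to generate: cohort and
#' group sizes, the protein abundance model (per-protein median log10
#' intensity, per-sample noise), a disease signature (additive log10
#' effects shared across cohorts), co-regulated protein blocks driven by
#' latent factors (a neuronal-like block and a blood-contamination block),
#' abundance-dependent missingness (logistic in log10 intensity, so
#' low-abundance proteins drop out more often, emulating DIA
#' left-censoring), per-cohort log10 offsets, and clinical covariates
#' coupled to disease status. The designated MAPT-like protein is not given
#' a fixed effect: its intensity tracks the latent log10 t-tau
#' concentration with a configurable target Pearson correlation, which both
#' produces its AD elevation and makes t-tau a meaningful correlate.
#'
#' @param cohorts Tibble with columns `cohort`, `group_label`, `n`,
#'   `is_ad`, `control_override`, `age_mean`, `age_sd`, and availability
#'   flags `has_ttau`, `has_ab40`, `has_mmse`.
#' @param n_proteins Number of protein groups.
#' @param base_abundance `c(mean, sd)` of per-protein median log10
#'   intensity (defaults give ~6 orders of magnitude dynamic range).
#' @param sample_noise_sd Per-sample log10 noise.
#' @param signature Tibble `protein` (index), `effect` (signed log10
#'   units); protein 1 is reserved for the MAPT-like marker.
#' @param mapt_coupling List: `gamma` (log10 intensity units per log10
#'   t-tau unit) and `r_target` (target Pearson r between log10 intensity
#'   and log10 t-tau).
#' @param clusters List of lists with `proteins` (indices) and `loading`
#'   (log10 units per latent-factor sd).
#' @param missingness List `midpoint` (log10 intensity of 50% dropout) and
#'   `slope` (> 0; log10 units).
#' @param cohort_offsets Named numeric log10 shifts per cohort.
#' @param clinical List of group means/sds for the covariates (see
#'   [default_paper_config()] source for the exact fields).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(cohorts, n_proteins, base_abundance = c(6, 1.2),
                              sample_noise_sd = 0.1,
                              signature = NULL,
                              mapt_coupling = list(gamma = 0.6, r_target = 0.8),
                              clusters = list(),
                              missingness = list(midpoint = NULL, slope = 0.5),
                              cohort_offsets = NULL,
                              clinical = default_clinical_model()) {
  stopifnot(all(cohorts$n > 0), n_proteins >= 1, sample_noise_sd >= 0)
  if (!is.null(signature) && any(!is.finite(signature$effect))) {
    stop("signature effects must be finite", call. = FALSE)
  }
  if (missingness$slope <= 0) stop("missingness slope must be > 0", call. = FALSE)
  idx_used <- c(if (!is.null(signature)) signature$protein,
                unlist(lapply(clusters, `[[`, "proteins")))
  if (length(idx_used) && max(idx_used) > n_proteins) {
    stop("signature/cluster protein indices exceed n_proteins", call. = FALSE)
  }
  if (is.null(missingness$midpoint)) {
    # 20th percentile of the base-abundance distribution
    missingness$midpoint <- qnorm(0.2, base_abundance[1], base_abundance[2])
  }
  if (is.null(cohort_offsets)) {
    cohort_offsets <- setNames(rep(0, length(unique(cohorts$cohort))),
                               unique(cohorts$cohort))
  }
  structure(list(cohorts = cohorts, n_proteins = n_proteins,
                 base_abundance = base_abundance,
                 sample_noise_sd = sample_noise_sd,
                 signature = signature, mapt_coupling = mapt_coupling,
                 clusters = clusters, missingness = missingness,
                 cohort_offsets = cohort_offsets, clinical = clinical),
            class = "simulation_config")
}

default_clinical_model <- function() {
  list(
    log_ttau = list(ad = c(2.845, 0.12), ctrl = c(2.447, 0.12)),
    ab42 = list(ad = c(420, 90), ctrl = c(810, 130), floor = 120),
    ab40 = list(all = c(9800, 1600), floor = 3000),
    mmse = list(ad = c(22.7, 4.5), ctrl = c(27.7, 1.9)),
    ptau_ratio = 0.1, ptau_sd = 5
  )
}

#' Study-calibrated simulation configuration
#'
#' The default conditions: three cohorts with group sizes 29/31 (Sweden-like:
#' AD / biochemical controls), 26/12/16 (Magdeburg/Kiel-like: AD /
#' biochemical controls / young emergency-department controls with missing
#' clinical chemistry and `control_override`), and 33/26/24 (Berlin-like:
#' AD / depression controls / subjective-cognitive-impairment controls) --
#' 197 samples, 88 AD and 109 non-AD. 1,500 proteins spanning about six
#' orders of magnitude; a 40-protein signature (35 elevated in AD, 5
#' reduced) whose median absolute fold change is 1.30; effects shared
#' across cohorts; a MAPT-like protein coupled to latent t-tau; a
#' neuronal-like correlated block and a blood-contamination block;
#' abundance-dependent missingness.
#'
#' @return A `simulation_config`.
#' @export
default_paper_config <- function() {
  cohorts <- tibble::tribble(
    ~cohort, ~group_label, ~n, ~is_ad, ~control_override,
    ~age_mean, ~age_sd, ~has_ttau, ~has_ab40, ~has_mmse,
    "sweden", "AD", 29L, TRUE, FALSE, 71, 8, TRUE, FALSE, FALSE,
    "sweden", "biochemical-control", 31L, FALSE, FALSE, 69, 8, TRUE, FALSE, FALSE,
    "magdeburg_kiel", "AD", 26L, TRUE, FALSE, 72, 8, TRUE, TRUE, FALSE,
    "magdeburg_kiel", "biochemical-control", 12L, FALSE, FALSE, 68, 8, TRUE, TRUE, FALSE,
    "magdeburg_kiel", "kiel-control", 16L, FALSE, TRUE, 34, 10, FALSE, FALSE, FALSE,
    "berlin", "AD", 33L, TRUE, FALSE, 71, 8, TRUE, TRUE, TRUE,
    "berlin", "depression-control", 26L, FALSE, FALSE, 67, 8, TRUE, TRUE, TRUE,
    "berlin", "sci-control", 24L, FALSE, FALSE, 66, 8, TRUE, TRUE, TRUE
  )
  # 39 fixed-effect signature proteins: |fold changes| geometric between
  # 1.25 and 1.352 so that, together with the stronger MAPT-like marker,
  # the 40-protein median |fold change| is 1.30. Five are reduced in AD.
  fc <- exp(seq(log(1.25), log(1.352), length.out = 39))
  dir <- rep(1, 39)
  dir[c(8, 15, 22, 29, 36)] <- -1
  signature <- tibble::tibble(protein = 2:40, effect = dir * log10(fc))
  clusters <- list(
    list(proteins = 41:90, loading = 0.12),   # neuronal-like block
    list(proteins = 91:130, loading = 0.25)   # blood-contamination block
  )
  simulation_config(
    cohorts = cohorts, n_proteins = 1500,
    signature = signature,
    clusters = clusters,
    cohort_offsets = c(sweden = 0, magdeburg_kiel = 0.05, berlin = -0.05)
  )
}

rnorm_floor <- function(n, mean, sd, floor) pmax(rnorm(n, mean, sd), floor)

#' Simulate a multi-cohort study with ground truth
#'
#' Per protein p and sample j the latent log10 intensity is
#' `base_p + cohort offset + status effect (signature proteins) +
#' cluster loadings x latent factors + N(0, noise)`; the MAPT-like protein
#' (index 1) instead tracks latent log10 t-tau (see
#' [simulation_config()]). Entries are set missing with probability
#' `plogis((midpoint - log10 I) / slope)`. Clinical covariates are drawn
#' per group; samples with `control_override` get their clinical chemistry
#' masked. Signature and MAPT-like base abundances are drawn from the upper
#' abundance range (they emulate reliably quantified CSF markers), all
#' other bases from the configured distribution. Deterministic given the
#' seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list with `bundle` (a [study_bundle()], linear scale) and
#'   `truth` (list: `status`, `signature`, `mapt_protein`, `clusters`,
#'   `factors`, `latent_log_ttau`).
#' @export
simulate_study <- function(config, seed = 0L) {
  withr::with_seed(as.integer(seed), simulate_study_impl(config))
}

simulate_study_impl <- function(config) {
  co <- config$cohorts
  groups <- co[rep(seq_len(nrow(co)), co$n), ]
  n_samp <- nrow(groups)
  groups$sample_id <- sprintf("S%03d", seq_len(n_samp))
  is_ad <- groups$is_ad
  np <- config$n_proteins

  base <- rnorm(np, config$base_abundance[1], config$base_abundance[2])
  sig <- config$signature
  sig_idx <- if (is.null(sig)) 1L else c(1L, sig$protein)
  # signature markers sit in the reliably quantified abundance range
  base[sig_idx] <- 6.2 + abs(rnorm(length(sig_idx), 0, 0.6))

  effects <- numeric(np)
  if (!is.null(sig)) effects[sig$protein] <- sig$effect

  # latent clinical t-tau (log10 ng/l) drives both the metadata and the
  # MAPT-like protein
  cl <- config$clinical
  log_ttau <- ifelse(is_ad,
                     rnorm(n_samp, cl$log_ttau$ad[1], cl$log_ttau$ad[2]),
                     rnorm(n_samp, cl$log_ttau$ctrl[1], cl$log_ttau$ctrl[2]))

  offset <- config$cohort_offsets[groups$cohort]
  x <- matrix(base, np, n_samp) +
    matrix(offset, np, n_samp, byrow = TRUE) +
    outer(effects, as.numeric(is_ad)) +
    matrix(rnorm(np * n_samp, 0, config$sample_noise_sd), np, n_samp)

  factors <- matrix(0, length(config$clusters), n_samp)
  for (k in seq_along(config$clusters)) {
    blk <- config$clusters[[k]]
    factors[k, ] <- rnorm(n_samp)
    x[blk$proteins, ] <- x[blk$proteins, ] +
      blk$loading * matrix(factors[k, ], length(blk$proteins), n_samp,
                           byrow = TRUE)
  }

  # MAPT-like protein: base + cohort offset + coupling to latent t-tau,
  # with residual noise sized to hit the target correlation
  gamma <- config$mapt_coupling$gamma
  r_t <- config$mapt_coupling$r_target
  signal <- gamma * (log_ttau - mean(log_ttau))
  resid_sd <- sd(signal) * sqrt(max(1 / r_t^2 - 1, 0))
  x[1, ] <- base[1] + offset + signal + rnorm(n_samp, 0, resid_sd)
  mapt_effect <- gamma * (cl$log_ttau$ad[1] - cl$log_ttau$ctrl[1])

  # abundance-driven dropout
  p_miss <- plogis((config$missingness$midpoint - x) / config$missingness$slope)
  x[matrix(runif(np * n_samp), np, n_samp) < p_miss] <- NA_real_

  gene <- sprintf("G%04d", seq_len(np))
  gene[1] <- "MAPTL"
  proteins <- tibble::tibble(protein_id = sprintf("P%04d", seq_len(np)),
                             gene_name = gene)
  vals <- 10^x
  colnames(vals) <- groups$sample_id
  matrix_tbl <- intensity_tbl(proteins, vals, scale = "linear")

  n_ad <- sum(is_ad)
  meta <- tibble::tibble(
    sample_id = groups$sample_id,
    cohort = groups$cohort,
    group_label = groups$group_label,
    age = round(pmax(rnorm(n_samp, groups$age_mean, groups$age_sd), 18)),
    sex = sample(c("male", "female"), n_samp, replace = TRUE),
    t_tau = round(10^log_ttau, 1),
    p_tau181 = round(pmax(cl$ptau_ratio * 10^log_ttau +
                            rnorm(n_samp, 0, cl$ptau_sd), 1), 1),
    ab42 = round(ifelse(is_ad,
                        rnorm_floor(n_samp, cl$ab42$ad[1], cl$ab42$ad[2],
                                    cl$ab42$floor),
                        rnorm_floor(n_samp, cl$ab42$ctrl[1], cl$ab42$ctrl[2],
                                    cl$ab42$floor)), 1),
    ab40 = round(rnorm_floor(n_samp, cl$ab40$all[1], cl$ab40$all[2],
                             cl$ab40$floor), 1),
    mmse = as.integer(pmin(pmax(round(ifelse(
      is_ad, rnorm(n_samp, cl$mmse$ad[1], cl$mmse$ad[2]),
      rnorm(n_samp, cl$mmse$ctrl[1], cl$mmse$ctrl[2]))), 0), 30)),
    control_override = groups$control_override
  )
  # availability masks: which assays each cohort/group ran
  meta$t_tau[!groups$has_ttau] <- NA_real_
  meta$p_tau181[!groups$has_ttau] <- NA_real_
  meta$ab42[groups$control_override] <- NA_real_
  meta$ab40[!groups$has_ab40] <- NA_real_
  meta$mmse[!groups$has_mmse] <- NA_integer_

  truth <- list(
    status = tibble::tibble(sample_id = groups$sample_id, is_ad = is_ad),
    signature = tibble::tibble(
      protein_id = proteins$protein_id[sig_idx],
      effect = c(mapt_effect, sig$effect),
      direction = sign(c(mapt_effect, sig$effect))
    ),
    mapt_protein = proteins$protein_id[1],
    clusters = lapply(config$clusters, function(blk)
      proteins$protein_id[blk$proteins]),
    factors = factors,
    latent_log_ttau = log_ttau
  )
  list(bundle = study_bundle(matrix_tbl, meta), truth = truth)
}

#' Simulate pooled-sample replicate plates for CV benchmarking
#'
#' One pooled CSF profile measured `n_replicates_per_plate` times on each
#' of `n_plates` plates (prepared on different days), with multiplicative
#' log-normal noise of fractional sd `cv_linear` plus a per-plate factor.
#'
#' @param n_proteins Number of proteins in the pool profile.
#' @param n_replicates_per_plate,n_plates Replicate design (>= 3 and >= 2).
#' @param cv_linear Target fractional sd of the replicate noise.
#' @param plate_sd Log-normal sd of the per-plate factor (log10 units).
#' @param seed Integer seed.
#' @return A list: `matrix` (linear-scale [intensity_tbl()]) and
#'   `plate_ids` (per replicate column).
#' @export
simulate_replicate_plates <- function(n_proteins = 500,
                                      n_replicates_per_plate = 5,
                                      n_plates = 3, cv_linear = 0.1,
                                      plate_sd = 0.01, seed = 0L) {
  if (n_replicates_per_plate < 3) {
    stop("need >= 3 replicates per plate", call. = FALSE)
  }
  if (n_plates < 2) {
    stop("inter-plate comparisons need >= 2 plates", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    profile <- 10^rnorm(n_proteins, 6, 1.2)
    sigma <- sqrt(log(1 + cv_linear^2))  # log-normal sd giving CV ~ cv_linear
    n_rep <- n_replicates_per_plate * n_plates
    plate <- rep(sprintf("plate%d", seq_len(n_plates)),
                 each = n_replicates_per_plate)
    plate_factor <- rep(10^rnorm(n_plates, 0, plate_sd),
                        each = n_replicates_per_plate)
    vals <- vapply(seq_len(n_rep), function(j) {
      profile * plate_factor[j] * exp(rnorm(n_proteins, 0, sigma))
    }, numeric(n_proteins))
    colnames(vals) <- sprintf("rep%02d", seq_len(n_rep))
    proteins <- tibble::tibble(protein_id = sprintf("P%04d", seq_len(n_proteins)),
                               gene_name = "")
    list(matrix = intensity_tbl(proteins, vals, scale = "linear"),
         plate_ids = plate)
  })
}

#' Annotation catalog matched to a simulated study
#'
#' Builds a GMT-style catalog: one "neuron-projection-like" term covering
#' the AD-elevated signature proteins plus `n_extra` non-signature
#' proteins, and `n_random_terms` random terms as background.
#'
#' @param truth Ground truth from [simulate_study()].
#' @param protein_ids All dataset protein ids.
#' @param n_extra Non-signature proteins added to the signature term.
#' @param n_random_terms,random_term_size Background terms.
#' @param seed Integer seed.
#' @return A catalog tibble as from [read_annotations()].
#' @export
simulated_catalog <- function(truth, protein_ids, n_extra = 20,
                              n_random_terms = 12, random_term_size = 40,
                              seed = 0L) {
  up <- truth$signature$protein_id[truth$signature$direction > 0]
  pool <- setdiff(protein_ids, truth$signature$protein_id)
  withr::with_seed(as.integer(seed), {
    neuron <- c(up, sample(pool, n_extra))
    rand <- lapply(seq_len(n_random_terms), function(i)
      sample(protein_ids, random_term_size))
  })
  tibble::tibble(
    term_id = c("neuron-projection-like",
                sprintf("random-term-%02d", seq_len(n_random_terms))),
    description = c("GOCC-like term covering the AD-elevated signature",
                    rep("random background term", n_random_terms)),
    members = c(list(neuron), rand),
    n_members = c(length(neuron), lengths(rand))
  )
}
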