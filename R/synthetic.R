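#' Configuration bundle for the synthetic-data generators
#'
#' Collects every tunable of the generators into one seedable list. The
#' defaults encode the study conditions the generators emulate: a screen of
#' 21 evaluable PDX models whose per-class exponential growth rates yield
#' 1 CR, 2 PR, 2 SD and 16 PD in the noiseless limit; IHC score
#' distributions separated by true resistance class with a label-noise
#' parameter; a metastatic cohort of 582 patients with exposure prevalence
#' 71/582 and a configurable double-hit-by-exposure log odds ratio; ex vivo
#' area changes of -50% (sensitive) vs 0% (resistant) with SD 10; and Ct
#' panels with two stable references. Each generator draws from its own
#' RNG stream derived from the master seed, so adding one generator never
#' shifts another's output.
#'
#' @param seed Master integer seed (mandatory).
#' @param n_models Number of PDX models in the growth screen.
#' @param class_counts Named integer vector of true response classes over
#'   the models (must sum to `n_models`).
#' @param tumors_per_model Treated tumors (and vehicle tumors) per model.
#' @param growth_noise_sd SD of the multiplicative lognormal measurement
#'   noise on volumes (log scale).
#' @param baseline_volume_range Range of baseline volumes in mm^3.
#' @param biomarker_n Panel size for the biomarker generator.
#' @param label_noise Probability that a panel's scores contradict its true
#'   class.
#' @param cohort_n Patients in the genomic cohort.
#' @param exposure_prev Probability of prior CDK4/6-inhibitor exposure.
#' @param mutation_prev,deletion_prev Marginal alteration probabilities in
#'   the unexposed stratum.
#' @param double_hit_log_or Interaction log odds ratio linking the joint
#'   mutation-and-deletion state to exposure.
#' @param exvivo_n_models Models in the ex vivo generator.
#' @param exvivo_sens_mean,exvivo_res_mean,exvivo_sd Class-conditional mean
#'   (and shared SD) of the percent area change.
#' @param qpcr_n_samples Samples in the Ct panel generator.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_models = 21,
                             class_counts = c(CR = 1, PR = 2, SD = 2, PD = 16),
                             tumors_per_model = 3,
                             growth_noise_sd = 0.05,
                             baseline_volume_range = c(100, 300),
                             biomarker_n = 200,
                             label_noise = 0.15,
                             cohort_n = 582,
                             exposure_prev = 71 / 582,
                             mutation_prev = 0.10,
                             deletion_prev = 0.25,
                             double_hit_log_or = 1.5,
                             exvivo_n_models = 37,
                             exvivo_sens_mean = -50,
                             exvivo_res_mean = 0,
                             exvivo_sd = 10,
                             qpcr_n_samples = 12) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(
    sum(class_counts) == n_models,
    growth_noise_sd >= 0, label_noise >= 0, label_noise <= 1,
    exposure_prev > 0, exposure_prev < 1,
    mutation_prev > 0, mutation_prev < 1,
    deletion_prev > 0, deletion_prev < 1
  )
  structure(
    list(
      seed = as.integer(seed),
      n_models = n_models,
      class_counts = class_counts,
      tumors_per_model = tumors_per_model,
      growth_noise_sd = growth_noise_sd,
      baseline_volume_range = baseline_volume_range,
      biomarker_n = biomarker_n,
      label_noise = label_noise,
      cohort_n = cohort_n,
      exposure_prev = exposure_prev,
      mutation_prev = mutation_prev,
      deletion_prev = deletion_prev,
      double_hit_log_or = double_hit_log_or,
      exvivo_n_models = exvivo_n_models,
      exvivo_sens_mean = exvivo_sens_mean,
      exvivo_res_mean = exvivo_res_mean,
      exvivo_sd = exvivo_sd,
      qpcr_n_samples = qpcr_n_samples
    ),
    class = "synthetic_config"
  )
}

# Stable per-generator RNG streams: a fixed label offset on the master seed.
stream_seed <- function(config, label) {
  offsets <- c(
    growth = 101L, biomarker = 211L, genomic = 307L,
    exvivo = 401L, qpcr = 503L
  )
  (config$seed + offsets[[label]]) %% .Machine$integer.max
}

# Per-class exponential growth rates (per day): chosen so the noiseless
# day-35 percent change sits well inside each response band.
class_growth_rates <- function() {
  c(
    CR = log(0.03) / 35, # -97%
    PR = log(0.40) / 35, # -60%
    SD = log(0.95) / 35, # -5%
    PD = log(4.00) / 35 # +300%
  )
}

#' Simulate a PDX growth screen
#'
#' Generates a caliper-measurement table for a treated and a vehicle arm of
#' every model. Treated volumes follow \eqn{V(t) = V_0 e^{rt}} with a
#' class-specific rate r (shrinking for responders, growing for
#' progressors); vehicle arms always grow. Length and width are back-solved
#' from the noisy volume with a fixed 1.25 aspect ratio, and measurement
#' noise is multiplicative lognormal. The true class of every model is
#' returned separately, never embedded in the measurement table.
#'
#' @param config A [synthetic_config()].
#' @return A list with `measurements` (caliper tibble) and `truth`
#'   (`model_id`, `true_class`).
#' @export
sim_growth_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  rates <- class_growth_rates()
  vehicle_rate <- log(3) / 35 # +200% at day 35: controls always progress
  days <- c(0, 3, 7, 10, 14, 17, 21, 24, 28, 31, 35)
  classes <- rep(names(config$class_counts), config$class_counts)
  withr::with_seed(stream_seed(config, "growth"), {
    truth <- tibble::tibble(
      model_id = sprintf("PDX%03d", seq_len(config$n_models)),
      true_class = sample(classes)
    )
    aspect <- 1.25
    meas <- purrr::pmap_dfr(truth, function(model_id, true_class) {
      purrr::map_dfr(c("treated", "vehicle"), function(arm) {
        r <- if (arm == "vehicle") vehicle_rate else rates[[true_class]]
        purrr::map_dfr(seq_len(config$tumors_per_model), function(tumor) {
          v0 <- stats::runif(
            1, config$baseline_volume_range[1],
            config$baseline_volume_range[2]
          )
          v <- v0 * exp(r * days) *
            exp(stats::rnorm(length(days), 0, config$growth_noise_sd))
          w <- (6 * v / (pi * aspect))^(1 / 3)
          tibble::tibble(
            model_id = model_id,
            animal_id = sprintf("%s_%s_%d", model_id, arm, tumor),
            arm = arm,
            day = days,
            length_mm = aspect * w,
            width_mm = w
          )
        })
      })
    })
  })
  list(measurements = meas, truth = truth)
}

# Score templates: a resistant-consistent panel fires exactly one rule; a
# sensitive-consistent panel fires none.
draw_panel_scores <- function(n, resistant_like) {
  rule <- ifelse(resistant_like, sample(c("p16", "prb", "cyclin", "basal"),
    n,
    replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1)
  ), "none")
  p16 <- ifelse(rule == "p16", sample(2:4, n, replace = TRUE),
    sample(0:1, n, replace = TRUE)
  )
  prb <- ifelse(rule == "prb", sample(0:2, n, replace = TRUE),
    sample(3:4, n, replace = TRUE)
  )
  e1 <- ifelse(rule == "cyclin", sample(5:8, n, replace = TRUE),
    sample(0:4, n, replace = TRUE)
  )
  d1 <- sample(0:6, n, replace = TRUE)
  subtype <- ifelse(rule == "basal", "Basal",
    sample(c("LumA", "LumB", "HER2E"), n, replace = TRUE)
  )
  tibble::tibble(
    p16 = p16, prb = prb, cyclin_e1 = e1, cyclin_d1 = d1, subtype = subtype
  )
}

#' Simulate an IHC biomarker panel cohort
#'
#' Draws true resistant/sensitive labels (balanced), then generates ordinal
#' scores that are consistent with the composite rule for the true class
#' with probability `1 - label_noise` and consistent with the opposite
#' class otherwise, so the composite classifier's expected accuracy equals
#' `1 - label_noise` by construction.
#'
#' @param config A [synthetic_config()].
#' @return A list with `panel` (scores + `sample_id`) and `truth`
#'   (`sample_id`, `response`).
#' @export
sim_biomarker_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$biomarker_n
  withr::with_seed(stream_seed(config, "biomarker"), {
    response <- sample(c("resistant", "sensitive"), n, replace = TRUE)
    flip <- stats::runif(n) < config$label_noise
    looks_resistant <- (response == "resistant") != flip
    scores <- draw_panel_scores(n, looks_resistant)
  })
  panel <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%03d", seq_len(n))),
    scores
  )
  truth <- tibble::tibble(panel$sample_id, response) %>%
    rlang::set_names(c("sample_id", "response"))
  list(panel = panel, truth = truth)
}

#' Simulate a metastatic exposure cohort with a double-hit association
#'
#' Exposure is Bernoulli with the configured prevalence. Given exposure
#' status, the joint mutation/deletion state is drawn from a log-linear
#' model whose interaction with exposure equals `double_hit_log_or`, so in
#' the logistic regression of exposure on mutation, deletion and their
#' product the interaction coefficient recovers exactly that log odds
#' ratio (and the main effects are null). Optionally the binary flags are
#' realized into concrete variant records (protein-change strings styled
#' after targeted-panel reports) and allele copy-number records consistent
#' with the flags.
#'
#' @param config A [synthetic_config()].
#' @param realize Also emit `variants` and `copy_numbers` tables
#'   implementing the flags (default `FALSE`).
#' @return A list with `cohort` (tibble: `patient_id`, `exposed`,
#'   `mutation`, `deletion`) and, when `realize = TRUE`, `variants` and
#'   `copy_numbers`.
#' @export
sim_genomic_cohort <- function(config, realize = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$cohort_n
  am <- stats::qlogis(config$mutation_prev)
  ad <- stats::qlogis(config$deletion_prev)
  joint_probs <- function(theta) {
    w <- c(
      `00` = 0,
      `10` = am,
      `01` = ad,
      `11` = am + ad + theta
    )
    exp(w) / sum(exp(w))
  }
  p0 <- joint_probs(0)
  p1 <- joint_probs(config$double_hit_log_or)
  states <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  withr::with_seed(stream_seed(config, "genomic"), {
    exposed <- stats::rbinom(n, 1, config$exposure_prev)
    idx <- ifelse(exposed == 1,
      sample.int(4, n, replace = TRUE, prob = p1),
      sample.int(4, n, replace = TRUE, prob = p0)
    )
    cohort <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      exposed = exposed,
      mutation = states[idx, 1],
      deletion = states[idx, 2]
    )
    out <- list(cohort = cohort)
    if (realize) {
      mut_ids <- cohort$patient_id[cohort$mutation == 1]
      templates <- c(
        "p.M695Nfs*26", "p.K810*", "p.X180_splice", "p.R320*",
        "p.Q217Efs*5", "p.L199P", "p.E137K"
      )
      out$variants <- tibble::tibble(
        sample_id = mut_ids,
        gene = "RB1",
        protein_change = sample(templates, length(mut_ids), replace = TRUE),
        consequence = NA_character_
      )
      minor <- ifelse(cohort$deletion == 1,
        stats::runif(n, 0, 0.009), stats::runif(n, 0.5, 1.2)
      )
      out$copy_numbers <- tibble::tibble(
        sample_id = cohort$patient_id,
        gene = "RB1",
        minor_cn = minor,
        major_cn = minor + stats::runif(n, 0.1, 1.0)
      )
    }
  })
  out
}

#' Simulate ex vivo spheroid readouts and dose-response plates
#'
#' Area changes are class-conditional normal (sensitive models centered at
#' the configured mean reduction, resistant at zero) and realized as
#' replicate spheroid areas around a vehicle mean. The dose plate is
#' generated from a known four-parameter logistic curve with configurable
#' multiplicative noise, for estimator-recovery testing.
#'
#' @param config A [synthetic_config()].
#' @param ic50_true True IC50 for the dose plate (default 1).
#' @param n_doses Number of log-spaced doses (default 8).
#' @param plate_noise_sd Multiplicative noise SD on the plate (default 0.1).
#' @return A list with `areas` (long spheroid tibble), `truth` (per-model
#'   response label and true change), and `plate` (normalized dose tibble
#'   with `dose`, `growth_pct`).
#' @export
sim_exvivo <- function(config, ic50_true = 1, n_doses = 8, plate_noise_sd = 0.1) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$exvivo_n_models
  withr::with_seed(stream_seed(config, "exvivo"), {
    response <- sample(c("sensitive", "resistant"), n,
      replace = TRUE, prob = c(0.4, 0.6)
    )
    mu <- ifelse(response == "sensitive", config$exvivo_sens_mean,
      config$exvivo_res_mean
    )
    change <- stats::rnorm(n, mu, config$exvivo_sd)
    truth <- tibble::tibble(
      model_id = sprintf("PDC%03d", seq_len(n)),
      response = response,
      true_change = change
    )
    areas <- purrr::pmap_dfr(truth, function(model_id, response, true_change) {
      veh <- stats::rlnorm(4, meanlog = log(10000), sdlog = 0.05)
      trt <- stats::rlnorm(4,
        meanlog = log(10000 * (1 + true_change / 100)), sdlog = 0.05
      )
      tibble::tibble(
        model_id = model_id,
        condition = rep(c("vehicle", "treated"), each = 4),
        replicate = rep(1:4, 2),
        area = c(veh, trt)
      )
    })
    doses <- 10^seq(log10(ic50_true) - 2, log10(ic50_true) + 2,
      length.out = n_doses
    )
    pl <- purrr::map_dfr(1:3, function(rep) {
      y <- 100 / (1 + (doses / ic50_true)) # 4PL: lower 0, upper 100, hill 1
      tibble::tibble(
        dose = doses, replicate = rep,
        growth_pct = y * exp(stats::rnorm(n_doses, 0, plate_noise_sd))
      )
    })
  })
  list(areas = areas, truth = truth, plate = pl)
}

#' Simulate a qPCR Ct panel with stable and unstable reference genes
#'
#' Each sample gets a shared offset (loading/input variation); stable
#' reference genes track that offset with small residual noise, unstable
#' candidates add large gene-specific noise, and target genes carry a
#' group effect for downstream comparison tests.
#'
#' @param config A [synthetic_config()].
#' @param n_targets Number of target genes (default 4).
#' @param stable_sd,unstable_sd Residual Ct SDs (defaults 0.05 and 1.5).
#' @return A list with `ct` (wide tibble, `gene` column + samples),
#'   `candidates` (the 3 reference candidates, two stable plus one
#'   unstable) and `groups` (two balanced sample groups).
#' @export
sim_qpcr <- function(config, n_targets = 4, stable_sd = 0.05, unstable_sd = 1.5) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$qpcr_n_samples
  samples <- sprintf("S%02d", seq_len(n))
  withr::with_seed(stream_seed(config, "qpcr"), {
    offset <- stats::rnorm(n, 0, 1)
    genes <- c(
      "GAPDH", "ACTB", "HK_unstable",
      sprintf("TARGET%d", seq_len(n_targets))
    )
    group <- rep(c("A", "B"), length.out = n)
    ct <- purrr::map(genes, function(g) {
      base <- stats::runif(1, 18, 28)
      eff <- if (grepl("^TARGET", g)) ifelse(group == "B", -1, 0) else 0
      noise_sd <- if (g == "HK_unstable") unstable_sd else stable_sd
      base + offset + eff + stats::rnorm(n, 0, noise_sd)
    })
  })
  m <- do.call(rbind, ct)
  rownames(m) <- genes
  colnames(m) <- samples
  ct_tbl <- tibble::as_tibble(m, rownames = "gene")
  list(
    ct = ct_tbl,
    candidates = c("GAPDH", "ACTB", "HK_unstable"),
    groups = tibble::tibble(
      sample = samples,
      group = rep(c("A", "B"), length.out = n)
    )
  )
}
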