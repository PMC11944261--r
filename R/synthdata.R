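#' Configuration of a synthetic 24-2 cohort
#'
#' Defines the statistical structure of a simulated clinic population:
#' demographics, disease prevalence, the mix of glaucomatous defect
#' archetypes (nerve-fibre-bundle-shaped location masks concentrated in
#' the superior-temporal and inferior-nasal regions, where glaucomatous
#' loss typically appears first), defect depth, measurement noise and
#' perimetric reliability. Demographic defaults describe a large tertiary
#' glaucoma-service population: age 61.86 (17.40) years, 58% female, a
#' majority-White race mix, log-normal follow-up with median about 2.5
#' years, and a false-positive-rate distribution under which roughly 4% of
#' exams fail the 33% reliability cut.
#'
#' Defect depth is controlled either by severity-band targeting (the
#' default: each glaucomatous eye draws a target mean deviation from the
#' configured mild / moderate / severe mixture and the archetype depth is
#' solved from it) or, when `severity_targets` is `NULL`, directly from
#' the depth distribution — the mode used for depth-controlled validation
#' experiments.
#'
#' @param n_patients Number of patients.
#' @param exams_per_patient Integer vector sampled uniformly per patient.
#' @param age_mean,age_sd,age_range Age distribution (years), truncated.
#' @param female_prop Proportion of female patients.
#' @param race_props Named race proportions (renormalised).
#' @param prevalence Proportion of glaucomatous (GL) patients.
#' @param archetype_mix Named mix over `ST_arcuate`, `IN_arcuate`,
#'   `nasal_step`, `paracentral`, `diffuse` (renormalised).
#' @param severity_targets Named fractions over mild/moderate/severe, or
#'   `NULL` for direct depth control.
#' @param defect_depth_mean,defect_depth_sd,defect_depth_min Depth (dB) of
#'   archetype defects when `severity_targets` is `NULL`.
#' @param noise_sd Measurement noise SD, dB.
#' @param fpr_shape1,fpr_shape2 Beta parameters of the false-positive
#'   rate.
#' @param follow_up_meanlog,follow_up_sdlog Log-normal follow-up (years),
#'   truncated to \[0.1, 30\].
#' @param progression_db_per_year Linear worsening on defect locations
#'   across visits (default 0: cross-sectional framing).
#' @param seed Integer seed.
#' @return A `vf_sim_config` list.
#' @export
vf_sim_config <- function(n_patients = 200,
                          exams_per_patient = c(2, 3),
                          age_mean = 61.86, age_sd = 17.40,
                          age_range = c(20, 95),
                          female_prop = 0.58,
                          race_props = c(White = 0.7018, Black = 0.1170,
                                         Asian = 0.0602,
                                         AmericanIndianAlaskaNative = 0.0398,
                                         Other = 0.0759),
                          prevalence = 0.45,
                          archetype_mix = c(ST_arcuate = 0.30,
                                            IN_arcuate = 0.25,
                                            nasal_step = 0.20,
                                            paracentral = 0.15,
                                            diffuse = 0.10),
                          severity_targets = c(mild = 0.5, moderate = 0.3,
                                               severe = 0.2),
                          defect_depth_mean = 12, defect_depth_sd = 4,
                          defect_depth_min = 4,
                          noise_sd = 1.5,
                          fpr_shape1 = 1, fpr_shape2 = 8,
                          follow_up_meanlog = log(2.49),
                          follow_up_sdlog = 1.81,
                          progression_db_per_year = 0,
                          seed = 1) {
  stopifnot(n_patients >= 1, prevalence >= 0, prevalence <= 1,
            age_sd >= 0, noise_sd >= 0, all(exams_per_patient >= 1))
  norm1 <- function(p) {
    if (abs(sum(p) - 1) > 0.02) stop_vf("proportions must sum to 1")
    p / sum(p)
  }
  cfg <- list(n_patients = as.integer(n_patients),
              exams_per_patient = as.integer(exams_per_patient),
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              female_prop = female_prop, race_props = norm1(race_props),
              prevalence = prevalence,
              archetype_mix = norm1(archetype_mix),
              severity_targets = if (is.null(severity_targets)) NULL
              else norm1(severity_targets),
              defect_depth_mean = defect_depth_mean,
              defect_depth_sd = defect_depth_sd,
              defect_depth_min = defect_depth_min,
              noise_sd = noise_sd,
              fpr_shape1 = fpr_shape1, fpr_shape2 = fpr_shape2,
              follow_up_meanlog = follow_up_meanlog,
              follow_up_sdlog = follow_up_sdlog,
              progression_db_per_year = progression_db_per_year,
              seed = as.integer(seed))
  class(cfg) <- "vf_sim_config"
  cfg
}

#' Packaged defect archetype masks
#'
#' Location-index masks (with per-location depth weights) for the defect
#' archetypes, defined in the OD coordinate frame and mirrored
#' automatically for OS grids. The `diffuse` archetype is a general
#' depression at 60% of the nominal depth with a superior arcuate focal
#' accent deeper than the nominal depth: pure diffuse loss with no focal
#' component is atypical of glaucomatous fields and would be invisible to
#' pattern-deviation criteria by construction, since pattern deviation
#' subtracts the general height.
#'
#' @param grid A [vf_grid()].
#' @return Named list of weight vectors over the 52 test locations
#'   (feature order).
#' @export
vf_archetype_masks <- function(grid = vf_grid("OD")) {
  path <- system.file("extdata", "archetypes.csv", package = "vfstack")
  tab <- utils::read.csv(path)
  if (attr(grid, "laterality") == "OS") tab$x <- -tab$x
  test <- grid[!grid$is_blind_spot, ]
  mask_of <- function(sub) {
    w <- numeric(52)
    for (i in seq_len(nrow(sub))) {
      f <- test$feature_index[test$x == sub$x[i] & test$y == sub$y[i]]
      if (length(f) != 1) stop_vf("archetype location (%g, %g) not on grid",
                                  sub$x[i], sub$y[i])
      w[f] <- sub$weight[i]
    }
    w
  }
  masks <- lapply(split(tab, tab$archetype), mask_of)
  masks$diffuse <- pmax(rep(0.6, 52), masks$diffuse_accent)
  masks$diffuse_accent <- NULL
  masks
}

# Sample a target MD for one glaucomatous eye from the configured severity
# mixture; band shapes follow truncated normals with the conventional band
# means/SDs.
sample_target_md <- function(cfg) {
  band <- sample(names(cfg$severity_targets), 1, prob = cfg$severity_targets)
  pars <- switch(band,
                 mild = c(-1.13, 1.73, -4.2, 2),
                 moderate = c(-5.83, 1.12, -8.17, -4.2),
                 severe = c(-16.34, 6.70, -33, -8.17))
  repeat {
    v <- stats::rnorm(1, pars[1], pars[2])
    if (v > pars[3] && v <= pars[4]) return(list(band = band, md = v))
  }
}

#' Simulate one visual field exam
#'
#' Sensitivity at each location is the age-expected normal minus the
#' archetype defect (glaucomatous eyes only) plus Gaussian measurement
#' noise, floored at 0 dB (not seen). TD is computed against the same
#' normative reference, so the stored ground-truth deviation map is
#' recovered exactly by [vf_total_deviation()].
#'
#' @param age Age in years.
#' @param defect Numeric vector of 52 defect depths (dB), e.g.
#'   `depth * vf_archetype_masks(grid)$ST_arcuate`; use zeros for a
#'   non-glaucomatous eye. Negative entries mean sensitivity above the
#'   age norm (used by severity-band targeting for mild fields).
#' @param noise_sd Measurement noise SD, dB.
#' @param norm A [vf_normative()].
#' @param seed Optional seed (omit when already inside a seeded stream).
#' @return List with `sensitivities`, `td`, `pd`, `md`, `true_deviation`.
#' @export
vf_simulate_exam <- function(age, defect = numeric(52), noise_sd = 1.5,
                             norm = vf_normative(), seed = NULL) {
  stopifnot(length(defect) == 52, all(is.finite(defect)))
  run <- function() {
    expected <- expected_sensitivity(norm, age)
    sens <- pmax(expected - defect + stats::rnorm(52, 0, noise_sd), 0)
    td <- sens - expected
    list(sensitivities = sens, td = td,
         pd = vf_pattern_deviation(td, norm$gh_rank),
         md = vf_mean_deviation(td), true_deviation = td)
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Simulate a longitudinal 24-2 cohort with ground-truth labels
#'
#' Draws patients with demographics, reliability indices and follow-up
#' from the configured distributions; glaucomatous patients carry a defect
#' archetype whose depth either targets a severity-band mean deviation or
#' follows the configured depth distribution. Exam dates span the
#' patient's follow-up time. Fully deterministic given `config$seed`.
#'
#' @param config A [vf_sim_config()].
#' @param grid A [vf_grid()].
#' @param norm A [vf_normative()].
#' @return List with `cohort` (cohort data frame, including the `label`
#'   column) and `truth` (per-patient archetype, depth, target band).
#' @export
vf_simulate_cohort <- function(config = vf_sim_config(),
                               grid = vf_grid("OD"),
                               norm = vf_normative(grid)) {
  stopifnot(inherits(config, "vf_sim_config"))
  masks <- vf_archetype_masks(grid)
  with_local_seed(config$seed, {
    rows <- list(); truth <- list()
    for (i in seq_len(config$n_patients)) {
      pid <- sprintf("P%05d", i)
      age0 <- min(max(stats::rnorm(1, config$age_mean, config$age_sd),
                      config$age_range[1]), config$age_range[2])
      gender <- if (stats::runif(1) < config$female_prop) "Female" else "Male"
      race <- sample(names(config$race_props), 1, prob = config$race_props)
      fup <- min(max(stats::rlnorm(1, config$follow_up_meanlog,
                                   config$follow_up_sdlog), 0.1), 30)
      is_gl <- stats::runif(1) < config$prevalence
      archetype <- NA_character_; depth <- 0; band <- NA_character_
      diffuse_db <- 0
      defect <- numeric(52)
      if (is_gl) {
        archetype <- sample(names(config$archetype_mix), 1,
                            prob = config$archetype_mix)
        w <- masks[[archetype]]
        if (!is.null(config$severity_targets)) {
          # A focal archetype alone cannot reach moderate/severe mean
          # deviations (advanced glaucomatous fields combine focal and
          # widespread loss), so the focal depth is capped and the
          # remaining MD target is carried by a uniform component, which
          # may be negative (a field sitting above the age norm) for mild
          # targets.
          tm <- sample_target_md(config)
          band <- tm$band
          depth <- min(max(-tm$md * 52 / sum(w), 4), 25)
          diffuse_db <- -tm$md - depth * sum(w) / 52
          defect <- depth * w + diffuse_db
        } else {
          depth <- max(stats::rnorm(1, config$defect_depth_mean,
                                    config$defect_depth_sd),
                       config$defect_depth_min)
          defect <- depth * w
        }
      }
      n_e <- if (length(config$exams_per_patient) == 1) {
        config$exams_per_patient
      } else {
        sample(config$exams_per_patient, 1)
      }
      t_offsets <- if (n_e == 1) 0 else seq(0, fup, length.out = n_e)
      date0 <- as.Date("2018-01-01") + floor(stats::runif(1, 0, 365))
      for (e in seq_len(n_e)) {
        d_e <- defect
        if (config$progression_db_per_year > 0 && is_gl) {
          d_e <- defect + (masks[[archetype]] > 0) *
            config$progression_db_per_year * t_offsets[e]
        }
        # ageing across visits, kept inside the normative fitted range
        age_e <- min(age0 + t_offsets[e], norm$age_range[2])
        ex <- vf_simulate_exam(age_e, d_e, config$noise_sd, norm)
        row <- data.frame(
          patient_id = pid, eye = attr(grid, "laterality"),
          date = date0 + round(t_offsets[e] * 365.25),
          age = age_e, gender = gender, race = race,
          follow_up_years = fup,
          fpr = stats::rbeta(1, config$fpr_shape1, config$fpr_shape2),
          md = ex$md, label = if (is_gl) "GL" else "non-GL",
          stringsAsFactors = FALSE)
        row[paste0("s", 1:52)] <- as.list(ex$sensitivities)
        row[paste0("td", 1:52)] <- as.list(ex$td)
        row[paste0("pd", 1:52)] <- as.list(ex$pd)
        rows[[length(rows) + 1L]] <- row
      }
      truth[[i]] <- data.frame(patient_id = pid,
                               label = if (is_gl) "GL" else "non-GL",
                               archetype = archetype, depth = depth,
                               diffuse_db = diffuse_db,
                               severity_band = band,
                               stringsAsFactors = FALSE)
    }
    list(cohort = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}
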