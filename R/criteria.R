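#' Parameterisation of one rule-based field criterion
#'
#' Every packaged criterion (LoGTS, UKGTS, Kang, HAP2 part 1, Foster) is an
#' instance of one generic cluster-rule engine: flag locations at or beyond
#' a probability level on the TD or PD map, find contiguous clusters, and
#' pass when a large-enough cluster contains at least one sufficiently
#' extreme "anchor" point, optionally conjoined with a glaucoma hemifield
#' test (GHT) and/or PSD abnormality requirement. An eye is called
#' glaucomatous when at least `confirmation_tests` exams on distinct dates
#' qualify.
#'
#' @param name Criterion name.
#' @param map_kind `"TD"` or `"PD"` — which probability map the rule reads.
#' @param cluster_min_size Minimum cluster size (>= 1).
#' @param cluster_level Probability category flagged points must reach
#'   (`"p<5%"`, `"p<2%"`, `"p<1%"`, `"p<0.5%"`).
#' @param anchor_level Category at least one cluster member must reach; at
#'   least as extreme as `cluster_level`.
#' @param non_edge_only Exclude edge locations before clustering.
#' @param same_hemifield Forbid clusters straddling the horizontal meridian.
#' @param require_ght_outside Additionally require GHT "outside normal
#'   limits".
#' @param require_psd_abnormal Additionally require PSD above the normative
#'   `psd_percentile`.
#' @param psd_percentile Percentile defining PSD abnormality (default 0.95).
#' @param confirmation_tests Number of qualifying distinct-date exams
#'   required (default 1).
#' @return A `vf_criterion_spec` object.
#' @export
vf_criterion_spec <- function(name, map_kind = c("TD", "PD"),
                              cluster_min_size = 3,
                              cluster_level = "p<5%",
                              anchor_level = "p<1%",
                              non_edge_only = FALSE,
                              same_hemifield = FALSE,
                              require_ght_outside = FALSE,
                              require_psd_abnormal = FALSE,
                              psd_percentile = 0.95,
                              confirmation_tests = 1) {
  map_kind <- match.arg(map_kind)
  lv <- vf_prob_levels()
  cl <- match(cluster_level, lv) - 1L
  an <- match(anchor_level, lv) - 1L
  if (is.na(cl) || cl < 1L) stop_vf("unknown cluster_level '%s'", cluster_level)
  if (is.na(an)) stop_vf("unknown anchor_level '%s'", anchor_level)
  if (an < cl) stop_vf("anchor_level must be at least as extreme as cluster_level")
  if (cluster_min_size < 1) stop_vf("cluster_min_size must be >= 1")
  if (confirmation_tests < 1) stop_vf("confirmation_tests must be >= 1")
  structure(list(
    name = name, map_kind = map_kind,
    cluster_min_size = as.integer(cluster_min_size),
    cluster_level = cluster_level, cluster_code = cl,
    anchor_level = anchor_level, anchor_code = an,
    non_edge_only = isTRUE(non_edge_only),
    same_hemifield = isTRUE(same_hemifield),
    require_ght_outside = isTRUE(require_ght_outside),
    require_psd_abnormal = isTRUE(require_psd_abnormal),
    psd_percentile = psd_percentile,
    confirmation_tests = as.integer(confirmation_tests)
  ), class = "vf_criterion_spec")
}

#' @export
print.vf_criterion_spec <- function(x, ...) {
  cat(sprintf(
    "%s: %s map, cluster >= %d @ %s (anchor %s)%s%s%s%s, confirm %d\n",
    x$name, x$map_kind, x$cluster_min_size, x$cluster_level, x$anchor_level,
    if (x$non_edge_only) ", non-edge" else "",
    if (x$same_hemifield) ", same hemifield" else "",
    if (x$require_ght_outside) ", GHT outside" else "",
    if (x$require_psd_abnormal) ", PSD abnormal" else "",
    x$confirmation_tests))
  invisible(x)
}

#' Load criterion specifications from a YAML config
#'
#' With no `path`, loads the five packaged default criteria.
#'
#' @param path YAML file: one block per criterion with the fields of
#'   [vf_criterion_spec()] (`map` for `map_kind`).
#' @return Named list of `vf_criterion_spec` objects.
#' @examples
#' specs <- vf_default_criteria()
#' names(specs)
#' @export
vf_read_criteria <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    b <- raw[[nm]]
    vf_criterion_spec(
      name = nm, map_kind = b$map %||% b$map_kind %||% "TD",
      cluster_min_size = b$cluster_min_size %||% 3,
      cluster_level = b$cluster_level %||% "p<5%",
      anchor_level = b$anchor_level %||% b$cluster_level %||% "p<5%",
      non_edge_only = b$non_edge_only %||% FALSE,
      same_hemifield = b$same_hemifield %||% FALSE,
      require_ght_outside = b$require_ght_outside %||% FALSE,
      require_psd_abnormal = b$require_psd_abnormal %||% FALSE,
      psd_percentile = b$psd_percentile %||% 0.95,
      confirmation_tests = b$confirmation_tests %||% 1
    )
  })
  stats::setNames(out, names(raw))
}

#' @rdname vf_read_criteria
#' @export
vf_default_criteria <- function() {
  vf_read_criteria(system.file("extdata", "criteria.yaml", package = "vfstack"))
}

#' Serialise criterion specifications back to YAML
#'
#' @param specs Named list of `vf_criterion_spec` objects.
#' @param path Output file.
#' @export
vf_write_criteria <- function(specs, path) {
  raw <- lapply(specs, function(s) list(
    map = s$map_kind, cluster_min_size = s$cluster_min_size,
    cluster_level = s$cluster_level, anchor_level = s$anchor_level,
    non_edge_only = s$non_edge_only, same_hemifield = s$same_hemifield,
    require_ght_outside = s$require_ght_outside,
    require_psd_abnormal = s$require_psd_abnormal,
    psd_percentile = s$psd_percentile,
    confirmation_tests = s$confirmation_tests))
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Evaluate the cluster component of a criterion on one exam
#'
#' @param prob Integer probability codes for the 52 test locations (feature
#'   order), as from [vf_probability_map()].
#' @param spec A [vf_criterion_spec()].
#' @param grid A [vf_grid()].
#' @param connectivity Contiguity scheme (8 or 4).
#' @return List with `passes` (logical) and `clusters` (the qualifying
#'   clusters, as location-index sets).
#' @export
vf_evaluate_cluster_rule <- function(prob, spec, grid, connectivity = 8) {
  if (length(prob) != 52 || anyNA(prob)) {
    stop_vf("need a complete 52-value probability map")
  }
  flags <- prob >= spec$cluster_code
  clusters <- vf_find_clusters(flags, grid,
                               non_edge_only = spec$non_edge_only,
                               same_hemifield = spec$same_hemifield,
                               connectivity = connectivity)
  loc_of_feat <- vf_location_of_feature(grid, 1:52)
  code_at_loc <- function(loc) prob[match(loc, loc_of_feat)]
  qual <- Filter(function(cl) {
    length(cl) >= spec$cluster_min_size &&
      any(code_at_loc(cl) >= spec$anchor_code)
  }, clusters)
  list(passes = length(qual) > 0, clusters = qual)
}

ght_zone_table <- function(grid) {
  path <- system.file("extdata", "ght_zones.csv", package = "vfstack")
  z <- utils::read.csv(path)
  if (attr(grid, "laterality") == "OS") z$x <- -z$x
  z
}

# probability-code -> GHT point score
ght_point_scores <- c(0, 2, 5, 8, 10)

#' Glaucoma hemifield test (simplified)
#'
#' Scores the PD probability levels of five superior zones and their
#' mirror-image inferior zones (packaged zone table covering all 26
#' superior test locations) and compares each mirrored pair. A pair whose
#' absolute score difference reaches `outside_threshold` makes the test
#' "outside normal limits"; reaching `borderline_threshold` makes it
#' "borderline"; otherwise "within normal limits". Point scores are 0 / 2 /
#' 5 / 8 / 10 for normal / p<5% / p<2% / p<1% / p<0.5%. This is an
#' approximation of the proprietary instrument test built from the same
#' ingredients (mirrored zones, pattern-deviation probabilities).
#'
#' @param pd_prob Integer PD probability codes for the 52 locations.
#' @param grid A [vf_grid()].
#' @param outside_threshold Zone score difference for "outside" (default 12).
#' @param borderline_threshold For "borderline" (default 6).
#' @return List with `result` in `{"outside_normal_limits", "borderline",
#'   "within_normal_limits"}` and the 5x2 `zone_scores` matrix.
#' @export
vf_ght <- function(pd_prob, grid, outside_threshold = 12,
                   borderline_threshold = 6) {
  if (length(pd_prob) != 52 || anyNA(pd_prob)) {
    stop_vf("need a complete 52-value PD probability map")
  }
  zones <- ght_zone_table(grid)
  loc_of_feat <- vf_location_of_feature(grid, 1:52)
  score_at <- function(x, y) {
    loc <- grid$index[grid$x == x & grid$y == y]
    ght_point_scores[pd_prob[match(loc, loc_of_feat)] + 1L]
  }
  zs <- matrix(0, nrow = 5, ncol = 2,
               dimnames = list(paste0("zone", 1:5), c("superior", "inferior")))
  for (k in 1:5) {
    zk <- zones[zones$zone == k, ]
    zs[k, "superior"] <- sum(mapply(score_at, zk$x, zk$y))
    zs[k, "inferior"] <- sum(mapply(score_at, zk$x, -zk$y))
  }
  d <- max(abs(zs[, 1] - zs[, 2]))
  result <- if (d >= outside_threshold) "outside_normal_limits"
  else if (d >= borderline_threshold) "borderline"
  else "within_normal_limits"
  list(result = result, zone_scores = zs)
}

# Evaluate one criterion on the probability maps / PSD of a single exam.
# prob_td / prob_pd: 52 integer codes; psd: scalar dB; norm supplies the
# PSD abnormality threshold.
criterion_exam_qualifies <- function(spec, prob_td, prob_pd, psd, grid, norm,
                                     connectivity = 8) {
  prob <- if (spec$map_kind == "TD") prob_td else prob_pd
  cl <- vf_evaluate_cluster_rule(prob, spec, grid, connectivity)
  ok <- cl$passes
  if (ok && spec$require_ght_outside) {
    ok <- vf_ght(prob_pd, grid)$result == "outside_normal_limits"
  }
  if (ok && spec$require_psd_abnormal) {
    thr <- norm$psd_p95
    if (spec$psd_percentile != 0.95 || is.na(thr)) {
      stop_vf("PSD abnormality threshold unavailable for percentile %g",
              spec$psd_percentile)
    }
    ok <- psd > thr
  }
  list(qualifies = ok, clusters = cl$clusters)
}

#' Classify one eye's exam series under a criterion
#'
#' Evaluates the per-exam rule on every exam and returns a glaucomatous
#' verdict when at least `spec$confirmation_tests` exams on distinct dates
#' qualify. Exams are rows of a cohort data frame for a single eye.
#'
#' @param exams Cohort rows for one eye (must contain `td1..td52`,
#'   `pd1..pd52` and `date`).
#' @param spec A [vf_criterion_spec()].
#' @param grid A [vf_grid()].
#' @param norm A [vf_normative()] (for probability maps and PSD threshold).
#' @param connectivity Contiguity scheme.
#' @return A `vf_criterion_verdict`: list with `name`, `is_glaucoma`,
#'   `qualifying_dates`, `evidence` (clusters of the qualifying exams) and
#'   `psd_values`.
#' @export
vf_classify_eye <- function(exams, spec, grid, norm, connectivity = 8) {
  if (nrow(exams) < 1) stop_vf("need at least one exam")
  ord <- order(as.Date(exams$date))
  exams <- exams[ord, , drop = FALSE]
  td <- vf_field_matrix(exams, "td")
  pd <- vf_field_matrix(exams, "pd")
  prob_td <- vf_probability_map(td, norm, "TD")
  prob_pd <- vf_probability_map(pd, norm, "PD")
  if (nrow(exams) == 1L) {
    prob_td <- matrix(prob_td, nrow = 1)
    prob_pd <- matrix(prob_pd, nrow = 1)
  }
  psd <- apply(td, 1, vf_psd)

  qual_dates <- character(0)
  evidence <- list()
  for (i in seq_len(nrow(exams))) {
    r <- criterion_exam_qualifies(spec, prob_td[i, ], prob_pd[i, ], psd[i],
                                  grid, norm, connectivity)
    if (r$qualifies) {
      qual_dates <- c(qual_dates, as.character(exams$date[i]))
      evidence[[length(evidence) + 1L]] <- r$clusters
    }
  }
  n_qual <- length(unique(qual_dates))
  structure(list(
    name = spec$name,
    is_glaucoma = n_qual >= spec$confirmation_tests,
    qualifying_dates = unique(qual_dates),
    evidence = evidence,
    psd_values = psd
  ), class = "vf_criterion_verdict")
}

#' Run all criteria over a cohort
#'
#' Applies [vf_classify_eye()] for every criterion to every eye and
#' returns the binary label matrix plus the pairwise agreement and
#' correlation among criteria.
#'
#' @param cohort Cohort data frame.
#' @param specs Named list of criterion specs (default: the five packaged
#'   criteria).
#' @param grid A [vf_grid()].
#' @param norm A [vf_normative()].
#' @param connectivity Contiguity scheme.
#' @return List with `labels` (data frame: patient_id, eye, one 0/1 column
#'   per criterion), `agreement` (pairwise fraction agreeing) and
#'   `correlation` (pairwise phi/Pearson correlation, `NA` where a column
#'   is constant).
#' @export
vf_run_all_criteria <- function(cohort, specs = vf_default_criteria(),
                                grid = vf_grid("OD"), norm = vf_normative(grid),
                                connectivity = 8) {
  key <- paste(cohort$patient_id, cohort$eye, sep = "|")
  eyes <- unique(key)
  lab <- matrix(0L, nrow = length(eyes), ncol = length(specs),
                dimnames = list(NULL, names(specs)))
  for (e in seq_along(eyes)) {
    rows <- cohort[key == eyes[e], , drop = FALSE]
    for (s in seq_along(specs)) {
      v <- vf_classify_eye(rows, specs[[s]], grid, norm, connectivity)
      lab[e, s] <- as.integer(v$is_glaucoma)
    }
  }
  ids <- do.call(rbind, strsplit(eyes, "|", fixed = TRUE))
  labels <- data.frame(patient_id = ids[, 1], eye = ids[, 2], lab,
                       stringsAsFactors = FALSE)
  k <- length(specs)
  agreement <- matrix(1, k, k, dimnames = list(names(specs), names(specs)))
  correlation <- agreement
  for (i in seq_len(k)) for (j in seq_len(k)) {
    agreement[i, j] <- mean(lab[, i] == lab[, j])
    correlation[i, j] <- if (stats::sd(lab[, i]) > 0 && stats::sd(lab[, j]) > 0) {
      stats::cor(lab[, i], lab[, j])
    } else NA_real_
  }
  list(labels = labels, agreement = agreement, correlation = correlation)
}
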