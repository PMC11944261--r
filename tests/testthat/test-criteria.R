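# Build a 52-vector of probability codes with chosen locations set to a
# level (codes: 0 normal, 1 p<5%, 2 p<2%, 3 p<1%, 4 p<0.5%).
prob_with <- function(locs, code, base = rep(0L, 52), grid = fix_grid) {
  feats <- grid$feature_index[match(locs, grid$index)]
  base[feats] <- code
  base
}

test_that("criterion specs validate their parameters", {
  expect_error(vf_criterion_spec("x", cluster_level = "p<1%",
                                 anchor_level = "p<5%"), "extreme")
  expect_error(vf_criterion_spec("x", cluster_level = "wrong"), "unknown")
  expect_error(vf_criterion_spec("x", cluster_min_size = 0), ">= 1")
  specs <- vf_default_criteria()
  expect_named(specs, c("LoGTS", "UKGTS", "Kang", "HAP2_p1", "Foster"))
  expect_equal(vapply(specs, function(s) s$map_kind, ""),
               c(LoGTS = "TD", UKGTS = "TD", Kang = "TD",
                 HAP2_p1 = "PD", Foster = "PD"))
})

test_that("the cluster rule needs size, anchor depth and location status", {
  g <- fix_grid
  spec <- vf_criterion_spec("hodapp", "PD", cluster_min_size = 3,
                            cluster_level = "p<5%", anchor_level = "p<1%",
                            non_edge_only = TRUE)
  expect_false(vf_evaluate_cluster_rule(rep(0L, 52), spec, g)$passes)

  # three contiguous non-edge points at p<5%, one at p<1%
  inner <- g$index[g$x %in% c(3, 9) & g$y == 9]        # (9,9), (3,9)
  trio <- c(inner, g$index[g$x == 9 & g$y == 15])      # + (9,15)
  expect_true(all(!g$is_edge[trio]))
  pm <- prob_with(trio, 1L)
  pm <- prob_with(trio[1], 3L, pm)
  r <- vf_evaluate_cluster_rule(pm, spec, g)
  expect_true(r$passes)
  expect_equal(sort(r$clusters[[1]]), sort(trio))

  # no anchor point -> fail
  expect_false(vf_evaluate_cluster_rule(prob_with(trio, 1L), spec, g)$passes)

  # same trio but one member replaced by an adjacent edge location -> fail
  edge_pt <- g$index[g$x == 15 & g$y == 15]
  pm2 <- prob_with(c(inner, edge_pt), 1L)
  pm2 <- prob_with(inner[1], 3L, pm2)
  expect_false(vf_evaluate_cluster_rule(pm2, spec, g)$passes)

  # the same map passes once edge points are allowed
  spec_all <- vf_criterion_spec("hodapp", "PD", 3, "p<5%", "p<1%",
                                non_edge_only = FALSE)
  expect_true(vf_evaluate_cluster_rule(pm2, spec_all, g)$passes)
  expect_error(vf_evaluate_cluster_rule(rep(0L, 10), spec, g), "52")
})

test_that("hemifield restriction severs clusters across the meridian", {
  g <- fix_grid
  straddle <- g$index[g$x == 3 & g$y %in% c(3, -3)]
  pm <- prob_with(straddle, 4L)
  spec2 <- vf_criterion_spec("pair", "TD", 2, "p<5%", "p<5%",
                             same_hemifield = TRUE)
  expect_false(vf_evaluate_cluster_rule(pm, spec2, g)$passes)
  spec2b <- vf_criterion_spec("pair", "TD", 2, "p<5%", "p<5%")
  expect_true(vf_evaluate_cluster_rule(pm, spec2b, g)$passes)
})

test_that("the hemifield test scores mirrored zones symmetrically", {
  g <- fix_grid
  expect_equal(vf_ght(rep(0L, 52), g)$result, "within_normal_limits")
  # deep superior arcuate, quiet inferior field
  sup_arc <- g$index[g$y == 9 & g$x %in% c(-3, 3, 9)]
  pm <- prob_with(sup_arc, 4L)
  r <- vf_ght(pm, g)
  expect_equal(r$result, "outside_normal_limits")
  expect_gte(max(abs(r$zone_scores[, 1] - r$zone_scores[, 2])), 12)
  # mirroring the field across the meridian leaves the verdict unchanged
  mirror_locs <- g$index[match(paste(g$x[sup_arc], -g$y[sup_arc]),
                               paste(g$x, g$y))]
  pm_m <- prob_with(mirror_locs, 4L)
  expect_equal(vf_ght(pm_m, g)$result, r$result)
  # a perfectly symmetric defect cancels
  pm_s <- prob_with(c(sup_arc, mirror_locs), 4L)
  expect_equal(vf_ght(pm_s, g)$result, "within_normal_limits")
})

test_that("eye-level classification honors confirmation requirements", {
  defect <- 18 * fix_masks$ST_arcuate
  e1 <- sim_exam_row(60, defect, 0.5, "2020-01-01", seed = 21)
  e2 <- sim_exam_row(60, defect, 0.5, "2020-06-01", seed = 22)
  e1b <- sim_exam_row(60, defect, 0.5, "2020-01-01", seed = 23)
  spec <- vf_default_criteria()$Kang
  spec2 <- vf_criterion_spec("Kang2", spec$map_kind, spec$cluster_min_size,
                             spec$cluster_level, spec$anchor_level,
                             spec$non_edge_only, spec$same_hemifield,
                             confirmation_tests = 2)
  expect_false(vf_classify_eye(e1, spec2, fix_grid, fix_norm)$is_glaucoma)
  expect_true(vf_classify_eye(rbind(e1, e2), spec2, fix_grid,
                              fix_norm)$is_glaucoma)
  # two qualifying exams on the same date do not confirm
  expect_false(vf_classify_eye(rbind(e1, e1b), spec2, fix_grid,
                               fix_norm)$is_glaucoma)
  # exam order within the data frame is irrelevant
  expect_true(vf_classify_eye(rbind(e2, e1), spec2, fix_grid,
                              fix_norm)$is_glaucoma)
  v <- vf_classify_eye(e1, spec, fix_grid, fix_norm)
  expect_true(v$is_glaucoma)
  expect_gt(length(v$evidence), 0)   # glaucoma verdicts carry evidence
  expect_error(vf_classify_eye(e1[0, ], spec, fix_grid, fix_norm), "one exam")
})

test_that("deep defects trip all five criteria; quiet fields none", {
  specs <- vf_default_criteria()
  gl <- sim_exam_row(62, 18 * fix_masks$IN_arcuate, 0.5, "2021-01-01",
                     seed = 31)
  quiet <- sim_exam_row(62, numeric(52), 0.5, "2021-01-01", seed = 32)
  for (s in specs) {
    expect_true(vf_classify_eye(gl, s, fix_grid, fix_norm)$is_glaucoma,
                label = paste(s$name, "on deep defect"))
    expect_false(vf_classify_eye(quiet, s, fix_grid, fix_norm)$is_glaucoma,
                 label = paste(s$name, "on quiet field"))
  }
})

test_that("verdicts are monotone in defect depth", {
  specs <- vf_default_criteria()
  base_mask <- fix_masks$ST_arcuate
  for (depth in c(6, 12, 20)) {
    shallow <- sim_exam_row(60, depth * base_mask, 0, "2020-01-01", seed = 1)
    deeper <- sim_exam_row(60, (depth + 6) * base_mask, 0, "2020-01-01",
                           seed = 1)
    for (s in specs) {
      v1 <- vf_classify_eye(shallow, s, fix_grid, fix_norm)$is_glaucoma
      v2 <- vf_classify_eye(deeper, s, fix_grid, fix_norm)$is_glaucoma
      expect_true(!v1 || v2, label = sprintf("%s depth %d", s$name, depth))
    }
  }
})

test_that("criterion specs round-trip through YAML with identical verdicts", {
  specs <- vf_default_criteria()
  path <- withr::local_tempfile(fileext = ".yaml")
  vf_write_criteria(specs, path)
  back <- vf_read_criteria(path)
  expect_equal(names(back), names(specs))
  exams <- do.call(rbind, lapply(1:6, function(i)
    sim_exam_row(55 + i, (4 * i) * fix_masks$nasal_step, 1,
                 sprintf("2020-%02d-01", i), pid = paste0("P", i),
                 seed = 40 + i)))
  for (nm in names(specs)) {
    for (i in 1:6) {
      row <- exams[i, , drop = FALSE]
      expect_equal(
        vf_classify_eye(row, back[[nm]], fix_grid, fix_norm)$is_glaucoma,
        vf_classify_eye(row, specs[[nm]], fix_grid, fix_norm)$is_glaucoma)
    }
  }
})

test_that("running all criteria yields per-eye labels and agreement", {
  cfg <- vf_sim_config(n_patients = 30, exams_per_patient = 1,
                       prevalence = 0.5, severity_targets = NULL,
                       defect_depth_mean = 16, defect_depth_sd = 2,
                       noise_sd = 1, seed = 77)
  sim <- vf_simulate_cohort(cfg, fix_grid, fix_norm)
  res <- vf_run_all_criteria(sim$cohort, grid = fix_grid, norm = fix_norm)
  expect_equal(nrow(res$labels), 30)
  expect_true(all(as.matrix(res$labels[, -(1:2)]) %in% 0:1))
  # shared signal: label columns correlate positively
  cc <- res$correlation[upper.tri(res$correlation)]
  expect_true(all(cc[!is.na(cc)] > 0))
  # quiet cohort -> all-zero matrix
  cfg0 <- vf_sim_config(n_patients = 10, exams_per_patient = 1,
                        prevalence = 0, noise_sd = 1, seed = 78)
  sim0 <- vf_simulate_cohort(cfg0, fix_grid, fix_norm)
  res0 <- vf_run_all_criteria(sim0$cohort, grid = fix_grid, norm = fix_norm)
  expect_true(all(as.matrix(res0$labels[, -(1:2)]) == 0))
})
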