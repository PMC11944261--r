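# Shared fixtures (built once per test run) and independent oracles used
# to cross-check the package's implementations.

fix_grid <- vf_grid("OD")
fix_grid_os <- vf_grid("OS")
fix_norm <- vf_normative(fix_grid)
fix_masks <- vf_archetype_masks(fix_grid)

# --- independent union-find over an explicit pair list -----------------------
# Used as the oracle for vf_find_clusters: connectivity is decided by a
# brute-force pairwise coordinate check, components by union-find.
oracle_clusters <- function(flags, grid, non_edge_only = FALSE,
                            same_hemifield = FALSE, connectivity = 8) {
  full <- logical(nrow(grid))
  full[!grid$is_blind_spot] <- flags[grid$feature_index[!grid$is_blind_spot]]
  active <- full & !grid$is_blind_spot
  if (non_edge_only) active <- active & !grid$is_edge
  idx <- which(active)
  if (length(idx) == 0) return(list())
  parent <- seq_len(nrow(grid))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in idx) for (b in idx) {
    if (a >= b) next
    dx <- abs(grid$x[a] - grid$x[b]); dy <- abs(grid$y[a] - grid$y[b])
    touch <- if (connectivity == 8) dx <= 6 && dy <= 6 else dx + dy == 6
    if (touch && same_hemifield &&
        sign(grid$y[a]) != sign(grid$y[b])) touch <- FALSE
    if (touch) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(idx, find, 1L)
  comps <- lapply(split(idx, roots), function(v) sort(unname(v)))
  comps <- unname(comps)
  ord <- order(-vapply(comps, length, 1L), vapply(comps, min, 1L))
  comps[ord]
}

# --- O(n^2) pairwise AUC oracle ---------------------------------------------
oracle_auc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# --- probability-category linear-scan oracle --------------------------------
oracle_prob_code <- function(dev, cuts) {
  # cuts: decreasing vector c(p5, p2, p1, p05); most extreme category whose
  # cutoff exceeds the deviation
  code <- 0L
  for (k in seq_along(cuts)) if (dev < cuts[k]) code <- k
  code
}

# A minimal cohort data frame of hand-set exams for filter tests.
make_mini_cohort <- function() {
  base <- data.frame(
    patient_id = c("A", "A", "B", "B", "C", "D", "D"),
    eye = "OD",
    date = as.Date(c("2020-01-01", "2020-09-01",   # A: span 0.67 y
                     "2020-01-01", "2020-01-01",   # B: same-day pair
                     "2020-01-01",                 # C: single exam
                     "2020-01-01", "2020-07-02")), # D: span exactly 0.5 y
    age = c(60, 60.7, 55, 55, 70, 65, 65.5),
    gender = "Female", race = "White",
    follow_up_years = 1, fpr = c(0.1, 0.2, 0.4, 0.33, 0.05, 0.1, 0.1),
    md = -1, stringsAsFactors = FALSE)
  base
}

# Simulated exams as one-row cohort data frames (for criteria tests).
sim_exam_row <- function(age, defect, noise_sd, date, pid = "P1",
                         norm = fix_norm, grid = fix_grid, seed = NULL) {
  ex <- vf_simulate_exam(age, defect, noise_sd, norm, seed = seed)
  row <- data.frame(patient_id = pid, eye = attr(grid, "laterality"),
                    date = as.Date(date), age = age, gender = "Female",
                    race = "White", follow_up_years = 1, fpr = 0.05,
                    md = ex$md, stringsAsFactors = FALSE)
  row[paste0("s", 1:52)] <- as.list(ex$sensitivities)
  row[paste0("td", 1:52)] <- as.list(ex$td)
  row[paste0("pd", 1:52)] <- as.list(ex$pd)
  row
}
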