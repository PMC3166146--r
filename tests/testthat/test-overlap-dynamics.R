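test_that("overlap classification covers all membership patterns", {
  cls <- classify_overlap(c("g1", "g2"), "g2", c("g2", "g3"))
  expect_identical(cls[c("g1", "g2", "g3")],
                   c(g1 = "ONLY_A", g2 = "ABC", g3 = "ONLY_C"))
  same <- classify_overlap(c("x", "y"), c("x", "y"), c("x", "y"))
  expect_true(all(same == "ABC"))
  disj <- classify_overlap("a", "b", "c")
  expect_identical(sort(unname(disj)), c("ONLY_A", "ONLY_B", "ONLY_C"))
  pairs <- classify_overlap(c("p", "q"), c("p", "r"), c("q", "r"))
  expect_identical(pairs[c("p", "q", "r")],
                   c(p = "AB", q = "CA", r = "BC"))
  expect_length(classify_overlap(character(0), character(0), character(0)), 0)
})

test_that("overlap fractions use the documented denominators", {
  expect_equal(consecutive_overlap_fraction(c("a", "b"), c("a", "b")), 1)
  expect_equal(consecutive_overlap_fraction(c("a", "b"), c("c", "d")), 0)
  expect_equal(consecutive_overlap_fraction(c("a", "b"), c("b", "c", "d")), 0.5)
  expect_true(is.na(consecutive_overlap_fraction(character(0), "a")))
  expect_equal(reference_overlap(c("a", "b"), c("a", "b", "c")),
               c(forward = 1, backward = 2 / 3))
  expect_equal(reference_overlap(letters[1:4], letters[1:3])[["backward"]], 1)
  q_i <- c("a", "b", "c", "x")
  q_ref <- c(letters[1:3], paste0("z", 1:27))
  expect_equal(reference_overlap(q_i, q_ref),
               c(forward = 0.75, backward = 0.10))
})

test_that("transition rates enumerate creations, deletions and moves", {
  prev <- c(g1 = "ONLY_A")
  curr <- c(g1 = "ABC", g2 = "ONLY_B")
  tr <- transition_rates(prev, curr, delta_n = 10)
  get <- function(cl, col) tr[tr$class == cl, col]
  expect_equal(get("ONLY_A", "move_out"), 1)
  expect_equal(get("ONLY_A", "deletion"), 0)
  expect_equal(get("ABC", "move_in"), 1)
  expect_equal(get("ABC", "creation"), 0)
  expect_equal(get("ONLY_B", "creation"), 1)
  expect_equal(get("ONLY_B", "creation_rate"), 0.1)
  same <- transition_rates(curr, curr, 5)
  expect_true(all(same[, c("creation", "deletion", "move_in", "move_out")] == 0))
  expect_error(transition_rates(prev, curr, 0), "positive")
})

test_that("class-count bookkeeping identity holds on real pipeline output", {
  pr <- moderate_run()
  tr <- pr$trajectories[[1]]
  rs <- rate_series(tr)
  for (i in 2:length(tr$sizes)) {
    step_rates <- rs[rs$step_to == i, ]
    for (cl in overlap_classes()) {
      r <- step_rates[step_rates$class == cl, ]
      expect_identical(
        tr$counts[i, cl],
        tr$counts[i - 1, cl] + r$creation + r$move_in - r$deletion - r$move_out,
        label = sprintf("bookkeeping for %s at step %d", cl, i))
    }
    # class counts partition the union of tissue detections
    expect_identical(sum(tr$counts[i, ]),
                     length(tr$membership[[i]]))
  }
})

test_that("distance and strength summaries average class members per tissue", {
  # minimal handcrafted series: one step, one replicate
  mk_scan <- function(tissue, ids, dist, p) {
    structure(list(eqtls = data.frame(
      transcript_id = ids, tissue = tissue, snp_id = paste0("s", seq_along(ids)),
      h = 1, p = p, distance_bp = dist, n_used = 10,
      stringsAsFactors = FALSE)), class = "scan_result")
  }
  series <- structure(list(
    sizes = 10L, tissues = c("A", "B", "C"),
    scans = list(list(list(
      A = mk_scan("A", c("g1", "g2"), c(5e5, -2e5), c(0.01, 1e-4)),
      B = mk_scan("B", "g2", 1e5, 1e-3),
      C = mk_scan("C", "g2", -3e5, 1e-5))))), class = "series_result")
  traj <- structure(list(membership = list(c(g1 = "ONLY_A", g2 = "ABC")),
                         sizes = 10L), class = "class_trajectory")
  ds <- distance_strength_summary(series, traj, step = 1, replicate = 1)
  only_a <- ds[ds$class == "ONLY_A" & ds$tissue == "A", ]
  expect_equal(only_a$mean_abs_delta_mb, 0.5)
  expect_equal(only_a$mean_neglog10p, 2)
  abc_a <- ds[ds$class == "ABC" & ds$tissue == "A", ]
  expect_equal(abc_a$mean_abs_delta_mb, 0.2)
  expect_equal(abc_a$mean_neglog10p, 4)
  # empty class x tissue cells are missing, not zero
  expect_true(is.na(ds$mean_abs_delta_mb[ds$class == "BC" & ds$tissue == "A"]))
  # two members with p = 0.01 and 0.0001: mean strength is 3.0
  expect_equal(mean(-log10(c(0.01, 1e-4))), 3)
})

test_that("Mann-Whitney comparison is exact for small samples and rank-invariant", {
  # U = 0 for fully separated samples of 3 vs 3: p = 2 / C(6,3) = 0.1
  expect_equal(compare_distance_distributions(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_gt(compare_distance_distributions(1:10, 1:10), 0.9)
  set.seed(61)
  x <- stats::rexp(30, 1 / 2e5)
  y <- stats::rexp(40, 1 / 5e5)
  expect_equal(compare_distance_distributions(x, y),
               compare_distance_distributions(log10(x), log10(y)))
  expect_error(compare_distance_distributions(numeric(0), 1:3), "non-empty")
})

test_that("specificity percentages are relative to each tissue's detections", {
  traj <- structure(list(
    membership = list(c(g1 = "ONLY_A", g2 = "ABC")), sizes = 10L),
    class = "class_trajectory")
  sp <- specificity_percentages(traj, 1)
  a <- sp[sp$tissue == "A", ]
  expect_equal(a$pct_specific, 50)
  expect_equal(a$pct_shared_all, 50)
  traj_abc <- structure(list(
    membership = list(c(g1 = "ABC", g2 = "ABC")), sizes = 10L),
    class = "class_trajectory")
  sp2 <- specificity_percentages(traj_abc, 1)
  expect_equal(sp2$pct_specific, c(0, 0, 0))
  expect_equal(sp2$pct_shared_all, c(100, 100, 100))
  # a tissue without detections reports missing, not zero
  traj_b <- structure(list(membership = list(c(g1 = "ONLY_B")), sizes = 10L),
                      class = "class_trajectory")
  sp3 <- specificity_percentages(traj_b, 1)
  expect_true(is.na(sp3$pct_specific[sp3$tissue == "A"]))
})

test_that("overlap curves cover both identity levels against the reference step", {
  pr <- moderate_run()
  oc <- overlap_curves(pr$series, "A", 1)
  expect_setequal(unique(oc$kind), c("consecutive", "forward_ref",
                                     "backward_ref"))
  expect_setequal(unique(oc$level), c("eqtl", "esnp"))
  k <- length(pr$series$sizes)
  # the reference step overlaps itself perfectly
  expect_equal(oc$value[oc$kind == "forward_ref" & oc$step == k], c(1, 1))
  expect_equal(oc$value[oc$kind == "backward_ref" & oc$step == k], c(1, 1))
  expect_true(all(oc$value >= 0 & oc$value <= 1, na.rm = TRUE))
})
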