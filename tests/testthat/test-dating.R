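test_that("divergence time follows T = Ks / 2r in Mya", {
  expect_equal(divergence_time(0, rate_model("r", 5.2e-9))$T_mya, 0)
  # within-Apiaceae clock on the youngest celery-coriander ortholog pair
  expect_equal(round(divergence_time(0.1103,
                                     rate_model("apiaceae", 5.2e-9))$T_mya, 2),
               10.61)
  # dicot clock on the youngest celery-Arabidopsis pair
  expect_equal(round(divergence_time(1.3407,
                                     rate_model("dicot", 1.5e-8))$T_mya, 2),
               44.69)
  expect_error(divergence_time(-0.1, rate_model("r", 5.2e-9)), "negative")
})

test_that("divergence time is linear in Ks and inverse in the rate", {
  r <- rate_model("r", 5.2e-9)
  r2 <- rate_model("r2", 2 * r$r)
  ks <- c(0.05, 0.3, 1.1)
  expect_equal(divergence_time(2 * ks, r)$T_mya,
               2 * divergence_time(ks, r)$T_mya)
  expect_equal(divergence_time(ks, r2)$T_mya,
               divergence_time(ks, r)$T_mya / 2)
  # saturation propagates
  expect_true(is.nan(divergence_time(NaN, r)$T_mya))
})

test_that("rate selection uses the shared-clade rule", {
  expect_equal(select_rate("celery", "coriander")$r, 5.2e-9)
  expect_equal(select_rate("celery", "carrot")$r, 5.2e-9)
  expect_equal(select_rate("celery", "arabidopsis")$r, 1.5e-8)
  expect_error(select_rate("celery", "unknown_sp"), "unknown_sp")
})

test_that("anchor sets validate and order their events", {
  a <- event_anchor_set("toy", c(late = 1.0, early = 0.2))
  expect_equal(names(a$anchors), c("early", "late"))
  expect_error(event_anchor_set("toy", c(a = 0.5, a = 0.7)), "duplicate")
  expect_error(event_anchor_set("toy", c(a = -1)), "positive")
  expect_error(event_anchor_set("toy", c(0.1, 0.2)), "named")
})

test_that("Ks values are attributed to the upper bounding event", {
  anchors <- polyploidy_anchors("celery")
  # the two younger celery paralog pairs fall between alpha and omega
  a1 <- assign_event(0.6081, anchors)
  expect_equal(a1$interval_label, "between_alpha_celery_omega")
  expect_equal(a1$attributed_event, "celery_omega")
  expect_equal(a1$color_class, "green")
  # the two older pairs fall between omega and gamma
  a2 <- assign_event(0.9464, anchors)
  expect_equal(a2$attributed_event, "gamma")
  expect_equal(a2$color_class, "orange")
  # above the oldest anchor: predates all events
  a3 <- assign_event(1.5, anchors)
  expect_equal(a3$interval_label, "before_gamma")
  expect_true(is.na(a3$attributed_event))
  expect_equal(a3$color_class, "blue")
  # below the youngest anchor
  a4 <- assign_event(0.1, anchors)
  expect_equal(a4$interval_label, "after_alpha")
  expect_equal(a4$attributed_event, "alpha")
  expect_equal(a4$color_class, "red")
  # boundary: a pair born at the event has exactly the anchor Ks
  expect_equal(assign_event(0.3659, anchors)$attributed_event, "alpha")
  # NaN Ks is a warning, not an error
  expect_warning(u <- assign_event(NaN, anchors), "unassigned")
  expect_equal(u$interval_label, "unassigned")
  expect_error(assign_event(-0.2, anchors), "negative")
})

test_that("every finite Ks receives exactly one interval (partition property)", {
  anchors <- polyploidy_anchors("celery")
  labels <- ksdater:::.interval_labels(anchors)
  set.seed(41)
  ks <- c(runif(10000, 0, 2), anchors$anchors, 0)
  asg <- assign_event(ks, anchors)
  expect_true(all(asg$interval_label %in% labels))
  # brute-force recomputation from the bin edges
  edges <- c(0, unname(anchors$anchors), Inf)
  brute <- unname(vapply(ks, function(k) {
    which(k <= edges[-1] & (k > edges[-length(edges)] | k == 0))[1]
  }, 1L))
  expect_equal(match(asg$interval_label, labels), brute)
})

test_that("bin_pairs tallies intervals and sidelines saturated pairs", {
  anchors <- polyploidy_anchors("celery")
  kaks <- data.frame(pair_id = paste0("p", 1:5),
                     Ks = c(0.6081, 0.6067, 0.9464, 0.9687, NaN))
  b <- bin_pairs(kaks, anchors)
  expect_equal(b$counts$n[b$counts$interval_label == "between_alpha_celery_omega"], 2L)
  expect_equal(b$counts$n[b$counts$interval_label == "between_celery_omega_gamma"], 2L)
  expect_equal(sum(b$counts$n), nrow(b$assignments))
  expect_equal(nrow(b$unassigned), 1L)

  empty <- bin_pairs(kaks[0, ], anchors)
  expect_equal(sum(empty$counts$n), 0L)
  expect_equal(nrow(empty$assignments), 0L)
})

test_that("built-in anchor sets carry the published event constants", {
  expect_equal(unname(polyploidy_anchors("coriander")$anchors),
               c(0.3659, 0.7194, 1.2560))
  expect_equal(unname(polyploidy_anchors("carrot")$anchors),
               c(0.3659, 0.7470, 1.2560))
  expect_equal(unname(polyploidy_anchors("ginseng")$anchors),
               c(0.0297, 0.2884, 1.2560))
  expect_equal(unname(polyploidy_anchors("lettuce")$anchors),
               c(0.6415, 1.2560))
})
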