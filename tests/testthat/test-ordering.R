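test_that("precedence pairs follow CI separation and clonality", {
  ev <- data.frame(
    patient_id = c("P1", "P1", "P2", "P2", "P3", "P3"),
    sample_id = "a", sample_order = 1L,
    event = c("+3", "+5", "13q del", "1p del", "+7", "+9"),
    t_lower = c(0.1, 0.6, NA, NA, 0.2, 0.3),
    t_upper = c(0.2, 0.8, NA, NA, 0.5, 0.6),
    ccf = c(NA, NA, 1.0, 0.4, NA, NA))
  pairs <- derive_precedence_pairs(ev)
  # CI strictly below: +3 before +5
  p1 <- pairs[pairs$patient_id == "P1", ]
  expect_equal(nrow(p1), 1L)
  expect_true(p1$a_before_b && p1$event_a == "+3")
  # clonal deletion precedes subclonal deletion
  p2 <- pairs[pairs$patient_id == "P2", ]
  expect_equal(nrow(p2), 1L)
  expect_true(p2$a_before_b && p2$event_a == "13q del")
  # overlapping CIs: abstain
  expect_equal(nrow(pairs[pairs$patient_id == "P3", ]), 0L)
})

test_that("only the earliest sample contributes when requested", {
  ev <- data.frame(
    patient_id = "P1", sample_id = c("a", "a", "b", "b"),
    sample_order = c(1L, 1L, 2L, 2L),
    event = c("+3", "+5", "+3", "+11"),
    t_lower = c(0.1, 0.6, 0.1, 0.5), t_upper = c(0.2, 0.8, 0.2, 0.9),
    ccf = NA)
  pairs <- derive_precedence_pairs(ev, use_earliest_sample_only = TRUE)
  expect_false("+11" %in% c(pairs$event_a, pairs$event_b))
  pairs_all <- derive_precedence_pairs(ev, use_earliest_sample_only = FALSE)
  expect_true("+11" %in% c(pairs_all$event_a, pairs_all$event_b))
})

test_that("balanced wins give equal abilities and tied ranks", {
  pairs <- data.frame(patient_id = rep("p", 10),
                      event_a = "A", event_b = "B",
                      a_before_b = rep(c(TRUE, FALSE), 5))
  fit <- fit_bradley_terry(pairs)
  expect_equal(fit$ranking$ability[1], fit$ranking$ability[2],
               tolerance = 1e-6)
  expect_equal(fit$ranking$rank, c(1L, 1L))
})

test_that("the MM fit matches the grid-search likelihood oracle", {
  pairs <- rbind(
    data.frame(patient_id = "p", event_a = "A", event_b = "B",
               a_before_b = rep(c(TRUE, FALSE), c(9, 1))),
    data.frame(patient_id = "p", event_a = "B", event_b = "C",
               a_before_b = rep(c(TRUE, FALSE), c(9, 1))))
  fit <- fit_bradley_terry(pairs)
  expect_equal(fit$ranking$event, c("A", "B", "C"))
  beta_fit <- fit$ranking$ability[match(c("A", "B", "C"),
                                        fit$ranking$event)]
  beta_oracle <- bt_grid_oracle(fit$wins)
  expect_lt(max(abs(beta_fit - beta_oracle)), 1e-3)
})

test_that("separable data stay finite under the ridge and are flagged", {
  pairs <- data.frame(patient_id = "p", event_a = "A", event_b = "B",
                      a_before_b = TRUE)
  fit <- fit_bradley_terry(pairs)
  expect_true(fit$separable)
  expect_true(all(is.finite(fit$ranking$ability)))
})

test_that("disconnected comparison graphs trigger a warning", {
  pairs <- data.frame(patient_id = "p",
                      event_a = c("A", "C"), event_b = c("B", "D"),
                      a_before_b = TRUE)
  expect_warning(fit_bradley_terry(pairs), "disconnected")
})

test_that("planted ability orders are recovered from simulated cohorts", {
  abilities <- stats::setNames(seq(1, -1, length.out = 8), paste0("E", 1:8))
  pairs <- simulate_precedence_cohort(abilities, 120,
                                      events_per_patient = 5, seed = 81)
  fit <- fit_bradley_terry(pairs)
  got <- fit$ranking$ability[match(names(abilities), fit$ranking$event)]
  tau <- stats::cor(abilities, got, method = "kendall")
  expect_gte(tau, 0.8)
})
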