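# constructed evidence matrices with known structure
ev_equal <- function(n_sub = 8, K = 4)
  evidence_matrix(matrix(0, n_sub, K, dimnames = list(NULL, as.character(1:K))))

test_that("fixed-effects BMS obeys the softmax identities", {
  # two models, equal pooled evidence -> 0.5 / 0.5
  ev <- evidence_matrix(cbind(a = c(1, 2), b = c(2, 1)))
  expect_equal(unname(ffx_compare(ev)$prob), c(0.5, 0.5))

  # summed gap of ln 3 -> (0.75, 0.25)
  ev <- evidence_matrix(cbind(a = c(0, log(3)), b = c(0, 0)))
  expect_equal(unname(ffx_compare(ev)$prob), c(0.75, 0.25), tolerance = 1e-12)

  # K equal models -> 1/K each
  ev <- ev_equal(5, 7)
  expect_equal(unname(ffx_compare(ev)$prob), rep(1 / 7, 7))
  expect_true(ffx_compare(ev)$tie)

  # invariance to per-subject constants
  ev1 <- evidence_matrix(matrix(rnorm(12), 3, 4))
  shifted <- unclass(ev1) + c(5, -2, 100)   # recycled per subject row
  ev2 <- evidence_matrix(shifted)
  expect_equal(ffx_compare(ev1)$prob, ffx_compare(ev2)$prob,
               ignore_attr = TRUE, tolerance = 1e-9)

  expect_error(ffx_compare(ev1, subset = character(0)), "empty")
  expect_error(evidence_matrix(cbind(c(1, NA))), "finite")
})

test_that("random-effects BMS gives symmetric EP under symmetric evidence", {
  ev <- ev_equal(10, 4)
  res <- rfx_compare(ev, n_samples = 1e5, seed = 3)
  expect_equal(sum(res$ep), 1, tolerance = 1e-12)
  expect_true(all(abs(res$ep - 0.25) < 0.02))
  expect_equal(sum(res$prob), 1, tolerance = 1e-12)
})

test_that("a model better by 10 nats per subject dominates the exceedance probability", {
  F <- matrix(0, 12, 3, dimnames = list(NULL, c("1", "2", "3")))
  F[, 2] <- 10
  res <- rfx_compare(evidence_matrix(F), n_samples = 1e5, seed = 4)
  expect_gt(res$ep[["2"]], 0.99)
  expect_identical(res$winner, "2")
  # independent check: sample directly from the converged Dirichlet
  set.seed(99)
  draws <- matrix(rgamma(3e4, rep(res$alpha, each = 1e4)), 1e4, 3)
  draws <- draws / rowSums(draws)
  ep_direct <- mean(max.col(draws) == 2)
  expect_equal(res$ep[["2"]], ep_direct, tolerance = 0.01)
})

test_that("RFX results are equivariant under model relabelling", {
  set.seed(5)
  F <- matrix(rnorm(30, sd = 2), 10, 3, dimnames = list(NULL, c("1", "2", "3")))
  r1 <- rfx_compare(evidence_matrix(F), n_samples = 5e4, seed = 6)
  perm <- c("3", "1", "2")
  r2 <- rfx_compare(evidence_matrix(F[, perm]), n_samples = 5e4, seed = 6)
  expect_equal(r2$prob[perm], r1$prob[perm], tolerance = 1e-9)
  expect_equal(unname(r2$ep[perm]), unname(r1$ep[perm]), tolerance = 0.02)
})

test_that("family comparison aggregates and marginalizes consistently", {
  set.seed(7)
  F <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, as.character(1:4)))
  ev <- evidence_matrix(F)

  # single family containing everything -> probability 1
  r <- family_compare(ev, list(all = 1:4), "FFX")
  expect_equal(unname(r$family_prob), 1, tolerance = 1e-12)

  # two singleton families reduce to the plain two-model comparison
  r2 <- family_compare(ev, list(a = 1, b = 2), "FFX")
  plain <- ffx_compare(ev, subset = c("1", "2"))
  expect_equal(unname(r2$family_prob), unname(plain$prob), tolerance = 1e-12)

  # FFX family probability = sum of member posteriors (equal-size families,
  # so the family-equalized prior is uniform over models)
  r3 <- family_compare(ev, list(a = 1:2, b = 3:4), "FFX")
  expect_equal(unname(r3$family_prob[["a"]]),
               sum(r3$prob[c("1", "2")]), tolerance = 1e-12)

  expect_error(family_compare(ev, list(a = 1:2, b = 2:4), "FFX"), "overlap")
})

test_that("RFX family comparison finds a planted dominant family", {
  F <- matrix(0, 14, 4, dimnames = list(NULL, as.character(1:4)))
  F[, 3:4] <- 6
  ev <- evidence_matrix(F)
  r <- family_compare(ev, list(first = 1:2, second = 3:4), "RFX", seed = 8)
  expect_gt(r$family_ep[["second"]], 0.95)
  expect_equal(sum(r$family_ep), 1, tolerance = 1e-12)
  expect_identical(r$winner, "second")
})

test_that("greedy search follows constructed evidence through the level structure", {
  space <- test_space()
  # evidence strongly favouring model 9 -> level-2 winner is the
  # interhemispheric family
  F <- matrix(0, 10, 21, dimnames = list(NULL, as.character(1:21)))
  F[, 9] <- 8
  gs <- greedy_family_search(evidence_matrix(F), space, n_samples = 2e4,
                             seed = 1)
  expect_identical(gs$steps$lIFG$winner, "without")
  expect_identical(gs$steps$interhemispheric$winner, "with")
  expect_identical(gs$survivor, "9")

  # evidence favouring model 14 -> survivor 14 via level 3
  F2 <- matrix(0, 10, 21, dimnames = list(NULL, as.character(1:21)))
  F2[, 14] <- 8
  gs2 <- greedy_family_search(evidence_matrix(F2), space, n_samples = 2e4,
                              seed = 2)
  expect_identical(gs2$steps$rIFG_input$winner, "with")
  expect_identical(gs2$survivor, "14")

  # all-equal evidence -> FFX families tie exactly (reported, not broken)
  F3 <- matrix(0, 10, 21, dimnames = list(NULL, as.character(1:21)))
  ffx_l1 <- family_compare(evidence_matrix(F3),
                           family_partition(space, 1), "FFX")
  expect_true(ffx_l1$tie)
})

test_that("greedy search handles reduced model subspaces", {
  space <- test_space()
  F <- matrix(0, 8, 3, dimnames = list(NULL, c("6", "14", "9")))
  F[, "14"] <- 5
  gs <- greedy_family_search(evidence_matrix(F), space, n_samples = 2e4,
                             seed = 3)
  expect_true(gs$steps$lIFG$degenerate)   # no with-lIFG model present
  expect_identical(gs$survivor, "14")
})

test_that("leave-one-out permutation BMS tallies winners correctly", {
  F <- matrix(0, 9, 3, dimnames = list(NULL, c("6", "9", "14")))
  F[, "14"] <- 10
  ev <- evidence_matrix(F)
  tab <- loo_bms_permutations(ev, n_perm = 50, seed = 4)
  expect_identical(tab$model, "14")
  expect_equal(tab$freq, 1)

  tab1 <- loo_bms_permutations(ev, n_perm = 1, seed = 5)
  expect_equal(sum(tab1$wins), 1)

  # near-tie between models 14 and 6: one subject favours 6 strongly, the
  # rest favour 14 slightly, so the winner flips when that subject is held out
  F2 <- matrix(0, 6, 2, dimnames = list(NULL, c("6", "14")))
  F2[, "14"] <- 0.6
  F2[1, "6"] <- 5
  tab2 <- loo_bms_permutations(evidence_matrix(F2), n_perm = 400, seed = 6,
                               method = "ffx")
  expect_setequal(tab2$model, c("6", "14"))
  expect_true(all(tab2$freq > 0))
  expect_equal(sum(tab2$freq), 1)

  expect_error(loo_bms_permutations(evidence_matrix(F2[1, , drop = FALSE]),
                                    n_perm = 5), "2 subjects")
})
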