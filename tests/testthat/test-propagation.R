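# well-plate set with fully scripted trajectories for pairing tests
make_paired_set <- function(trajectories, container = "well24") {
  # trajectories: list of c(effect@48, effect@96) effect-id pairs
  experiments <- tibble::tibble(
    experiment_id = "E1", substance_type = "single",
    exposure_start_hpf = 0L, container_type = container,
    temperature_C = NA_real_, date = NA_character_, strain = NA_character_)
  treatments <- tibble::tibble(
    treatment_id = c("E1_C", "E1_T1"), experiment_id = "E1",
    substance_id = c("CONTROL", "S"), substance_name = c("control", "s"),
    concentration_umol_L = c(0, 5),
    is_control = c(TRUE, FALSE), is_solvent_control = FALSE)
  obs <- purrr::imap(trajectories, function(tr, i) {
    tibble::tibble(
      experiment_id = "E1", embryo_id = sprintf("e%02d", i),
      treatment_id = "E1_T1", well_row = "A", well_col = as.integer(i),
      time_hpf = c(48L, 96L), effect_id = as.integer(tr), value = 1)
  })
  # one control embryo so the set has a control arm
  ctrl <- tibble::tibble(
    experiment_id = "E1", embryo_id = "c01", treatment_id = "E1_C",
    well_row = "D", well_col = 6L, time_hpf = c(48L, 96L), effect_id = 3L,
    value = 1)
  zfet_set(experiments, treatments, dplyr::bind_rows(obs, list(ctrl)))
}

test_that("pairing builds indicators for tracked, non-control embryos only", {
  set <- make_paired_set(list(c(3, 2), c(3, 3), c(25, 25)))
  paired <- pair_embryo_observations(set)
  expect_equal(nrow(paired), 3)  # control embryo excluded
  expect_equal(paired$`normal@48`, c(1L, 1L, 0L))
  expect_equal(paired$`coagulated@96`, c(1L, 0L, 0L))
  expect_equal(paired$`developmental delay@96`, c(0L, 0L, 1L))
  # vial experiments cannot track individuals and are excluded entirely
  vial <- make_paired_set(list(c(3, 2), c(3, 3), c(25, 25)),
                          container = "vial")
  expect_error(pair_embryo_observations(vial), "well-type")
})

test_that("correlations match the textbook formula and a brute-force oracle", {
  tr <- c(rep(list(c(25, 50)), 3), rep(list(c(25, 3)), 2),
          rep(list(c(3, 3)), 5))
  set <- make_paired_set(tr)
  pm <- effect_correlation_matrix(pair_embryo_observations(set))
  # x = delay@48 (5 of 10), y = no hatching@96 (3 of 10), overlap 3:
  # r = (n*sxy - sx*sy) / sqrt((n*sxx - sx^2)(n*syy - sy^2))
  r_hand <- (10 * 3 - 5 * 3) / sqrt((10 * 5 - 25) * (10 * 3 - 9))
  expect_equal(pm$pcc["developmental delay@48", "no hatching@96"], r_hand,
               tolerance = 1e-12)
  # normal is anticorrelated with every other observed effect
  others <- setdiff(colnames(pm$pcc), "normal@96")
  expect_true(all(pm$pcc["normal@48", others] < 0))
  # identical indicator columns correlate perfectly
  set_id <- make_paired_set(c(rep(list(c(25, 50)), 3), rep(list(c(3, 3)), 7)))
  pm_id <- effect_correlation_matrix(pair_embryo_observations(set_id))
  expect_equal(pm_id$pcc["developmental delay@48", "no hatching@96"], 1)

  # brute-force covariance oracle on a larger random table
  set.seed(7)
  n <- 100
  X <- matrix(rbinom(n * 4, 1, 0.4), n, 4,
              dimnames = list(NULL, paste0(c("a", "b", "c", "d"), "@48")))
  Y <- matrix(rbinom(n * 3, 1, 0.3), n, 3,
              dimnames = list(NULL, paste0(c("u", "v", "w"), "@96")))
  tbl <- tibble::as_tibble(cbind(X, Y))
  tbl <- dplyr::mutate(tbl, experiment_id = "E", embryo_id = as.character(1:n),
                       .before = 1)
  tbl <- structure(tbl, class = c("zfet_paired", class(tbl)), t1 = 48, t2 = 96)
  pm2 <- effect_correlation_matrix(tbl)
  for (i in 1:4) for (j in 1:3) {
    x <- X[, i]; y <- Y[, j]
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pm2$pcc[i, j], r_oracle, tolerance = 1e-12)
  }
  # two-sided p-value from the t statistic, checked against cor.test
  ct <- stats::cor.test(X[, 1], Y[, 1])
  expect_equal(pm2$p_value[1, 1], ct$p.value, tolerance = 1e-10)
  expect_equal(pm2$significant[1, 1], ct$p.value < 0.01)
})

test_that("zero-variance columns are flagged undefined, never silently zero", {
  tbl <- tibble::tibble(experiment_id = "E", embryo_id = c("1", "2", "3"),
                        `a@48` = c(1L, 1L, 1L), `b@96` = c(1L, 0L, 1L))
  tbl <- structure(tbl, class = c("zfet_paired", class(tbl)), t1 = 48, t2 = 96)
  pm2 <- effect_correlation_matrix(tbl)
  expect_true(is.na(pm2$pcc["a@48", "b@96"]))
  expect_false(pm2$defined["a@48", "b@96"])
  expect_false(pm2$significant["a@48", "b@96"])
  tiny <- tbl[1:2, ]
  tiny <- structure(tiny, class = class(tbl), t1 = 48, t2 = 96)
  expect_error(effect_correlation_matrix(tiny), "at least 3")
})

test_that("display clustering keeps correlated blocks contiguous", {
  # block-diagonal structure: effects 1-2 and 3-4 form separate blocks
  set.seed(13)
  n <- 60
  base1 <- rbinom(n, 1, 0.5); base2 <- rbinom(n, 1, 0.5)
  mk <- function(b) ifelse(runif(n) < 0.9, b, 1 - b)
  tbl <- tibble::tibble(
    experiment_id = "E", embryo_id = as.character(1:n),
    `a1@48` = mk(base1), `a2@48` = mk(base1),
    `b1@48` = mk(base2), `b2@48` = mk(base2),
    `a1@96` = mk(base1), `a2@96` = mk(base1),
    `b1@96` = mk(base2), `b2@96` = mk(base2))
  tbl <- structure(tbl, class = c("zfet_paired", class(tbl)), t1 = 48, t2 = 96)
  pm <- effect_correlation_matrix(tbl)
  ord <- cluster_propagation(pm)
  labels <- substr(rownames(pm$pcc)[ord$row_order], 1, 1)
  expect_equal(length(rle(labels)$lengths), 2)  # a-block and b-block contiguous
  # permuting rows preserves the partition
  perm <- c(3, 1, 4, 2)
  pm_perm <- pm
  pm_perm$pcc <- pm$pcc[perm, ]; pm_perm$defined <- pm$defined[perm, ]
  ord2 <- cluster_propagation(pm_perm)
  labels2 <- substr(rownames(pm_perm$pcc)[ord2$row_order], 1, 1)
  expect_equal(length(rle(labels2)$lengths), 2)
  # degenerate 1x1 matrix
  one <- pm
  one$pcc <- pm$pcc[1, 1, drop = FALSE]
  one$defined <- pm$defined[1, 1, drop = FALSE]
  expect_equal(cluster_propagation(one)$row_order, 1L)
})

test_that("planted transitions surface as the strongest cross-time correlate", {
  # archetype with the decreased-heartbeat -> no-heartbeat transition
  study <- simulate_study(
    study_config(n_substances = 2, archetypes = zfet_archetypes()["no_hatch_heartbeat"],
                 embryos_per_concentration = 20), seed = 3)
  paired <- pair_embryo_observations(study$set)
  pm <- effect_correlation_matrix(paired)
  src <- "decreased heartbeat@48"
  succ <- "no heartbeat@96"
  expect_true(src %in% rownames(pm$pcc) && succ %in% colnames(pm$pcc))
  # empirical transition frequency near the planted 0.8, among embryos
  # still alive at 96 hpf (coagulation pre-empts the successor effect)
  alive <- if ("coagulated@96" %in% names(paired)) {
    paired[["coagulated@96"]]
  } else rep(0L, nrow(paired))
  had <- paired[[src]] == 1 & alive == 0
  p_hat <- mean(paired[[succ]][had])
  se <- sqrt(0.8 * 0.2 / sum(had))
  expect_lte(abs(p_hat - 0.8), 3 * se + 1e-9)
})
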