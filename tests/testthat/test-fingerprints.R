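# a fingerprint object built directly, bypassing observation data
fake_fingerprint <- function(id, props, n_embryos) {
  v <- zfet_vocabulary()
  qual <- v[v$category %in% c("lethal", "sublethal"), c("effect_id", "effect")]
  qual$proportion <- 0
  qual$proportion[match(names(props), qual$effect)] <- unname(props)
  structure(qual, class = c("zfet_fingerprint", class(qual)),
            substance_id = id, observation_hpf = 96, n_embryos = n_embryos,
            window = tibble::tibble(low = 0, high = Inf))
}

valid_fit <- function(family, b, e) {
  structure(list(family = family, b = b, e = e, vcov = NULL, valid = TRUE,
                 invalid_reasons = character()), class = "zfet_fit")
}

test_that("the fingerprint window spans EC5 to LC99, falling back when lethal fails", {
  cum <- valid_fit("LL2", -2, 10)
  let <- valid_fit("LL2", -2, 50)
  w <- concentration_window(cum, let)
  expect_equal(w$low, 10 * exp(log(0.95 / 0.05) / -2))
  expect_equal(w$high, 50 * exp(log(0.01 / 0.99) / -2))
  expect_true(w$low < w$high)
  # no or invalid lethal fit: open above
  expect_equal(concentration_window(cum, NULL)$high, Inf)
  bad_let <- valid_fit("LL2", -2, 50); bad_let$valid <- FALSE
  expect_equal(concentration_window(cum, bad_let)$high, Inf)
  # steep lethal curve below the EC5: empty window with warning
  expect_warning(w2 <- concentration_window(cum, valid_fit("LL2", -8, 0.5)),
                 "empty fingerprint window")
  expect_true(w2$high < w2$low)
  cum_invalid <- valid_fit("LL2", -2, 10); cum_invalid$valid <- FALSE
  expect_error(concentration_window(cum_invalid), "not valid")
})

test_that("fingerprints are proportions among non-normal embryos", {
  set <- make_tiny_set()
  fp <- build_fingerprint(set, "S1", observation_hpf = 96)
  # non-normal embryos at 96: t1 (edema), t3 (coagulated), t4 (edema + no
  # hatching) and the E2 embryo carrying only a heart-rate measurement
  # (quantitative terms stay out of the vector but the embryo is not normal)
  expect_equal(attr(fp, "n_embryos"), 4L)
  expect_equal(fp$proportion[fp$effect == "yolk sac edema"], 2 / 4)
  expect_equal(fp$proportion[fp$effect == "coagulated"], 1 / 4)
  expect_equal(fp$proportion[fp$effect == "no hatching"], 1 / 4)
  # proportions need not sum to one: multi-effect embryos count per effect
  expect_gte(sum(fp$proportion), 1)
  # no uninformative or quantitative columns
  expect_false(any(fp$effect %in% c("normal", "miscellaneous", "no embryo",
                                    "beats per minute",
                                    "hours post fertilization")))
  # scale invariance: duplicating every record leaves proportions unchanged
  dup <- zfet_set(set$experiments, set$treatments,
                  dplyr::bind_rows(
                    set$observations,
                    dplyr::mutate(set$observations,
                                  embryo_id = paste0(embryo_id, "b"))))
  fp2 <- build_fingerprint(dup, "S1", observation_hpf = 96)
  expect_equal(fp2$proportion, fp$proportion)
})

test_that("matrix assembly applies the row filter before the column filter", {
  # rare effect carried only by the small substance: with row-first
  # filtering the column mean is computed without that substance
  fps <- list(
    fake_fingerprint("A", c("yolk sac edema" = 0.8, "no hatching" = 0.5), 100),
    fake_fingerprint("B", c("yolk sac edema" = 0.6, "scoliosis" = 0.005), 100),
    fake_fingerprint("C", c("yolk sac edema" = 0.7, "tremor" = 0.9), 29)
  )
  mat <- assemble_fingerprint_matrix(fps)
  expect_equal(rownames(mat), c("A", "B"))        # C fails the 30-embryo rule
  expect_false("tremor" %in% colnames(mat))       # only C carried it
  expect_false("scoliosis" %in% colnames(mat))    # mean 0.0025 < 1%
  expect_true(all(c("yolk sac edema", "no hatching") %in% colnames(mat)))
  # column order follows the vocabulary
  v <- zfet_vocabulary()
  expect_equal(colnames(mat),
               v$effect[v$effect %in% colnames(mat)])
  # untouched matrix passes through
  fps_ok <- fps[1:2]
  fps_ok[[2]] <- fake_fingerprint("B", c("yolk sac edema" = 0.6), 100)
  mat2 <- assemble_fingerprint_matrix(fps_ok, min_mean_prop = 0)
  expect_equal(nrow(mat2), 2)
})

test_that("clustering separates planted groups and is permutation stable", {
  rows <- rbind(matrix(rep(c(1, 0, 0), 3), 3, byrow = TRUE),
                matrix(rep(c(0, 1, 0.5), 3), 3, byrow = TRUE))
  rownames(rows) <- letters[1:6]
  colnames(rows) <- c("coagulated", "no hatching", "yolk sac edema")
  cl <- cluster_fingerprints(rows, k = 2)
  expect_equal(cl$cluster[1:3], rep(cl$cluster[1], 3))
  expect_equal(cl$cluster[4:6], rep(cl$cluster[4], 3))
  expect_false(cl$cluster[1] == cl$cluster[4])
  expect_equal(unique(cluster_fingerprints(rows, k = 1)$cluster), 1L)
  expect_error(cluster_fingerprints(rows, k = 7), "exceeds")
  # shuffling rows changes labels only
  perm <- c(4, 2, 6, 1, 3, 5)
  cl2 <- cluster_fingerprints(rows[perm, ], k = 2)
  pairs_same <- function(cl, ids) {
    m <- outer(cl$cluster, cl$cluster, "==")
    dimnames(m) <- list(cl$substance_id, cl$substance_id)
    m[ids, ids]
  }
  expect_equal(pairs_same(cl2, letters[1:6]), pairs_same(cl, letters[1:6]))
})

test_that("archetype studies are recovered by Ward clustering of fingerprints", {
  skip_if_not_installed("mclust")
  # ~3 replicate experiments per substance, matching the archive-scale
  # pooling that real fingerprints are built from
  study <- simulate_study(
    study_config(n_substances = 20, experiments_per_substance = 3),
    seed = 42)
  res <- run_zfet_pipeline(study$set,
                           pipeline_config(k_clusters = 4,
                                           min_fingerprint_embryos = 30))
  truth <- study$truth$substances
  cl <- res$clusters
  planted <- truth$archetype[match(cl$substance_id, truth$substance_id)]
  ari <- mclust::adjustedRandIndex(cl$cluster, planted)
  expect_gte(ari, 0.9)
})

test_that("PCA importance ranks the high-variance effect first, sign-invariantly", {
  set.seed(5)
  n <- 12
  mat <- cbind(
    coagulated = rep(c(0.9, 0.1), each = n / 2),       # dominant variance
    `no hatching` = runif(n, 0.4, 0.45),
    `yolk sac edema` = runif(n, 0.1, 0.14),
    shivering = rep(0.2, n)
  )
  rownames(mat) <- sprintf("s%02d", 1:n)
  imp <- pca_effect_importance(mat)
  expect_equal(imp$effect[1], "coagulated")
  # importance is a norm: flipping the sign of all loadings cannot change it
  imp2 <- pca_effect_importance(-mat)
  expect_equal(imp2$importance[match(imp$effect, imp2$effect)],
               imp$importance, tolerance = 1e-12)
  # raw-loading variant: at full rank every row of the orthonormal rotation
  # has unit norm, so restrict to the leading component to discriminate
  imp3 <- pca_effect_importance(mat, method = "loadings", n_components = 1)
  expect_equal(imp3$effect[1], "coagulated")
  imp_full <- pca_effect_importance(mat, method = "loadings")
  expect_true(all(imp_full$importance <= 1 + 1e-9))
  expect_error(pca_effect_importance(matrix(0.5, 4, 3)), "no variance")
})
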