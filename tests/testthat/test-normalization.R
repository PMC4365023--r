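test_that("stabilization applies the majority label to all replicates", {
  l <- function(...) setNames(c(...), c("A01", "A02"))
  reps <- list(l("active", "active"), l("active", "non-active"),
               l("non-active", "non-active"))
  out <- stabilize_labels(reps, proportion = 0.5)
  # A01 active in 2/3 >= 0.5, A02 in 1/3 < 0.5
  for (r in out) expect_identical(r, l("active", "non-active"))
  # already-identical labels are a fixed point
  same <- list(l("active", "non-active"), l("active", "non-active"))
  expect_identical(stabilize_labels(same, 0.5), same)
  # mismatched wells error
  bad <- list(l("active", "active"),
              setNames("active", "B01"))
  expect_error(stabilize_labels(bad), "mismatched well sets")
})

test_that("base curves average pooled profiles in the least-squares sense", {
  times <- grid_coarse()
  # all active wells on the same noise-free curve -> base equals the curve
  curve <- logistic_curve(times, 220, 11, 2)
  sig <- matrix(rep(curve, each = 4), 4, dimnames = list(well_ids()[1:4], NULL))
  p <- pm_plate("b", times, sig)
  labels <- setNames(rep("active", 4), rownames(sig))
  bases <- fit_base_curves(p, labels)
  expect_equal(bases$active$values, curve, tolerance = 1e-6)
  expect_null(bases$`non-active`)
  # two symmetric active subpopulations: asym ~ midpoint, by the
  # independent pooled-LS oracle
  sig2 <- rbind(
    matrix(rep(logistic_curve(times, 200, 12, 2), each = 2), 2),
    matrix(rep(logistic_curve(times, 300, 12, 2), each = 2), 2)
  )
  rownames(sig2) <- well_ids()[1:4]
  p2 <- pm_plate("b2", times, sig2)
  bases2 <- fit_base_curves(p2, setNames(rep("active", 4), rownames(sig2)))
  pooled_t <- rep(times, times = 4)
  pooled_y <- as.vector(t(sig2))
  sse <- function(par) {
    sum((pooled_y - logistic_curve(pooled_t, par[1], par[2], par[3]))^2)
  }
  oracle <- optim(c(250, 12, 2), sse, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-14))$par
  expect_equal(bases2$active$source_fit$params$asym, oracle[1],
               tolerance = 1e-3)
  expect_equal(bases2$active$source_fit$params$asym, 250, tolerance = 0.02)
})

test_that("reference selection minimizes summed Euclidean distance", {
  mkbase <- function(level, n = 10) list(group = "active",
                                         values = rep(level, n))
  # single array is its own reference
  expect_identical(select_reference(list(a1 = mkbase(100))), "a1")
  # 90 / 100 / 120: distance sums 40, 30, 50 -> the level-100 array
  expect_identical(
    select_reference(list(x = mkbase(90), y = mkbase(100), z = mkbase(120))),
    "y"
  )
  # tie between two identical bases -> smaller array id
  expect_identical(
    select_reference(list(`2` = mkbase(100), `1` = mkbase(100),
                          `3` = mkbase(200))),
    "1"
  )
  # brute-force check on random curves
  set.seed(9)
  bases <- lapply(setNames(1:4, paste0("arr", 1:4)),
                  function(i) list(group = "active", values = runif(10, 0, 300)))
  vals <- sapply(bases, `[[`, "values")
  sums <- sapply(colnames(vals), function(i) {
    sum(sqrt(colSums((vals - vals[, i])^2)))
  })
  expect_identical(select_reference(bases), names(which.min(sums)))
})

test_that("normalization factors are time-sum ratios", {
  b1 <- list(group = "active", values = rep(10, 20))
  b2 <- list(group = "active", values = rep(5, 20))
  expect_equal(normalization_factor(b1, b1), 1)
  expect_equal(normalization_factor(b1, b2), 2)
  expect_error(normalization_factor(b1, list(group = "active",
                                             values = rep(0, 20))),
               "degenerate")
})

test_that("scaled replicates are normalized back to the reference level", {
  fx <- scaled_replicates(c(1.25, 1.0, 0.8))
  gs <- lapply(fx$experiment$plates, group_plate, threshold = 100)
  norm <- normalize_experiment(fx$experiment, gs)
  f <- norm$factors
  # the unscaled replicate is the reference, NF exactly 1
  for (g in c("active", "non-active")) {
    fg <- f[f$group == g, ]
    expect_identical(fg$array_id[fg$reference], "2")
    expect_equal(fg$nf[fg$reference], 1)
    expect_equal(fg$nf[fg$array_id == "1"], 1 / 1.25, tolerance = 0.02)
    expect_equal(fg$nf[fg$array_id == "3"], 1 / 0.8, tolerance = 0.02)
  }
  # normalized signals match the reference and stay non-negative
  for (id in c("1", "3")) {
    expect_equal(norm$experiment$plates[[id]]$signals,
                 norm$experiment$plates[["2"]]$signals, tolerance = 1e-6)
    expect_true(all(norm$experiment$plates[[id]]$signals >= 0))
  }
})

test_that("normalizing identical replicates changes nothing", {
  fx <- scaled_replicates(c(1, 1, 1))
  gs <- lapply(fx$experiment$plates, group_plate, threshold = 100)
  norm <- normalize_experiment(fx$experiment, gs)
  expect_true(all(abs(norm$factors$nf - 1) < 1e-10))
  expect_equal(norm$experiment$plates[["1"]]$signals,
               fx$experiment$plates[["1"]]$signals)
})

test_that("stabilization equalizes active counts across replicates", {
  fx <- scaled_replicates(c(1.25, 1.0, 0.8))
  gs <- lapply(fx$experiment$plates, group_plate, threshold = 100)
  # perturb one replicate's labels to disagree
  gs[[1]]$labels[1] <- "non-active"
  gs[[3]]$labels[15] <- "active"
  norm <- normalize_experiment(fx$experiment, gs, stabilize = TRUE)
  counts <- vapply(norm$labels, count_active, integer(1))
  expect_true(length(unique(counts)) == 1)
  # without stabilization the perturbed labels survive
  norm2 <- normalize_experiment(fx$experiment, gs, stabilize = FALSE)
  expect_gt(length(unique(vapply(norm2$labels, count_active, integer(1)))), 1)
})

test_that("a single-replicate setup gets factor 1 with a warning", {
  times <- grid_coarse()
  sig <- matrix(rep(logistic_curve(times, 200, 10, 2), each = 2), 2,
                dimnames = list(well_ids()[1:2], NULL))
  p <- pm_plate("only", times, sig, "28", "s", 1)
  exp <- pm_experiment(list(p), c("28", "s"))
  g <- list(only = group_plate(p, threshold = 100))
  expect_warning(norm <- normalize_experiment(exp, g), "single replicate")
  expect_true(all(norm$factors$nf == 1))
})
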