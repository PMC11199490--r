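test_that("the distance transform matches the brute-force oracle exactly", {
  set.seed(4)
  for (rep in 1:30) {
    dims <- sample(10:24, 3, replace = TRUE)
    m <- array(runif(prod(dims)) < 0.02, dims)
    if (!any(m)) m[sample(prod(dims), 1)] <- TRUE
    e <- perilacunar:::cpp_edt3(m, dims)
    expect_identical(as.vector(e$dist2), as.vector(brute_edt2(m)))
  }
})

test_that("distance maps are zero on the target and one spacing at a unit step", {
  m <- array(0L, c(9, 9, 9)); m[5, 5, 5] <- 1L
  vol <- volume3d(m, 1.3, "binary")
  d <- distance_map(vol, "canals")
  expect_equal(d$data[5, 5, 5], 0)
  expect_equal(d$data[6, 5, 5], 1.3)
  expect_equal(d$data[5, 6, 6], 1.3 * sqrt(2))
  empty <- volume3d(array(0L, c(4, 4, 4)), 1.3, "binary")
  expect_error(distance_map(empty, "endosteum"), "endosteum")
})

make_assignment_fixture <- function() {
  dims <- c(21, 61, 61)
  sp <- 1
  endo <- array(0L, dims); endo[, , 1] <- 1L
  peri <- array(0L, dims); peri[, , 61] <- 1L
  canal <- array(0L, dims); canal[, 31, 21] <- 1L
  lac <- array(0L, dims)
  lac[10:12, 30:32, 30:32] <- 1L   # ~10 vox from canal, ~29/29 from surfaces
  list(dims = dims, sp = sp,
       endo = volume3d(endo, sp, "binary"),
       peri = volume3d(peri, sp, "binary"),
       canal = volume3d(canal, sp, "binary"),
       lac = volume3d(lac, sp, "labels"))
}

test_that("lacunae are assigned to the closest surface with the documented tie rule", {
  f <- make_assignment_fixture()
  tab <- data.frame(id = 1L, volume_um3 = 27)
  out <- assign_lacunae(tab, f$lac, f$endo, f$peri, f$canal)
  expect_equal(out$assigned_surface, "canals")
  expect_equal(out$d_vasculature_um,
               min(out$d_endosteum_um, out$d_canal_um, out$d_periosteum_um))

  # exact symmetric tie between endosteum and periosteum -> endosteum
  dims <- c(5, 5, 21)
  endo <- array(0L, dims); endo[, , 1] <- 1L
  peri <- array(0L, dims); peri[, , 21] <- 1L
  lac <- array(0L, dims); lac[3, 3, 11] <- 1L
  out2 <- assign_lacunae(data.frame(id = 1L, volume_um3 = 1),
                         volume3d(lac, 1, "labels"),
                         volume3d(endo, 1, "binary"),
                         volume3d(peri, 1, "binary"), canal_mask = NULL) |>
    suppressWarnings()
  expect_equal(out2$assigned_surface, "endosteum")
  expect_true(is.na(out2$d_canal_um))
})

test_that("per-lacuna distances agree with a direct per-voxel minimum", {
  cfg <- small_phantom_config(seed = 9L, n_lacunae = 12L, n_canals = 2L)
  ph <- generate_phantom(cfg)
  tr <- ph$truth
  tab <- data.frame(id = tr$lacuna_params$id,
                    volume_um3 = tr$lacuna_params$analytic_volume_um3)
  out <- assign_lacunae(tab, tr$lacuna_labels, tr$endosteum_mask,
                        tr$periosteum_mask,
                        volume3d((tr$canal_labels$data > 0) + 0L,
                                 cfg$spacing_um, "binary"))
  expect_equal(out$d_vasculature_um,
               pmin(out$d_endosteum_um, out$d_canal_um, out$d_periosteum_um))
  # spot-check one lacuna against the brute-force oracle
  id <- out$id[1]
  d2 <- brute_edt2(tr$endosteum_mask$data > 0)
  d_oracle <- sqrt(min(d2[tr$lacuna_labels$data == id])) * cfg$spacing_um
  expect_equal(out$d_endosteum_um[1], d_oracle, tolerance = 1e-12)
})

test_that("pooled quartiles follow the sort-based definition", {
  tab <- data.frame(volume_um3 = c(8, 1, 5, 3, 7, 2, 6, 4),
                    cohort = rep(c("a", "b"), 4))
  q <- volume_quartiles(tab)
  expect_equal(as.vector(table(q$table$volume_quartile)), c(2, 2, 2, 2))
  # independent quantile oracle (linear interpolation of order statistics)
  v <- sort(tab$volume_um3)
  oracle <- sapply(c(0.25, 0.5, 0.75), function(p) {
    h <- (length(v) - 1) * p + 1
    v[floor(h)] + (h - floor(h)) * (v[floor(h) + 1] - v[floor(h)])
  })
  expect_equal(unname(q$boundaries), oracle)
  expect_error(volume_quartiles(data.frame(volume_um3 = 1:3)), "fewer than 4")
})

test_that("a stochastically larger cohort concentrates in the upper quartiles", {
  set.seed(5)
  base <- rlnorm(400, log(160), 0.4)
  tab <- data.frame(volume_um3 = c(base, base * 1.6),
                    cohort = rep(c("virgin", "lactating"), each = 400))
  pr <- volume_quartiles(tab)$proportions
  expect_true(all(diff(pr["lactating", ]) > 0))
  expect_true(all(diff(pr["virgin", ]) < 0))
})

test_that("quartile cell means reduce to hand-computed group-by averages", {
  toy <- data.frame(
    cohort = c(rep("a", 6), rep("b", 4)),
    sample_id = c("a1", "a1", "a1", "a2", "a2", "a2", "b1", "b1", "b2", "b2"),
    volume_quartile = c("Q1", "Q1", "Q2", "Q1", "Q2", "Q2", "Q1", "Q2", "Q1", "Q2"),
    d_vasculature_um = c(10, 14, 20, 12, 30, 10, 8, 6, 4, 2))
  res <- mean_min_distance_by_quartile(toy)
  pc <- res$per_cohort
  # cohort a, Q1: bones a1 (12), a2 (12) -> 12; cohort a, Q2: a1 20, a2 20 -> 20
  expect_equal(pc$mean_distance_um[pc$cohort == "a" & pc$volume_quartile == "Q1"], 12)
  expect_equal(pc$mean_distance_um[pc$cohort == "a" & pc$volume_quartile == "Q2"], 20)
  expect_equal(pc$mean_distance_um[pc$cohort == "b" & pc$volume_quartile == "Q1"], 6)
  # constant field: all distances equal -> all cell means equal
  toy$d_vasculature_um <- 7
  pc2 <- mean_min_distance_by_quartile(toy)$per_cohort
  expect_true(all(pc2$mean_distance_um == 7))
  # empty cell reported as missing, not zero
  toy2 <- toy[!(toy$cohort == "b" & toy$volume_quartile == "Q2"), ]
  pc3 <- mean_min_distance_by_quartile(toy2)$per_cohort
  expect_true(is.na(pc3$mean_distance_um[pc3$cohort == "b" &
                                           pc3$volume_quartile == "Q2"]))
})

test_that("centroid mode agrees with surface mode for a symmetric lacuna", {
  f <- make_assignment_fixture()
  tab <- data.frame(id = 1L, volume_um3 = 27)
  s1 <- assign_lacunae(tab, f$lac, f$endo, f$peri, f$canal, mode = "surface")
  s2 <- assign_lacunae(tab, f$lac, f$endo, f$peri, f$canal, mode = "centroid")
  expect_equal(s1$assigned_surface, s2$assigned_surface)
  expect_gte(s2$d_canal_um, s1$d_canal_um)  # centroid cannot be closer
})

test_that("endosteum-proximal enlarged lacunae make Q4 sit closer to the endosteum", {
  base <- small_phantom_config(seed = 77L, n_lacunae = 40L, n_canals = 0L,
                               noise = 0)
  base$lacunae$endosteal_volume_scale <- 2.0
  ph <- generate_phantom(base)
  tr <- ph$truth
  tab <- data.frame(id = tr$lacuna_params$id,
                    volume_um3 = tr$lacuna_params$voxel_count * 1.3^3)
  tab <- suppressWarnings(assign_lacunae(tab, tr$lacuna_labels,
                                         tr$endosteum_mask, tr$periosteum_mask))
  q <- volume_quartiles(tab)$table
  m <- tapply(q$d_endosteum_um, q$volume_quartile, mean)
  expect_lt(m[["Q4"]], m[["Q1"]])
})
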