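test_that("weighted 1-D PMF follows -RT ln of assigned mass", {
  # equal split over two bins: both PMF values 0
  p <- weighted_pmf(rep(0.25, 4), c(0, 0.1, 1, 1.1), bins = c(0, 1), 300)
  expect_equal(p$pmf, c(0, 0))
  # 2/3 vs 1/3 at 300 K: difference RT ln 2 = 0.4132 kcal/mol
  p2 <- weighted_pmf(c(2, 1) / 3, c(0, 1), bins = c(0, 1), 300)
  expect_equal(p2$pmf[2] - p2$pmf[1], 1.987204e-3 * 300 * log(2),
               tolerance = 1e-10)
  expect_equal(p2$pmf[2] - p2$pmf[1], 0.4132, tolerance = 1e-4)
})

test_that("nearest-bin ties go to the lower-index bin", {
  # 0.5 is equidistant from centers 0 and 1
  p <- weighted_pmf(c(1), c(0.5), bins = c(0, 1), 300)
  expect_true(p$occupied[1])
  expect_false(p$occupied[2])
  expect_true(is.na(p$pmf[2]))
})

test_that("1-D PMF flags degenerate mass and rejects zero weight", {
  p <- weighted_pmf(c(1, 1), c(0, 0.01), bins = c(0, 1, 2), 300)
  expect_equal(p$occupied, c(TRUE, FALSE, FALSE))
  expect_error(weighted_pmf(c(0, 0), c(0, 1), bins = c(0, 1), 300),
               "zero")
})

test_that("PMFs are invariant to the overall weight scale", {
  w <- runif(50)
  x <- rnorm(50)
  p1 <- weighted_pmf(w, x, bins = -2:2, 300)
  p2 <- weighted_pmf(7.3 * w, x, bins = -2:2, 300)
  expect_equal(p1$pmf, p2$pmf)
})

test_that("grid PMF anchors its minimum voxel at the origin", {
  g1 <- grid_pmf(c(1), matrix(c(5.2, 3.1, -2.2), 1), 1, 300)
  expect_equal(g1$dg$dg, 0)
  expect_equal(unlist(g1$dg[1, c("ix", "iy", "iz")]), c(ix = 0, iy = 0, iz = 0))
  # two voxels with weights w and w/e differ by exactly RT
  pos <- rbind(c(0.5, 0.5, 0.5), c(3.5, 0.5, 0.5))
  g2 <- grid_pmf(c(1, exp(-1)), pos, 1, 300)
  expect_equal(sort(g2$dg$dg), c(0, rt(300)), tolerance = 1e-12)
})

test_that("halving the voxel size and re-coarsening reproduces the grid", {
  withr::with_seed(31, {
    pos <- matrix(rnorm(3 * 4000, sd = 2), ncol = 3)
    w <- rexp(4000)
    w <- w / sum(w)
    coarse <- grid_pmf(w, pos, 1, 300)
    fine <- grid_pmf(w, pos, 0.5, 300)
    rt_ <- rt(300)
    # recover absolute voxel indices, coarsen by Boltzmann-summing masses
    fabs <- sweep(as.matrix(fine$dg[, c("ix", "iy", "iz")]), 2,
                  as.numeric(fine$origin), "+")
    cidx <- floor(fabs / 2)
    mass <- exp(-fine$dg$dg / rt_)
    key <- paste(cidx[, 1], cidx[, 2], cidx[, 3])
    m2 <- rowsum(mass, key)
    dg2 <- -rt_ * log(m2[, 1])
    dg2 <- dg2 - min(dg2)
    cabs <- sweep(as.matrix(coarse$dg[, c("ix", "iy", "iz")]), 2,
                  as.numeric(coarse$origin), "+")
    ckey <- paste(cabs[, 1], cabs[, 2], cabs[, 3])
    expect_setequal(rownames(m2), ckey)
    expect_equal(dg2[ckey], coarse$dg$dg, tolerance = 1e-10,
                 ignore_attr = TRUE)
  })
})

test_that("direct Boltzmann samples of a harmonic well give dG = kappa/2 |x|^2", {
  kappa <- 0.5
  sigma <- sqrt(rt(300) / kappa)
  n <- 1e5
  withr::with_seed(7, {
    pos <- matrix(rnorm(3 * n, sd = sigma), ncol = 3)
  })
  g <- grid_pmf(rep(1 / n, n), pos, 1, 300)
  # exact finite-voxel oracle: voxel mass is a product of Gaussian CDF
  # differences over the voxel faces (absolute centers via g$origin)
  ctr <- sweep(as.matrix(g$dg[, c("ix", "iy", "iz")]), 2,
               as.numeric(g$origin), "+") + 0.5
  lmass <- rowSums(log(pnorm((ctr + 0.5) / sigma) -
                         pnorm((ctr - 0.5) / sigma)))
  pred <- -rt(300) * lmass
  pred <- pred - pred[1]               # anchored at the minimum-dG voxel
  n_v <- n * exp(lmass)                # expected counts per voxel
  sel <- n_v >= 100
  dev <- abs(g$dg$dg[sel] - pred[sel])
  expect_true(all(dev < 4 * rt(300) / sqrt(n_v[sel]) + 0.02))
  # shell means track kappa/2 r^2 coarsely (voxel-center offsets remain)
  rp <- as.data.frame(radial_profile(g, 1))
  shells <- rp[rp$shell_center > 1 & rp$shell_center < 3, ]
  expect_equal(shells$mean_pmf, 0.5 * kappa * shells$shell_center^2,
               tolerance = 0.3)
})

test_that("radial profile averages shells with population sd", {
  mk_grid <- function(df) structure(
    list(voxel_size = 1, dg = df, origin = c(0, 0, 0), temperature = 300),
    class = "grid_pmf")
  # two voxels on the same shell with dG 1 and 3: mean 2, population sd 1
  g <- mk_grid(data.frame(ix = c(0, 3, -3), iy = 0, iz = 0, dg = c(0, 1, 3)))
  rp <- as.data.frame(radial_profile(g, 1))
  sh <- rp[rp$shell_center == 3.5, ]
  expect_equal(sh$mean_pmf, 2)
  expect_equal(sh$sd_pmf, 1)
  expect_equal(sh$n_voxels, 2L)
  # single-voxel shells report sd 0
  expect_equal(rp$sd_pmf[rp$n_voxels == 1], 0)
})

test_that("a linear-in-|x| grid PMF yields linear shell means", {
  a <- 0.7
  ax <- -8:8
  vox <- expand.grid(ix = ax, iy = ax, iz = ax)
  r <- sqrt(vox$ix^2 + vox$iy^2 + vox$iz^2)
  g <- structure(list(voxel_size = 1,
                      dg = cbind(vox, dg = a * r),
                      origin = c(0, 0, 0), temperature = 300),
                 class = "grid_pmf")
  rp <- as.data.frame(radial_profile(g, 1))
  inner <- rp[rp$shell_center < 7, ]
  # means follow a * shell radius up to voxelisation scatter
  expect_equal(inner$mean_pmf, a * inner$shell_center, tolerance = 0.06)
  expect_true(all(inner$sd_pmf[inner$n_voxels > 1] < a * 0.5))
})

test_that("bulk plateau estimation uses Boltzmann-summed shell mass", {
  # a grid whose every voxel in the 4-6 A shell has dG = v must report v
  ax <- -7:7
  vox <- expand.grid(ix = ax, iy = ax, iz = ax)
  r <- sqrt(vox$ix^2 + vox$iy^2 + vox$iz^2)
  keep <- r <= 6.5
  v <- 3.2
  dgv <- ifelse(r[keep] < 4, 0, v)
  g <- structure(list(voxel_size = 1,
                      dg = cbind(vox[keep, ], dg = dgv),
                      origin = c(0, 0, 0), temperature = 300),
                 class = "grid_pmf")
  gd <- grid_pmf_difference(g, c(4, 6))
  expect_equal(gd$bulk_value, v, tolerance = 1e-10)
  expect_equal(gd$difference, -v, tolerance = 1e-10)
  expect_equal(gd$n_voxels_occupied, gd$n_voxels_geometric)
  expect_error(grid_pmf_difference(g, c(20, 30)), "no occupied voxels")
})
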