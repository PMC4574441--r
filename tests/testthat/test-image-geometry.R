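test_that("anisotropic distance transform matches brute force on small masks", {
  set.seed(101)
  cases <- list(list(dims = c(16L, 16L, 16L), vs = c(0.08, 0.08, 0.2)),
                list(dims = c(24L, 20L, 12L), vs = c(0.1, 0.13, 0.31)),
                list(dims = c(9L, 25L, 7L), vs = c(1, 1, 1)))
  for (cs in cases) {
    sites <- array(runif(prod(cs$dims)) < 0.15, cs$dims)
    sites[1, 1, 1] <- TRUE # guarantee at least one site
    f <- nucpos:::cpp_edt_feature(sites, cs$dims, cs$vs)
    bf <- brute_force_edt(sites, cs$vs)
    expect_lt(max(abs(f$dist - bf)), 1e-6)
    # the stored nearest site actually attains the distance
    lin <- which(!sites)
    d <- dim(sites)
    near <- f$nearest[lin]
    p <- cbind((lin - 1) %% d[1], ((lin - 1) %/% d[1]) %% d[2],
               (lin - 1) %/% (d[1] * d[2])) + 0.5
    q <- cbind((near - 1) %% d[1], ((near - 1) %/% d[1]) %% d[2],
               (near - 1) %/% (d[1] * d[2])) + 0.5
    attained <- sqrt(rowSums((sweep(p, 2, cs$vs, "*") -
                                sweep(q, 2, cs$vs, "*"))^2))
    expect_lt(max(abs(attained - f$dist[lin])), 1e-9)
  }
})

test_that("measured distances reproduce analytic sphere geometry", {
  vs <- c(0.08, 0.08, 0.2)
  fix <- fixture_ellipsoid(c(10, 10, 10), vs)
  fix <- fixture_add_chromocenter(fix, c(3, 0, 0), 1)
  d <- measure_distances(fix$center_um + c(6, 0, 0), fix$nucleus)
  diag_half <- sqrt(sum(vs^2)) # one voxel diagonal tolerance
  expect_lt(abs(d$d_chromocenter_um - 2), diag_half)
  expect_lt(abs(d$d_periphery_um - 4), diag_half)
  # locus at the chromocenter centre scores zero
  d0 <- measure_distances(fix$center_um + c(3, 0, 0), fix$nucleus)
  expect_identical(d0$d_chromocenter_um, 0)
  # locus at the mask edge: periphery distance below one voxel diagonal
  dedge <- measure_distances(fix$center_um + c(9.98, 0, 0), fix$nucleus)
  expect_lte(dedge$d_periphery_um, diag_half)
})

test_that("chromocenter distance is missing (not zero) without chromocenters, and points outside the mask error", {
  fix <- fixture_ellipsoid(c(2, 2, 1.2), c(0.1, 0.1, 0.25))
  d <- measure_distances(fix$center_um, fix$nucleus)
  expect_true(is.na(d$d_chromocenter_um))
  expect_gt(d$d_periphery_um, 0)
  expect_error(measure_distances(fix$center_um + c(5, 0, 0), fix$nucleus),
               "outside the nuclear mask")
})

test_that("distances scale exactly with voxel size", {
  set.seed(66)
  fix1 <- fixture_ellipsoid(c(2, 2, 1), c(0.1, 0.1, 0.25))
  fix1 <- fixture_add_chromocenter(fix1, c(0.8, 0, 0), 0.3)
  s <- 2 # power of two keeps voxel lookup bit-identical under scaling
  nuc2 <- nucleus_model(fix1$nucleus$mask, fix1$nucleus$voxel_size * s,
                        fix1$nucleus$chromocenters, validate = FALSE)
  pts <- sweep(matrix(runif(30, 0.4, 0.6), ncol = 3), 2,
               fix1$center_um * 2, "*")
  keep <- !vapply(seq_len(nrow(pts)), function(i)
    inherits(try(measure_distances(pts[i, , drop = FALSE], fix1$nucleus),
                 silent = TRUE), "try-error"), logical(1))
  pts <- pts[keep, , drop = FALSE]
  skip_if(nrow(pts) == 0)
  d1 <- measure_distances(pts, fix1$nucleus)
  d2 <- measure_distances(pts * s, nuc2)
  expect_lt(max(abs(d2$d_periphery_um - d1$d_periphery_um * s)), 1e-10)
  expect_lt(max(abs(d2$d_chromocenter_um - d1$d_chromocenter_um * s),
                na.rm = TRUE), 1e-10)
})

test_that("no periphery distance exceeds the ellipsoid in-radius", {
  vs <- c(0.1, 0.1, 0.25)
  fix <- fixture_ellipsoid(c(4, 3, 1.5), vs)
  bg <- sample_background(fix$nucleus, 2000, rng_seed = 5)
  expect_lte(max(bg$d_periphery), 1.5 + sqrt(sum(vs^2)) / 2)
  expect_gte(min(bg$d_periphery), 0)
})

test_that("nucleus segmentation recovers synthetic ground truth", {
  cfg <- synthetic_config(rng_seed = 21, n_nuclei = 1,
                          nucleus_semiaxes = c(3, 3, 1.8),
                          voxel_size = c(0.1, 0.1, 0.25),
                          noise_sd_image = 0) # noise-free stack
  gen <- generate_nuclei(cfg, render = TRUE)
  seg <- segment_nucleus(gen$stacks[[1]], cfg$voxel_size)
  truth <- gen$nuclei[[1]]$mask
  jac <- sum(seg$mask & truth) / sum(seg$mask | truth)
  expect_gte(jac, 0.95)
  # all-zero stack is a segmentation error
  expect_error(segment_nucleus(array(0, c(10, 10, 5)), cfg$voxel_size),
               "segmentation error")
  # two equal blobs: exactly one retained, deterministically
  two <- array(0, c(30, 12, 6))
  two[3:8, 4:9, 2:5] <- 1
  two[20:25, 4:9, 2:5] <- 1
  seg2 <- segment_nucleus(two, c(1, 1, 1), sigma_um = 0.5)
  lab <- nucpos:::cpp_label3d(seg2$mask, dim(seg2$mask))
  expect_identical(max(lab), 1L)
  seg2b <- segment_nucleus(two, c(1, 1, 1), sigma_um = 0.5)
  expect_identical(seg2$mask, seg2b$mask)
})

test_that("chromocenter segmentation recovers planted counts and responds to k", {
  cfg <- synthetic_config(rng_seed = 22, n_nuclei = 3,
                          nucleus_semiaxes = c(3, 3, 1.8),
                          voxel_size = c(0.1, 0.1, 0.25),
                          preset = "MT", noise_sd_image = 0)
  gen <- generate_nuclei(cfg, render = TRUE)
  for (i in 1:3) {
    seg <- segment_chromocenters(gen$stacks[[i]], gen$nuclei[[i]], k = 2)
    expect_identical(max(seg$chromocenters),
                     gen$truth$nuclei$n_chromocenters[i])
  }
  # extremely large k: empty mask is permitted
  seg0 <- segment_chromocenters(gen$stacks[[1]], gen$nuclei[[1]], k = 1e6)
  expect_identical(max(seg0$chromocenters), 0L)
  expect_error(segment_chromocenters(gen$stacks[[1]], gen$nuclei[[1]], k = 0),
               "strictly positive")
})

test_that("myoblast-like preset yields more, smaller chromocenters than myotube-like", {
  mb <- generate_nuclei(synthetic_config(rng_seed = 23, n_nuclei = 4,
                                         nucleus_semiaxes = c(3.5, 3.5, 2),
                                         voxel_size = c(0.12, 0.12, 0.3),
                                         preset = "MB"))
  mt <- generate_nuclei(synthetic_config(rng_seed = 24, n_nuclei = 4,
                                         nucleus_semiaxes = c(3.5, 3.5, 2),
                                         voxel_size = c(0.12, 0.12, 0.3),
                                         preset = "MT"))
  expect_gt(mean(mb$truth$nuclei$n_chromocenters),
            mean(mt$truth$nuclei$n_chromocenters))
  expect_lt(mean(mb$truth$chromocenters$radius_um),
            mean(mt$truth$chromocenters$radius_um))
  # recovered counts from rendered stacks preserve the ordering
  mb2 <- generate_nuclei(synthetic_config(rng_seed = 23, n_nuclei = 4,
                                          nucleus_semiaxes = c(3.5, 3.5, 2),
                                          voxel_size = c(0.12, 0.12, 0.3),
                                          preset = "MB", noise_sd_image = 0),
                         render = TRUE)
  mt2 <- generate_nuclei(synthetic_config(rng_seed = 24, n_nuclei = 4,
                                          nucleus_semiaxes = c(3.5, 3.5, 2),
                                          voxel_size = c(0.12, 0.12, 0.3),
                                          preset = "MT", noise_sd_image = 0),
                         render = TRUE)
  rec <- function(gen) mean(vapply(1:4, function(i)
    max(segment_chromocenters(gen$stacks[[i]], gen$nuclei[[i]])$chromocenters),
    integer(1)))
  expect_gt(rec(mb2), rec(mt2))
})

test_that("spot detection finds planted Gaussian spots with sub-voxel accuracy", {
  vs <- c(0.1, 0.1, 0.25)
  fix <- fixture_ellipsoid(c(3, 3, 1.8), vs)
  gauss_spot <- function(img, p, sigma = c(0.15, 0.15, 0.25)) {
    d <- dim(img)
    xs <- (seq_len(d[1]) - 0.5) * vs[1]
    ys <- (seq_len(d[2]) - 0.5) * vs[2]
    zs <- (seq_len(d[3]) - 0.5) * vs[3]
    img + outer(outer(exp(-(xs - p[1])^2 / (2 * sigma[1]^2)),
                      exp(-(ys - p[2])^2 / (2 * sigma[2]^2))),
                exp(-(zs - p[3])^2 / (2 * sigma[3]^2)))
  }
  blank <- array(0.02, dim(fix$nucleus$mask))
  p1 <- fix$center_um + c(0.7, 0.3, 0.2)
  one <- gauss_spot(blank, p1)
  sp <- detect_spots(one, fix$nucleus)
  expect_identical(nrow(sp), 1L)
  expect_lt(max(abs(c(sp$x_um, sp$y_um, sp$z_um) - p1)), max(vs))
  # zero spots planted: empty result, not an error
  expect_identical(nrow(detect_spots(blank, fix$nucleus)), 0L)
  # two spots 3 um apart: two detections
  p2 <- p1 - c(3, 0, 0)
  two <- gauss_spot(gauss_spot(blank, p1), p2)
  expect_identical(nrow(detect_spots(two, fix$nucleus)), 2L)
})

test_that("nucleus model validates containment and connectivity, and stacks round-trip through TIFF", {
  m <- array(FALSE, c(8, 8, 4)); m[2:4, 2:4, 2:3] <- TRUE
  cc <- array(0L, c(8, 8, 4)); cc[7, 7, 1] <- 1L # outside the mask
  expect_error(nucleus_model(m, c(1, 1, 1), cc), "outside the nuclear mask")
  m2 <- m; m2[7, 7, 4] <- TRUE # second component
  expect_error(nucleus_model(m2, c(1, 1, 1)), "connected components")
  expect_error(nucleus_model(m, c(1, -1, 1)), "positive")
  tf <- tempfile(fileext = ".tif")
  stack <- array(runif(8 * 8 * 4), c(8, 8, 4))
  write_stack(stack, tf)
  back <- read_stack(tf)
  expect_lt(max(abs(back - stack)), 1 / 65535 + 1e-7) # 16-bit quantization
})
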