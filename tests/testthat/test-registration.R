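test_that("rigid fit recovers exact and constructed transforms", {
  pts <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  fit <- fit_rigid_transform(pts, pts)
  expect_equal(fit$transform$angle, 0, tolerance = 1e-12)
  expect_equal(c(fit$transform$dx, fit$transform$dy), c(0, 0),
               tolerance = 1e-12)
  expect_equal(fit$rms_um, 0, tolerance = 1e-12)
  # forward-construct: points_b are points_a moved by the inverse of the
  # target transform, so the fit must recover it
  target <- rigid_transform(30 * pi / 180, 5, -2)
  pb <- apply_transform(invert_transform(target), pts)
  fit <- fit_rigid_transform(pts, pb)
  expect_equal(fit$transform$angle, target$angle, tolerance = 1e-9)
  expect_equal(c(fit$transform$dx, fit$transform$dy), c(5, -2),
               tolerance = 1e-9)
  expect_lt(fit$rms_um, 1e-9)
})

test_that("rigid fit refuses insufficient or coincident fiducials", {
  expect_error(fit_rigid_transform(cbind(1, 1), cbind(1, 1)),
               class = "glom_insufficient_fiducials")
  same <- cbind(c(2, 2), c(3, 3))
  expect_error(fit_rigid_transform(same, same),
               class = "glom_insufficient_fiducials")
})

test_that("noisy-fit residuals match the rigid-dof closed form", {
  # N points with iid Gaussian coordinate noise sigma leave expected squared
  # residual sigma^2 (2N - 3) / N per point after fitting 3 rigid dof
  set.seed(99)
  sigma <- 0.5
  n_fid <- 4
  pts <- cbind(c(0, 40, 40, 0), c(0, 0, 40, 40))
  ms <- replicate(1000, {
    tr <- rand_rigid()
    pb <- apply_transform(invert_transform(tr), pts) +
      matrix(stats::rnorm(2 * n_fid, 0, sigma), ncol = 2)
    fit_rigid_transform(pts, pb)$rms_um^2
  })
  expected <- sigma^2 * (2 * n_fid - 3) / n_fid
  expect_lt(abs(mean(ms) - expected) / expected, 0.10)
})

test_that("fit never reflects, even on noisy near-degenerate input", {
  set.seed(17)
  for (i in 1:50) {
    # nearly collinear points plus a mirrored, noisy counterpart
    pa <- cbind(seq(0, 10, length.out = 4),
                stats::rnorm(4, 0, 0.01))
    pb <- cbind(-pa[, 1], pa[, 2]) + matrix(stats::rnorm(8, 0, 0.1), ncol = 2)
    fit <- fit_rigid_transform(pa, pb)
    ang <- fit$transform$angle
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("alignment chains compose along the stack", {
  # single section: identity only
  empty <- fiducial_pair(0L, 1L, cbind(c(0, 1), c(0, 1)),
                         cbind(c(0, 1), c(0, 1)))[0, ]
  ch <- build_alignment_chain(empty, reference_index = 0L)
  expect_equal(names(ch$transforms), "0")
  expect_equal(ch$transforms[["0"]]$angle, 0)
  # 3 sections, each adjacent step a pure translation (1, 0):
  # section b's coordinates are 1 um to the left of section a's
  pts <- cbind(c(0, 10, 3), c(0, 2, 8))
  pairs <- dplyr::bind_rows(
    fiducial_pair(0L, 1L, pts, sweep(pts, 2, c(1, 0))),
    fiducial_pair(1L, 2L, pts, sweep(pts, 2, c(1, 0)))
  )
  ch <- build_alignment_chain(pairs, reference_index = 2L)
  expect_equal(c(ch$transforms[["0"]]$dx, ch$transforms[["0"]]$dy), c(-2, 0),
               tolerance = 1e-12)
  expect_equal(ch$transforms[["2"]]$dx, 0)
  # gap detection
  gappy <- dplyr::bind_rows(
    fiducial_pair(0L, 1L, pts, pts),
    fiducial_pair(2L, 3L, pts, pts)
  )
  expect_error(build_alignment_chain(gappy), class = "glom_chain_gap")
})

test_that("chain recovers phantom ground-truth composites", {
  spec <- small_phantom_spec(seed = 21, noise_sigma = 0)
  truth <- generate_phantom(spec)
  render <- render_sections(truth, draw_fiducials = FALSE)
  chain <- build_alignment_chain(render$fiducial_pairs)
  tc <- phantom_true_chain(truth, chain$reference_index)
  for (s in names(chain$transforms)) {
    expect_equal(chain$transforms[[s]]$angle, tc$transforms[[s]]$angle,
                 tolerance = 1e-6)
    expect_equal(c(chain$transforms[[s]]$dx, chain$transforms[[s]]$dy),
                 c(tc$transforms[[s]]$dx, tc$transforms[[s]]$dy),
                 tolerance = 1e-6)
  }
  # associativity: direct 0 -> 2 fit equals composition through section 1
  fp <- render$fiducial_points
  direct <- fit_rigid_transform(fp[[1]], fp[[3]])$transform
  step01 <- fit_rigid_transform(fp[[1]], fp[[2]])$transform
  step12 <- fit_rigid_transform(fp[[2]], fp[[3]])$transform
  comp <- compose_transforms(step01, step12)
  expect_equal(direct$angle, comp$angle, tolerance = 1e-9)
  expect_equal(c(direct$dx, direct$dy), c(comp$dx, comp$dy),
               tolerance = 1e-9)
  # alignment strictly reduces fiducial scatter
  ref <- chain$reference_index + 1L
  rms_to_ref <- function(apply_chain) {
    mean(vapply(seq_along(fp), function(i) {
      q <- if (apply_chain) {
        apply_transform(chain$transforms[[as.character(i - 1L)]], fp[[i]])
      } else {
        fp[[i]]
      }
      sqrt(mean(rowSums((q - fp[[ref]])^2)))
    }, numeric(1)))
  }
  expect_lt(rms_to_ref(TRUE), rms_to_ref(FALSE))
})
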