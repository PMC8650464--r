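test_that("zero source yields the zero field; bad inputs error", {
  mesh <- box_mesh(c(8, 8, 8))
  src <- source_spec(c(0.4, 0.4, 0.4), rate = 0)
  sol <- solve_transport(mesh, transport_params(), src, c(0, 5, 10))
  expect_equal(max(abs(sol$values)), 0)
  expect_error(solve_transport(mesh, transport_params(),
                               source_spec(c(50, 50, 50)), c(0, 5)),
               "outside mesh")
  expect_error(source_spec(c(0, 0, 0), start = 10, stop = 5), "stop > start")
})

test_that("mass is conserved exactly after the source switches off", {
  mesh <- box_mesh(c(10, 10, 10))
  src <- source_spec(c(0.45, 0.45, 0.45), rate = 0.1, start = 0, stop = 1)
  sol <- solve_transport(mesh, transport_params(), src,
                         c(0, 2, 5, 10, 20, 40))
  amt <- nodal_amount(sol, mesh)$amount_umol
  expect_equal(amt[1], 0)
  # total = rate * duration = 0.1 umol, drift <= 1e-6 relative per frame
  expect_true(all(abs(amt[-1] - 0.1) / 0.1 < 1e-6))
})

test_that("continuous-source solve matches the erfc closed form, converging", {
  D <- 0.1; q <- 0.01
  extent <- 3.2                           # fixed physical domain (mm)
  # compare beyond 3 cell diameters (diam of a hex cell = sqrt(3) h) of the
  # finer mesh, in a fixed physical window untouched by the boundary
  rmin <- 3 * sqrt(3) * extent / 32
  run <- function(n, dt) {
    dims <- rep(n, 3)
    vs <- extent / n
    mask <- array(TRUE, dims)
    labels <- subdomain_labels(array(label_codes()[["BT"]], dims), vs)
    mesh <- tag_subdomains(build_mesh(mask, vs), labels)
    ctr <- rep(extent / 2 + vs / 2, 3)    # snap to a cell center
    src <- source_spec(ctr, rate = q, start = 0, stop = 100)
    sol <- solve_transport(mesh, transport_params(c(BT = D, PAS_Surf = 1,
                                                    PAS_Branch = 1)),
                           src, c(0, 2), solver_config(dt = dt))
    rr <- sqrt(colSums((t(mesh$nodes) - ctr)^2))
    sel <- rr >= rmin & rr <= 0.8
    ana <- analytic_point_source(D, rr[sel], 2, "continuous", q = q)
    max(abs(sol$values[sel, 2] - ana) / ana)
  }
  err_c <- run(16L, 0.1)
  err_f <- run(32L, 0.05)
  expect_lt(err_f, 0.05)
  expect_lt(err_f, err_c)                 # refinement reduces oracle error
})

test_that("analytic point source: quadrature, limits, guards", {
  D <- 0.05; Q <- 2; t <- 3
  # instantaneous kernel integrates to Q over all space
  integrand <- function(r)
    4 * pi * r^2 * analytic_point_source(D, r, t, "instantaneous", Q = Q) /
      1000
  got <- stats::integrate(integrand, 1e-9, Inf)$value
  expect_equal(got, Q, tolerance = 1e-6)
  # t -> large: instantaneous concentration vanishes
  expect_lt(analytic_point_source(D, 1, 1e9, "instantaneous", Q = Q), 1e-9)
  # continuous, t -> large: steady q/(4 pi D r)
  q <- 0.3; r <- 0.7
  expect_equal(analytic_point_source(D, r, 1e9, "continuous", q = q),
               1000 * q / (4 * pi * D * r), tolerance = 1e-4)
  expect_error(analytic_point_source(D, 0, 1, "continuous", q = 1),
               "singular")
})

test_that("centered source in a symmetric box gives a symmetric field", {
  dims <- c(9, 9, 9)
  mesh <- box_mesh(dims)
  ctr <- dims * 0.1 / 2
  src <- source_spec(ctr, rate = 0.05, start = 0, stop = 5)
  sol <- solve_transport(mesh, transport_params(), src, c(0, 4))
  v <- array(sol$values[, 2], dims)
  expect_equal(v, v[9:1, , ], tolerance = 1e-9)
  expect_equal(v, aperm(v, c(2, 1, 3)), tolerance = 1e-9)
})

test_that("raising a subdomain Deff lowers source-node concentration", {
  gt <- small_ground_truth()
  mesh <- build_mesh(gt$brain_mask, gt$spec$voxel_size, factor = 1L)
  mesh <- tag_subdomains(mesh, gt$labels)
  src <- source_spec(gt$spec$injection_site)
  at_src <- function(deff_bt) {
    p <- transport_params(c(BT = deff_bt, PAS_Surf = 95, PAS_Branch = 60))
    sol <- solve_transport(mesh, p, src, c(0, 20))
    sol$values[sol$source_cell, 2]
  }
  expect_gt(at_src(0.05), at_src(0.5))
})

test_that("sample_to_voxels: constant field, masking, IDW round trip", {
  gt <- small_ground_truth()
  mesh <- build_mesh(gt$brain_mask, gt$spec$voxel_size, factor = 1L)
  mesh <- tag_subdomains(mesh, gt$labels)
  nf <- structure(list(values = matrix(2.5, nrow(mesh$nodes), 1),
                       times = 10), class = "nodal_series")
  cs <- sample_to_voxels(nf, mesh)
  expect_equal(unique(cs$data[, , , 1][cs$mask]), 2.5)
  expect_equal(unique(cs$data[, , , 1][!cs$mask]), 0)
  # smooth nodal field -> voxels -> IDW back to nodes stays within 2%
  sm <- 1 + exp(-colSums((t(mesh$nodes) - c(1.6, 1.6, 1.2))^2))
  nf2 <- structure(list(values = matrix(sm, ncol = 1), times = 10),
                   class = "nodal_series")
  cs2 <- sample_to_voxels(nf2, mesh)
  back <- interpolate_idw(cs2$data[, , , 1], mesh)
  interior <- braintransport:::mask_distance(!gt$brain_mask, 4) > 4
  keep <- interior[cbind(mesh$cell_ijk)]
  expect_lt(max(abs(back[keep] - sm[keep]) / sm[keep]), 0.02)
})
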