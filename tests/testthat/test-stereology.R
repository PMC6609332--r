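square_ann <- function(gold, centres = tibble::tibble(x_nm = double(),
                                                      y_nm = double()),
                       side = 1000, image_area = 4) {
  # 1 um x 1 um square bouton at the image origin corner
  em_annotation(
    gold = gold, dcv_centers = centres,
    bouton_outline = rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)),
    image_area = image_area, image_id = "sq"
  )
}

test_that("compartment assignment follows the dcv > membrane > cytoplasm priority", {
  centres <- tibble::tibble(x_nm = 500, y_nm = 500)
  gold <- tibble::tibble(
    x_nm = c(500, 560, 505, 990, 1500, 530),
    y_nm = c(500, 500, 495, 500, 1500, 510)
  )
  lab <- assign_gold_compartments(square_ann(gold, centres))
  expect_equal(as.character(lab$compartment),
               c("dcv",        # at the DCV centre
                 "cytoplasm",  # 60 nm from the centre, > 20 nm from boundary
                 "dcv",        # just inside the 50 nm disc
                 "membrane",   # 10 nm inside the outline
                 "outside",
                 "dcv"))       # within the disc: disc beats everything
  # a particle 10 nm outside the outline is still membrane band
  out_band <- assign_gold_compartments(square_ann(
    tibble::tibble(x_nm = 1010, y_nm = 500), centres))
  expect_equal(as.character(out_band$compartment), "membrane")
})

test_that("assignment matches a brute-force geometric oracle exactly", {
  for (s in 1:4) {
    ann <- simulate_em_annotation(em_sim_params(seed = s))
    pts <- ann$gold
    got <- as.character(assign_gold_compartments(ann)$compartment)
    want <- oracle_compartment(pts$x_nm, pts$y_nm,
                               as.matrix(ann$dcv_centers),
                               ann$dcv_disc_radius, ann$bouton_outline,
                               ann$membrane_band_halfwidth)
    expect_equal(got, want)
  }
  # random scattered points over the whole image, not just simulated gold
  set.seed(5)
  ann <- simulate_em_annotation(em_sim_params(seed = 5))
  side <- sqrt(ann$image_area) * 1000
  pts <- tibble::tibble(x_nm = runif(400, 0, side), y_nm = runif(400, 0, side))
  ann2 <- em_annotation(pts, ann$dcv_centers, ann$bouton_outline,
                        ann$image_area)
  got <- as.character(assign_gold_compartments(ann2)$compartment)
  want <- oracle_compartment(pts$x_nm, pts$y_nm, as.matrix(ann$dcv_centers),
                             50, ann$bouton_outline, 20)
  expect_equal(got, want)
})

test_that("compartment counts always partition the gold total", {
  for (s in 1:6) {
    ann <- simulate_em_annotation(em_sim_params(seed = s + 100))
    lab <- assign_gold_compartments(ann)
    expect_equal(sum(table(lab$compartment)), nrow(ann$gold))
    rep <- density_report(list(ann))
    expect_equal(sum(rep$compartments$count), nrow(ann$gold))
  }
})

test_that("grid-intersection area estimation counts grid points", {
  sq <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  est <- grid_area_estimate(sq, 50)
  expect_lt(abs(est - 1) / 1, 0.05)
  # the counting formula itself: 20 x 20 cell-centre points inside
  expect_equal(est, 20^2 * 50^2 / 1e6)

  expect_warning(e0 <- grid_area_estimate(sq, 5000), "spacing")
  expect_error(grid_area_estimate(sq, -1), "spacing")

  # halving the spacing never increases the mean absolute error
  set.seed(31)
  polys <- lapply(1:20, function(i) {
    th <- sort(runif(10, 0, 2 * pi))
    r <- 400 * (1 + 0.4 * (runif(10) - 0.5))
    cbind(500 + r * cos(th), 500 + r * sin(th))
  })
  err <- function(spacing) {
    mean(vapply(polys, function(p) {
      abs(grid_area_estimate(p, spacing) - polygon_area(p) / 1e6)
    }, numeric(1)))
  }
  errs <- vapply(c(200, 100, 50, 25), err, numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("compartment areas satisfy the band bookkeeping identity", {
  for (s in 1:3) {
    ann <- simulate_em_annotation(em_sim_params(seed = s))
    rep <- density_report(list(ann))
    a <- rep$compartments
    lhs <- sum(a$area_um2[a$compartment %in% c("dcv", "cytoplasm", "membrane")])
    rhs <- polygon_area(ann$bouton_outline) / 1e6 +
      polygon_perimeter(ann$bouton_outline) * ann$membrane_band_halfwidth / 1e6
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("density recovery: uniform labelling gives a ratio near 1", {
  p <- em_sim_params(density_dcv = 5, density_cytoplasm = 5,
                     density_membrane_band = 5, density_outside = 5)
  anns <- lapply(1:40, function(s) {
    p$seed <- s + 300
    simulate_em_annotation(p, image_id = paste0("im", s))
  })
  rep <- density_report(anns)
  areas <- rep$compartments
  lam_d <- 5 * areas$area_um2[areas$compartment == "dcv"]
  lam_c <- 5 * areas$area_um2[areas$compartment == "cytoplasm"]
  ci <- poisson_ratio_interval(1, lam_d, lam_c)
  expect_gt(rep$dcv_over_bouton, ci[1])
  expect_lt(rep$dcv_over_bouton, ci[2])
  # both pooling schemes and both area conventions are reported
  expect_equal(nrow(rep$ratios), 4)
  expect_true(all(is.finite(rep$ratios$dcv_over_bouton)))
})

test_that("per-image pooling flags infinite ratios instead of failing", {
  ann <- simulate_em_annotation(em_sim_params(
    density_cytoplasm = 0, density_membrane_band = 0, density_outside = 0,
    density_dcv = 40, seed = 9))
  rep <- density_report(list(ann), pooling = "per_image_mean")
  expect_true(rep$infinite_image_ratio)
  expect_false(is.finite(rep$dcv_over_bouton))
})

test_that("background density pools control images against the ceiling", {
  empty <- simulate_control_annotation(10, density = 0, seed = 1)
  bg0 <- background_density(list(empty))
  expect_equal(bg0$density, 0)
  expect_true(bg0$below_threshold)

  ctrl <- lapply(1:30, function(s)
    simulate_control_annotation(10, density = 0.3, seed = 400 + s))
  bg <- background_density(ctrl)
  lam <- 0.3 * bg$total_area_um2
  ci <- c(stats::qpois(0.025, lam), stats::qpois(0.975, lam)) / bg$total_area_um2
  expect_gte(bg$density, ci[1])
  expect_lte(bg$density, ci[2])
  expect_true(bg$below_threshold)

  expect_error(background_density(list()), "at least one")
  expect_error(assign_gold_compartments(empty), "no bouton outline")
})
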