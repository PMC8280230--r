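test_that("Bray-Curtis handles identity, disjoint and hand-computed cases", {
  m <- community_matrix(matrix(c(1, 0, 1, 2), 2, 2,
                               dimnames = list(c("s1", "s2"), c("a", "b"))),
                        "biomass")
  D <- bray_curtis(m)
  # rows (1,1) and (0,2): (|1-0| + |1-2|) / (1+0+1+2) = 0.5
  expect_equal(D["s1", "s2"], 0.5)
  expect_equal(attr(D, "transform"), "raw-biomass")
  ident <- community_matrix(matrix(c(2, 2, 3, 3), 2, 2,
                                   dimnames = list(c("s1", "s2"),
                                                   c("a", "b"))), "biomass")
  expect_equal(bray_curtis(ident)["s1", "s2"], 0)
  disj <- community_matrix(matrix(c(2, 0, 0, 3), 2, 2,
                                  dimnames = list(c("s1", "s2"),
                                                  c("a", "b"))), "biomass")
  expect_equal(bray_curtis(disj)["s1", "s2"], 1)
  # read counts are square-root transformed first
  r <- community_matrix(matrix(c(4L, 0L, 0L, 9L), 2, 2,
                               dimnames = list(c("s1", "s2"),
                                               c("a", "b"))), "reads")
  Dr <- bray_curtis(r)
  expect_equal(attr(Dr, "transform"), "sqrt-reads")
  expect_equal(Dr["s1", "s2"], 1)
  # all-zero pair defined as 0 with a warning
  z <- community_matrix(matrix(c(0, 0, 1, 0, 0, 1), 3, 2,
                               dimnames = list(c("s1", "s2", "s3"),
                                               c("a", "b"))), "biomass")
  expect_warning(Dz <- bray_curtis(z), "all-zero")
  expect_equal(Dz["s1", "s2"], 0)
})

test_that("nested variance components match a univariate ANOVA oracle", {
  # univariate data with Euclidean distance: the distance-based nested
  # decomposition must equal classical method-of-moments variance components
  des <- fixture_design(ns = 3, nt = 2, nb = 2)
  set.seed(31)
  site_eff <- rnorm(3, 0, 2)[rep(1:3, each = 4)]
  tr_eff <- rnorm(6, 0, 1)[rep(1:6, each = 2)]
  y <- site_eff + tr_eff + rnorm(12, 0, 0.5)
  D <- as.matrix(dist(y))
  dimnames(D) <- list(des$sample_id, des$sample_id)
  vp <- hierarchical_varpart(D, des)
  # classical balanced nested EMS estimates
  ms <- anova(aov(y ~ factor(des$site_id) / factor(des$transect_id)))
  ms_site <- ms$`Mean Sq`[1]; ms_tr <- ms$`Mean Sq`[2]; ms_e <- ms$`Mean Sq`[3]
  s2_e <- ms_e
  s2_tr <- (ms_tr - ms_e) / 2          # 2 bottles per transect
  s2_site <- (ms_site - ms_tr) / 4     # 4 bottles per site
  expect_equal(vp$variance, c(s2_site, s2_tr, s2_e), tolerance = 1e-10)
  expect_equal(sum(vp$percent), 100, tolerance = 1e-10)
})

test_that("variance percentages sum to 100 even with negative components", {
  des <- fixture_design(ns = 3, nt = 2, nb = 2)
  found_negative <- FALSE
  for (s in 1:30) {
    set.seed(s)
    y <- rnorm(12)  # no group structure: components fluctuate around zero
    D <- as.matrix(dist(y))
    dimnames(D) <- list(des$sample_id, des$sample_id)
    vp <- hierarchical_varpart(D, des)
    expect_equal(sum(vp$percent), 100, tolerance = 1e-8)
    if (any(vp$percent < 0)) found_negative <- TRUE
  }
  expect_true(found_negative)
})

test_that("site-free noise leaves the site component near zero", {
  des <- fixture_design(ns = 4, nt = 2, nb = 2)
  perc <- replicate(20, {
    m <- matrix(rpois(16 * 12, exp(rnorm(12, 2, 1))), 16, 12, byrow = TRUE,
                dimnames = list(des$sample_id, sprintf("x%d", 1:12)))
    D <- bray_curtis(community_matrix(m, "reads"))
    hierarchical_varpart(D, des)$percent[1]
  })
  expect_lt(abs(mean(perc)), 10)  # centred near zero within Monte Carlo error
})

test_that("the Mantel test is exact on perfectly correlated matrices", {
  des <- fixture_design(ns = 4, nt = 2, nb = 1, spacing_km = 9)
  geo <- geo_distances(des)
  D <- 0.1 + 0.005 * geo; diag(D) <- 0
  mt <- mantel_test(D, geo, n_perm = 199, seed = 1)
  expect_equal(mt$statistic, 1, tolerance = 1e-12)
  expect_equal(mt$p_value, 1 / 200)
  # invariance under strictly increasing affine transforms
  mt2 <- mantel_test(3 + 2 * D, 10 * geo, n_perm = 199, seed = 1)
  expect_equal(mt2$statistic, 1, tolerance = 1e-12)
  # agreement with vegan's Mantel statistic on unstructured matrices
  set.seed(8)
  y <- rnorm(8)
  Dc <- as.matrix(dist(y)); dimnames(Dc) <- dimnames(geo)
  expect_equal(mantel_test(Dc, geo, n_perm = 9, seed = 1)$statistic,
               unname(vegan::mantel(Dc, geo, permutations = 9)$statistic),
               tolerance = 1e-12)
})

test_that("the Mantel test holds its size under independence", {
  des <- fixture_design(ns = 4, nt = 2, nb = 1, spacing_km = 9)
  geo <- geo_distances(des)
  set.seed(17)
  rej <- mean(replicate(400, {
    y <- rnorm(8)
    D <- as.matrix(dist(y)); dimnames(D) <- dimnames(geo)
    mantel_test(D, geo, n_perm = 99)$p_value <= 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("distance decay recovers a noiseless linear similarity field", {
  des <- fixture_design(ns = 6, nt = 2, nb = 1, spacing_km = 12)
  geo <- geo_distances(des)
  D <- 1 - (0.58 - 0.0026 * geo); diag(D) <- 0
  dd <- distance_decay(D, geo, n_perm = 199, seed = 2)
  expect_equal(dd$intercept, 0.58, tolerance = 1e-10)
  expect_equal(dd$slope, -0.0026, tolerance = 1e-12)
  expect_equal(abs(dd$mantel_r), 1, tolerance = 1e-10)
  expect_equal(dd$mantel_p, 1 / 200)
})

test_that("NMDS embeds exactly embeddable configurations with low stress", {
  set.seed(23)
  pts <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(sprintf("s%d", 1:10), sprintf("s%d", 1:10))
  em <- suppressWarnings(nmds_embed(D, k = 2, n_restarts = 5, seed = 3))
  expect_lt(em$stress, 0.01)
  em2 <- suppressWarnings(nmds_embed(D, k = 2, n_restarts = 5, seed = 3))
  expect_identical(em$points, em2$points)
})

test_that("Mantel power is near the nominal size at zero effect", {
  pw <- mantel_power("UVC", r_grid = 0, n_sim = 200, n_perm = 99,
                     n_cal = 20, seed = 5)
  expect_lt(abs(pw$power - 0.05), 2 * sqrt(0.05 * 0.95 / 200) + 1e-9)
})

test_that("Mantel power rises with effect size and with sample number", {
  pe <- mantel_power("eDNA", r_grid = c(0.1, 0.3, 0.5), n_sim = 120,
                     n_perm = 99, n_cal = 60, cal_tol = 0.01, seed = 6)
  expect_true(!is.unsorted(pe$power))
  expect_gt(pe$power[3], 0.99)  # large-effect limit
  pu <- mantel_power("UVC", r_grid = 0.3, n_sim = 120, n_perm = 99,
                     n_cal = 60, cal_tol = 0.01, seed = 6)
  # the 49-sample bottle design outpowers the 27-transect design
  expect_gte(pe$power[2], pu$power[1])
})

test_that("an unreachable effect size fails with a clear calibration error", {
  expect_error(mantel_power("UVC", r_grid = 0.9, n_sim = 10, n_perm = 19,
                            n_cal = 20, seed = 7), "unreachable")
})
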