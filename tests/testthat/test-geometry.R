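test_that("dihedral reproduces planar and perpendicular reference cases", {
  # trans-planar zig-zag
  expect_equal(dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)),
               180)
  # perpendicular quadruple, checked against the independent atan2 oracle
  p <- list(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  expect_equal(dihedralAngle(p[[1]], p[[2]], p[[3]], p[[4]]),
               oracleDihedral(p[[1]], p[[2]], p[[3]], p[[4]]))
  expect_equal(dihedralAngle(p[[1]], p[[2]], p[[3]], p[[4]]), 90)
  # tiny perturbation of the trans case stays near 180
  expect_equal(abs(dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                 c(2, 1, 1e-4))), 180, tolerance = 0.01)
})

test_that("dihedral agrees with the oracle on random quadruples and is reversal-invariant", {
  set.seed(11)
  for (k in 1:100) {
    p <- lapply(1:4, function(i) stats::rnorm(3))
    ours <- dihedralAngle(p[[1]], p[[2]], p[[3]], p[[4]])
    expect_equal(ours, oracleDihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
                 tolerance = 1e-9)
    # reversing the quadruple leaves the torsion unchanged
    expect_equal(dihedralAngle(p[[4]], p[[3]], p[[2]], p[[1]]), ours,
                 tolerance = 1e-9)
  }
})

test_that("dihedral is invariant under rigid transforms", {
  set.seed(12)
  for (k in 1:20) {
    p <- lapply(1:4, function(i) stats::rnorm(3))
    g <- randomRigid()
    q <- lapply(p, function(x) as.numeric(g$R %*% x + g$t))
    expect_equal(dihedralAngle(q[[1]], q[[2]], q[[3]], q[[4]]),
                 dihedralAngle(p[[1]], p[[2]], p[[3]], p[[4]]),
                 tolerance = 1e-9)
  }
})

test_that("dihedral rejects collinear triplets, naming atoms when given", {
  expect_error(dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "degenerate")
  expect_error(
    dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0),
                  labels = c("1:C", "2:N", "2:CA", "2:C")),
    "2:CA")
})

test_that("superposition recovers rigid motions exactly", {
  top <- hairpinTop()
  conf <- buildConformer(top, hairpinTorsions(top, "II'"))
  sel <- backboneSelection(2:11)
  expect_equal(superpose(conf, conf, sel)@rmsd, 0, tolerance = 1e-12)
  set.seed(13)
  for (k in 1:10) {
    g <- randomRigid()
    moved <- conf
    moved@coords <- applyRigidTo(conf@coords, g)
    fit <- superpose(conf, moved, sel)
    expect_lt(fit@rmsd, 1e-9)
    expect_equal(det(fit@rotation), 1, tolerance = 1e-9)
    # applying the fit maps mobile onto the reference
    back <- applySuperposition(fit, moved@coords)
    expect_lt(max(abs(back - conf@coords)), 1e-9)
  }
})

test_that("superposition rmsd matches the quaternion oracle and is symmetric", {
  top <- hairpinTop()
  sel <- backboneSelection(2:11)
  set.seed(14)
  e <- smallFoldedEnsemble(n = 6, sigma = 12, seed = 99)
  for (k in 1:8) {
    i <- sample(6, 2)
    a <- getConformer(e, i[1]); b <- getConformer(e, i[2])
    selKeys <- paste0(rep(2:11, each = 3), ":", c("N", "CA", "C"))
    A <- a@coords[selKeys, ]; B <- b@coords[selKeys, ]
    expect_equal(superpose(a, b, sel)@rmsd, oracleRmsd(A, B),
                 tolerance = 1e-9)
    expect_equal(superpose(a, b, sel)@rmsd, superpose(b, a, sel)@rmsd,
                 tolerance = 1e-12)
  }
})

test_that("superposition rejects degenerate selections", {
  co <- rbind("1:N" = c(0, 0, 0), "1:CA" = c(1, 0, 0), "1:C" = c(2, 0, 0))
  conf <- new("Conformer", coords = co, frameIndex = 0L, timePs = NA_real_)
  sel <- atomSelection(1, c("N", "CA", "C"))
  expect_error(superpose(conf, conf, sel), "collinear")
  expect_error(superpose(conf, conf, atomSelection(1, c("N", "CA"))),
               "at least 3")
})

test_that("rmsd series is zero for copies and matches per-frame superposition", {
  top <- hairpinTop()
  conf <- buildConformer(top, hairpinTorsions(top, "II'"))
  sel <- backboneSelection(2:11)
  ens <- ensembleFromCoords(top, list(conf@coords, conf@coords, conf@coords))
  expect_equal(rmsdSeries(ens, conf, sel), c(0, 0, 0), tolerance = 1e-12)
  # a rigidly moved copy still reads zero
  g <- list(R = diag(c(-1, -1, 1)), t = c(1, 1, 1))  # 180 deg about z + shift
  ens2 <- ensembleFromCoords(top, list(conf@coords,
                                       applyRigidTo(conf@coords, g)))
  expect_lt(max(rmsdSeries(ens2, conf, sel)), 1e-9)
  # jittered frames match one-by-one superposition
  e <- smallFoldedEnsemble(n = 4, sigma = 10, seed = 5)
  rs <- rmsdSeries(e, conf, sel)
  for (i in 1:4)
    expect_equal(rs[i], superpose(conf, getConformer(e, i), sel)@rmsd,
                 tolerance = 1e-12)
})

test_that("rmsd of uniformly jittered coordinates matches a Monte-Carlo oracle", {
  # frames = reference + iid uniform noise on every coordinate; the mean
  # fitted RMSD is estimated by direct simulation with the oracle
  top <- hairpinTop()
  conf <- buildConformer(top, hairpinTorsions(top, "II'"))
  sel <- backboneSelection(2:11)
  selKeys <- paste0(rep(2:11, each = 3), ":", c("N", "CA", "C"))
  sigma <- 0.02
  set.seed(21)
  mk <- function() {
    co <- conf@coords
    co <- co + matrix(stats::runif(length(co), -sigma * sqrt(3),
                                   sigma * sqrt(3)), nrow(co), 3)
    co
  }
  frames <- replicate(40, mk(), simplify = FALSE)
  ens <- ensembleFromCoords(top, frames)
  ours <- mean(rmsdSeries(ens, conf, sel))
  oracle <- mean(vapply(replicate(40, mk(), simplify = FALSE),
                        function(co) oracleRmsd(conf@coords[selKeys, ],
                                                co[selKeys, ]),
                        numeric(1)))
  expect_equal(ours, oracle, tolerance = 0.1)
})
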