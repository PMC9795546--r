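test_that("canonical turn centers classify exactly", {
  expect_equal(classifyTurn(c(60, 30), c(90, 0)), "I'")
  expect_equal(classifyTurn(c(60, -120), c(-80, 0)), "II'")
  # near-canonical II' case
  expect_equal(classifyTurn(c(55, -110), c(-75, 10)), "II'")
  # far from both centers
  expect_equal(classifyTurn(c(-120, 130), c(-120, 130)), "other")
})

test_that("classifyTurn matches a brute-force wrapped nearest-center search", {
  canon <- turnCanon()
  bruteForce <- function(x) {
    wd <- function(a, b) {
      d <- (a - b) %% 360
      pmin(d, 360 - d)
    }
    dist <- vapply(canon, function(cn)
      sqrt(sum(wd(x, as.vector(t(cn)))^2)), numeric(1))
    if (min(dist) > 60) "other" else names(canon)[which.min(dist)]
  }
  set.seed(51)
  for (k in 1:200) {
    x <- stats::runif(4, -180, 180)
    expect_equal(classifyTurn(x[1:2], x[3:4]), bruteForce(x))
  }
})

test_that("psi-only classifier follows the wrapped midpoint boundaries", {
  expect_equal(classifyTurnByPsi(30), "I'")
  expect_equal(classifyTurnByPsi(-120), "II'")
  expect_equal(classifyTurnByPsi(140), "II'")  # wraps nearer -120
  # boundary values (wrapped midpoints -45 and 135) go to II'
  expect_equal(classifyTurnByPsi(-45), "II'")
  expect_equal(classifyTurnByPsi(135), "II'")
  # arithmetic check against direct wrapped distances on a grid
  psi <- seq(-179.5, 180, by = 7.3)
  wd <- function(a, b) { d <- abs(a - b) %% 360; pmin(d, 360 - d) }
  expect_equal(classifyTurnByPsi(psi),
               ifelse(wd(psi, 30) < wd(psi, -120), "I'", "II'"))
})

test_that("flip counting handles carries, debounce and stable runs", {
  expect_equal(countFlips(c("I'", "I'", "II'", "II'", "I'")), 2)
  expect_equal(countFlips(rep("II'", 10)), 0)
  # "other" frames inherit the previous defined label
  expect_equal(countFlips(c("I'", "other", "other", "II'")), 1)
  expect_equal(countFlips(c("other", "I'", "II'")), 1)
  expect_equal(countFlips(rep("other", 4)), 0)
  # appending a frame equal to the last never changes the count
  set.seed(52)
  for (k in 1:20) {
    lab <- sample(c("I'", "II'", "other"), 30, replace = TRUE)
    expect_equal(countFlips(c(lab, lab[30])), countFlips(lab))
  }
  # debounce removes short excursions
  lab <- c(rep("I'", 10), "II'", rep("I'", 10), rep("II'", 10))
  expect_equal(countFlips(lab, debounce = 1), 3)
  expect_equal(countFlips(lab, debounce = 3), 1)
})

test_that("flip counts recover planted state changes exactly at zero jitter", {
  top <- hairpinTop()
  st <- list(stateTemplate("folded_I", hairpinTorsions(top, "I'"), 0),
             stateTemplate("folded_II", hairpinTorsions(top, "II'"), 0))
  P <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2, byrow = TRUE)
  gen <- generateMarkovEnsemble(markovSpec(st, P, "folded_II",
                                           nFrames = 120, seed = 99),
                                hairpinTop())
  planted <- sum(gen$statePath[-1] != gen$statePath[-120])
  su <- turnSummary(gen$ensemble)
  expect_equal(su$flips, planted)
  expect_equal(su$flipsByPsi, planted)
})

test_that("twist series equals the dihedral oracle and is rigid-invariant", {
  top <- hairpinTop()
  e <- smallFoldedEnsemble(n = 10, sigma = 10, seed = 12)
  tw <- twistSeries(e)
  expect_true(all(tw$angles > -180 & tw$angles <= 180))
  for (f in c(1, 5, 10)) {
    co <- e@coords[, , f]
    rownames(co) <- atomKeys(e)
    expect_equal(tw$angles[f],
                 oracleDihedral(co["1:C", ], co["12:N", ], co["8:C", ],
                                co["5:N", ]), tolerance = 1e-9)
  }
  set.seed(53)
  g <- randomRigid()
  tw2 <- twistSeries(rigidEnsemble(e, g))
  expect_equal(tw2$angles, tw$angles, tolerance = 1e-9)
  # four coplanar trans atoms give 180
  top2 <- peptideTopology(c("GLY", "GLY"), nTermProtonated = FALSE,
                          cTermAmide = FALSE)
  conf <- buildConformer(top2, torsionSet(phi = c(NA, 180), psi = c(180, NA)))
  e2 <- ensembleFromCoords(top2, list(conf@coords))
  expect_equal(twistSeries(e2, c("1:N", "1:CA", "1:C", "2:N"))$angles, 180)
})

test_that("circular twist mean matches the linear mean away from the seam", {
  top <- hairpinTop()
  e <- smallFoldedEnsemble(n = 50, sigma = 1, seed = 14)
  tw <- twistSeries(e)
  # concentrated distribution: circular and linear means coincide closely
  expect_lt(abs(tw$mean - mean(tw$angles)), 0.1)
  # across the +/-180 seam only the circular mean stays meaningful: frames
  # engineered with twist angles 175 and -175 must average to 180, not 0
  top2 <- peptideTopology(c("GLY", "GLY"), nTermProtonated = FALSE,
                          cTermAmide = FALSE)
  base <- buildConformer(top2, extendedTorsions(top2))@coords
  mk <- function(tauDeg) {
    co <- base
    t <- tauDeg * pi / 180
    co["1:N", ] <- c(1, 0, -1)
    co["1:CA", ] <- c(0, 0, 0)
    co["1:C", ] <- c(0, 0, 1)
    co["2:N", ] <- c(cos(t), sin(t), 2)
    co
  }
  e3 <- ensembleFromCoords(top2, list(mk(175), mk(-175)))
  tw2 <- twistSeries(e3, c("1:N", "1:CA", "1:C", "2:N"))
  expect_equal(sort(tw2$angles), c(-175, 175), tolerance = 1e-9)
  expect_equal(abs(tw2$mean), 180, tolerance = 1e-9)
  expect_equal(mean(tw2$angles), 0)  # the linear mean collapses
})

test_that("Ramachandran boxes classify representative points", {
  expect_equal(ramaRegion(-120, 130), "beta")
  expect_equal(ramaRegion(-65, -40), "alpha")
  expect_equal(ramaRegion(60, 30), "other")     # left-handed region
  expect_equal(ramaRegion(-120, -170), "beta")  # lower beta tail
})

test_that("uniform torsions give region fractions near the box-area ratios", {
  set.seed(54)
  n <- 1e5
  phi <- stats::runif(n, -180, 180); psi <- stats::runif(n, -180, 180)
  reg <- ramaRegion(phi, psi)
  areaBeta <- (135 * 165) / 360^2
  areaAlpha <- (140 * 150) / 360^2
  expect_equal(mean(reg == "beta"), areaBeta, tolerance = 0.01 / areaBeta)
  expect_equal(mean(reg == "alpha"), areaAlpha, tolerance = 0.01 / areaAlpha)
})

test_that("per-residue occupancy fractions sum to one", {
  e <- smallFoldedEnsemble(n = 8, sigma = 20, seed = 15)
  occ <- ramaOccupancy(e)
  expect_true(all(abs(occ$alpha + occ$beta + occ$other - 1) < 1e-12))
  # strand residues of the folded template live in the beta region
  expect_gt(occ$beta[occ$resno == 3], 0.8)
})
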