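# Helper: a 3-atom donor/H/acceptor conformer with forced geometry.
dhaConformer <- function(hPos, oPos) {
  co <- rbind("1:N" = c(0, 0, 0), "1:H" = hPos, "1:CA" = c(0, 0.1, 0),
              "1:C" = c(0.1, 0.15, 0), "1:O" = c(0, 0.2, 0.2),
              "2:N" = c(0.5, 0.5, 0.5), "2:H" = c(0.6, 0.5, 0.5),
              "2:CA" = c(0.5, 0.6, 0.5), "2:C" = c(0.5, 0.5, 0.6),
              "2:O" = oPos)
  new("Conformer", coords = co, frameIndex = 0L, timePs = NA_real_)
}
dhaPair <- data.frame(donorRes = 1, donorHeavy = "N", donorH = "H",
                      acceptorRes = 2, acceptorAtom = "O",
                      label = "1NH-2O")

test_that("boundary geometries classify exactly under both criteria", {
  ms <- hbondCriteria("medium_strong"); wk <- hbondCriteria("weak")
  # d = 0.2 nm, angle 180: present under both
  c1 <- dhaConformer(c(0.1, 0, 0), c(0.3, 0, 0))
  expect_true(detectHBonds(c1, dhaPair, ms)$present)
  expect_true(detectHBonds(c1, dhaPair, wk)$present)
  # d = 0.30 nm, angle 180: weak only
  c2 <- dhaConformer(c(0.1, 0, 0), c(0.4, 0, 0))
  expect_false(detectHBonds(c2, dhaPair, ms)$present)
  expect_true(detectHBonds(c2, dhaPair, wk)$present)
  # d = 0.24 nm, angle 120: fails the 135-degree cut, weak only
  h <- c(0.1, 0, 0)
  o <- h + 0.24 * c(cos(pi / 3), sin(pi / 3), 0)  # 120 deg at the hydrogen
  c3 <- dhaConformer(h, o)
  expect_false(detectHBonds(c3, dhaPair, ms)$present)
  expect_true(detectHBonds(c3, dhaPair, wk)$present)
})

test_that("thresholds are strict: exact-boundary geometry counts as absent", {
  # H at the origin, O at exactly 0.25 nm (exactly representable): the
  # distance boundary is NOT a medium-strong bond, but 0.25 - eps is
  mk <- function(oPos) {
    co <- rbind("1:N" = c(-0.1, 0, 0), "1:H" = c(0, 0, 0), "2:O" = oPos)
    new("Conformer", coords = co, frameIndex = 0L, timePs = NA_real_)
  }
  pair <- data.frame(donorRes = 1, donorHeavy = "N", donorH = "H",
                     acceptorRes = 2, acceptorAtom = "O", label = "1NH-2O")
  ms <- hbondCriteria("medium_strong")
  expect_false(detectHBonds(mk(c(0.25, 0, 0)), pair, ms)$present)
  expect_true(detectHBonds(mk(c(0.25 - 1e-9, 0, 0)), pair, ms)$present)
  # the weak distance boundary (0.32 nm) is absent too
  wk <- hbondCriteria("weak")
  expect_false(detectHBonds(mk(c(0.32, 0, 0)), pair, wk)$present)
  # an angle a hair below 135 degrees fails the medium-strong cut
  th <- pi * (180 - 135 + 1e-7) / 180
  o <- 0.2 * c(cos(th), sin(th), 0)
  expect_false(detectHBonds(mk(o), pair, ms)$present)
  th2 <- pi * (180 - 135 - 1e-4) / 180
  expect_true(detectHBonds(mk(0.2 * c(cos(th2), sin(th2), 0)), pair,
                           ms)$present)
})

test_that("pair enumeration follows donor chemistry", {
  top <- hairpinTop(aminated = c(2, 9))
  pairs <- enumeratePairs(top)
  donors <- unique(paste0(pairs$donorRes, ":", pairs$donorH))
  # N-terminal NH3 hydrogens, reported separately
  expect_true(all(c("1:H1", "1:H2", "1:H3") %in% donors))
  # proline contributes no amide donor
  expect_false(any(pairs$donorRes == 6))
  # aminated residues donate via NB hydrogens only
  expect_true(all(c("2:HB1", "2:HB2", "9:HB1", "9:HB2") %in% donors))
  expect_false("2:H" %in% donors)
  # manual donor count: res1 x3, res3,4,5,7,8,10,11,12 amide x1, res2,9 x2
  expect_length(donors, 3 + 8 + 4)
  # intraresidue pairs excluded except NB->O(i)
  same <- pairs[pairs$donorRes == pairs$acceptorRes, ]
  expect_true(all(same$donorHeavy == "NB"))
  expect_true("2NBHB2-2O" %in% same$label)
})

test_that("populations count frames and respect the report threshold", {
  top <- peptideTopology(c("GLY", "GLY"), nTermProtonated = FALSE,
                         cTermAmide = FALSE)
  pairs <- data.frame(donorRes = 2, donorHeavy = "N", donorH = "H",
                      acceptorRes = 1, acceptorAtom = "O",
                      label = "2NH-1O")
  base <- buildConformer(top, torsionSet(phi = c(NA, -80), psi = c(60, NA)))
  near <- base@coords
  # move O(1) next to H(2) at a straight angle to force the bond
  h <- near["2:H", ]; n <- near["2:N", ]
  near["1:O", ] <- h + 0.18 * (h - n) / sqrt(sum((h - n)^2))
  far <- base@coords; far["1:O", ] <- far["1:O", ] + c(5, 0, 0)
  ens <- ensembleFromCoords(top, c(replicate(5, near, simplify = FALSE),
                                   replicate(5, far, simplify = FALSE)))
  tab <- hbondPopulations(ens, pairs, hbondCriteria("medium_strong"))
  expect_equal(tab$population, 50)
  expect_equal(tab$nFrames, 10)
  # threshold: a 50% bond survives minReport 10, dies at minReport 60
  expect_equal(nrow(hbondPopulations(ens, pairs, hbondCriteria("medium_strong"),
                                     minReport = 10)), 1)
  expect_equal(nrow(hbondPopulations(ens, pairs, hbondCriteria("medium_strong"),
                                     minReport = 60)), 0)
  # population invariant under frame reordering
  perm <- sample(10)
  tab2 <- hbondPopulations(subsetFrames(ens, perm), pairs,
                           hbondCriteria("medium_strong"))
  expect_equal(tab2$population, tab$population)
})

test_that("medium-strong bonds are a subset of weak bonds on random ensembles", {
  set.seed(41)
  top <- hairpinTop(aminated = 9)
  e <- smallFoldedEnsemble(n = 30, sigma = 25, seed = 7, topology = top)
  pairs <- enumeratePairs(top)
  ms <- hairpintools:::.presenceMatrix(e, pairs, hbondCriteria("medium_strong"))
  wk <- hairpintools:::.presenceMatrix(e, pairs, hbondCriteria("weak"))
  expect_true(all(wk[ms]))
})

test_that("detection is invariant under rigid transforms of the conformer", {
  top <- hairpinTop(aminated = 9)
  conf <- buildConformer(top, hairpinTorsions(top, "II'"))
  pairs <- enumeratePairs(top)
  ref <- detectHBonds(conf, pairs, hbondCriteria("weak"))$present
  set.seed(42)
  for (k in 1:5) {
    g <- randomRigid()
    moved <- conf
    moved@coords <- applyRigidTo(conf@coords, g)
    expect_identical(detectHBonds(moved, pairs, hbondCriteria("weak"))$present,
                     ref)
  }
})

test_that("the folded template forms the canonical cross-strand bonds", {
  top <- hairpinTop()
  pairs <- enumeratePairs(top)
  wk <- hbondCriteria("weak")
  for (turn in c("II'", "I'")) {
    conf <- buildConformer(top, hairpinTorsions(top, turn))
    det <- detectHBonds(conf, pairs, wk)
    present <- det$label[det$present]
    expect_true(all(c("3NH-10O", "5NH-8O", "10NH-3O") %in% present),
                label = paste("canonical bonds under weak criterion,", turn))
  }
})

test_that("NH2-group rows can be combined to the higher population", {
  top <- hairpinTop(aminated = 9)
  e <- smallFoldedEnsemble(n = 10, sigma = 10, seed = 3, topology = top)
  full <- hbondPopulations(e, criteria = hbondCriteria("weak"))
  comb <- hbondPopulations(e, criteria = hbondCriteria("weak"),
                           combineNH2 = TRUE)
  # combined row for 9NB -> 7O equals max of the HB1/HB2 rows
  p1 <- full$population[full$label == "9NBHB1-7O"]
  p2 <- full$population[full$label == "9NBHB2-7O"]
  pc <- comb$population[comb$label == "9NBH2-7O"]
  expect_equal(pc, max(p1, p2))
})

test_that("amination report lists C6 and (i,i-2) rows per site", {
  top <- hairpinTop(aminated = c(2, 3, 9))
  e <- smallFoldedEnsemble(n = 3, sigma = 5, seed = 8, topology = top)
  rep <- aminationReport(e)
  expect_true(all(c("2NBHB2-2O", "3NBHB2-3O", "3NBHB1-1O",
                    "9NBHB2-9O", "9NBHB1-7O") %in% rep$label))
  # residue 2 has no i-2 partner
  expect_false(any(rep$class == "i_minus_2" & startsWith(rep$label, "2")))
  # no aminated residues -> empty report, not an error
  e0 <- smallFoldedEnsemble(n = 2, sigma = 5, seed = 9)
  expect_equal(nrow(aminationReport(e0)), 0)
})

test_that("the C6 geometry holds on the noiseless beta-strand template", {
  top <- hairpinTop(aminated = 9)
  conf <- buildConformer(top, hairpinTorsions(top, "II'"))
  ens <- ensembleFromCoords(top, list(conf@coords))
  rep <- aminationReport(ens)
  expect_equal(rep$population[rep$label == "9NBHB2-9O"], 100)
})
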