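test_that("Weibel trees have 2^N terminals and the stated daughter scaling", {
  expect_equal(nTerminals(weibelTree(9)), 512L)
  expect_equal(nTerminals(weibelTree(1)), 2L)
  # symmetric case: every branch in a generation identical, factor (1/2)^(1/3)
  tr0 <- weibelTree(2, 0)
  tb <- branchTable(tr0)
  gen1 <- tb$radius_mm[tb$prox == 2]
  expect_equal(gen1, rep(9 * 0.5^(1 / 3), 2))
  # extreme asymmetry: minor daughter radius ratio ((1-0.98)/2)^(1/3)
  tr <- weibelTree(2, 0.98)
  ratios <- sort(unique(round(branchTable(tr)$radius_mm[2:3] / 9, 10)))
  expect_equal(ratios, round(c((0.01)^(1 / 3), (0.99)^(1 / 3)), 10))
})

test_that("Weibel generation volumes are conserved independently of asymmetry", {
  for (A in c(0, 0.4, 0.9)) {
    tr <- weibelTree(5, A)
    tb <- branchTable(tr)
    depth <- horsfieldOrders(tr, recompute = TRUE)
    gen <- max(depth) - depth   # 0 = trachea
    vol <- pi * tb$radius_mm^2 * tb$length_mm
    perGen <- tapply(vol, gen, sum)
    # every generation's total volume equals the trachea's volume
    expect_equal(as.numeric(perGen), rep(perGen[[1]], length(perGen)),
                 tolerance = 1e-12)
  }
})

test_that("Weibel equivalent resistance follows the closed form r1 (N+1) for all A", {
  # under equal terminal pressures each daughter pair combines in parallel
  # to its parent's resistance, so every generation adds one trachea-level
  # resistance: R_eq = r_trachea * (N + 1), independent of A
  for (N in c(1, 4, 9)) {
    for (A in c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 0.95, 0.98)) {
      tr <- weibelTree(N, A)
      sol <- solveFixedPressure(tr, 1)
      Req <- -1 / sum(sol@QTerminal)
      expect_equal(Req, resistances(tr)[1] * (N + 1), tolerance = 1e-8)
    }
  }
})

test_that("daughter pairs combine in parallel to the parent resistance", {
  tr <- weibelTree(1, 0.6)
  r <- resistances(tr)
  expect_equal(1 / (1 / r[2] + 1 / r[3]), r[1], tolerance = 1e-12)
})

test_that("Horsfield recursion reproduces the Fibonacci terminal count", {
  tab <- horsfieldTable(
    order = 1:5,
    childOrders = c(list(integer(0)),
                    lapply(2:5, function(g) c(g - 1L, g - 2L))),
    meanRadius = 0.3 * 1.4^(0:4),
    meanLength = 1.8 * 1.4^(0:4))
  tr <- horsfieldTree(tab, rootOrder = 5, terminationOrder = 1)
  # T(g) = T(g-1) + T(g-2), T(<=1) = 1 -> T(5) = 8
  expect_equal(nTerminals(tr), 8L)
  expect_equal(max(horsfieldOrders(tr)), 5L)
})

test_that("a symmetric noise-free table reproduces the symmetric Weibel tree", {
  N <- 4
  diam <- 18 * (0.5^(1 / 3))^((N):0)   # order g radius matches weibel gen
  tab <- horsfieldTable(
    order = 1:(N + 1),
    childOrders = c(list(integer(0)),
                    lapply(2:(N + 1), function(g) c(g - 1L, g - 1L))),
    meanRadius = diam / 2,
    meanLength = 3 * diam)
  th <- horsfieldTree(tab, rootOrder = N + 1, terminationOrder = 1)
  tw <- weibelTree(N, 0)
  expect_equal(th@prox, tw@prox)
  expect_equal(th@radius, tw@radius, tolerance = 1e-12)
  expect_equal(resistances(th), resistances(tw), tolerance = 1e-12)
})

test_that("Horsfield geometry noise is seed-reproducible and truncated", {
  tab <- demoHorsfieldTable()
  t1 <- horsfieldTree(tab, 8, noiseFraction = 0.2, seed = 42)
  t2 <- horsfieldTree(tab, 8, noiseFraction = 0.2, seed = 42)
  t3 <- horsfieldTree(tab, 8, noiseFraction = 0.2, seed = 43)
  expect_identical(t1@radius, t2@radius)
  expect_identical(t1@prox, t3@prox)          # same topology
  expect_false(identical(t1@radius, t3@radius))
  # all draws clear the resampling floor
  means <- tab@meanRadius[match(pmax(horsfieldOrders(t1), 1L), tab@order)]
  expect_true(all(t1@radius > 0.05 * means))
})

test_that("distal diameter assignment follows the log-linear taper", {
  tr <- horsfieldTree(demoHorsfieldTable(), 6)
  ord <- horsfieldOrders(tr)
  out <- assignDistalDiameters(tr, anchorOrder = 6, anchorDiameter = 1.15 * 2,
                               ratio = 1.15)
  # anchored branches keep measured diameters
  expect_equal(out@radius[ord == 6], tr@radius[ord == 6])
  # one order below the anchor with D_N = 1.15 R = 1.15: D = 1.0
  expect_equal(unique(2 * out@radius[ord == 5]), 2.3 / 1.15)
  d <- vapply(1:5, function(g) unique(2 * out@radius[ord == g]), numeric(1))
  expect_true(all(diff(d) > 0))               # strictly decreasing toward g = 1
  # resistances rescaled consistently with the new radii
  fresh <- poiseuilleResistances(out)
  expect_equal(resistances(out), resistances(fresh), tolerance = 1e-12)
})

test_that("constrictions are seeded, nested across f, and leave the rest intact", {
  tr <- weibelTree(6, 0.2)
  ord <- horsfieldOrders(tr)
  g <- 4L
  f0 <- applyConstrictions(tr, order = g, fraction = 0, seed = 7)
  expect_equal(f0@radius, tr@radius)
  a <- applyConstrictions(tr, order = g, fraction = 0.3, seed = 7)
  b <- applyConstrictions(tr, order = g, fraction = 0.6, seed = 7)
  selA <- which(a@radius < tr@radius)
  selB <- which(b@radius < tr@radius)
  expect_equal(length(selA), ceiling(0.3 * sum(ord == g)))
  expect_true(all(selA %in% selB))            # nested under the fixed seed
  expect_true(all(ord[selB] == g))
  expect_equal(a@length, tr@length)
  expect_equal(a@prox, tr@prox)
  # reductions fall in the configured band and resistances follow a^-4
  u <- 1 - a@radius[selA] / tr@radius[selA]
  expect_true(all(u >= 0.5 & u <= 0.95))
  expect_equal(a@resistance[selA],
               tr@resistance[selA] * (tr@radius[selA] / a@radius[selA])^4)
  # deterministic limit: f = 1 with a degenerate range halves every radius
  c1 <- applyConstrictions(tr, order = g, fraction = 1,
                           reductionRange = c(0.5, 0.5), seed = 1)
  expect_equal(c1@radius[ord == g], tr@radius[ord == g] / 2)
  expect_equal(c1@resistance[ord == g], tr@resistance[ord == g] * 16)
  expect_error(applyConstrictions(tr, order = 99L, fraction = 0.5),
               "order")
})

test_that("peripheral orders hold more branches than proximal ones", {
  tr <- horsfieldTree(demoHorsfieldTable(), 10)
  ord <- horsfieldOrders(tr)
  expect_true(sum(ord == 3) > sum(ord == 8))
})
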