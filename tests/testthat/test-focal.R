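test_that("candidate detection marks only-outgoing nodes of a focal pattern", {
  grid <- buildGrid(2, layers = 2)
  org <- wallOrigin(grid)
  fo <- genFocal(grid, org$pos, cv = 0.6, beatTimes = c(100, 400))
  frames <- analyzeFrames(fo$events, grid,
                          graphParams(deltaT = 150, latWindow = 300))
  cand <- detectFocalCandidates(frames)
  expect_true(org$id %in% cand$electrode)
  # the origin is a candidate at (about) each beat time
  tOrg <- sort(cand$time[cand$electrode == org$id])
  expect_true(any(abs(tOrg - 100) < 1))
  expect_true(any(abs(tOrg - 400) < 1))

  # an isolated node (no edges at all) is not a candidate
  g2 <- tinyGrid(rbind(c(0, 0, 0), c(4, 0, 0), c(100, 100, 100)))
  p <- graphParams(deltaT = 50, latWindow = 500)
  ev <- data.frame(electrode = 1:3, time = c(10, 15, 500))
  g <- buildActivationGraph(ev, g2, 10, p)
  fr <- list(times = 10, graphs = list(mergeGraphs(g, g)))
  cand2 <- detectFocalCandidates(fr)
  expect_false(3 %in% cand2$electrode)
  expect_true(1 %in% cand2$electrode)
})

test_that("planar wavefront candidates sit on the entry boundary and are rejected", {
  grid <- buildGrid(2, layers = 2)
  pl <- genPlanar(grid, c(1, 0, 0), cv = 0.8)
  frames <- analyzeFrames(pl$events, grid,
                          graphParams(deltaT = 40, latWindow = 100))
  cand <- detectFocalCandidates(frames)
  expect_gt(nrow(cand), 0)
  pos <- electrodePositions(grid, cand$electrode)
  # entry boundary: all candidates in the earlier-activated half
  expect_true(all(pos[, 1] <= median(electrodePositions(grid)[, 1])))
  # RS morphology rejects them all
  egm <- genElectrograms(pl$events, grid, pl$truth)
  ver <- verifyFocal(cand, egm = egm)
  expect_true(all(ver$status == "rejected"))
})

test_that("morphology verification separates QS from RS and honours the bound", {
  grid <- buildGrid(2, layers = 2)
  org <- wallOrigin(grid)
  fo <- genFocal(grid, org$pos, cv = 0.6, beatTimes = 200)
  egm <- genElectrograms(fo$events, grid, fo$truth)
  cand <- data.frame(electrode = org$id, time = 200, status = "auto")
  expect_equal(verifyFocal(cand, egm = egm)$status,
               "electrogram_confirmed")
  # a far electrode activated by the incoming wave has RS morphology
  far <- fo$events[which.max(fo$events$time), ]
  candF <- data.frame(electrode = far$electrode, time = far$time,
                      status = "auto")
  expect_equal(verifyFocal(candF, egm = egm)$status, "rejected")
  # degenerate bound: upstroke fraction 1 confirms everything
  both <- rbind(cand, candF)
  expect_true(all(verifyFocal(both, egm = egm,
                              upstrokeFraction = 1)$status ==
                  "electrogram_confirmed"))
  expect_error(verifyFocal(data.frame(electrode = 99999, time = 1,
                                      status = "auto"), egm = egm),
               "trace")
})

test_that("silence fallback confirms pre-beat quiet sites only", {
  grid <- buildGrid(2, layers = 2)
  org <- wallOrigin(grid)
  fo <- genFocal(grid, org$pos, cv = 0.6, beatTimes = c(100, 420))
  cand <- data.frame(electrode = org$id, time = c(100, 420),
                     status = "auto")
  ver <- verifyFocal(cand, grid = grid, events = fo$events)
  expect_true(all(ver$status == "silence_confirmed"))
  # a downstream electrode whose neighbors fired just before: rejected
  late <- fo$events[which.max(fo$events$time), ]
  verL <- verifyFocal(data.frame(electrode = late$electrode,
                                 time = late$time, status = "auto"),
                      grid = grid, events = fo$events)
  expect_equal(verL$status, "rejected")
  expect_error(verifyFocal(cand), "fallback")
})

test_that("heatmaps conserve source counts", {
  grid <- buildGrid(1, layers = 2)
  hm0 <- focalHeatmap(data.frame(electrode = integer(0)), grid)
  expect_true(all(hm0$count == 0))
  hm3 <- focalHeatmap(data.frame(electrode = c(5L, 5L, 5L)), grid)
  expect_equal(hm3$count[hm3$electrode == 5], 3)
  expect_equal(sum(hm3$count), 3)
  set.seed(2)
  src <- data.frame(electrode = sample(usableElectrodes(grid), 57,
                                       replace = TRUE))
  expect_equal(sum(focalHeatmap(src, grid)$count), 57)
})

test_that("the binomial null is a proper pmf with the stated values", {
  expect_equal(unname(binomialNull(1, 2)$px["1"]), 0.5)
  nb <- binomialNull(7, 3)
  expect_equal(sum(nb$px), 1, tolerance = 1e-12)
  expect_true(all(nb$px >= 0 & nb$px <= 1))
  expect_equal(sum(binomialNull(120, 173)$px), 1, tolerance = 1e-12)
  expect_error(binomialNull(5, 0))
})

test_that("randomness table flags impossible occupancy and not uniform placement", {
  grid <- buildGrid(1)   # 240 electrodes
  # all sources on one electrode: that row must be flagged
  ids <- usableElectrodes(grid)
  srcs <- data.frame(electrode = rep(ids[7], 12))
  hm <- focalHeatmap(srcs, grid)
  tab <- randomnessTable(hm, binomialNull(12, length(ids)))
  expect_true(tab$flag[tab$x == 12])
  expect_equal(sum(tab$observed_electrodes * tab$x), 12)

  # uniform placement: n=200 over e=100 electrodes, flags are rare
  flagged <- vapply(1:100, function(s) {
    set.seed(s)
    counts <- tabulate(sample.int(100, 200, replace = TRUE), nbins = 100)
    hmU <- data.frame(electrode = 1:100, x = 0, y = 0, z = 0,
                      count = counts)
    any(randomnessTable(hmU, binomialNull(200, 100))$flag)
  }, logical(1))
  expect_gte(mean(!flagged), 0.95)

  expect_error(randomnessTable(hm, binomialNull(5, 7)), "totals")
})
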