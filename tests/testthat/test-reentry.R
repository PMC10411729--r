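test_that("cycle enumeration is exact on hand-built and random graphs", {
  sq <- tinyGrid(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0),
                       c(0, 10, 0)))
  ring <- edgesToMerged(data.frame(src = c(1, 2, 3, 4),
                                   dst = c(2, 3, 4, 1)))
  cys <- findCycles(ring, sq)
  expect_length(cys, 1)
  expect_equal(cys[[1]]$electrodes, c(1, 2, 3, 4))
  expect_equal(cys[[1]]$center, c(x = 5, y = 5, z = 0))

  # acyclic graph: empty result
  dag <- edgesToMerged(data.frame(src = c(1, 1, 2), dst = c(2, 3, 3)))
  expect_length(findCycles(dag, sq), 0)

  # random digraphs up to 10 nodes vs exhaustive path enumeration
  set.seed(20)
  gridN <- tinyGrid(matrix(runif(30, 0, 50), ncol = 3))
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    p <- runif(1, 0.1, 0.4)
    adj <- matrix(runif(n * n) < p, n, n); diag(adj) <- FALSE
    edges <- which(adj, arr.ind = TRUE)
    if (!nrow(edges)) next
    ed <- data.frame(src = edges[, 1], dst = edges[, 2])
    got <- findCycles(edgesToMerged(ed), gridN, maxLen = n)
    want <- bruteCycles(ed, maxLen = n)
    gotKeys <- sort(vapply(got, function(cy)
      paste(cy$electrodes, collapse = "-"), character(1)))
    expect_identical(gotKeys, names(want))
  }
})

test_that("representative cycles are true elementary cycles covering each SCC", {
  set.seed(33)
  gridN <- tinyGrid(matrix(runif(45, 0, 50), ncol = 3))
  for (rep in 1:20) {
    n <- sample(6:15, 1)
    adj <- matrix(runif(n * n) < 0.25, n, n); diag(adj) <- FALSE
    edges <- which(adj, arr.ind = TRUE)
    if (!nrow(edges)) next
    ed <- data.frame(src = edges[, 1], dst = edges[, 2])
    m <- edgesToMerged(ed)
    reps <- findCycles(m, gridN, maxLen = n, method = "representative")
    exact <- findCycles(m, gridN, maxLen = n, method = "exact")
    exactKeys <- vapply(exact, function(cy)
      paste(cy$electrodes, collapse = "-"), character(1))
    for (cy in reps) {
      expect_true(paste(cy$electrodes, collapse = "-") %in% exactKeys)
    }
    # representative mode finds cycles iff the graph has any
    expect_equal(length(reps) > 0, length(exact) > 0)
  }
})

test_that("impossible loops are filtered by angle and crossing rules", {
  # square loop: right angles, cos 0 <= 0.75 -> kept
  sq <- tinyGrid(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0),
                       c(0, 10, 0)))
  cys <- findCycles(edgesToMerged(
    data.frame(src = c(1, 2, 3, 4), dst = c(2, 3, 4, 1))), sq)
  expect_length(filterCycles(cys, sq), 1)

  # U-turn vertex: segments to (-4,0,0) and (-4,1,0) -> cos 0.970 > 0.75
  ut <- tinyGrid(rbind(c(0, 0, 0), c(-4, 0, 0), c(-4, 1, 0)))
  cyU <- findCycles(edgesToMerged(
    data.frame(src = c(2, 1, 3), dst = c(1, 3, 2))), ut)
  expect_length(cyU, 1)
  expect_length(filterCycles(cyU, ut), 0)

  # figure-eight: the bowtie traversal 1->4->3->2->1 crosses itself in
  # plane and is removed; the rectangle traversal of the same points is
  # kept
  f8 <- tinyGrid(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 0),
                       c(10, 8, 0)))
  cy8 <- findCycles(edgesToMerged(
    data.frame(src = c(1, 2, 4, 3), dst = c(2, 4, 3, 1))), f8)
  cyX <- findCycles(edgesToMerged(
    data.frame(src = c(1, 4, 3, 2), dst = c(4, 3, 2, 1))), f8)
  expect_length(filterCycles(cy8, f8), 1)
  expect_length(filterCycles(cyX, f8), 0)
})

test_that("DBSCAN grouping reproduces hand-run and brute-force results", {
  p <- clusterParams(dEps = 10, minPts = 2)
  mkCycle <- function(ctr) list(electrodes = 1L, center = ctr)

  # {0, 5, 30} on a line: first two merge, third is singleton noise
  cl <- groupLoops(lapply(list(c(0, 0, 0), c(5, 0, 0), c(30, 0, 0)),
                          mkCycle), p)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$n, c(2, 1))

  # chain {0, 8, 16}: one cluster by density reachability
  cl2 <- groupLoops(lapply(list(c(0, 0, 0), c(8, 0, 0), c(16, 0, 0)),
                           mkCycle), p)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$n, 3)
  expect_equal(cl2$x, 8)

  # single cycle: one singleton reentry
  cl3 <- groupLoops(list(mkCycle(c(1, 2, 3))), p)
  expect_equal(nrow(cl3), 1)

  # order invariance
  set.seed(9)
  ctrs <- lapply(1:12, function(i) runif(3, 0, 40))
  a <- groupLoops(lapply(ctrs, mkCycle), p)
  b <- groupLoops(lapply(rev(ctrs), mkCycle), p)
  expect_equal(sort(a$n), sort(b$n))
  expect_equal(sort(round(a$x + a$y + a$z, 9)),
               sort(round(b$x + b$y + b$z, 9)))
})

test_that("DBSCAN labels agree with the density-reachability closure", {
  set.seed(14)
  for (rep in 1:60) {
    n <- sample(3:20, 1)
    x <- matrix(runif(3 * n, 0, 40), ncol = 3)
    minPts <- sample(1:4, 1)
    strict <- rep %% 2 == 0
    lab <- dbscanLabels(x, dEps = 10, minPts = minPts, strict = strict)
    ref <- bruteReach(x, dEps = 10, minPts = minPts, strict = strict)
    # cores must partition identically
    for (cl in unique(ref$coreLabels[ref$coreLabels > 0])) {
      mem <- which(ref$coreLabels == cl)
      expect_equal(length(unique(lab[mem])), 1)
      expect_true(all(lab[mem] > 0))
    }
    # border points must sit in a cluster of one of their reaching cores
    for (q in seq_len(n)) {
      if (ref$core[q]) next
      if (length(ref$borderOf[[q]])) {
        cores <- which(ref$coreLabels %in% ref$borderOf[[q]])
        expect_true(lab[q] %in% lab[cores])
      } else {
        expect_equal(lab[q], 0)   # noise
      }
    }
  }
})

test_that("strict core rule demotes coincident pairs to noise", {
  x <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(dbscanLabels(x, 10, 2, strict = FALSE), c(1, 1))
  expect_equal(dbscanLabels(x, 10, 2, strict = TRUE), c(0, 0))
})

test_that("loop classification uses unsigned winding around cavity axes", {
  grid <- buildGrid(2, layers = 1)
  el <- grid@electrodes
  # small triangle in the LV free wall: winding 0 -> localized
  lv <- el[el$wall == "LV" & el$terminal >= 1, ]
  tri <- list(electrodes = lv$id[1:3])
  expect_equal(classifyLoop(tri, grid), "localized")
  # ring of LV+septum tips encircling the LV axis -> holo_LV, both ways
  mr <- genMacroReentry(grid, "LV")
  ring <- list(electrodes = mr$truth$path)
  expect_equal(classifyLoop(ring, grid), "holo_LV")
  ringRev <- list(electrodes = rev(mr$truth$path))
  expect_equal(classifyLoop(ringRev, grid), "holo_LV")
  # outer ring around both cavities -> biventricular
  mb <- genMacroReentry(grid, "both")
  expect_equal(classifyLoop(list(electrodes = mb$truth$path), grid),
               "biventricular")
})

test_that("temporal tracking links stationary clusters and splits distant ones", {
  mkFrame <- function(centers) {
    do.call(rbind, lapply(seq_along(centers), function(i)
      data.frame(reentry = i, n = 1, x = centers[[i]][1],
                 y = centers[[i]][2], z = centers[[i]][3],
                 class = "localized")))
  }
  times <- seq(0, 450, by = 50)
  one <- lapply(times, function(t) mkFrame(list(c(10, 10, 10))))
  tr1 <- trackReentries(one, times, linkingRadius = 10)
  expect_equal(nrow(tr1), 1)
  expect_equal(tr1$start, 0)
  expect_equal(tr1$end, 500)   # last frame + step

  two <- lapply(times, function(t)
    mkFrame(list(c(0, 0, 0), c(40, 0, 0))))
  tr2 <- trackReentries(two, times, linkingRadius = 10)
  expect_equal(nrow(tr2), 2)
  expect_true(all(tr2$nFrames == length(times)))
})

test_that("frame sequences reproduce printed reentry intervals", {
  # three reentries: [1000,2400], [1300,1450], [1800,2100] at 50 ms frames
  step <- 50
  times <- seq(1000, 2400 - step, by = step)
  mk <- function(t) {
    ctrs <- list()
    ctrs[[length(ctrs) + 1]] <- c(0, 0, 0)
    if (t >= 1300 && t < 1450) ctrs[[length(ctrs) + 1]] <- c(40, 0, 0)
    if (t >= 1800 && t < 2100) ctrs[[length(ctrs) + 1]] <- c(0, 40, 0)
    do.call(rbind, lapply(seq_along(ctrs), function(i)
      data.frame(reentry = i, n = 1, x = ctrs[[i]][1], y = ctrs[[i]][2],
                 z = ctrs[[i]][3], class = "localized")))
  }
  frames <- lapply(times, mk)
  tracks <- trackReentries(frames, times, linkingRadius = 10)
  expect_equal(nrow(tracks), 3)
  expect_equal(sort(tracks$start), c(1000, 1300, 1800))
  expect_equal(sort(tracks$end), c(1450, 2100, 2400))
  prof <- simultaneousProfile(tracks)
  expect_equal(prof$max, 2)
  expect_equal(unname(round(prof$fractions["1"], 1)), 67.9)
  expect_equal(unname(round(prof$fractions["2"], 1)), 32.1)
})

test_that("simultaneous profile fractions always sum to 100", {
  one <- data.frame(start = 0, end = 1000, class = "localized")
  p1 <- simultaneousProfile(one)
  expect_equal(unname(p1$fractions["1"]), 100)
  expect_equal(p1$mean, 1)
  expect_equal(p1$holoFraction, 0)

  set.seed(4)
  for (rep in 1:25) {
    k <- sample(1:6, 1)
    st <- runif(k, 0, 900)
    tracks <- data.frame(start = st, end = st + runif(k, 20, 600),
                         class = sample(c("localized", "holo_LV"), k,
                                        replace = TRUE))
    prof <- simultaneousProfile(tracks)
    expect_equal(sum(prof$fractions), 100, tolerance = 1e-9)
    expect_gte(prof$holoFraction, 0)
    expect_lte(prof$holoFraction, 100)
    expect_gte(prof$mean, 1)
  }
  empty <- simultaneousProfile(NULL)
  expect_equal(empty$mean, 0)
  expect_true(is.na(empty$holoFraction))
})
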