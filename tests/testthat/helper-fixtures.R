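# Shared fixtures and independent oracles.

# minimal grid from explicit positions: one electrode per needle, so the
# collinearity validity check is vacuous and arbitrary geometries can be
# used in unit tests
tinyGrid <- function(pos, wall = NULL) {
  n <- nrow(pos)
  if (is.null(wall)) wall <- rep("LV", n)
  el <- data.frame(id = seq_len(n), needle = seq_len(n), layer = 0L,
                   terminal = 0L, x = pos[, 1], y = pos[, 2],
                   z = pos[, 3], wall = wall, usable = TRUE)
  ctr <- colMeans(pos)
  ax <- list(point = ctr, dir = c(0, 0, 1))
  new("ElectrodeGrid", electrodes = el, configId = 1L,
      layerSpacing = 12, terminalSpacing = 4,
      cavities = list(LV = ax, RV = ax, both = ax))
}

# wrap an edge table into a MergedGraph for cycle-enumeration tests
edgesToMerged <- function(edges) {
  verts <- sort(unique(c(edges$src, edges$dst)))
  nodes <- data.frame(electrode = verts, lat1 = NA_real_,
                      lat2 = NA_real_)
  e <- data.frame(src = edges$src, dst = edges$dst,
                  dist = 1, dlat = 1, cv = 1)
  e <- e[!duplicated(e[, c("src", "dst")]), ]
  new("MergedGraph", buildTimes = c(0, 1), nodes = nodes, edges = e)
}

# independent elementary-cycle oracle: enumerate all simple paths from
# every start vertex, canonicalize by rotating the smallest vertex first
bruteCycles <- function(edges, maxLen = 20L) {
  verts <- sort(unique(c(edges$src, edges$dst)))
  adj <- lapply(verts, function(v) edges$dst[edges$src == v])
  names(adj) <- verts
  found <- new.env()
  walk <- function(path) {
    v <- path[length(path)]
    for (w in adj[[as.character(v)]]) {
      if (w == path[1] && length(path) >= 3L) {
        i0 <- which.min(path)
        canon <- c(path[i0:length(path)], path[seq_len(i0 - 1L)])
        assign(paste(canon, collapse = "-"), canon, envir = found)
      } else if (!(w %in% path) && length(path) < maxLen) {
        walk(c(path, w))
      }
    }
  }
  for (v in verts) walk(v)
  out <- as.list(found)
  if (!length(out)) return(stats::setNames(list(), character(0)))
  out[order(names(out))]
}

# one-sided exact p oracle: distribution of the observed-direction U over
# all assignments of the pooled values
bruteOneSidedP <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  vals <- c(a, b)
  u <- bruteU(a, b)
  pick <- combn(n1 + n2, n1)
  u1s <- apply(pick, 2, function(ix) bruteU(vals[ix], vals[-ix])["u1"])
  if (u["u1"] <= u["u2"]) mean(u1s <= u["u1"] + 1e-9)
  else mean((n1 * n2 - u1s) <= u["u2"] + 1e-9)
}

# independent density-reachability oracle following the textbook
# definitions literally; returns list(coreClusters, borderOf, noise)
bruteReach <- function(x, dEps, minPts, strict = FALSE) {
  n <- nrow(x)
  D <- as.matrix(dist(x))
  nbr <- lapply(seq_len(n), function(i) which(D[i, ] <= dEps))
  core <- if (strict) lengths(nbr) > minPts else lengths(nbr) >= minPts
  # density-reachability closure among cores: transitive closure of
  # "core p directly reaches core q" (q in N(p))
  reach <- matrix(FALSE, n, n)
  for (p in which(core)) reach[p, nbr[[p]]] <- TRUE
  repeat {
    nxt <- reach | (reach[, core, drop = FALSE] %*%
                    reach[core, , drop = FALSE] > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  coreIdx <- which(core)
  # partition cores: p,q in same cluster iff mutually density-reachable
  lbl <- integer(n); cl <- 0L
  for (p in coreIdx) {
    if (lbl[p]) next
    cl <- cl + 1L
    mates <- coreIdx[reach[p, coreIdx] | coreIdx == p]
    lbl[mates] <- cl
  }
  borderOf <- lapply(seq_len(n), function(q) {
    if (core[q]) return(integer(0))
    unique(lbl[coreIdx[vapply(coreIdx, function(p) q %in% nbr[[p]],
                              logical(1))]])
  })
  noise <- which(!core & lengths(borderOf) == 0L)
  list(core = core, coreLabels = lbl, borderOf = borderOf, noise = noise)
}

# independent U statistic: pair counting with half credit for ties
bruteU <- function(a, b) {
  u1 <- sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
  c(u1 = u1, u2 = length(a) * length(b) - u1)
}

# Table of per-episode average simultaneous loop counts (NT then ST)
ntLoops <- c(2.21, 3.00, 2.61, 1.45, 2.02, 3.29, 3.14, 2.94, 3.80)
stLoops <- c(1.29, 1.19, 1.83, 1.00)

# wall-electrode focal origin in the standard grid (mid-wall, mid-layer)
wallOrigin <- function(grid) {
  el <- grid@electrodes
  lay <- sort(unique(el$layer))
  midLayer <- lay[ceiling(length(lay) / 2)]
  oe <- el[el$wall == "LV" & el$layer == midLayer & el$terminal == 2L, ][1, ]
  list(id = oe$id, pos = c(oe$x, oe$y, oe$z))
}
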