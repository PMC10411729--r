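## Episode labelling, group summaries, exact Mann-Whitney comparison.

#' Summarize one tachycardia episode
#'
#' Combines the reentry tracks and verified focal sources of one episode
#' into the per-episode record used for group comparisons.  Episodes
#' lasting `ntThreshold` seconds or more are labelled non-terminating
#' ("NT", the recording was stopped by defibrillation); shorter ones
#' self-terminating ("ST").
#'
#' @param tracks data.frame from [trackReentries()] (may be empty).
#' @param sources data.frame of focal sources with a `status` column;
#'   confirmed ones are counted.
#' @param duration episode duration in seconds.
#' @param episode episode identifier.
#' @param ntThreshold seconds (default 10).
#' @return data.frame with one row: episode, label, duration_s,
#'   n_reentries, mean_loops, max_loops, holo_pct, n_focal.
#' @export
summarizeEpisode <- function(tracks, sources, duration, episode = 1L,
                             ntThreshold = 10) {
  prof <- simultaneousProfile(tracks)
  confirmed <- if (nrow(sources))
    sum(grepl("confirmed", sources$status)) else 0L
  data.frame(
    episode = episode,
    label = if (duration >= ntThreshold) "NT" else "ST",
    duration_s = duration,
    n_reentries = prof$nTracks,
    mean_loops = prof$mean,
    max_loops = prof$max,
    holo_pct = prof$holoFraction,
    n_focal = confirmed)
}

#' Arithmetic mean of per-episode values
#'
#' @param values non-empty numeric vector.
#' @return the mean.
#' @export
groupMean <- function(values) {
  if (!length(values)) stop("empty input")
  mean(values)
}

## U statistic with 0.5 credit for ties, computed from pooled ranks
uStatistic <- function(a, b) {
  r <- rank(c(a, b))
  n1 <- length(a); n2 <- length(b)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  c(u1 = u1, u2 = u2)
}

#' Exact Mann-Whitney U test by full enumeration
#'
#' Computes U = min(U1, U2) with 0.5 credit for ties, and exact one- and
#' two-sided p-values from the full permutation distribution: every
#' choose(n1+n2, n1) assignment of the pooled values to the two groups.
#' The one-sided p is P(U* <= U_obs) for the observed direction; the
#' two-sided p doubles it (capped at 1).  Beyond `maxEnumeration`
#' assignments the normal approximation with tie correction is used.
#'
#' @param a,b numeric group values (non-empty).
#' @param maxEnumeration largest enumeration size attempted
#'   (default 1e6 assignments).
#' @return list: `U`, `U1`, `U2`, `p_one_sided`, `p_two_sided`, `n1`,
#'   `n2`, `exact` (logical).
#' @export
mannWhitneyExact <- function(a, b, maxEnumeration = 1e6) {
  if (!length(a) || !length(b)) stop("empty group")
  n1 <- length(a); n2 <- length(b)
  u <- uStatistic(a, b)
  U <- min(u)
  if (choose(n1 + n2, n1) <= maxEnumeration) {
    pool <- c(a, b)
    r <- rank(pool)
    sets <- utils::combn(n1 + n2, n1)
    u1s <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    # distribution of U for the group-a side; take the side achieving U
    us <- if (u["u1"] <= u["u2"]) u1s else n1 * n2 - u1s
    pOne <- mean(us <= U + 1e-9)
    pTwo <- min(1, mean(us <= U + 1e-9) +
                   mean(us >= n1 * n2 - U - 1e-9))
    exact <- TRUE
  } else {
    mu <- n1 * n2 / 2
    ties <- table(c(a, b))
    n <- n1 + n2
    sig <- sqrt(n1 * n2 / 12 *
                ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
    z <- (U - mu) / sig
    pOne <- stats::pnorm(z)
    pTwo <- min(1, 2 * pOne)
    exact <- FALSE
  }
  list(U = unname(U), U1 = unname(u["u1"]), U2 = unname(u["u2"]),
       p_one_sided = pOne, p_two_sided = pTwo,
       n1 = n1, n2 = n2, exact = exact)
}
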