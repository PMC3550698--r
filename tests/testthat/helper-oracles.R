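# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the code paths they check.

# --- geometric fixtures -----------------------------------------------------

# A stack of identical annulus slices: wall at radius `r_mid` (voxel units),
# width `w`, count `c_wall`; optional sector at reduced uptake.
annulus_volume <- function(n_slices = 8, n = 41, r_mid = 12, w = 3,
                           c_wall = 1000, sector = NULL,
                           voxel = c(8, 2, 2), tracer = "TL_STRESS") {
  ctr <- (n + 1) / 2
  sl <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    rho <- sqrt((i - ctr)^2 + (j - ctr)^2)
    if (abs(rho - r_mid) <= w / 2) {
      v <- c_wall
      if (!is.null(sector)) {
        # angle from anterior (up), counterclockwise from apex view
        a <- (atan2(-(i - ctr), j - ctr) * 180 / pi - 90) %% 360
        d <- abs((a - sector$center) %% 360)
        if (min(d, 360 - d) <= sector$width / 2) v <- c_wall * sector$frac
      }
      sl[i, j] <- v
    }
  }
  counts <- array(0, c(n_slices, n, n))
  for (s in seq_len(n_slices)) counts[s, , ] <- sl
  short_axis_volume(counts, voxel_size_mm = voxel, tracer = tracer)
}

# Brute-force circumferential profile: dense angular sub-sampling around each
# bin centre direction is not needed (one ray per bin is the contract), but
# the radius marching is done independently, on a 10x finer step, directly in
# voxel coordinates with its own bilinear interpolation.
oracle_profile <- function(slice, center_rc, n_angles, dy = 1, dx = 1) {
  interp <- function(m, r, c) {
    nr <- nrow(m); nc <- ncol(m)
    if (r < 1 || r > nr || c < 1 || c > nc) return(0)
    r0 <- min(floor(r), nr - 1); c0 <- min(floor(c), nc - 1)
    fr <- r - r0; fc <- c - c0
    m[r0, c0] * (1 - fr) * (1 - fc) + m[r0 + 1, c0] * fr * (1 - fc) +
      m[r0, c0 + 1] * (1 - fr) * fc + m[r0 + 1, c0 + 1] * fr * fc
  }
  vapply(seq_len(n_angles), function(j) {
    phi <- pi / 2 + (j - 1) * 2 * pi / n_angles
    ts <- seq(0, sqrt((nrow(slice) * dy)^2 + (ncol(slice) * dx)^2),
              by = min(dy, dx) / 20)
    best <- 0
    for (t in ts) {
      v <- interp(slice, center_rc[1] - t * sin(phi) / dy,
                  center_rc[2] + t * cos(phi) / dx)
      if (v > best) best <- v
    }
    best
  }, numeric(1))
}

# --- survival oracles -------------------------------------------------------

# Product-limit estimator computed directly from risk sets.
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events]))
  s <- 1
  data.frame(time = ut, surv = vapply(ut, function(t) {
    d <- sum(times == t & events)
    r <- sum(times >= t)
    s <<- s * (1 - d / r)
    s
  }, numeric(1)))
}

# Two-group log-rank: observed-minus-expected summed over event times.
oracle_logrank <- function(t1, e1, t2, e2) {
  times <- c(t1, t2); events <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  ut <- sort(unique(times[events]))
  o_minus_e <- 0; v <- 0
  for (t in ut) {
    n <- sum(times >= t); n1 <- sum(times >= t & grp == 1)
    d <- sum(times == t & events)
    d1 <- sum(times == t & events & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(chisq = o_minus_e^2 / v)
}

# AUC by exhaustive pair counting, ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Pearson chi-square for a 2x2 table, closed form.
oracle_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# --- cohort fixture ---------------------------------------------------------

# minimal schema-valid cohort with prescribed flag/event cell counts:
# rows ordered TP, FN, FP, TN; `flag` is the matching abnormality vector
counts_cohort <- function(tp, fp, fn, tn, hard_tp = 0, hard_fn = 0) {
  n <- tp + fp + fn + tn
  ev <- c(rep("soft", tp + fn), rep("none", fp + tn))
  if (hard_tp > 0) ev[seq_len(hard_tp)] <- "hard"
  if (hard_fn > 0) ev[tp + seq_len(hard_fn)] <- "hard"
  flag <- c(rep(TRUE, tp), rep(FALSE, fn), rep(TRUE, fp), rep(FALSE, tn))
  list(cohort = data.frame(
    id = sprintf("P%d", seq_len(n)), age = 65, sex = "male", dm = 0,
    lvef = 65, htn = 0, dyslipidemia = 0, smoking = 0, uap = 0, ace = 0,
    bb = 0, ccb = 0, sss = 0, srs = 0, sds = 0, sbs = 0,
    followup_days = 1000, event = ev), flag = flag)
}
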