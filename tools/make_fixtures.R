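# Build fixture cohorts under inst/extdata/.
# Each cohort is constructed segment-by-segment so that its cumulative
# margins (N, N_pos, TP, TN) match the worked-example per-stage checkpoints, and
# milestone positives land exactly at the recorded N (so participant-level
# interim cuts reproduce the recorded group sizes).

# segment of dn participants: dpos positives (dtp with index=1),
# dn-dpos negatives (dtn with index=0); positives spread evenly;
# end_pos forces the last participant of the segment to be a positive.
segment <- function(dn, dpos, dtp, dtn, end_pos = FALSE) {
  dneg <- dn - dpos
  stopifnot(dpos >= 0, dneg >= 0, dtp <= dpos, dtn <= dneg)
  ref <- integer(dn)
  if (dpos > 0) {
    pos_idx <- unique(round(seq_len(dpos) * dn / dpos))
    stopifnot(length(pos_idx) == dpos)
    if (end_pos) pos_idx[dpos] <- dn
    ref[pos_idx] <- 1L
  }
  idx <- integer(dn)
  # distribute successes evenly within each group
  p <- which(ref == 1L); n_ <- which(ref == 0L)
  if (dtp > 0) idx[p[unique(round(seq_len(dtp) * dpos / dtp))]] <- 1L
  stopifnot(sum(idx[p]) == dtp)
  fp <- dneg - dtn
  if (fp > 0) idx[n_[unique(round(seq_len(fp) * dneg / fp))]] <- 1L
  stopifnot(sum(1L - idx[n_]) == dtn)
  data.frame(reference = ref, index = idx)
}

# checkpoints: matrix with rows (N, pos, TP, TN); end_pos flags per row
build_cohort <- function(ck, end_pos) {
  prev <- c(0, 0, 0, 0)
  segs <- list()
  for (i in seq_len(nrow(ck))) {
    d <- ck[i, ] - prev
    dneg <- d[1] - d[2]
    segs[[i]] <- segment(d[1], d[2], d[3], d[4], end_pos = end_pos[i])
    prev <- ck[i, ]
  }
  out <- do.call(rbind, segs)
  out <- cbind(order = seq_len(nrow(out)), out)
  # verify all checkpoints
  cp <- cumsum(out$reference)
  ctp <- cumsum(out$reference * out$index)
  ctn <- cumsum((1 - out$reference) * (1 - out$index))
  for (i in seq_len(nrow(ck))) {
    N <- ck[i, 1]
    stopifnot(cp[N] == ck[i, 2], ctp[N] == ck[i, 3], ctn[N] == ck[i, 4])
    if (end_pos[i]) stopifnot(out$reference[N] == 1)
  }
  out
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

## Simulated dataset 1
ck1 <- rbind(c(25, 8, 6, 13),     # N=25:  sens 6/8,   spec 13/17
             c(46, 15, 10, 25),   # 15th positive at N=46: 10/15, 25/31
             c(63, 25, 15, 32),   # 25th positive at N=63: 15/25, 32/38
             c(75, 29, 18, 38),   # N=75:  18/29, 38/46
             c(128, 50, 28, 64),  # 50th positive at N=128: 28/50, 64/78
             c(150, 58, 34, 77),  # N=150: 34/58, 77/92
             c(200, 76, 45, 104)) # tail: continue at ~35% prevalence
d1 <- build_cohort(ck1, end_pos = c(FALSE, TRUE, TRUE, FALSE, TRUE,
                                    FALSE, FALSE))
write.csv(d1, "inst/extdata/sim_cohort1.csv", row.names = FALSE,
          quote = FALSE)

## Simulated dataset 2
ck2 <- rbind(c(23, 15, 11, 7),    # 15th positive at N=23: 11/15, 7/8
             c(25, 16, 12, 8),    # N=25: 12/16, 8/9
             c(41, 25, 18, 14),   # 25th positive at N=41: 18/25, 14/16
             c(75, 44, 32, 26),   # N=75: 32/44, 26/31
             c(94, 50, 35, 36),   # 50th positive at N=94: 35/50, 36/44
             c(150, 72, 48, 64),  # N=150: 48/72, 64/78
             c(200, 89, 59, 92))
d2 <- build_cohort(ck2, end_pos = c(TRUE, FALSE, TRUE, FALSE, TRUE,
                                    FALSE, FALSE))
write.csv(d2, "inst/extdata/sim_cohort2.csv", row.names = FALSE,
          quote = FALSE)

## RAPTOR-C19 synthetic reconstructions (negative groups solved from the
## recorded specificity estimates and boundaries).
## Batched (daily) accrual: the day column is constructed so that the
## first day-end at/after 50, 100 and 150 positives carries the recorded
## overshoot counts.
add_days <- function(cohort, milestones, checkpointN, chunk = 12L) {
  cp <- cumsum(cohort$reference)
  n <- nrow(cohort)
  breaks <- integer(0)
  seg_start <- 1L
  for (k in seq_along(milestones)) {
    q <- which(cp == milestones[k] - 1L)       # last index before crossing
    q <- q[length(q)]
    stopifnot(length(q) == 1L, q >= seg_start, q < checkpointN[k])
    reg <- seq(seg_start + chunk - 1L, q, by = chunk)
    breaks <- c(breaks, reg[reg < q], q, checkpointN[k])
    seg_start <- checkpointN[k] + 1L
  }
  if (seg_start <= n)
    breaks <- c(breaks, seq(seg_start + chunk - 1L, n - 1L, by = chunk), n)
  breaks <- sort(unique(breaks))
  stopifnot(breaks[length(breaks)] == n)
  day <- rep(seq_along(breaks), times = diff(c(0L, breaks)))
  # verify: first day-end with >= milestone positives is the checkpoint
  ends <- breaks
  for (k in seq_along(milestones)) {
    hit <- ends[which(cp[ends] >= milestones[k])[1]]
    stopifnot(hit == checkpointN[k])
  }
  cbind(cohort, day = day)
}

## BD Veritor: interim positives 52 (TP 38), 103 (TP 80), final 150 (TP 118)
## negatives 116 (TN 114), 180 (TN 177), 230 (TN 227)
ck_bd <- rbind(c(168, 52, 38, 114),
               c(283, 103, 80, 177),
               c(380, 150, 118, 227))
bd <- build_cohort(ck_bd, end_pos = c(TRUE, TRUE, TRUE))
bd <- add_days(bd, milestones = c(50, 100, 150),
               checkpointN = c(168, 283, 380))
write.csv(bd, "inst/extdata/raptor_bd_veritor_synthetic.csv",
          row.names = FALSE, quote = FALSE)

## SD Biosensor: positives 53 (TP 47), 103 (TP 85), final 150 (TP 124)
## negatives 83 (TN 81), 170 (TN 166), 262 (TN 258)
ck_sd <- rbind(c(136, 53, 47, 81),
               c(273, 103, 85, 166),
               c(412, 150, 124, 258))
sd <- build_cohort(ck_sd, end_pos = c(TRUE, TRUE, TRUE))
sd <- add_days(sd, milestones = c(50, 100, 150),
               checkpointN = c(136, 273, 412))
write.csv(sd, "inst/extdata/raptor_sd_biosensor_synthetic.csv",
          row.names = FALSE, quote = FALSE)

cat("fixtures written\n")
for (f in list.files("inst/extdata", full.names = TRUE))
  cat(sprintf("  %-50s %6d bytes\n", f, file.size(f)))
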