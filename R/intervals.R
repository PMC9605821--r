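# Interval algebra on half-open-in-spirit [start, end] pairs held as
# data.frames with POSIXct `start`/`end` columns. Touching intervals
# (end == next start) count as overlapping throughout: merging them avoids
# zero-gap episode fragmentation downstream.

empty_intervals <- function() {
  data.frame(
    start = num_to_instant(numeric(0)),
    end = num_to_instant(numeric(0))
  )
}

as_intervals <- function(start, end) {
  data.frame(start = num_to_instant(as.numeric(start)), end = num_to_instant(as.numeric(end)))
}

#' Union of intervals
#'
#' Replaces overlapping or touching intervals by their union; output is
#' sorted by start and pairwise disjoint.
#'
#' @param iv data.frame with `start` and `end` (`POSIXct`).
#' @return data.frame with the same columns.
#' @keywords internal
interval_union <- function(iv) {
  interval_gap_merge(iv, gap = 0)
}

# Merge intervals whose inter-interval gap is strictly below `gap` seconds.
# gap = 0 merges exactly the overlapping-or-touching pairs.
interval_gap_merge <- function(iv, gap) {
  if (nrow(iv) == 0) return(empty_intervals())
  s <- as.numeric(iv$start)
  e <- as.numeric(iv$end)
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  out_s <- s[1]; out_e <- e[1]
  for (i in seq_along(s)[-1]) {
    cur <- length(out_s)
    if (s[i] - out_e[cur] <= gap) {
      out_e[cur] <- max(out_e[cur], e[i])
    } else {
      out_s <- c(out_s, s[i])
      out_e <- c(out_e, e[i])
    }
  }
  as_intervals(out_s, out_e)
}

# Set difference a \ b; partial overlaps truncate rather than delete.
# Degenerate (zero-length) remainders are dropped.
interval_subtract <- function(a, b) {
  if (nrow(a) == 0) return(empty_intervals())
  b <- interval_union(b)
  if (nrow(b) == 0) return(a[order(a$start), , drop = FALSE])
  bs <- as.numeric(b$start); be <- as.numeric(b$end)
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    segs_s <- as.numeric(a$start[i])
    segs_e <- as.numeric(a$end[i])
    for (j in seq_along(bs)) {
      new_s <- numeric(0); new_e <- numeric(0)
      for (k in seq_along(segs_s)) {
        s <- segs_s[k]; e <- segs_e[k]
        if (be[j] <= s || bs[j] >= e) {
          new_s <- c(new_s, s); new_e <- c(new_e, e)
        } else {
          if (bs[j] > s) { new_s <- c(new_s, s); new_e <- c(new_e, bs[j]) }
          if (be[j] < e) { new_s <- c(new_s, be[j]); new_e <- c(new_e, e) }
        }
      }
      segs_s <- new_s; segs_e <- new_e
      if (length(segs_s) == 0) break
    }
    out_s <- c(out_s, segs_s); out_e <- c(out_e, segs_e)
  }
  keep <- out_e > out_s
  iv <- as_intervals(out_s[keep], out_e[keep])
  iv[order(iv$start), , drop = FALSE]
}

# Total time (seconds) in the pairwise intersection of two interval sets.
interval_intersect_secs <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(as.numeric(a$start[i]), as.numeric(b$start))
    hi <- pmin(as.numeric(a$end[i]), as.numeric(b$end))
    tot <- tot + sum(pmax(0, hi - lo))
  }
  tot
}

interval_total_secs <- function(iv) {
  sum(as.numeric(iv$end) - as.numeric(iv$start))
}
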