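# Sliding-window bookkeeping shared by the pi, FST and Hp scans.
#
# Windows are half-open intervals [start, start + window) in bp with 1-based
# starts at multiples of the step: start_j = 1 + j*step, j = 0, 1, ...
# A SNP at position pos therefore belongs to every window index j with
#   floor((pos-1-window)/step) < j <= floor((pos-1)/step), j >= 0.

# long (site, win) assignment table for one chromosome's positions
window_assignments <- function(pos, window, step) {
  stopifnot(window > 0, step > 0)
  k_max <- ceiling(window / step)
  jmax <- (pos - 1) %/% step
  out_site <- integer(0)
  out_win <- integer(0)
  for (o in seq_len(k_max) - 1L) {
    j <- jmax - o
    keep <- j >= 0 & (j * step) > (pos - 1 - window)
    out_site <- c(out_site, which(keep))
    out_win <- c(out_win, j[keep])
  }
  tibble::tibble(site = out_site, win = as.integer(out_win))
}

# full step-aligned grid from the first window containing the first SNP to
# the last window starting at or before the last SNP
window_grid_range <- function(pos, window, step) {
  j_first <- max(0, (min(pos) - 1 - window) %/% step + 1)
  j_last <- (max(pos) - 1) %/% step
  as.integer(j_first:j_last)
}

window_bounds <- function(win, window, step) {
  start <- 1 + as.numeric(win) * step
  tibble::tibble(start = start, end = start + window)
}

# per-window sums of per-site columns in `values` (a named list of numeric
# vectors over sites of one chromosome); returns one row per window that
# contains >= 1 SNP
window_sums <- function(pos, values, window, step) {
  asg <- window_assignments(pos, window, step)
  sums <- lapply(values, function(v) {
    as.numeric(rowsum(v[asg$site], asg$win, reorder = TRUE))
  })
  win <- sort(unique(asg$win))
  out <- tibble::tibble(win = win, n_snps = as.integer(table(asg$win)))
  for (nm in names(sums)) out[[nm]] <- sums[[nm]]
  out
}
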