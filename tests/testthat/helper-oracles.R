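# Independent oracles and tiny fixture builders used across the suite.

# Brute-force grayscale opening: erosion then dilation with a flat centred
# window, truncated at the ends. Direct nested min/max scans.
bruteOpening <- function(x, window) {
  n <- length(x)
  h <- (window - 1) / 2
  win <- function(i) max(1, i - h):min(n, i + h)
  eroded <- vapply(seq_len(n), function(i) min(x[win(i)]), numeric(1))
  vapply(seq_len(n), function(i) max(eroded[win(i)]), numeric(1))
}

# A dataset from a bare peak table; spots get default coordinates on one row.
makeTestDataset <- function(peaks, regions, mzRange = c(800, 4500)) {
  ids <- names(regions)
  spots <- data.frame(spot_id = ids, x = seq_along(ids) - 1L, y = 0L,
                      region = unname(regions), stringsAsFactors = FALSE)
  MsiDataset(spots, peaks, mzRange)
}

# One-peak-per-spot dataset on a 2-row grid: `hits` names the spots that
# carry a peak at `mz`.
presenceDataset <- function(nTreated, nControl, hitsTreated, hitsControl,
                            mz = 1500, extra = NULL) {
  ids <- c(sprintf("t%02d", seq_len(nTreated)), sprintf("c%02d", seq_len(nControl)))
  spots <- data.frame(spot_id = ids,
                      x = c(seq_len(nTreated) - 1L, seq_len(nControl) - 1L),
                      y = rep(0:1, c(nTreated, nControl)),
                      region = rep(c("treated", "control"), c(nTreated, nControl)),
                      stringsAsFactors = FALSE)
  hit <- c(sprintf("t%02d", hitsTreated), sprintf("c%02d", hitsControl))
  peaks <- data.frame(spot_id = hit, mz = rep(mz, length(hit)),
                      intensity = rep(10, length(hit)), snr = rep(5, length(hit)))
  if (!is.null(extra)) peaks <- rbind(peaks, extra)
  MsiDataset(spots, peaks, c(800, 4500))
}
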