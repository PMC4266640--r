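# Quality filtering with Trimmomatic-equivalent semantics:
# LEADING/TRAILING hard quality cutoffs, 5'->3' sliding-window mean-quality
# truncation, a minimum-length fraction of the original read length, and
# discarding of reads containing ambiguous bases.

#' Quality-filter parameters
#'
#' Defaults correspond to `LEADING:3 TRAILING:3 SLIDINGWINDOW:4:15` and a
#' minimum surviving length of 3/4 of the original read length (applied with
#' floor rounding, e.g. 112 for 150 bp reads, 187 for 250 bp, 225 for 300 bp).
#'
#' @param lead_q minimum quality kept at the 5' end.
#' @param trail_q minimum quality kept at the 3' end.
#' @param window sliding window size in bases.
#' @param window_meanq minimum mean quality of a window.
#' @param minlen_frac minimum surviving length as a fraction of
#'   `original_length`.
#' @param original_length the as-sequenced read length (per run); used to
#'   derive the MINLEN cutoff.
#' @return a list of class `qc_params`.
#' @export
qc_params <- function(lead_q = 3L, trail_q = 3L, window = 4L,
                      window_meanq = 15, minlen_frac = 3 / 4,
                      original_length = 250L) {
  if (original_length <= 0) stop("original_length must be positive")
  stopifnot(lead_q > 0, trail_q > 0, window > 0, window_meanq > 0,
            minlen_frac > 0, minlen_frac <= 1)
  structure(list(lead_q = as.integer(lead_q), trail_q = as.integer(trail_q),
                 window = as.integer(window), window_meanq = window_meanq,
                 minlen_frac = minlen_frac,
                 original_length = as.integer(original_length)),
            class = "qc_params")
}

#' Derive the minimum-length cutoff from the original read length
#'
#' `floor(minlen_frac * original_length)`; floor is the only rounding
#' consistent with the canonical worked values (112/150, 187/250, 225/300).
#'
#' @param original_length as-sequenced read length.
#' @param minlen_frac fraction of the original length required to survive.
#' @return integer minimum length.
#' @export
min_length_cutoff <- function(original_length, minlen_frac = 3 / 4) {
  if (any(original_length <= 0)) stop("original_length must be positive")
  as.integer(floor(minlen_frac * original_length))
}

# indices kept after LEADING/TRAILING on one quality vector
trim_ends_range <- function(q, lead_q, trail_q) {
  keep_head <- which(q >= lead_q)
  if (!length(keep_head)) return(integer())
  from <- keep_head[1]
  to <- max(which(q >= trail_q))
  if (to < from) return(integer())
  from:to
}

#' Trim low-quality read ends
#'
#' Removes the maximal prefix of bases with quality below `lead_q`, then the
#' maximal suffix with quality below `trail_q`. May return an empty read.
#'
#' @param seq sequence string.
#' @param qual integer Phred quality vector (same length as `seq`).
#' @param lead_q,trail_q quality cutoffs.
#' @return list with elements `seq` and `qual`.
#' @export
trim_ends <- function(seq, qual, lead_q = 3L, trail_q = 3L) {
  stopifnot(nchar(seq) == length(qual))
  idx <- trim_ends_range(qual, lead_q, trail_q)
  if (!length(idx)) return(list(seq = "", qual = integer()))
  list(seq = substr(seq, idx[1], idx[length(idx)]), qual = qual[idx])
}

# kept length under the 5'->3' sliding-window rule
sliding_window_keep <- function(q, window, meanq) {
  n <- length(q)
  if (n == 0L) return(0L)
  if (n < window) return(if (mean(q) >= meanq) n else 0L)
  cs <- c(0, cumsum(q))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  fail <- which(means < meanq)
  if (!length(fail)) n else fail[1] - 1L
}

#' Sliding-window quality truncation
#'
#' Scans windows of `window` bases starting at every position from the 5'
#' end; at the first window whose arithmetic-mean quality drops below
#' `meanq` the read is truncated at that window's start. Reads shorter than
#' one window are kept only if their overall mean quality passes.
#'
#' @inheritParams trim_ends
#' @param window window size in bases.
#' @param meanq minimum mean window quality.
#' @return list with elements `seq` and `qual`.
#' @export
sliding_window_trim <- function(seq, qual, window = 4L, meanq = 15) {
  stopifnot(nchar(seq) == length(qual))
  k <- sliding_window_keep(qual, window, meanq)
  list(seq = substr(seq, 1L, k), qual = qual[seq_len(k)])
}

qc_filter_one <- function(lib, params) {
  n <- length(lib)
  keep <- logical(n)
  seqs <- lib$seq
  quals <- lib$qual
  minlen <- min_length_cutoff(params$original_length, params$minlen_frac)
  for (i in seq_len(n)) {
    t1 <- trim_ends(seqs[i], quals[[i]], params$lead_q, params$trail_q)
    t2 <- sliding_window_trim(t1$seq, t1$qual, params$window,
                              params$window_meanq)
    seqs[i] <- t2$seq
    quals[[i]] <- t2$qual
    keep[i] <- nchar(t2$seq) >= minlen && !grepl("[^ACGT]", t2$seq)
  }
  seq_library(lib$type, lib$id[keep], seqs[keep], lib$sample_id[keep],
              qual = quals[keep])
}

#' Quality-filter a pair of read libraries
#'
#' Applies, per read: end trimming, sliding-window truncation, the
#' minimum-length cutoff (floor of `minlen_frac` times the original length,
#' evaluated against each mate's own original length), and discarding of any
#' read still containing a non-ACGT character. Surviving sets are reported
#' per mate; pairing is enforced downstream by [pair_and_trim()].
#'
#' @param r1,r2 quality-bearing [seq_library()] objects.
#' @param params_r1 a [qc_params()] whose `original_length` matches R1.
#' @param params_r2 same for R2; defaults to `params_r1`.
#' @return list with filtered `r1` and `r2` libraries and a `log` data.frame
#'   of input/surviving counts.
#' @export
quality_filter <- function(r1, r2, params_r1 = qc_params(),
                           params_r2 = params_r1) {
  if (is.null(r1$qual) || is.null(r2$qual))
    stop("quality_filter requires quality-bearing libraries")
  out1 <- qc_filter_one(r1, params_r1)
  out2 <- qc_filter_one(r2, params_r2)
  log <- data.frame(mate = c("R1", "R2"),
                    input = c(length(r1), length(r2)),
                    surviving = c(length(out1), length(out2)))
  list(r1 = out1, r2 = out2, log = log)
}
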