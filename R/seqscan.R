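.AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.check_seq <- function(seq, allow_x = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  ok <- .AA1
  if (allow_x) ok <- c(ok, "X")
  bad <- setdiff(unique(chars), ok)
  if (length(bad)) {
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  }
  chars
}

#' Count basic residues in a sequence
#'
#' @param seq One-letter amino-acid string.
#' @param basic_set Residue letters counted as positively charged
#'   (default K and R; histidine can be added via
#'   `basic_set = c("K", "R", "H")`).
#' @param allow_x Pass through unknown residues written as `X` instead of
#'   erroring.
#' @return Integer count.
#' @examples
#' count_basic("LPFCRRRMKRKLDH")  # 6
#' @export
count_basic <- function(seq, basic_set = c("K", "R"), allow_x = FALSE) {
  chars <- .check_seq(seq, allow_x = allow_x)
  sum(chars %in% toupper(basic_set))
}

#' Find clusters of consecutive basic residues
#'
#' Reports maximal runs of consecutive basic residues of length at least
#' `min_run`, as 1-based inclusive spans in input coordinates. The
#' experimentally characterised Fbw7gamma* NoLS peptide, for instance,
#' carries its six basic residues in two such clusters.
#'
#' @inheritParams count_basic
#' @param min_run Minimum run length to report (default 2).
#' @return A data frame with columns `start`, `end`, `length`.
#' @examples
#' basic_clusters("LPFCRRRMKRKLDH")  # spans (5,7) and (9,11)
#' @export
basic_clusters <- function(seq, min_run = 2L, basic_set = c("K", "R"),
                           allow_x = FALSE) {
  chars <- .check_seq(seq, allow_x = allow_x)
  is_basic <- chars %in% toupper(basic_set)
  if (!length(is_basic) || !any(is_basic)) {
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  }
  r <- rle(is_basic)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Sliding-window scan configuration
#'
#' Parameters of the charge-based NoLS scan: window length 13 with slippage
#' of one residue, score threshold 0.8, and a score that saturates at
#' `s_max = 6` basic residues per window (the basic count of the
#' experimentally confirmed NoLS epitope).
#'
#' @param window Window length in residues (default 13).
#' @param step Window slippage in residues (default 1).
#' @param threshold Score cutoff in (0, 1] above which a window is called
#'   (default 0.8, strict inequality).
#' @param s_max Basic-residue count that saturates the score (default 6).
#' @param basic_set Residue letters counted as positive (default K, R).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(window = 13L, step = 1L, threshold = 0.8,
                        s_max = 6L, basic_set = c("K", "R")) {
  stopifnot(window >= 1L, step >= 1L, threshold > 0, threshold <= 1,
            s_max >= 1L)
  structure(list(window = as.integer(window), step = as.integer(step),
                 threshold = threshold, s_max = as.integer(s_max),
                 basic_set = toupper(basic_set)),
            class = "scan_config")
}

#' Scan a sequence for putative NoLS segments
#'
#' Slides a window along the sequence and scores each window as
#' `min(1, n_basic / s_max)`, a transparent charge-count surrogate for
#' neural-network NoLS predictors. Windows whose score exceeds the
#' threshold are merged (union of overlapping windows) into candidate NoLS
#' segments. Sequences shorter than the window are scored as a single
#' truncated window and flagged.
#'
#' @inheritParams count_basic
#' @param config A [scan_config()].
#' @param id Sequence identifier carried into the profile.
#' @return An object of class `nols_scan`: a list with `profile` (data
#'   frame: `id`, `start`, `end`, `score`), `segments` (data frame:
#'   `start`, `end`, `peak_score`), and `truncated` (logical flag).
#' @examples
#' scan_nols("LPFCRRRMKRKLDH")$segments
#' @export
scan_nols <- function(seq, config = scan_config(), id = "seq",
                      allow_x = FALSE) {
  stopifnot(inherits(config, "scan_config"))
  chars <- .check_seq(seq, allow_x = allow_x)
  L <- length(chars)
  if (L < 1L) stop("empty sequence")
  is_basic <- chars %in% config$basic_set
  truncated <- L < config$window
  if (truncated) {
    starts <- 1L
    ends <- L
    counts <- sum(is_basic)
  } else {
    starts <- seq.int(1L, L - config$window + 1L, by = config$step)
    ends <- starts + config$window - 1L
    cs <- c(0L, cumsum(is_basic))
    counts <- cs[ends + 1L] - cs[starts]
  }
  scores <- pmin(1, counts / config$s_max)
  profile <- data.frame(id = id, start = starts, end = ends, score = scores)
  hit <- scores > config$threshold
  segments <- if (!any(hit)) {
    data.frame(start = integer(), end = integer(), peak_score = numeric())
  } else {
    # merge overlapping (or touching) above-threshold windows
    hs <- starts[hit]; he <- ends[hit]; hp <- scores[hit]
    seg_start <- hs[1L]; seg_end <- he[1L]; seg_peak <- hp[1L]
    out <- list()
    if (length(hs) > 1L) {
      for (i in 2L:length(hs)) {
        if (hs[i] <= seg_end + 1L) {
          seg_end <- max(seg_end, he[i])
          seg_peak <- max(seg_peak, hp[i])
        } else {
          out[[length(out) + 1L]] <- c(seg_start, seg_end, seg_peak)
          seg_start <- hs[i]; seg_end <- he[i]; seg_peak <- hp[i]
        }
      }
    }
    out[[length(out) + 1L]] <- c(seg_start, seg_end, seg_peak)
    m <- do.call(rbind, out)
    data.frame(start = as.integer(m[, 1L]), end = as.integer(m[, 2L]),
               peak_score = m[, 3L])
  }
  structure(list(id = id, profile = profile, segments = segments,
                 truncated = truncated, config = config),
            class = "nols_scan")
}

#' @export
print.nols_scan <- function(x, ...) {
  cat("NoLS scan of '", x$id, "': ", nrow(x$profile), " window(s)",
      if (x$truncated) " [truncated: sequence shorter than window]",
      "\n", sep = "")
  if (nrow(x$segments)) {
    for (i in seq_len(nrow(x$segments))) {
      cat(sprintf("  segment %d-%d (peak score %.2f)\n",
                  x$segments$start[i], x$segments$end[i],
                  x$segments$peak_score[i]))
    }
  } else {
    cat("  no segment above threshold\n")
  }
  invisible(x)
}

#' @export
plot.nols_scan <- function(x, ...) {
  p <- x$profile
  mid <- (p$start + p$end) / 2
  plot(mid, p$score, type = "l", ylim = c(0, 1),
       xlab = "window centre (residue)", ylab = "score", ...)
  graphics::abline(h = x$config$threshold, lty = 2)
  if (nrow(x$segments)) {
    graphics::rect(x$segments$start, 0, x$segments$end, 0.02,
                   col = "grey30", border = NA)
  }
  invisible(x)
}

#' Scan every record of a FASTA file for NoLS segments
#'
#' @param path Path to a (multi-record) amino-acid FASTA file.
#' @param config A [scan_config()].
#' @param allow_x Pass through `X` residues.
#' @return A named list of [scan_nols()] results, one per record.
#' @export
scan_fasta <- function(path, config = scan_config(), allow_x = TRUE) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    scan_nols(as.character(seqs[[i]]), config = config,
              id = names(seqs)[i], allow_x = allow_x)
  })
  names(out) <- names(seqs)
  out
}

#' Write scan outputs to disk
#'
#' `write_scan_profile()` writes the per-window profile as CSV
#' (`id,start,end,score`, 1-based inclusive coordinates);
#' `write_scan_segments()` writes segments as BED-like 4-column text
#' (`id`, 0-based half-open `start`/`end`, peak score).
#'
#' @param scan A `nols_scan` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_profile <- function(scan, path) {
  if (inherits(scan, "nols_scan")) scan <- list(scan)
  prof <- do.call(rbind, lapply(scan, `[[`, "profile"))
  write.csv(prof, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_profile
#' @export
write_scan_segments <- function(scan, path) {
  if (inherits(scan, "nols_scan")) scan <- list(scan)
  rows <- lapply(scan, function(s) {
    if (!nrow(s$segments)) return(NULL)
    # 1-based inclusive -> 0-based half-open
    sprintf("%s\t%d\t%d\t%.4f", s$id, s$segments$start - 1L,
            s$segments$end, s$segments$peak_score)
  })
  writeLines(unlist(rows), path)
  invisible(path)
}
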