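# Windowed GC analysis, low-GC anomalous-region detection, terminal-repeat
# scaffold joining, and per-region gene composition (viral-footprint scan).

#' Sliding-window GC track
#'
#' Windows start at 1 and advance by `step`; only windows fully inside the
#' sequence are emitted.  GC is (G+C)/(A+C+G+T); ambiguous bases are
#' excluded from numerator and denominator, and a window with no
#' unambiguous base gets `NA`.
#'
#' @param sequence a [Biostrings::DNAString], single-element
#'   `DNAStringSet`, or character scalar.
#' @param window window size in bp.
#' @param step step in bp (`window >= step >= 1`).
#' @param scaffold scaffold name recorded in the track.
#' @return data frame of class `gc_track`: scaffold, start, end, gc;
#'   attributes `window`, `step`.
#' @export
gc_windows <- function(sequence, window = 5000, step = 1000,
                       scaffold = "scaffold_1") {
  if (!(window >= step && step >= 1))
    stop("need window >= step >= 1", call. = FALSE)
  seq <- as_dnastring(sequence)
  L <- length(seq)
  if (L < window)
    return(empty_gc_track(scaffold, window, step))
  starts <- seq.int(1L, L - window + 1L, by = step)
  v <- Biostrings::Views(seq, start = starts, width = window)
  freq <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
  denom <- rowSums(freq)
  gc <- ifelse(denom > 0, (freq[, "C"] + freq[, "G"]) / denom, NA_real_)
  out <- data.frame(scaffold = scaffold, start = starts,
                    end = starts + window - 1L, gc = gc,
                    stringsAsFactors = FALSE)
  attr(out, "window") <- as.integer(window)
  attr(out, "step") <- as.integer(step)
  class(out) <- c("gc_track", "data.frame")
  out
}

as_dnastring <- function(x) {
  if (inherits(x, "DNAString")) return(x)
  if (inherits(x, "DNAStringSet")) {
    if (length(x) != 1L) stop("expected a single sequence", call. = FALSE)
    return(x[[1L]])
  }
  Biostrings::DNAString(as.character(x))
}

empty_gc_track <- function(scaffold, window, step) {
  out <- data.frame(scaffold = character(0), start = integer(0),
                    end = integer(0), gc = numeric(0),
                    stringsAsFactors = FALSE)
  attr(out, "window") <- as.integer(window)
  attr(out, "step") <- as.integer(step)
  class(out) <- c("gc_track", "data.frame")
  out
}

#' Detect anomalously low-GC regions on a GC track
#'
#' Windows with GC below `median - z_cut * MAD` (MAD scaled by 1.4826,
#' i.e. a robust z-score rule) are collected into maximal runs, runs
#' separated by at most one window are merged, and regions shorter than
#' `min_length` bp are discarded.  Region boundaries snap to window edges.
#' The baseline is computed from the track itself unless supplied.
#'
#' @param track a [gc_windows()] track.
#' @param baseline optional `c(center, spread)`; default
#'   `median(gc)` and `mad(gc)`.
#' @param min_length minimal region length in bp.
#' @param z_cut robust z threshold (default 4).
#' @return data frame: scaffold, start, end, n_windows, mean_gc; zero rows
#'   when nothing is detected.
#' @export
detect_low_gc_regions <- function(track, baseline = NULL,
                                  min_length = 20000, z_cut = 4) {
  stopifnot(inherits(track, "gc_track"))
  empty <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      mean_gc = numeric(0), stringsAsFactors = FALSE)
  gc <- track$gc
  ok <- !is.na(gc)
  if (sum(ok) == 0) return(empty)
  if (is.null(baseline)) baseline <- c(median(gc[ok]), mad(gc[ok]))
  cutoff <- baseline[1] - z_cut * baseline[2]
  low <- ok & gc < cutoff
  if (!any(low)) return(empty)
  idx <- which(low)
  # merge runs across gaps of <= 1 window
  brk <- c(TRUE, diff(idx) > 2L)
  run <- cumsum(brk)
  rows <- lapply(split(idx, run), function(ii) {
    data.frame(scaffold = track$scaffold[ii[1]],
               start = track$start[min(ii)],
               end = track$end[max(ii)],
               n_windows = length(ii),
               mean_gc = mean(track$gc[ii], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$end - out$start + 1L >= min_length, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# primitive (shortest, >= min_unit) tandem unit whose array of
# >= min_copies exact copies terminates the given sequence end; the
# shortest period is canonical, so two arrays of the same unit but
# different copy numbers discover the same unit
find_terminal_array <- function(seq_chr, end = c("right", "left"),
                                min_unit = 20, min_copies = 3,
                                search_window = 5000) {
  end <- match.arg(end)
  L <- nchar(seq_chr)
  win <- substr(seq_chr, max(1L, L - search_window + 1L), L)
  if (end == "left")
    win <- substr(seq_chr, 1L, min(L, search_window))
  wl <- nchar(win)
  best <- NULL
  for (u in seq.int(min_unit, wl %/% min_copies)) {
    if (end == "right") {
      unit <- substr(win, wl - u + 1L, wl)
      copies <- 1L
      while ((cs <- wl - (copies + 1L) * u + 1L) >= 1L &&
             substr(win, cs, cs + u - 1L) == unit)
        copies <- copies + 1L
    } else {
      unit <- substr(win, 1L, u)
      copies <- 1L
      while ((cs <- copies * u + 1L) + u - 1L <= wl &&
             substr(win, cs, cs + u - 1L) == unit)
        copies <- copies + 1L
    }
    if (copies >= min_copies) {
      best <- list(unit = unit, unit_length = u, copies = copies)
      break
    }
  }
  best
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Join two scaffolds sharing a terminal tandem-repeat array
#'
#' Each scaffold must terminate (3' end) in a tandem array of at least
#' `min_copies` exact copies of the same unit (the second scaffold's array
#' may match in reverse complement, as expected when two scaffold ends of
#' one chromosome face each other).  The repeat unit is discovered by
#' exact tandem decomposition of the terminal `search_window` bp — the
#' primitive (shortest) unit with enough copies wins, so arrays with
#' different copy numbers still agree on the unit.  The join retains a single array
#' copy: `A` (array collapsed to one copy) followed by the
#' reverse-complemented `B` body, so the joined length is
#' `lenA + lenB - (copiesA + copiesB - 1) * unit_length`.
#'
#' @param a,b scaffold sequences (character, `DNAString`, or one-element
#'   `DNAStringSet`).
#' @param min_unit minimal repeat unit length considered.
#' @param min_copies minimal exact tandem copies required at each end.
#' @param search_window terminal window scanned for the array.
#' @return `NULL` when no shared terminal array exists; otherwise a list
#'   with `sequence` (character), `unit`, `unit_length`, `copies_a`,
#'   `copies_b`, `joined_length` and `map` (data frame mapping each
#'   original scaffold to its interval on the joined scaffold).
#' @export
terminal_repeat_join <- function(a, b, min_unit = 20, min_copies = 3,
                                 search_window = 5000) {
  a_chr <- as.character(as_dnastring(a))
  b_chr <- as.character(as_dnastring(b))
  arr_a <- find_terminal_array(a_chr, "right", min_unit, min_copies,
                               search_window)
  arr_b <- find_terminal_array(b_chr, "right", min_unit, min_copies,
                               search_window)
  if (is.null(arr_a) || is.null(arr_b)) return(NULL)
  same <- is_rotation(arr_a$unit, arr_b$unit) ||
    is_rotation(arr_a$unit, revcomp_chr(arr_b$unit))
  if (!same) return(NULL)
  u <- arr_a$unit_length
  lenA <- nchar(a_chr); lenB <- nchar(b_chr)
  body_a <- substr(a_chr, 1L, lenA - arr_a$copies * u)
  body_b <- substr(b_chr, 1L, lenB - arr_b$copies * u)
  joined <- paste0(body_a, arr_a$unit, revcomp_chr(body_b))
  jl <- nchar(joined)
  map <- data.frame(
    scaffold = c("A", "B"),
    orig_start = c(1L, 1L),
    orig_end = c(nchar(body_a) + u, nchar(body_b)),
    joined_start = c(1L, nchar(body_a) + u + 1L),
    joined_end = c(nchar(body_a) + u, jl),
    orientation = c("+", "-"),
    stringsAsFactors = FALSE
  )
  list(sequence = joined, unit = arr_a$unit, unit_length = u,
       copies_a = arr_a$copies, copies_b = arr_b$copies,
       joined_length = jl, map = map)
}

# tandem arrays make the discovered unit phase-ambiguous; compare units up
# to cyclic rotation
is_rotation <- function(x, y) {
  nchar(x) == nchar(y) && grepl(x, paste0(y, y), fixed = TRUE)
}

#' Gene composition of a genomic region vs the rest of the genome
#'
#' Genes belong to the region when their midpoint falls inside it.  For
#' the region and for the genome remainder the report gives counts and
#' fractions per best-hit affinity class and the intron-bearing gene
#' fraction.
#'
#' @param region list or one-row data frame with `scaffold`, `start`,
#'   `end`.
#' @param genes gene table with `scaffold`, `start`, `end`, `affinity`,
#'   `introns`.
#' @return list with `region` and `rest`, each holding `n_genes`,
#'   `affinity_counts`, `affinity_fractions` (named over all affinity
#'   classes, summing to 1; all-`NA` when the region holds no gene) and
#'   `intron_fraction`.
#' @export
region_gene_report <- function(region, genes) {
  mid <- (genes$start + genes$end) / 2
  inside <- genes$scaffold == region$scaffold &
    mid >= region$start & mid <= region$end
  summarize <- function(g) {
    n <- nrow(g)
    counts <- table(factor(g$affinity, levels = AFFINITY_CLASSES))
    counts <- setNames(as.integer(counts), AFFINITY_CLASSES)
    if (n == 0) {
      fr <- setNames(rep(NA_real_, length(AFFINITY_CLASSES)),
                     AFFINITY_CLASSES)
      return(list(n_genes = 0L, affinity_counts = counts,
                  affinity_fractions = fr, intron_fraction = NA_real_))
    }
    list(n_genes = n, affinity_counts = counts,
         affinity_fractions = counts / n,
         intron_fraction = mean(g$introns > 0))
  }
  list(region = summarize(genes[inside, , drop = FALSE]),
       rest = summarize(genes[!inside, , drop = FALSE]))
}
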