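#' Construct a genomic bin grid
#'
#' A bin grid is an ordered set of non-overlapping genomic bins shared by all
#' copy-number profiles of an analysis. Coordinates are 0-based, half-open
#' `[start, end)` (BED convention).
#'
#' @param chrom Character vector of chromosome labels.
#' @param start,end Integer-ish vectors of bin boundaries in bp, `start < end`.
#' @return A tibble with columns `chrom`, `start`, `end`, validated and
#'   carrying class `"bin_grid"` in addition to the data-frame classes.
#' @examples
#' bin_grid(c("1", "1", "2"), c(0, 10, 0), c(10, 20, 10))
#' @export
bin_grid <- function(chrom, start, end) {
  g <- tibble::tibble(chrom = as.character(chrom),
                      start = as.numeric(start),
                      end = as.numeric(end))
  validate_bin_grid(g)
  class(g) <- c("bin_grid", class(g))
  g
}

validate_bin_grid <- function(g) {
  if (!all(c("chrom", "start", "end") %in% names(g))) {
    abort("a bin grid needs columns chrom, start, end")
  }
  if (nrow(g) == 0) abort("empty bin grid")
  if (any(g$start >= g$end)) abort("bins must satisfy start < end")
  ch <- chrom_index(g)
  if (anyDuplicated(rle(as.integer(ch))$values)) {
    abort("chromosome blocks must be contiguous in the grid")
  }
  for (cc in split(seq_len(nrow(g)), ch)) {
    s <- g$start[cc]; e <- g$end[cc]
    if (is.unsorted(s, strictly = TRUE)) abort("bins must be sorted by start within chromosome")
    if (any(s[-1] < e[-length(e)])) abort("bins must not overlap")
  }
  invisible(g)
}

#' Default genome bin grid
#'
#' Twenty-two autosomes at approximate human (GRCh37) lengths, cut into fixed
#' width bins. The 10-Mb default yields 287 bins, a coarse abstraction of the
#' genome suitable for simulation and desk-scale inference; 500-kb bins give
#' the resolution typical of shallow-WGS copy-number calling.
#'
#' @param bin_size Bin width in bp (default 10 Mb).
#' @return A [bin_grid()] tibble.
#' @export
default_bin_grid <- function(bin_size = 10e6) {
  len_mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135,
              134, 115, 107, 103, 90, 81, 78, 59, 63, 48, 51)
  chroms <- as.character(seq_along(len_mb))
  pieces <- lapply(seq_along(chroms), function(i) {
    n <- max(1L, floor(len_mb[i] * 1e6 / bin_size))
    tibble::tibble(chrom = chroms[i],
                   start = (seq_len(n) - 1) * bin_size,
                   end = seq_len(n) * bin_size)
  })
  g <- dplyr::bind_rows(pieces)
  class(g) <- c("bin_grid", class(g))
  g
}

# integer chromosome index per bin, preserving grid order
chrom_index <- function(x) {
  as.integer(factor(x$chrom, levels = unique(x$chrom)))
}

# first/last grid row index of each chromosome
chrom_bounds <- function(x) {
  ch <- chrom_index(x)
  list(first = match(unique(ch), ch),
       last = length(ch) - match(unique(ch), rev(ch)) + 1L,
       id = ch)
}

sample_cols <- function(x) setdiff(names(x), c("chrom", "start", "end"))

#' Extract the sample matrix of a bin table
#'
#' Bin tables are wide tibbles: `chrom`, `start`, `end`, then one numeric
#' column per sample. This returns the bins-by-samples numeric matrix.
#'
#' @param x A bin table.
#' @return Numeric matrix with one column per sample.
#' @export
cn_matrix <- function(x) {
  sc <- sample_cols(x)
  if (length(sc) == 0) abort("bin table has no sample columns")
  m <- as.matrix(x[sc])
  if (is.numeric(m)) storage.mode(m) <- "double"
  m
}

#' Assemble a wide bin table from a grid and a sample matrix
#'
#' @param grid A [bin_grid()] (or any table with `chrom`, `start`, `end`).
#' @param m Bins-by-samples matrix.
#' @param sample_ids Column names to use; defaults to `colnames(m)`.
#' @return A wide bin table tibble.
#' @export
bin_table <- function(grid, m, sample_ids = colnames(m)) {
  m <- as.matrix(m)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(m)))
  stopifnot(nrow(m) == nrow(grid))
  out <- tibble::as_tibble(grid[c("chrom", "start", "end")])
  out[sample_ids] <- as.data.frame(m)
  out
}

check_shared_grid <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(as.character(a$chrom), as.character(b$chrom)) ||
      !identical(as.numeric(a$start), as.numeric(b$start))) {
    abort("profiles must share one bin grid")
  }
  invisible(TRUE)
}

#' Read / write a bin table
#'
#' BED-like TSV with a header row: `chrom`, `start`, `end`, then one column
#' per sample (integer copy number or real log2 ratio).
#'
#' @param path File path.
#' @param x Bin table to write.
#' @return `read_cn_table()` returns the tibble; `write_cn_table()` returns
#'   `x` invisibly.
#' @export
read_cn_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  x$chrom <- as.character(x$chrom)
  validate_bin_grid(x[c("chrom", "start", "end")])
  x
}

#' @rdname read_cn_table
#' @export
write_cn_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

# lower-median of an integer vector: for even n the lower middle value, so the
# baseline is always an attained copy number
lower_median <- function(v) {
  sort(v)[ceiling(length(v) / 2)]
}

#' Baseline ploidy of each sample
#'
#' The baseline (reference) copy number of a sample is the median of its
#' per-bin integer copy numbers; for even bin counts the lower middle value is
#' taken so the baseline is always an attained integer state. Gains and losses
#' are called relative to this baseline, which makes calls ploidy-relative: a
#' uniformly tetraploid genome-doubled sample has baseline 4 and no altered
#' bins.
#'
#' @param x Bin table of integer copy numbers.
#' @return Tibble with columns `sample_id`, `baseline`.
#' @examples
#' g <- default_bin_grid()
#' tbl <- bin_table(g, matrix(2, nrow(g), 1, dimnames = list(NULL, "a")))
#' @export
baseline_ploidy <- function(x) {
  m <- cn_matrix(x)
  if (nrow(m) == 0) abort("empty profile")
  tibble::tibble(sample_id = colnames(m),
                 baseline = unname(apply(m, 2, lower_median)))
}

#' Percentage of genome altered
#'
#' Fraction of bins whose integer copy number differs from the sample's
#' baseline ploidy (the per-sample median copy number, unless an explicit
#' baseline is supplied).
#'
#' @param x Bin table of integer copy numbers.
#' @param baseline Optional named vector or single integer overriding the
#'   per-sample median baseline.
#' @return Tibble with `sample_id`, `baseline`, `pga` (fraction in `[0, 1]`).
#' @export
pga <- function(x, baseline = NULL) {
  m <- cn_matrix(x)
  if (nrow(m) == 0) abort("empty profile")
  bl <- resolve_baseline(m, baseline)
  tibble::tibble(
    sample_id = colnames(m),
    baseline = unname(bl),
    pga = vapply(seq_len(ncol(m)), function(j) mean(m[, j] != bl[j]), 0)
  )
}

resolve_baseline <- function(m, baseline) {
  if (is.null(baseline)) {
    bl <- apply(m, 2, lower_median)
  } else if (length(baseline) == 1 && is.null(names(baseline))) {
    bl <- rep(as.numeric(baseline), ncol(m))
  } else {
    if (!all(colnames(m) %in% names(baseline))) {
      abort("baseline must name every sample")
    }
    bl <- as.numeric(baseline[colnames(m)])
  }
  if (any(bl < 0)) abort("baseline must be >= 0")
  names(bl) <- colnames(m)
  bl
}

#' Number of copy-number segments
#'
#' Counts maximal runs of constant copy number per chromosome and sums them;
#' adjacency never crosses a chromosome boundary, so a fully constant genome
#' has as many segments as chromosomes. Set `chrom_breaks = FALSE` to treat
#' the genome as one sequence.
#'
#' @param x Bin table of integer copy numbers.
#' @param chrom_breaks Should chromosome boundaries always split segments?
#' @return Tibble with `sample_id`, `n_segments`.
#' @export
count_segments <- function(x, chrom_breaks = TRUE) {
  m <- cn_matrix(x)
  ch <- if (chrom_breaks) chrom_index(x) else rep(1L, nrow(x))
  ns <- vapply(seq_len(ncol(m)), function(j) {
    sum(vapply(split(m[, j], ch), function(v) length(rle(v)$lengths), 0L))
  }, 0L)
  tibble::tibble(sample_id = colnames(m), n_segments = ns)
}

#' Call gain/loss/baseline states
#'
#' Per bin and sample: `"gain"` if copy number exceeds the baseline, `"loss"`
#' below it, `"baseline"` otherwise. The baseline defaults to each sample's
#' own median ploidy, so states are ploidy-relative.
#'
#' @inheritParams pga
#' @return Bin table with character state columns.
#' @export
call_states <- function(x, baseline = NULL) {
  m <- cn_matrix(x)
  bl <- resolve_baseline(m, baseline)
  s <- state_matrix(m, bl)
  lab <- matrix(c("loss", "baseline", "gain")[s + 2L], nrow(s),
                dimnames = dimnames(s))
  bin_table(x, lab, colnames(m))
}

# integer-coded states: -1 loss, 0 baseline, +1 gain
state_matrix <- function(m, bl) {
  s <- sign(sweep(m, 2, bl))
  storage.mode(s) <- "integer"
  s
}

#' Consensus regions from multi-sample breakpoints
#'
#' Splits the grid at every position where any sample's copy number differs
#' between two consecutive bins (plus chromosome boundaries) and drops
#' resulting regions spanning fewer than `min_bins` bins. This produces the
#' comparable region set used for phylogenetic analysis of multi-sample
#' copy-number data (default `min_bins = 4`; use 2 for single-cell data).
#'
#' @param x Bin table of integer copy numbers (all samples on one grid).
#' @param min_bins Minimum number of bins a region must span.
#' @param chrom_breaks Should chromosome boundaries always induce breakpoints?
#' @return Tibble with `chrom`, `start`, `end`, `start_bin`, `end_bin`,
#'   `n_bins` (bin indices 1-based, inclusive).
#' @export
consensus_regions <- function(x, min_bins = 4, chrom_breaks = TRUE) {
  m <- cn_matrix(x)
  n <- nrow(m)
  ch <- if (chrom_breaks) chrom_index(x) else rep(1L, n)
  # break before bin i when any sample changes between i-1 and i, or new chrom
  brk <- c(TRUE, (ch[-1] != ch[-n]) |
             rowSums(m[-1, , drop = FALSE] != m[-n, , drop = FALSE]) > 0)
  region_id <- cumsum(brk)
  idx <- split(seq_len(n), region_id)
  out <- purrr::map_dfr(idx, function(i) {
    tibble::tibble(chrom = x$chrom[i[1]],
                   start = x$start[i[1]],
                   end = x$end[i[length(i)]],
                   start_bin = i[1], end_bin = i[length(i)],
                   n_bins = length(i))
  })
  dplyr::filter(out, .data$n_bins >= min_bins)
}
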