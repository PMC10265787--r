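#' Library insert-size profile
#'
#' Describes one paired-read library: mean and standard deviation of the
#' insert size (the outer distance from the leftmost base of the forward read
#' to the rightmost base of the reverse read) and the pair orientation.
#'
#' @param mu Insert-size mean in bp; must be positive.
#' @param v Insert-size standard deviation in bp; floored at 1.
#' @param orientation `"FR"` (innies, the Illumina paired-end convention) or
#'   `"RF"`; RF libraries are normalised to FR at ingest.
#' @return An object of class `lib_profile`.
#' @export
lib_profile <- function(mu, v, orientation = "FR") {
  stopifnot(mu > 0, v >= 0, orientation %in% c("FR", "RF"))
  structure(list(mu = as.numeric(mu), v = max(as.numeric(v), 1),
                 orientation = orientation),
            class = "lib_profile")
}

#' @export
print.lib_profile <- function(x, ...) {
  cat(sprintf("<lib_profile> mu = %g bp, v = %g bp, %s\n",
              x$mu, x$v, x$orientation))
  invisible(x)
}

#' Tandem-repeat specification for the genome simulator
#'
#' @param unit Repeat unit, a DNA string over ACGT.
#' @param copies Number of copies; fractional values allowed (e.g. 2.9),
#'   the implanted span is `round(copies * nchar(unit))` bp.
#' @param locus 0-based genome offset at which the repeat array starts.
#' @return An object of class `repeat_spec`.
#' @export
repeat_spec <- function(unit, copies, locus) {
  stopifnot(nchar(unit) >= 1, grepl("^[ACGT]+$", unit), copies >= 1, locus >= 0)
  structure(list(unit = unit, copies = copies, locus = as.integer(locus)),
            class = "repeat_spec")
}

#' Simulate a random genome with implanted tandem repeats
#'
#' Draws an i.i.d. nucleotide sequence at the requested GC content and
#' implants each repeat array verbatim at its locus. Deterministic for a
#' fixed seed.
#'
#' @param length Genome length in bp.
#' @param repeats List of [repeat_spec()] objects; implanted spans must not
#'   overlap each other.
#' @param gc GC fraction of the random background (default 0.5).
#' @param seed Integer seed.
#' @return A DNA string of length `length`.
#' @export
simulate_genome <- function(length, repeats = list(), gc = 0.5, seed = 1) {
  stopifnot(length >= 1)
  spans <- lapply(repeats, function(r) {
    len <- round(r$copies * nchar(r$unit))
    c(r$locus, r$locus + len)
  })
  if (length(spans)) {
    ord <- order(vapply(spans, `[`, numeric(1), 1L))
    spans <- spans[ord]
    for (k in seq_along(spans)) {
      if (spans[[k]][2] > length)
        stop("repeat span exceeds genome length")
      if (k > 1 && spans[[k]][1] < spans[[k - 1]][2])
        stop("implanted repeat spans overlap")
    }
  }
  set.seed(seed)
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  g <- sample(names(base_probs), length, replace = TRUE, prob = base_probs)
  for (r in repeats) {
    len <- round(r$copies * nchar(r$unit))
    arr <- strsplit(strrep(r$unit, ceiling(r$copies)), "")[[1]][seq_len(len)]
    g[(r$locus + 1):(r$locus + len)] <- arr
  }
  paste(g, collapse = "")
}

#' Replace genome intervals by N-runs to build a draft with gaps
#'
#' Each interval is replaced by a run of `N` whose length defaults to the
#' true span but can be perturbed (`size_error`) to mimic the inaccuracy of
#' scaffolder gap-size estimates. The true intervals and the genome-to-draft
#' coordinate map are recorded as ground truth.
#'
#' @param genome DNA string.
#' @param gap_intervals List of 0-based half-open `c(start, end)` intervals on
#'   the genome; pairwise disjoint, not abutting either sequence end (a gap
#'   needs two flanks).
#' @param size_error Integer vector (recycled) added to each true span to get
#'   the reported N-run length; floored at 1.
#' @return A list of class `sim_truth` with elements `draft` (DNA string with
#'   N-runs), `genome`, `gap_intervals` (true, sorted), `reported_sizes`, and
#'   `draft_gaps` (0-based half-open N-run intervals on the draft).
#' @export
make_draft <- function(genome, gap_intervals, size_error = 0) {
  glen <- nchar(genome)
  if (!length(gap_intervals))
    return(structure(list(draft = genome, genome = genome,
                          gap_intervals = list(), reported_sizes = integer(),
                          draft_gaps = list()), class = "sim_truth"))
  ivs <- gap_intervals[order(vapply(gap_intervals, `[`, numeric(1), 1L))]
  size_error <- rep_len(as.integer(size_error), length(ivs))
  prev_end <- 0
  for (iv in ivs) {
    if (iv[1] <= 0 || iv[2] >= glen || iv[2] <= iv[1])
      stop("gap interval must lie strictly inside the genome")
    if (iv[1] < prev_end) stop("gap intervals overlap")
    prev_end <- iv[2]
  }
  pieces <- character(0)
  draft_gaps <- vector("list", length(ivs))
  reported <- integer(length(ivs))
  cur <- 0      # genome cursor (0-based)
  dcur <- 0     # draft cursor
  for (k in seq_along(ivs)) {
    iv <- ivs[[k]]
    flank <- substr(genome, cur + 1, iv[1])
    nlen <- max(1L, as.integer(iv[2] - iv[1]) + size_error[k])
    pieces <- c(pieces, flank, strrep("N", nlen))
    dcur <- dcur + nchar(flank)
    draft_gaps[[k]] <- c(dcur, dcur + nlen)
    dcur <- dcur + nlen
    reported[k] <- nlen
    cur <- iv[2]
  }
  pieces <- c(pieces, substr(genome, cur + 1, glen))
  structure(list(draft = paste(pieces, collapse = ""), genome = genome,
                 gap_intervals = ivs, reported_sizes = reported,
                 draft_gaps = draft_gaps),
            class = "sim_truth")
}

# Internal: map a 0-based genome position to a 0-based draft position, or NA
# if it falls inside a (true) gap interval. Positions right of a gap shift by
# the accumulated difference between reported and true gap sizes.
genome_to_draft <- function(truth, pos) {
  if (!length(truth$gap_intervals)) return(pos)
  starts <- vapply(truth$gap_intervals, `[`, numeric(1), 1L)
  ends <- vapply(truth$gap_intervals, `[`, numeric(1), 2L)
  shifts <- cumsum(truth$reported_sizes - (ends - starts))
  out <- pos
  for (k in seq_along(pos)) {
    p <- pos[k]
    inside <- which(p >= starts & p < ends)
    if (length(inside)) { out[k] <- NA_integer_; next }
    nleft <- sum(ends <= p)
    out[k] <- p + if (nleft) shifts[nleft] else 0L
  }
  out
}

#' Simulate an FR paired-end library with truth coordinates and a fixture SAM
#'
#' Draws fragments uniformly over the genome with insert sizes from a normal
#' distribution truncated to `[2 * read_len, mu + 5 v]`, sequences both ends
#' inward (FR), applies substitution errors at `err_rate` with matching Phred
#' qualities, and emits a SAM against the draft in which each read is placed
#' at its true position; reads whose true span intersects a gap interval are
#' flagged unmapped with their mate's coordinates, mimicking what a mapper
#' produces for reads originating inside N-runs.
#'
#' @param truth A `sim_truth` from [make_draft()] (or a plain genome string,
#'   in which case the draft equals the genome).
#' @param lib A [lib_profile()]; `lib$mu` must exceed `read_len`.
#' @param read_len Read length in bp.
#' @param coverage Sequence coverage; pair count =
#'   `round(coverage * genome_length / (2 * read_len))`.
#' @param err_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, `reads_1.fastq`,
#'   `reads_2.fastq`, `alignments.sam` and `draft.fasta` are written there.
#' @param lib_id Library identifier recorded with each read.
#' @return A list of class `sim_reads`: `r1`, `r2` (data.frames with `id`,
#'   `seq`, `qual` as sequenced), `read_truth` (data.frame `id`, `mate`,
#'   `end` = 0-based genome offset of the ending base of the read's
#'   forward-strand image, `strand`), `sam` (character vector of SAM lines),
#'   `lib`, and the file `paths` when `dir` was given.
#' @export
simulate_paired_reads <- function(truth, lib, read_len = 100, coverage = 30,
                                  err_rate = 0, seed = 1, dir = NULL,
                                  lib_id = "lib1") {
  if (is.character(truth))
    truth <- structure(list(draft = truth, genome = truth,
                            gap_intervals = list(), reported_sizes = integer(),
                            draft_gaps = list()), class = "sim_truth")
  stopifnot(inherits(truth, "sim_truth"), inherits(lib, "lib_profile"),
            lib$mu > read_len, coverage > 0)
  genome <- truth$genome
  glen <- nchar(genome)
  npairs <- max(1L, round(coverage * glen / (2 * read_len)))
  set.seed(seed)

  lo <- 2 * read_len
  hi <- lib$mu + 5 * lib$v
  if (lo > hi) stop("insert-size truncation interval is empty")
  inserts <- numeric(0)
  while (length(inserts) < npairs) {
    s <- rnorm(npairs * 2, lib$mu, lib$v)
    inserts <- c(inserts, s[s >= lo & s <= hi])
  }
  inserts <- round(inserts[seq_len(npairs)])
  inserts <- pmin(inserts, glen)
  starts <- floor(runif(npairs, 0, glen - inserts + 1)) # 0-based fragment start

  gvec <- strsplit(genome, "")[[1]]
  ids <- sprintf("frag%06d", seq_len(npairs))
  q_per_base <- if (err_rate > 0) min(40L, round(-10 * log10(err_rate))) else 40L
  qchr <- rawToChar(as.raw(q_per_base + 33L))

  extract <- function(s0) { # 0-based start, forward read_len bases
    paste(gvec[(s0 + 1):(s0 + read_len)], collapse = "")
  }
  r1_fwd <- vapply(starts, extract, character(1))
  r2_start <- starts + inserts - read_len
  r2_fwd <- vapply(r2_start, extract, character(1))

  add_errors <- function(seqs) {
    if (err_rate <= 0) return(seqs)
    vapply(seqs, function(s) {
      b <- strsplit(s, "")[[1]]
      hit <- which(runif(length(b)) < err_rate)
      if (length(hit)) {
        for (h in hit) b[h] <- sample(setdiff(c("A", "C", "G", "T"), b[h]), 1)
      }
      paste(b, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  r1_fwd <- add_errors(r1_fwd)
  r2_fwd <- add_errors(r2_fwd)
  qual <- strrep(qchr, read_len)

  # as sequenced: R1 forward, R2 reverse-complement of the fragment end
  r1 <- data.frame(id = paste0(ids, "/1"), seq = r1_fwd, qual = qual,
                   stringsAsFactors = FALSE)
  r2 <- data.frame(id = paste0(ids, "/2"), seq = revcomp_many(r2_fwd),
                   qual = qual, stringsAsFactors = FALSE)

  read_truth <- data.frame(
    id = c(r1$id, r2$id),
    mate = rep(1:2, each = npairs),
    end = c(starts + read_len - 1, starts + inserts - 1),
    strand = rep(c("+", "-"), each = npairs),
    stringsAsFactors = FALSE)

  # fixture SAM against the draft
  gap_s <- vapply(truth$gap_intervals, `[`, numeric(1), 1L)
  gap_e <- vapply(truth$gap_intervals, `[`, numeric(1), 2L)
  clear <- function(s0) { # TRUE when [s0, s0+read_len) avoids every gap
    if (!length(gap_s)) return(rep(TRUE, length(s0)))
    ok <- rep(TRUE, length(s0))
    for (k in seq_along(gap_s))
      ok <- ok & (s0 + read_len <= gap_s[k] | s0 >= gap_e[k])
    ok
  }
  m1 <- clear(starts)
  m2 <- clear(r2_start)
  p1 <- genome_to_draft(truth, starts)
  p2 <- genome_to_draft(truth, r2_start)
  m1 <- m1 & !is.na(p1)
  m2 <- m2 & !is.na(p2)

  flag1 <- 0x1 + 0x40 + ifelse(m1, 0, 0x4) + ifelse(m2, 0x20, 0x8) +
    ifelse(m1 & m2, 0x2, 0)
  flag2 <- 0x1 + 0x80 + 0x10 * as.integer(m2) + ifelse(m2, 0, 0x4) +
    ifelse(m1, 0, 0x8) + ifelse(m1 & m2, 0x2, 0)
  # SAM: unmapped reads inherit the mate's RNAME/POS when the mate is mapped
  pos1 <- ifelse(m1, p1 + 1, ifelse(m2, p2 + 1, 0))
  pos2 <- ifelse(m2, p2 + 1, ifelse(m1, p1 + 1, 0))
  rname <- ifelse(m1 | m2, "scaffold1", "*")
  cig1 <- ifelse(m1, paste0(read_len, "M"), "*")
  cig2 <- ifelse(m2, paste0(read_len, "M"), "*")
  mapq1 <- ifelse(m1, 60L, 0L)
  mapq2 <- ifelse(m2, 60L, 0L)
  # SEQ convention: mapped reads store forward-strand bases; unmapped reads
  # store the raw as-sequenced bases (R2 reverse-complemented)
  seq1 <- r1_fwd
  seq2 <- ifelse(m2, r2_fwd, r2$seq)
  qual2 <- qual # constant quality, palindromic under reversal

  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:scaffold1\tLN:%d", nchar(truth$draft)))
  rec <- function(id, flag, rname, pos, mapq, cig, pnext, seqs, quals)
    paste(id, flag, rname, pos, mapq, cig, "=", pnext, 0, seqs, quals,
          sep = "\t")
  lines1 <- rec(ids, flag1, rname, pos1, mapq1, cig1, pos2, seq1, qual)
  lines2 <- rec(ids, flag2, rname, pos2, mapq2, cig2, pos1, seq2, qual2)
  lines1[rname == "*"] <- sub("\t=\t", "\t*\t",
                              lines1[rname == "*"], fixed = TRUE)
  lines2[rname == "*"] <- sub("\t=\t", "\t*\t",
                              lines2[rname == "*"], fixed = TRUE)
  sam <- c(hdr, as.vector(rbind(lines1, lines2)))

  out <- structure(list(r1 = r1, r2 = r2, read_truth = read_truth, sam = sam,
                        lib = lib, lib_id = lib_id, truth = truth,
                        read_len = read_len),
                   class = "sim_reads")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fq <- function(df, path) {
      con <- file(path, "w")
      writeLines(paste0("@", df$id, "\n", df$seq, "\n+\n", df$qual), con)
      close(con)
    }
    paths <- list(r1 = file.path(dir, "reads_1.fastq"),
                  r2 = file.path(dir, "reads_2.fastq"),
                  sam = file.path(dir, "alignments.sam"),
                  draft = file.path(dir, "draft.fasta"))
    fq(r1, paths$r1); fq(r2, paths$r2)
    writeLines(sam, paths$sam)
    write_fasta(setNames(truth$draft, "scaffold1"), paths$draft)
    out$paths <- paths
  }
  out
}
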