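#' Read / write FASTA
#'
#' Thin wrappers over Biostrings keeping sequences as named character vectors,
#' the representation used throughout the package. FASTA output is wrapped at
#' 80 columns.
#'
#' @param path File path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @param seqs Named character vector of DNA sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Locate N-gaps in a draft genome
#'
#' Finds maximal runs of at least `min_n` consecutive `N`/`n` characters in
#' each scaffold. Scaffolds consisting entirely of N are skipped with a
#' warning. Coordinates are 0-based half-open.
#'
#' @param draft Named character vector of scaffold sequences (or a FASTA
#'   path).
#' @param min_n Minimum run length to report (default 1).
#' @return A data.frame with columns `scaffold`, `start`, `end`,
#'   `reported_size` (= `end - start`), `left_flank_id`, `right_flank_id`,
#'   and `gap_id`.
#' @export
find_gaps <- function(draft, min_n = 1) {
  stopifnot(min_n >= 1)
  if (length(draft) == 1 && file.exists(draft[1]) && is.null(names(draft)))
    draft <- read_fasta(draft)
  if (is.null(names(draft))) names(draft) <- paste0("seq", seq_along(draft))
  rows <- list()
  for (sc in names(draft)) {
    s <- draft[[sc]]
    if (grepl("^[Nn]+$", s)) {
      warning("scaffold ", sc, " is all N; skipped")
      next
    }
    m <- gregexpr("[Nn]+", s)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    keep <- len >= min_n
    if (!any(keep)) next
    st <- as.integer(m[keep]) - 1L
    en <- st + as.integer(len[keep])
    rows[[sc]] <- data.frame(
      scaffold = sc, start = st, end = en, reported_size = en - st,
      left_flank_id = sprintf("%s.ctg%d", sc, seq_along(st)),
      right_flank_id = sprintf("%s.ctg%d", sc, seq_along(st) + 1L),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold = character(), start = integer(), end = integer(),
               reported_size = integer(), left_flank_id = character(),
               right_flank_id = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$gap_id <- if (nrow(out)) sprintf("%s:%d-%d", out$scaffold, out$start,
                                       out$end) else character(0)
  out
}

#' Read paired alignments from SAM/BAM
#'
#' Parses a SAM or BAM file via Rsamtools, drops secondary and supplementary
#' records, and pairs mates by query name. SAM's 1-based leftmost positions
#' are converted to 0-based at this boundary; all package-internal
#' coordinates are 0-based half-open.
#'
#' @param path SAM or BAM file.
#' @return A data.frame with one row per primary record: `qname`, `mate`
#'   (1 or 2), `mapped`, `rname`, `pos` (0-based leftmost, NA if unmapped),
#'   `strand` (`"+"`/`"-"`/NA), `mapq`, `seq`, `qual` (SAM conventions: SEQ of
#'   a reverse-strand-mapped read is the forward-genome sequence; unmapped
#'   records keep whatever the producer stored).
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "seq", "qual")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  flag <- res$flag
  keep <- bitwAnd(flag, 0x100) == 0 & bitwAnd(flag, 0x800) == 0
  flag <- flag[keep]
  mapped <- bitwAnd(flag, 0x4) == 0
  data.frame(
    qname = res$qname[keep],
    mate = ifelse(bitwAnd(flag, 0x40) > 0, 1L,
                  ifelse(bitwAnd(flag, 0x80) > 0, 2L, 1L)),
    mapped = mapped,
    rname = as.character(res$rname[keep]),
    pos = ifelse(mapped, res$pos[keep] - 1L, NA_integer_),
    strand = ifelse(!mapped, NA_character_,
                    ifelse(bitwAnd(flag, 0x10) > 0, "-", "+")),
    mapq = res$mapq[keep],
    seq = as.character(res$seq[keep]),
    qual = as.character(res$qual[keep]),
    stringsAsFactors = FALSE)
}

#' Pair mate records into one row per read pair
#'
#' @param aln A data.frame from [read_alignments()].
#' @return A data.frame with one row per qname and suffixed columns `*_1`,
#'   `*_2`; orphan mates get NA in the absent mate's columns.
#' @export
pair_alignments <- function(aln) {
  a1 <- aln[aln$mate == 1L, , drop = FALSE]
  a2 <- aln[aln$mate == 2L, , drop = FALSE]
  merge(a1, a2, by = "qname", all = TRUE, suffixes = c("_1", "_2"),
        sort = TRUE)
}

#' Splice gap results into the draft and write outputs
#'
#' Closed gaps replace their N-run with the consensus sequence; one-sided
#' extensions shorten the N-run from the corresponding side. Non-gap bases
#' are preserved byte-for-byte. A per-gap TSV report is produced.
#'
#' @param draft Named character vector of scaffolds.
#' @param gaps Data.frame from [find_gaps()] (rows matching `results`).
#' @param results List of `gap_result` objects parallel to `gaps` rows.
#' @param dir Optional output directory; writes `genome.fasta`,
#'   `gap_sequences.fastq` (consensus with Phred qualities) and
#'   `report.tsv`.
#' @return A list with `genome` (spliced scaffolds) and `report` (data.frame).
#' @export
write_result_genome <- function(draft, gaps, results, dir = NULL) {
  stopifnot(nrow(gaps) == length(results))
  genome <- draft
  report <- data.frame(
    gap_id = gaps$gap_id,
    status = vapply(results, function(r) r$status, character(1)),
    filled_length = vapply(results, function(r) r$filled_length, numeric(1)),
    n_reads = vapply(results, function(r) r$n_reads %||% NA_real_, numeric(1)),
    n_observations = vapply(results, function(r) r$n_observations %||% NA_real_,
                            numeric(1)),
    n_outliers = vapply(results, function(r) r$n_outliers %||% NA_real_,
                        numeric(1)),
    stringsAsFactors = FALSE)

  # splice right-to-left within each scaffold so earlier coordinates hold
  ord <- order(gaps$scaffold, -gaps$start)
  for (k in ord) {
    r <- results[[k]]
    sc <- gaps$scaffold[k]
    s <- genome[[sc]]
    gs <- gaps$start[k]; ge <- gaps$end[k]
    left <- substr(s, 1, gs)
    right <- substr(s, ge + 1, nchar(s))
    nlen <- ge - gs
    # one-sided extensions are capped at the N-run length so an overshooting
    # extension can never duplicate bases of the opposite flank
    ext_l <- substr(r$sequence, 1, min(nchar(r$sequence), nlen))
    ext_r <- substr(r$sequence,
                    max(1, nchar(r$sequence) - nlen + 1), nchar(r$sequence))
    mid <- switch(r$status,
      closed = r$sequence,
      left_extended = paste0(ext_l, strrep("N", max(nlen - nchar(ext_l), 0))),
      right_extended = paste0(strrep("N", max(nlen - nchar(ext_r), 0)), ext_r),
      strrep("N", nlen))
    genome[[sc]] <- paste0(left, mid, right)
  }

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(genome, file.path(dir, "genome.fasta"))
    filled <- which(report$status != "unfilled" &
                    vapply(results, function(r) nchar(r$sequence) > 0,
                           logical(1)))
    if (length(filled)) {
      lines <- unlist(lapply(filled, function(k)
        c(paste0("@", gaps$gap_id[k], " ", report$status[k]),
          results[[k]]$sequence, "+", results[[k]]$qualities)))
      writeLines(lines, file.path(dir, "gap_sequences.fastq"))
    }
    write.table(report, file.path(dir, "report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(genome = genome, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
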