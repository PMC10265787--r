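#' Run configuration for the gap-closing pipeline
#'
#' @param overlap An [overlap_config()].
#' @param robust A [robust_config()].
#' @param flank_len Pseudo-read length in bp (default 150).
#' @param min_flank Minimum flank for a pseudo read (default 20).
#' @param min_mapq MAPQ threshold for unique mapping (default 20).
#' @param use_lib_weights Per-library initial observation weights
#'   (default FALSE; with one library all weights are 1 either way).
#' @param use_qualities Quality-aware consensus (default TRUE).
#' @param band,min_identity,min_overlap_cols MSA parameters, see
#'   [build_msa()].
#' @param iterations Rounds of closing in [iterate_closing()] (default 1).
#' @param threads Worker count for per-gap parallelism (default 1); results
#'   are independent of the worker count.
#' @return An object of class `run_config`.
#' @export
run_config <- function(overlap = overlap_config(), robust = robust_config(),
                       flank_len = 150, min_flank = 20, min_mapq = 20,
                       use_lib_weights = FALSE, use_qualities = TRUE,
                       band = 3, min_identity = 0.5, min_overlap_cols = 10,
                       iterations = 1, threads = 1) {
  stopifnot(iterations >= 1, threads >= 1)
  structure(list(overlap = overlap, robust = robust, flank_len = flank_len,
                 min_flank = min_flank, min_mapq = min_mapq,
                 use_lib_weights = use_lib_weights,
                 use_qualities = use_qualities, band = band,
                 min_identity = min_identity,
                 min_overlap_cols = min_overlap_cols,
                 iterations = iterations, threads = threads),
            class = "run_config")
}

#' Close a single gap
#'
#' Collects reads for the gap from every library, adds the pseudo reads,
#' detects overlaps, fits the two-step robust regression, and anchors the
#' consensus. Exposed mainly for inspection; [close_all_gaps()] drives it.
#'
#' @param gap One row of [find_gaps()] output.
#' @param scaffold_seq Sequence of the gap's scaffold.
#' @param libraries List of libraries, each a list with elements `pairs`
#'   (from [pair_alignments()]), `profile` (a [lib_profile()]), and
#'   optionally `id`.
#' @param config A [run_config()].
#' @return A `gap_result`, with the fitted pieces attached as attributes
#'   `placed`, `fit` and `observations` for diagnostics.
#' @export
close_gap <- function(gap, scaffold_seq, libraries, config = run_config()) {
  placed_list <- list()
  gsizes <- numeric(0)
  for (k in seq_along(libraries)) {
    lb <- libraries[[k]]
    lid <- lb$id %||% paste0("lib", k)
    gs <- estimate_gap_size(gap, lb$pairs, lb$profile,
                            min_mapq = config$min_mapq)
    gsizes <- c(gsizes, gs)
    placed_list[[k]] <- collect_gap_reads(gap, lb$pairs, lb$profile, gs,
                                          min_mapq = config$min_mapq,
                                          lib_id = lid)
  }
  gap_size <- max(1, round(median(gsizes)))
  placed <- do.call(rbind, placed_list)
  pseudo <- make_pseudo_reads(gap, scaffold_seq, gap_size,
                              flank_len = config$flank_len,
                              min_flank = config$min_flank)
  placed <- rbind(pseudo, placed)
  rownames(placed) <- NULL
  if (!nrow(placed) || !any(placed$is_pseudo)) {
    res <- structure(list(status = "unfilled", sequence = "", qualities = "",
                          filled_length = 0, n_reads = nrow(placed),
                          n_observations = 0, n_outliers = 0,
                          dropped = character(0),
                          note = "no usable flank"),
                     class = "gap_result")
    return(res)
  }
  obs <- build_observations(placed, config$overlap,
                            use_lib_weights = config$use_lib_weights)
  anchors <- placed$anchor
  prob <- build_problem(obs, nrow(placed), priors = placed$p,
                        anchors = anchors)
  fit <- two_step_fit(prob, config$robust)
  res <- anchor_and_emit(fit, placed, band = config$band,
                         min_identity = config$min_identity,
                         min_overlap_cols = config$min_overlap_cols,
                         use_qualities = config$use_qualities)
  attr(res, "placed") <- placed
  attr(res, "fit") <- fit
  attr(res, "observations") <- obs
  res
}

#' Close every gap of a draft genome
#'
#' Gaps are processed independently (optionally across `config$threads`
#' forked workers; the result is identical for any worker count because each
#' gap's computation is self-contained and deterministic) and spliced into
#' the draft. Gaps whose N-run touches a scaffold end are left untouched
#' (no second flank). A gap raising an internal error is logged, reported
#' as unfilled, and the run continues.
#'
#' @param draft Named character vector of scaffolds (or FASTA path).
#' @param libraries As in [close_gap()]; profiles may be omitted, in which
#'   case they are estimated from the alignments via
#'   [estimate_insert_stats()].
#' @param config A [run_config()].
#' @param dir Optional output directory for
#'   [write_result_genome()] artifacts.
#' @return A list: `genome` (spliced scaffolds), `report` (per-gap
#'   data.frame), `gaps`, `results` (list of `gap_result`).
#' @export
close_all_gaps <- function(draft, libraries, config = run_config(),
                           dir = NULL) {
  if (length(draft) == 1 && is.null(names(draft)) && file.exists(draft[1]))
    draft <- read_fasta(draft)
  for (k in seq_along(libraries)) {
    if (is.null(libraries[[k]]$profile))
      libraries[[k]]$profile <- estimate_insert_stats(libraries[[k]]$pairs)
  }
  gaps <- find_gaps(draft)
  if (nrow(gaps)) {
    lens <- nchar(draft)[gaps$scaffold]
    interior <- gaps$start > 0 & gaps$end < lens
    gaps <- gaps[interior, , drop = FALSE]
  }
  if (!nrow(gaps))
    return(list(genome = draft, report = data.frame(), gaps = gaps,
                results = list()))
  worker <- function(k) {
    tryCatch(
      close_gap(gaps[k, , drop = FALSE], draft[[gaps$scaffold[k]]],
                libraries, config),
      error = function(e) structure(
        list(status = "unfilled", sequence = "", qualities = "",
             filled_length = 0, n_reads = NA_real_,
             n_observations = NA_real_, n_outliers = NA_real_,
             dropped = character(0), note = conditionMessage(e)),
        class = "gap_result"))
  }
  idx <- seq_len(nrow(gaps))
  results <- if (config$threads > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, worker, mc.cores = config$threads,
                       mc.preschedule = TRUE)
  } else {
    lapply(idx, worker)
  }
  out <- write_result_genome(draft, gaps, results, dir = dir)
  c(out, list(gaps = gaps, results = results))
}

#' Place reads on a genome by exact matching
#'
#' A minimal internal mapper for iterative closing: each read (and its
#' reverse complement) is searched for exact full-length occurrences with
#' `Biostrings::matchPDict`; reads with exactly one hit across both strands
#' are placed with MAPQ 60, reads with several hits are treated as
#' multi-mapped (MAPQ 0), and unmatched reads are unmapped. Suitable for
#' error-free reads (every simulated read with `err_rate = 0` relocates
#' exactly); for real data supply mapper-produced SAM instead.
#'
#' @param genome Named character vector of scaffolds.
#' @param reads Data.frame with `id` (`.../1`, `.../2` suffixes), `seq`,
#'   `qual` (as sequenced).
#' @return A data.frame in [read_alignments()] layout.
#' @export
place_reads_exact <- function(genome, reads) {
  n <- nrow(reads)
  res <- data.frame(qname = sub("/[12]$", "", reads$id),
                    mate = ifelse(grepl("/2$", reads$id), 2L, 1L),
                    mapped = FALSE, rname = NA_character_,
                    pos = NA_integer_, strand = NA_character_, mapq = 0L,
                    seq = reads$seq, qual = reads$qual,
                    stringsAsFactors = FALSE)
  widths <- nchar(reads$seq)
  for (w in unique(widths)) {
    sel <- which(widths == w)
    fwd <- Biostrings::DNAStringSet(reads$seq[sel])
    rev <- Biostrings::reverseComplement(fwd)
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(rev)
    hits <- vector("list", length(sel))
    for (sc in names(genome)) {
      subj <- Biostrings::DNAString(genome[[sc]])
      mf <- Biostrings::matchPDict(pd_f, subj)
      mr <- Biostrings::matchPDict(pd_r, subj)
      for (t in seq_along(sel)) {
        sf <- Biostrings::startIndex(mf)[[t]]
        sr <- Biostrings::startIndex(mr)[[t]]
        if (length(sf)) hits[[t]] <- rbind(hits[[t]],
          data.frame(rname = sc, pos = sf - 1L, strand = "+"))
        if (length(sr)) hits[[t]] <- rbind(hits[[t]],
          data.frame(rname = sc, pos = sr - 1L, strand = "-"))
      }
    }
    for (t in seq_along(sel)) {
      h <- hits[[t]]
      if (is.null(h) || !nrow(h)) next
      k <- sel[t]
      res$mapped[k] <- TRUE
      res$rname[k] <- h$rname[1]
      res$pos[k] <- h$pos[1]
      res$strand[k] <- h$strand[1]
      res$mapq[k] <- if (nrow(h) == 1) 60L else 0L
      if (h$strand[1] == "-") { # SAM convention: store forward-strand bases
        res$seq[k] <- revcomp(reads$seq[k])
        res$qual[k] <- paste(rev(strsplit(reads$qual[k], "")[[1]]),
                             collapse = "")
      }
    }
  }
  res
}

#' Iterative gap closing
#'
#' Runs [close_all_gaps()] for up to `config$iterations` rounds, re-deriving
#' gaps and read placements from the current genome each round; stops early
#' when a round neither closes nor extends any gap. Round 1 can use supplied
#' alignments; later rounds re-place the library reads with
#' [place_reads_exact()] (or a user-supplied `placer` function taking the
#' current genome and a library and returning a [read_alignments()]-style
#' data.frame).
#'
#' @param draft Named character vector of scaffolds.
#' @param libraries List of libraries: each a list with `reads` (data.frame
#'   `id`, `seq`, `qual`; both mates), `profile`, optionally `pairs` for
#'   round 1 and `id`.
#' @param config A [run_config()].
#' @param placer Placement function for rounds without `pairs`
#'   (default [place_reads_exact()]).
#' @return List: `genome`, `rounds_used`, `reports` (per-round), `closed`
#'   (cumulative closed-gap count per round).
#' @export
iterate_closing <- function(draft, libraries, config = run_config(),
                            placer = place_reads_exact) {
  genome <- draft
  reports <- list()
  closed_cum <- integer(0)
  total_closed <- 0L
  for (round in seq_len(config$iterations)) {
    libs <- lapply(libraries, function(lb) {
      if (round == 1 && !is.null(lb$pairs)) return(lb)
      stopifnot(!is.null(lb$reads))
      aln <- placer(genome, lb$reads)
      lb$pairs <- pair_alignments(aln)
      lb
    })
    res <- close_all_gaps(genome, libs, config)
    reports[[round]] <- res$report
    n_closed <- sum(res$report$status == "closed")
    n_ext <- sum(res$report$status %in% c("left_extended", "right_extended"))
    total_closed <- total_closed + n_closed
    closed_cum <- c(closed_cum, total_closed)
    genome <- res$genome
    if (n_closed + n_ext == 0) break
  }
  list(genome = genome, rounds_used = length(reports), reports = reports,
       closed = closed_cum)
}
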