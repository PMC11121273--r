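#' Parameters for runs-of-homozygosity detection
#'
#' Defaults are tuned to sparse GBS panels (~20 markers/Mb): the scanning
#' window and the minimum SNP count per run are far smaller than the classic
#' array-density PLINK defaults, because a 1 Mb run — the shortest length of
#' interest — carries only ~20 GBS markers. All values are configurable.
#'
#' @param min_length_bp minimum physical span of a reported run.
#' @param min_snps minimum marker count in a run.
#' @param max_het_in_run maximum heterozygous calls tolerated inside one run.
#' @param max_missing_in_run maximum missing calls tolerated inside one
#'   scanning window.
#' @param max_gap_bp adjacent-marker gap above which a run is split.
#' @param window_snps scanning-window size in markers.
#' @param window_het_allowance heterozygous calls tolerated per window.
#' @param window_overlap_frac a marker is run-eligible when more than this
#'   fraction of the windows overlapping it are homozygous-compatible.
#' @param autosome_length_kb total autosomal genome length L (Kb) used by
#'   [froh()]; the default is the donkey autosome complement,
#'   2,302,664.694 Mb-equivalent Kb.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_length_bp = 1e6, min_snps = 15,
                       max_het_in_run = 1, max_missing_in_run = 3,
                       max_gap_bp = 1e6, window_snps = 20,
                       window_het_allowance = 1,
                       window_overlap_frac = 0.05,
                       autosome_length_kb = 2302664.694) {
  stopifnot(min_length_bp > 0, min_snps >= 1, max_het_in_run >= 0,
            max_missing_in_run >= 0, max_gap_bp > 0, window_snps >= 1,
            window_het_allowance >= 0, autosome_length_kb > 0)
  structure(list(min_length_bp = min_length_bp, min_snps = min_snps,
                 max_het_in_run = max_het_in_run,
                 max_missing_in_run = max_missing_in_run,
                 max_gap_bp = max_gap_bp, window_snps = window_snps,
                 window_het_allowance = window_het_allowance,
                 window_overlap_frac = window_overlap_frac,
                 autosome_length_kb = autosome_length_kb),
            class = "roh_params")
}

# window-vote eligibility of each marker on one chromosome
roh_eligible <- function(het, miss, params) {
  m <- length(het)
  w <- min(params$window_snps, m)
  nwin <- m - w + 1L
  ch <- cumsum(c(0L, het))
  cm <- cumsum(c(0L, miss))
  starts <- seq_len(nwin)
  ok <- (ch[starts + w] - ch[starts]) <= params$window_het_allowance &
        (cm[starts + w] - cm[starts]) <= params$max_missing_in_run
  cok <- cumsum(c(0L, ok))
  j <- seq_len(m)
  lo <- pmax(j - w + 1L, 1L)
  hi <- pmin(j, nwin)
  n_ok <- cok[hi + 1L] - cok[lo]
  (n_ok / (hi - lo + 1L)) > params$window_overlap_frac
}

#' Detect runs of homozygosity for one sample
#'
#' PLINK-style two-stage scan over the autosomal markers of one individual,
#' chromosome by chromosome. Stage 1 slides a window of `window_snps`
#' markers and calls a window homozygous-compatible when it contains at most
#' `window_het_allowance` heterozygous and `max_missing_in_run` missing
#' calls; a marker is eligible when more than `window_overlap_frac` of the
#' windows overlapping it are compatible. Stage 2 takes maximal stretches of
#' eligible markers, splits them wherever two adjacent markers are more than
#' `max_gap_bp` apart, then splits greedily (left to right) wherever a
#' heterozygous call would push a run past `max_het_in_run`, trims each run
#' so it begins and ends on a called homozygous marker, and reports runs
#' holding at least `min_snps` markers and spanning at least
#' `min_length_bp`. Run bounds are the first and last marker positions
#' (inclusive), so on sparse panels they are accurate only to the local
#' marker spacing.
#'
#' @param gm a [genotype_matrix()]; variants must be position-sorted within
#'   chromosomes (enforced by the class).
#' @param sample_id sample to scan.
#' @param params a [roh_params()].
#' @param autosomes chromosome labels scanned (non-autosomal markers are
#'   ignored).
#' @return A data.frame of runs: `sample_id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_bp`.
#' @export
detect_roh <- function(gm, sample_id, params = roh_params(),
                       autosomes = as.character(1:30)) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(params, "roh_params"))
  si <- match(sample_id, gm$samples$id)
  if (is.na(si)) stop("unknown sample id: ", sample_id)
  out <- list()
  for (ch in intersect(unique(gm$variants$chrom), autosomes)) {
    vi <- which(gm$variants$chrom == ch)
    dos <- gm$dosage[si, vi]
    pos <- gm$variants$pos[vi]
    het <- !is.na(dos) & dos == 1L
    miss <- is.na(dos)
    elig <- roh_eligible(het, miss, params)
    if (!any(elig)) next
    # maximal eligible stretches, split at large physical gaps
    r <- rle(elig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (b in which(r$values)) {
      seg_idx <- starts[b]:ends[b]
      gaps <- diff(pos[seg_idx])
      cut <- which(gaps > params$max_gap_bp)
      pieces <- split(seg_idx,
                      cumsum(c(0L, as.integer(seq_along(gaps) %in% cut))))
      for (pc in pieces) {
        for (run in split_het_budget(pc, het, params$max_het_in_run)) {
          run <- trim_run_ends(run, het, miss)
          if (length(run) < params$min_snps) next
          span <- pos[run[length(run)]] - pos[run[1]] + 1
          if (span < params$min_length_bp) next
          out[[length(out) + 1L]] <- data.frame(
            sample_id = sample_id, chrom = ch,
            start_bp = pos[run[1]], end_bp = pos[run[length(run)]],
            n_snps = length(run), length_bp = span,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else empty_roh()
}

# greedy left-to-right split of a marker-index run so that each sub-run
# carries at most `budget` heterozygous calls; the het that would exceed the
# budget is dropped and a fresh sub-run starts after it
split_het_budget <- function(idx, het, budget) {
  runs <- list()
  cur <- integer(0)
  count <- 0L
  for (j in idx) {
    if (het[j] && count == budget) {
      if (length(cur)) runs[[length(runs) + 1L]] <- cur
      cur <- integer(0)
      count <- 0L
    } else {
      if (het[j]) count <- count + 1L
      cur <- c(cur, j)
    }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  runs
}

# runs must begin and end on called homozygous markers
trim_run_ends <- function(run, het, miss) {
  bad <- het[run] | miss[run]
  if (all(bad)) return(integer(0))
  run[min(which(!bad)):max(which(!bad))]
}

empty_roh <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             start_bp = numeric(0), end_bp = numeric(0),
             n_snps = integer(0), length_bp = numeric(0),
             stringsAsFactors = FALSE)
}

#' Detect runs of homozygosity for every sample
#'
#' @inheritParams detect_roh
#' @return Row-bound output of [detect_roh()] over all samples.
#' @export
detect_roh_all <- function(gm, params = roh_params(),
                           autosomes = as.character(1:30)) {
  segs <- lapply(gm$samples$id, function(id)
    detect_roh(gm, id, params = params, autosomes = autosomes))
  do.call(rbind, c(segs, make.row.names = FALSE))
}

#' ROH-based genomic inbreeding coefficient
#'
#' `F_ROH = sum_k length(ROH_k) / L`: the fraction of the autosomal genome
#' (length `L`, in Kb) lying inside an individual's runs of homozygosity.
#'
#' @param segments ROH table for one sample (as from [detect_roh()]); may be
#'   empty.
#' @param L autosomal genome length in Kb (donkey default 2,302,664.694 Kb).
#' @return A list with `sample_id`, `n_segments`, `total_roh_length_kb` and
#'   `froh`.
#' @export
froh <- function(segments, L = 2302664.694) {
  if (L <= 0) stop("autosome length L must be positive")
  if (nrow(segments) && length(unique(segments$sample_id)) > 1)
    stop("froh expects segments of a single sample")
  total_kb <- sum(segments$length_bp) / 1000
  list(sample_id = if (nrow(segments)) segments$sample_id[1] else NA_character_,
       n_segments = nrow(segments),
       total_roh_length_kb = total_kb,
       froh = total_kb / L)
}

#' Per-sample F_ROH table
#'
#' @param segments pooled ROH table (as from [detect_roh_all()]).
#' @param sample_ids all sample ids (so animals without any run get
#'   `froh = 0`).
#' @param L autosomal genome length in Kb.
#' @return A data.frame with `sample_id`, `n_segments`,
#'   `total_roh_length_kb`, `froh`.
#' @export
froh_all <- function(segments, sample_ids, L = 2302664.694) {
  rows <- lapply(sample_ids, function(id)
    as.data.frame(froh(segments[segments$sample_id == id, , drop = FALSE],
                       L = L))[-1])
  out <- cbind(data.frame(sample_id = sample_ids, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Population summaries of detected ROH
#'
#' @param segments pooled ROH table.
#' @param sample_ids sample ids of the analyzed population.
#' @param L autosomal genome length in Kb.
#' @param bin_edges_mb run-length bin edges in Mb (right-open bins, last bin
#'   open-ended).
#' @param indiv_bin_mb width (Mb) of the per-individual total-ROH-length
#'   histogram bins.
#' @return A list with `n_segments`, `mean_length_mb`, `length_bins`
#'   (data.frame bin/count/proportion), `per_chromosome` counts,
#'   `per_individual` (total-length histogram over samples) and `froh`
#'   (the [froh_all()] table).
#' @export
roh_summaries <- function(segments, sample_ids, L = 2302664.694,
                          bin_edges_mb = c(1, 5, 10, Inf),
                          indiv_bin_mb = 5) {
  stopifnot(length(bin_edges_mb) >= 2)
  len_mb <- segments$length_bp / 1e6
  bins <- cut(len_mb, breaks = bin_edges_mb, right = FALSE,
              include.lowest = FALSE)
  length_bins <- as.data.frame(table(bins), stringsAsFactors = FALSE)
  names(length_bins) <- c("bin", "count")
  length_bins$proportion <- if (nrow(segments))
    length_bins$count / nrow(segments) else 0

  per_chrom <- if (nrow(segments)) {
    tb <- as.data.frame(table(segments$chrom), stringsAsFactors = FALSE)
    names(tb) <- c("chrom", "count")
    tb
  } else data.frame(chrom = character(0), count = integer(0),
                    stringsAsFactors = FALSE)

  fr <- froh_all(segments, sample_ids, L = L)
  tot_mb <- fr$total_roh_length_kb / 1000
  max_bin <- max(indiv_bin_mb, ceiling(max(c(tot_mb, 0)) / indiv_bin_mb) *
                   indiv_bin_mb)
  ibins <- cut(tot_mb, breaks = seq(0, max_bin, by = indiv_bin_mb),
               right = FALSE, include.lowest = TRUE)
  per_individual <- as.data.frame(table(total_roh_mb = ibins),
                                  stringsAsFactors = FALSE)
  names(per_individual) <- c("total_roh_mb", "n_individuals")

  list(n_segments = nrow(segments),
       mean_length_mb = if (nrow(segments)) mean(len_mb) else 0,
       length_bins = length_bins,
       per_chromosome = per_chrom,
       per_individual = per_individual,
       froh = fr)
}
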