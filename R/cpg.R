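# Promoter windows, CpG-island detection, CpG density and in-silico
# bisulfite conversion.

#' Extract a strand-aware 2 kb promoter window
#'
#' Returns the `[tss - 1000, tss + 1000)` window (0-based, half-open) around
#' a transcription start site. On the minus strand the reverse complement is
#' returned, so upstream sequence is always to the left of the TSS in the
#' returned window.
#'
#' @param fasta Path to a FASTA file or a [Biostrings::DNAStringSet].
#' @param gene Gene symbol to attach to the record.
#' @param chrom Contig name (must be present in `fasta`).
#' @param tss 0-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @param flank Half-window size in bp; default 1000.
#' @return A one-row tibble: `gene`, `chrom`, `tss`, `strand`, `sequence`.
#' @export
extract_promoter_window <- function(fasta, gene, chrom, tss, strand = "+",
                                    flank = 1000L) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!chrom %in% names(seqs)) {
    abort(paste0("contig not found in reference: ", chrom),
          class = "methcascade_validation_error")
  }
  contig <- seqs[[chrom]]
  start0 <- tss - flank
  end0 <- tss + flank
  if (start0 < 0 || end0 > length(contig)) {
    abort(paste0("promoter window [", start0, ", ", end0, ") for ", gene,
                 " falls outside contig ", chrom, " (length ",
                 length(contig), ")"),
          class = "methcascade_validation_error")
  }
  window <- Biostrings::subseq(contig, start = start0 + 1L, end = end0)
  if (strand == "-") window <- Biostrings::reverseComplement(window)
  tibble::tibble(gene = gene, chrom = chrom, tss = as.integer(tss),
                 strand = strand, sequence = as.character(window))
}

# base-composition indicator vectors; N never counts toward GC or CpG
seq_indicators <- function(seq) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(x) > 0 && !all(x %in% c("A", "C", "G", "T", "N"))) {
    abort("sequence must be over the alphabet {A, C, G, T, N}",
          class = "methcascade_validation_error")
  }
  is_c <- x == "C"
  is_g <- x == "G"
  n <- length(x)
  is_cpg <- if (n > 1) is_c[-n] & is_g[-1] else logical(0)
  list(n = n, is_c = is_c, is_g = is_g, is_cpg = is_cpg)
}

# threshold test shared by all segment checks: GC fraction and obs/exp CpG.
# obs_exp = #CpG * L / (#C * #G), defined as 0 when #C * #G == 0.
segment_qualifies <- function(n_c, n_g, n_cpg, len, gc_min, oe_min) {
  gc_ok <- (n_c + n_g) >= gc_min * len
  prod <- n_c * n_g
  oe_ok <- ifelse(prod > 0, n_cpg * len >= oe_min * prod, oe_min <= 0)
  gc_ok & oe_ok
}

#' Detect CpG islands in a sequence
#'
#' Finds CpG islands defined by three thresholds: minimum length, minimum
#' GC fraction, and minimum observed/expected CpG ratio
#' (`#CpG * L / (#C * #G)` for a segment of length `L`). The defaults
#' (500 bp, 50% GC, obs/exp 0.6) follow the classical island definition of
#' a region longer than 500 bp rich in CG dinucleotides, augmented with the
#' standard obs/exp criterion that separates true CpG islands from merely
#' GC-rich sequence.
#'
#' Algorithm: every window of exactly `min_length` bases is tested; the
#' qualifying windows are merged into maximal segments (overlapping or
#' adjacent windows coalesce); each merged segment is re-checked against
#' all three thresholds. A merged segment that fails the re-check is split
#' recursively: its longest qualifying sub-segment (leftmost on ties) is
#' emitted and the flanks on either side are processed the same way.
#' Emitted islands are therefore pairwise disjoint and each satisfies all
#' three thresholds. `N` bases count toward segment length but never
#' toward GC or CpG.
#'
#' @param seq A single DNA sequence (string over A/C/G/T/N).
#' @param min_length Minimum island length in bp; default 500.
#' @param gc_min Minimum GC fraction; default 0.5.
#' @param oe_min Minimum observed/expected CpG ratio; default 0.6.
#' @return A tibble with 0-based half-open `start`, `end`, plus
#'   `gc_fraction` and `obs_exp` per island.
#' @export
#' @examples
#' find_cpg_islands(strrep("CG", 300))   # one island [0, 600), obs/exp 2
find_cpg_islands <- function(seq, min_length = 500L, gc_min = 0.5,
                             oe_min = 0.6) {
  empty <- tibble::tibble(start = integer(), end = integer(),
                          gc_fraction = double(), obs_exp = double())
  ind <- seq_indicators(seq)
  n <- ind$n
  w <- as.integer(min_length)
  if (n < w || w < 1) return(empty)

  cum_c <- c(0L, cumsum(ind$is_c))
  cum_g <- c(0L, cumsum(ind$is_g))
  cum_cpg <- c(0L, cumsum(ind$is_cpg))

  # counts over [i, i+w) for 0-based starts 0 .. n-w
  starts <- 0:(n - w)
  n_c <- cum_c[starts + w + 1L] - cum_c[starts + 1L]
  n_g <- cum_g[starts + w + 1L] - cum_g[starts + 1L]
  # CpG dinucleotides fully inside the window start at i .. i+w-2
  n_cpg <- cum_cpg[starts + w] - cum_cpg[starts + 1L]
  ok <- segment_qualifies(n_c, n_g, n_cpg, w, gc_min, oe_min)
  seeds <- starts[ok]
  if (length(seeds) == 0) return(empty)

  merged <- IRanges::reduce(IRanges::IRanges(start = seeds + 1L, width = w))
  segment_counts <- function(a, b) { # 0-based half-open [a, b)
    len <- b - a
    c_cnt <- cum_c[b + 1L] - cum_c[a + 1L]
    g_cnt <- cum_g[b + 1L] - cum_g[a + 1L]
    cpg_cnt <- if (len > 1) cum_cpg[b] - cum_cpg[a + 1L] else 0L
    list(c = c_cnt, g = g_cnt, cpg = cpg_cnt, len = len)
  }

  # longest qualifying sub-segment of [a, b), leftmost on ties; NULL if none
  best_subsegment <- function(a, b) {
    if (b - a < w) return(NULL)
    for (len in seq(b - a, w)) {
      for (s in a:(b - len)) {
        cs <- segment_counts(s, s + len)
        if (segment_qualifies(cs$c, cs$g, cs$cpg, len, gc_min, oe_min)) {
          return(c(s, s + len))
        }
      }
    }
    NULL
  }
  # emit the best sub-segment, then process the flanks recursively
  split_component <- function(a, b) {
    hit <- best_subsegment(a, b)
    if (is.null(hit)) return(NULL)
    unname(rbind(split_component(a, hit[1]), hit,
                 split_component(hit[2], b)))
  }

  out <- purrr::map(seq_along(merged), function(i) {
    a <- IRanges::start(merged)[i] - 1L
    b <- IRanges::end(merged)[i]
    segs <- split_component(a, b)
    if (is.null(segs)) return(NULL)
    purrr::map(seq_len(nrow(segs)), function(j) {
      cnt <- segment_counts(segs[j, 1], segs[j, 2])
      prod <- cnt$c * cnt$g
      tibble::tibble(
        start = as.integer(segs[j, 1]), end = as.integer(segs[j, 2]),
        gc_fraction = (cnt$c + cnt$g) / cnt$len,
        obs_exp = if (prod > 0) cnt$cpg * cnt$len / prod else 0
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$start)
}

#' CpG density of a promoter window
#'
#' Percent of the promoter window covered by the union of its CpG islands:
#' `100 * covered_bases / window_length`.
#'
#' @param islands Tibble with 0-based half-open `start`, `end` (as returned
#'   by [find_cpg_islands()]).
#' @param window_length Window size in bp; default 2000.
#' @return A single percentage in `[0, 100]`.
#' @export
cpg_density <- function(islands, window_length = 2000L) {
  islands <- tibble::as_tibble(islands)
  if (nrow(islands) == 0) return(0)
  if (any(islands$start < 0) || any(islands$end > window_length) ||
      any(islands$end <= islands$start)) {
    abort("islands must lie within [0, window_length)",
          class = "methcascade_validation_error")
  }
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = islands$start + 1L, end = islands$end)
  )))
  100 * covered / window_length
}

#' In-silico bisulfite conversion
#'
#' Bisulfite treatment deaminates unmethylated cytosine to uracil (read as
#' T after PCR) while 5-methylcytosine is protected. With
#' `methylated_cpg = TRUE` every C immediately followed by G (the CpG
#' context, where methylation resides) is preserved and all other Cs become
#' T; with `methylated_cpg = FALSE` every C becomes T.
#'
#' @param seq Character vector of DNA sequences over A/C/G/T/N.
#' @param methylated_cpg Logical; is CpG cytosine methylated (protected)?
#' @return The converted sequence(s).
#' @export
#' @examples
#' bisulfite_convert("ACGTCC", methylated_cpg = TRUE)   # "ACGTTT"
#' bisulfite_convert("ACGTCC", methylated_cpg = FALSE)  # "ATGTTT"
bisulfite_convert <- function(seq, methylated_cpg = FALSE) {
  seq <- toupper(seq)
  if (any(grepl("[^ACGTN]", seq))) {
    abort("sequence must be over the alphabet {A, C, G, T, N}",
          class = "methcascade_validation_error")
  }
  if (methylated_cpg) {
    gsub("C(?!G)", "T", seq, perl = TRUE)
  } else {
    chartr("C", "T", seq)
  }
}

#' Islands and CpG density for a set of promoter sequences
#'
#' Convenience wrapper running [find_cpg_islands()] and [cpg_density()] per
#' gene over a promoter table.
#'
#' @param promoters Tibble with `gene` and `sequence` columns (e.g. from
#'   [simulate_promoters()]`$sequences` or [read_promoter_fasta()]).
#' @param min_length,gc_min,oe_min Island thresholds, see
#'   [find_cpg_islands()].
#' @return A list with `islands` (per-gene island tibble) and `densities`
#'   (tibble: `gene`, `cpg_density_percent`).
#' @export
scan_promoters <- function(promoters, min_length = 500L, gc_min = 0.5,
                           oe_min = 0.6) {
  promoters <- tibble::as_tibble(promoters)
  islands <- promoters |>
    dplyr::mutate(islands = purrr::map(.data$sequence, find_cpg_islands,
                                       min_length = min_length,
                                       gc_min = gc_min, oe_min = oe_min)) |>
    dplyr::select("gene", "islands")
  densities <- islands |>
    dplyr::mutate(
      window = nchar(promoters$sequence),
      cpg_density_percent = purrr::map2_dbl(
        .data$islands, .data$window, cpg_density
      )
    ) |>
    dplyr::select("gene", "cpg_density_percent")
  list(islands = tidyr::unnest(islands, "islands"), densities = densities)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA file; record names are taken as gene symbols.
#' @return A tibble with `gene` and `sequence`.
#' @export
read_promoter_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble::tibble(gene = sub("\\s.*$", "", names(seqs)),
                 sequence = as.character(seqs))
}

#' Write detected islands as BED
#'
#' @param islands Tibble with `gene`, `start`, `end` (0-based half-open,
#'   window coordinates).
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
write_islands_bed <- function(islands, path) {
  bed <- tibble::tibble(
    chrom = islands$gene,
    start = islands$start,
    end = islands$end,
    name = sprintf("CpG_island_%d", seq_len(nrow(islands))),
    score = 0L,
    strand = "+"
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
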