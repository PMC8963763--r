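# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's prefix-sum / vectorised code paths: counting is done
# per substring, merging by an explicit loop.

oracle_segment_qualifies <- function(s, gc_min, oe_min) {
  L <- nchar(s)
  nc <- stringr::str_count(s, "C")
  ng <- stringr::str_count(s, "G")
  ncpg <- stringr::str_count(s, "CG")
  gc_ok <- (nc + ng) >= gc_min * L
  oe_ok <- ifelse(nc * ng > 0, ncpg * L >= oe_min * nc * ng, oe_min <= 0)
  gc_ok & oe_ok
}

oracle_find_islands <- function(seq, min_length = 500, gc_min = 0.5,
                                oe_min = 0.6) {
  empty <- tibble::tibble(start = integer(), end = integer(),
                          gc_fraction = double(), obs_exp = double())
  n <- nchar(seq)
  w <- min_length
  if (n < w) return(empty)
  starts <- 0:(n - w)
  wins <- substring(seq, starts + 1, starts + w)
  seeds <- starts[oracle_segment_qualifies(wins, gc_min, oe_min)]
  if (length(seeds) == 0) return(empty)

  segs <- list()
  cur <- c(seeds[1], seeds[1] + w)
  for (s in seeds[-1]) {
    if (s <= cur[2]) cur[2] <- s + w
    else {
      segs <- c(segs, list(cur))
      cur <- c(s, s + w)
    }
  }
  segs <- c(segs, list(cur))

  oracle_best <- function(a, b) {
    if (b - a < w) return(NULL)
    for (len in seq(b - a, w)) {
      for (s2 in a:(b - len)) {
        if (oracle_segment_qualifies(substring(seq, s2 + 1, s2 + len),
                                     gc_min, oe_min)) {
          return(c(s2, s2 + len))
        }
      }
    }
    NULL
  }
  oracle_split <- function(a, b) {
    hit <- oracle_best(a, b)
    if (is.null(hit)) return(NULL)
    unname(rbind(oracle_split(a, hit[1]), hit, oracle_split(hit[2], b)))
  }

  rows <- lapply(segs, function(ab) {
    pieces <- oracle_split(ab[1], ab[2])
    if (is.null(pieces)) return(NULL)
    dplyr::bind_rows(lapply(seq_len(nrow(pieces)), function(j) {
      a <- pieces[j, 1]; b <- pieces[j, 2]
      sub <- substring(seq, a + 1, b)
      L <- b - a
      nc <- stringr::str_count(sub, "C")
      ng <- stringr::str_count(sub, "G")
      ncpg <- stringr::str_count(sub, "CG")
      tibble::tibble(start = a, end = b,
                     gc_fraction = (nc + ng) / L,
                     obs_exp = if (nc * ng > 0) ncpg * L / (nc * ng) else 0)
    }))
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$start), ]
}

# random iid sequence with a given GC fraction
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# small annotated BW fixture: long tibble with given probe x sample values
make_bw_fixture <- function(values, formula = "literal_quotient",
                            region_of_probe = NULL, gene_of_region = NULL) {
  probes <- rownames(values)
  samples <- colnames(values)
  region_of_probe <- region_of_probe %||% setNames(probes, probes)
  tbl <- tibble::tibble(
    probe_id = rep(probes, times = ncol(values)),
    region_id = rep(unname(region_of_probe[probes]), times = ncol(values)),
    sample_id = rep(samples, each = nrow(values)),
    bw = as.vector(values)
  )
  if (!is.null(gene_of_region)) {
    tbl$gene <- unname(gene_of_region[tbl$region_id])
  } else {
    tbl$gene <- tbl$region_id
  }
  attr(tbl, "bw_formula") <- formula
  tbl
}

`%||%` <- rlang::`%||%`
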