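# Independent oracles used across the suite. These deliberately re-derive
# results by enumeration / brute force, never by calling the code paths they
# check.

# Brute-force pairwise overlap counter (1-based closed coordinates).
oracle_count_overlaps <- function(query, subject, min_overlap = 1L) {
  qs <- GenomicRanges::start(query); qe <- GenomicRanges::end(query)
  qc <- as.character(GenomicRanges::seqnames(query))
  ss <- GenomicRanges::start(subject); se <- GenomicRanges::end(subject)
  sc <- as.character(GenomicRanges::seqnames(subject))
  vapply(seq_along(query), function(i) {
    ov <- pmin(qe[i], se) - pmax(qs[i], ss) + 1L
    sum(sc == qc[i] & ov >= min_overlap)
  }, integer(1))
}

# Exhaustive greedy-backtracking enumerator for the quadparser pattern
# (G{g,} loop{lmin,lmax}){k,} G{g,}. Replicates the priority order of a
# backtracking regex engine explicitly: prefer one more group iteration over
# exiting; within an iteration prefer longer G-runs, then longer loops; the
# trailing G-run is maximal. Finds leftmost non-overlapping matches,
# resuming after each match end.
oracle_g4_scan <- function(seq, params) {
  n <- nchar(seq)
  y <- charToRaw(toupper(seq))
  isG <- y == as.raw(71L)
  # grun[i]: remaining G-run length starting at i (0 off-run)
  r <- rle(isG)
  grun <- integer(n)
  ends <- cumsum(r$lengths)
  gi <- which(r$values)
  if (length(gi))
    grun[unlist(lapply(gi, function(j) (ends[j] - r$lengths[j] + 1L):ends[j]))] <-
      unlist(lapply(r$lengths[gi], function(L) L:1L))
  g <- params$g_run_min; lmin <- params$loop_min; lmax <- params$loop_max
  K <- params$n_runs - 1L
  # memo[pos, jcap+1]: 0 unknown, -1 fail, else match end
  memo <- matrix(0L, nrow = n + 1L, ncol = K + 1L)
  rec <- function(pos, jcap) {
    if (pos > n) return(-1L)
    m <- memo[pos, jcap + 1L]
    if (m != 0L) return(m)
    res <- -1L
    if (grun[pos] >= g) {
      # priority 1: one more (G-run, loop) iteration, greedy in both parts
      for (t in grun[pos]:g) {
        base <- pos + t
        for (l in lmax:lmin) {
          if (base + l > n) next
          r <- rec(base + l, min(jcap + 1L, K))
          if (r > 0L) { res <- r; break }
        }
        if (res > 0L) break
      }
      # priority 2: exit the loop and take the maximal trailing G-run
      if (res < 0L && jcap >= K) res <- pos + grun[pos] - 1L
    }
    memo[pos, jcap + 1L] <<- res
    res
  }
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (grun[i] >= g) {
      e <- rec(i, 0L)
      if (e > 0L) {
        starts <- c(starts, i); ends <- c(ends, e)
        # finditer semantics: resume after the match end (memoized states
        # stay valid; they never encode the non-overlap constraint)
        i <- e + 1L
        next
      }
    }
    i <- i + 1L
  }
  data.frame(start = starts, end = ends)
}

# Both-strand motif table via the enumerator, matching the layout of
# find_g4_motifs (start/end/strand only).
oracle_g4_both <- function(seq, params) {
  n <- nchar(seq)
  plus <- oracle_g4_scan(seq, params)
  if (nrow(plus)) plus$strand <- "+"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  minus <- oracle_g4_scan(rc, params)
  if (nrow(minus)) {
    minus <- data.frame(start = n - minus$end + 1L, end = n - minus$start + 1L,
                        strand = "-")
  }
  parts <- Filter(nrow, list(plus, minus))
  if (length(parts) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  out <- do.call(rbind, parts)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact binomial tails by direct summation of the mass function.
oracle_binom_tails <- function(n, k, p) {
  mass <- vapply(0:n, function(x) choose(n, x) * p^x * (1 - p)^(n - x),
                 numeric(1))
  list(lower = sum(mass[seq_len(k + 1)]),
       upper = sum(mass[(k + 1):(n + 1)]))
}
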