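# in-code fixtures shared across test files

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force two-sided Fisher oracle: exhaustive enumeration of all tables
# with the observed margins via log-binomial coefficients (independent of the
# package's dhyper-based implementation)
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  xs <- max(0, k - m2):min(k, m1)
  p <- exp(lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(m1 + m2, k))
  sum(p[p <= p[a - xs[1] + 1] * (1 + 1e-7)])
}

# a 60-bp toy reference with a C at forward position 30 and a G at 40,
# written fresh into tempdir each run
tiny_reference <- function() {
  path <- file.path(tempdir(), "tiny_ref.fa")
  seq60 <- paste(rep("ACGTTGCAGT", 6), collapse = "")
  seq60 <- paste0(substr(seq60, 1, 29), "C", substr(seq60, 31, 39), "G",
                  substr(seq60, 41, 60))
  writeLines(c(">tiny", seq60), path)
  path
}

tiny_site <- function(strand = "+", position = if (strand == "+") 30L else 40L) {
  site_catalog(tibble::tibble(
    site_id = paste0("toy-C", position), chrom = "tiny",
    position = position, strand = strand, gene = "toy",
    codon_number = as.integer(position / 3), codon_position = 1L
  ))
}

# hand-built SAM: reads fully aligned to `tiny`, with a chosen base (and
# optionally base quality) at a chosen position
tiny_sam <- function(path, bases_at, position, quals = NULL, mapq = 60L,
                     cigars = NULL, starts = NULL) {
  ref <- readLines(tiny_reference())[2]
  n <- length(bases_at)
  starts <- starts %||% rep(max(1L, position - 20L), n)
  rlen <- 25L
  cigars <- cigars %||% rep(paste0(rlen, "M"), n)
  seqs <- vapply(seq_len(n), function(i) {
    s <- substr(ref, starts[i], starts[i] + rlen - 1L)
    at <- position - starts[i] + 1L
    if (at >= 1 && at <= rlen) substr(s, at, at) <- bases_at[i]
    s
  }, "")
  qual <- vapply(seq_len(n), function(i) {
    q <- rep("I", rlen)  # Q40
    if (!is.null(quals)) {
      at <- position - starts[i] + 1L
      q[at] <- quals[i]
    }
    paste(q, collapse = "")
  }, "")
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:tiny\tLN:60",
    sprintf("r%03d\t0\ttiny\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            seq_len(n), starts, mapq, cigars, seqs, qual)
  )
  writeLines(lines, path)
  path
}
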