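# Shared fixtures, built in code.

## A tiny fixed reference with hand-picked sequences (substring-free by
## construction) so tests can target exact tags.
tiny_reference <- function() {
  structure(list(
    mirna = data.frame(
      mirna_id = c("miR-a", "miR-b", "miR-c"),
      mature_seq = c("ACGTACGTACGTACGTAC",          # 18 nt
                     "TTGGCCAATTGGCCAATTGGCC",      # 22 nt
                     "GATTACAGATTACAGATTACAGATT"),  # 25 nt
      stringsAsFactors = FALSE),
    contaminants = data.frame(
      class = c("tRNA", "rRNA"),
      seq = c("CCCCAAAAGGGGTTTTCCCCA",             # 21 nt
              "AGAGAGAGAGAGAGAGAGAGAGAG"),          # 24 nt
      stringsAsFactors = FALSE)
  ), class = "mirna_reference")
}

## In-memory FASTQ construction for filter tests.
make_reads <- function(seqs, quals, ids = sprintf("r%03d", seq_along(seqs))) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::QualityScaledDNAStringSet(
    x, Biostrings::PhredQuality(Biostrings::BStringSet(quals)))
}

## Direct factorial evaluation of the exact-test pmf, valid for small counts:
## the independent oracle for the log-space implementation.
ac_pmf_direct <- function(x, y, N1, N2) {
  r <- N2 / N1
  r^y * factorial(x + y) / (factorial(x) * factorial(y) * (1 + r)^(x + y + 1))
}

## Exhaustive-enumeration hypergeometric upper tail, for small N: counts
## favourable draws directly from the combinatorial definition.
hyper_upper_enum <- function(k, K, n, N) {
  sum(vapply(k:min(K, n), function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
}
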