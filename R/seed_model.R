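#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases the input and converts T to U. Any character outside
#' A/C/G/U/T raises an error naming the first offending position.
#'
#' @param seq A single nucleotide string (DNA or RNA, any case).
#' @return The normalized RNA string (A/C/G/U, uppercase).
#' @export
#' @examples
#' normalize_rna("atgcT")  # "AUGCU"
normalize_rna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  out <- chartr("tT", "uU", seq)
  out <- toupper(out)
  bad <- regexpr("[^ACGU]", out)
  if (bad > 0L) {
    stop("non-nucleotide character '", substr(seq, bad, bad),
         "' at position ", bad, call. = FALSE)
  }
  out
}

#' Reverse complement of a nucleotide sequence
#'
#' Input may be DNA or RNA (case-insensitive); the result is always in the
#' RNA alphabet, so `reverse_complement(reverse_complement(x))` equals
#' `normalize_rna(x)`.
#'
#' @param seq A single nucleotide string.
#' @return The reverse complement, 5'->3', RNA alphabet.
#' @export
#' @examples
#' reverse_complement("GGAAUGU")  # "ACAUUCC"
reverse_complement <- function(seq) {
  s <- normalize_rna(seq)
  comp <- chartr("ACGU", "UGCA", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Construct a miRNA specification
#'
#' Holds a mature miRNA's name, its 5'->3' sequence and the derived seed
#' (nucleotides 2-8), the primary determinant of target recognition.
#'
#' @param name miRNA identifier.
#' @param sequence Mature miRNA sequence, 5'->3' (DNA or RNA letters);
#'   must be 18-26 nt long.
#' @return An object of class `mirna_spec` with fields `name`, `sequence`
#'   and `seed`.
#' @export
#' @examples
#' m <- mirna_spec("miR-1", "UGGAAUGUAAAGAAGUAUGUAU")
#' m$seed  # "GGAAUGU"
mirna_spec <- function(name, sequence) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  if (n < 18L || n > 26L) {
    stop("miRNA sequence must be 18-26 nt, got ", n, " for '", name, "'",
         call. = FALSE)
  }
  structure(
    list(name = as.character(name), sequence = sequence,
         seed = derive_seed(sequence)),
    class = "mirna_spec"
  )
}

#' @export
print.mirna_spec <- function(x, ...) {
  cat("<mirna_spec>", x$name, " ", x$sequence, " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Derive the seed region (nucleotides 2-8) of a miRNA
#'
#' @param mirna A `mirna_spec` or a plain sequence string of length >= 8.
#' @return The 7-nt seed, RNA alphabet.
#' @export
derive_seed <- function(mirna) {
  seq <- if (inherits(mirna, "mirna_spec")) mirna$sequence else normalize_rna(mirna)
  if (nchar(seq) < 8L) {
    stop("sequence too short to derive a seed (need >= 8 nt, got ",
         nchar(seq), ")", call. = FALSE)
  }
  substr(seq, 2L, 8L)
}

# Site match strings on the UTR (sense strand, 5'->3'):
#  - m8 heptamer: reverse complement of miRNA nt 2-8,
#  - core hexamer: reverse complement of miRNA nt 2-7
#    (equals positions 2-7 of the m8 heptamer).
.site_strings <- function(mirna) {
  seed <- if (inherits(mirna, "mirna_spec")) mirna$seed else derive_seed(mirna)
  m8 <- reverse_complement(seed)
  list(m8 = m8, core = substr(m8, 2L, 7L))
}

.SEED_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer", "else")

#' Classify a candidate seed-match site
#'
#' Determines the Bartel seed-type of a match beginning at `offset`
#' (0-based) on the UTR, by precedence 8mer > 7mer-m8 > 7mer-A1 > 6mer:
#' an 8mer is the reverse complement of miRNA nt 2-8 immediately followed
#' on the UTR by an A (the position opposite miRNA nt 1); a 7mer-m8 is the
#' same heptamer without the trailing A; a 7mer-A1 is the reverse
#' complement of nt 2-7 plus the trailing A, without the m8 pairing; a
#' 6mer is the 2-7 core alone.
#'
#' @param utr UTR sequence (5'->3').
#' @param offset 0-based offset of the first matched base.
#' @param mirna A `mirna_spec`.
#' @return One of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`, `"else"`.
#' @export
classify_site <- function(utr, offset, mirna) {
  utr <- normalize_rna(utr)
  n <- nchar(utr)
  if (offset < 0L || offset >= n) {
    stop("offset ", offset, " out of bounds for UTR of length ", n,
         call. = FALSE)
  }
  ss <- .site_strings(mirna)
  at <- function(i, len) if (i + len <= n) substr(utr, i + 1L, i + len) else NA_character_
  if (identical(at(offset, 7L), ss$m8)) {
    nxt <- at(offset + 7L, 1L)
    if (identical(nxt, "A")) return("8mer") else return("7mer-m8")
  }
  if (identical(at(offset, 6L), ss$core)) {
    nxt <- at(offset + 6L, 1L)
    if (identical(nxt, "A")) return("7mer-A1") else return("6mer")
  }
  "else"
}

.seed_site <- function(utr_id, start, end, seed_type, matched_seq) {
  tibble::tibble(utr_id = as.character(utr_id), start = as.integer(start),
                 end = as.integer(end), seed_type = as.character(seed_type),
                 matched_seq = as.character(matched_seq))
}

#' Scan a UTR for canonical seed-match sites
#'
#' Finds every occurrence of the miRNA's 2-7 core match on the UTR and
#' reports one maximal-precedence site per core: the site is extended to
#' 7mer-m8/8mer when the m8-pairing base lies immediately 5' of the core on
#' the UTR, or to 7mer-A1 when an A follows the core; lower-precedence
#' matches at the same core are subsumed. Coordinates are 0-based
#' half-open, reported left to right.
#'
#' @param utr UTR sequence (5'->3').
#' @param mirna A `mirna_spec`.
#' @param utr_id Identifier recorded in the output (default `"utr"`).
#' @return A tibble with columns `utr_id`, `start`, `end`, `seed_type`,
#'   `matched_seq`; zero rows when the UTR has no core match.
#' @export
#' @examples
#' m <- mirna_spec("miR-1", "UGGAAUGUAAAGAAGUAUGUAU")
#' find_seed_sites("ACAUUCCA", m)  # one 8mer site spanning [0, 8)
find_seed_sites <- function(utr, mirna, utr_id = "utr") {
  utr <- normalize_rna(utr)
  ss <- .site_strings(mirna)
  n <- nchar(utr)
  subject <- Biostrings::RNAString(utr)
  match0 <- function(pat) {
    BiocGenerics::start(Biostrings::matchPattern(pat, subject)) - 1L
  }
  m8_starts <- match0(ss$m8)
  core_starts <- match0(ss$core)
  followed_by_a <- function(pos) {
    if (length(pos) == 0L) return(logical(0))
    pos < n & substring(utr, pos + 1L, pos + 1L) == "A"
  }
  # m8-anchored sites (8mer when the UTR base opposite miRNA nt 1 is an A)
  m8_is_8mer <- followed_by_a(m8_starts + 7L)
  # core-only sites, unless the offset itself or the one 5' of it opens an
  # m8-anchored site (same 2-7 core: subsumed by the higher-precedence match)
  keep <- !(core_starts %in% m8_starts) & !((core_starts - 1L) %in% m8_starts)
  core_keep <- core_starts[keep]
  core_is_a1 <- followed_by_a(core_keep + 6L)
  start <- c(m8_starts, core_keep)
  end <- c(m8_starts + ifelse(m8_is_8mer, 8L, 7L),
           core_keep + ifelse(core_is_a1, 7L, 6L))
  type <- c(ifelse(m8_is_8mer, "8mer", "7mer-m8"),
            ifelse(core_is_a1, "7mer-A1", "6mer"))
  ord <- order(start, end)
  matched <- if (length(start)) substring(utr, start[ord] + 1L, end[ord]) else
    character(0)
  .seed_site(rep(utr_id, length(start)), start[ord], end[ord], type[ord],
             matched)
}

#' Reference seed-site scanner (exhaustive offset enumeration)
#'
#' Independent validation oracle for [find_seed_sites()]: classifies every
#' offset of the UTR with [classify_site()] and applies the same
#' subsumption rule (a 7mer-A1/6mer whose core belongs to an 8mer/7mer-m8
#' starting one base 5' is dropped). Pure character-level loop; no shared
#' scanning code with the main implementation.
#'
#' @inheritParams find_seed_sites
#' @return Same layout as [find_seed_sites()].
#' @export
scan_sites_brute <- function(utr, mirna, utr_id = "utr") {
  utr <- normalize_rna(utr)
  n <- nchar(utr)
  start <- integer(); end <- integer(); type <- character()
  for (i in seq_len(n) - 1L) {
    ty <- classify_site(utr, i, mirna)
    if (ty == "else") next
    if (ty %in% c("7mer-A1", "6mer")) {
      # subsumed if the previous offset opens an m8-extended site on the same core
      if (i >= 1L && classify_site(utr, i - 1L, mirna) %in% c("8mer", "7mer-m8")) next
    }
    len <- switch(ty, "8mer" = 8L, "7mer-m8" = 7L, "7mer-A1" = 7L, "6mer" = 6L)
    start <- c(start, i); end <- c(end, i + len); type <- c(type, ty)
  }
  matched <- if (length(start)) substring(utr, start + 1L, end) else character(0)
  .seed_site(rep(utr_id, length(start)), start, end, type, matched)
}

#' Export seed sites as a BED-like table
#'
#' @param sites A site tibble from [find_seed_sites()].
#' @return A 6-column data frame (utr_id, start, end, name = seed type,
#'   score = ".", strand = "+"), 0-based half-open.
#' @export
sites_to_bed <- function(sites) {
  data.frame(chrom = sites$utr_id, start = sites$start, end = sites$end,
             name = sites$seed_type, score = ".", strand = "+",
             stringsAsFactors = FALSE)
}
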