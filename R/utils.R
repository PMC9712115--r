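# Shared sequence helpers. All sequences are plain upper-case character
# scalars over {A,C,G,T,N}; Biostrings does the heavy lifting where it can.

#' Reverse complement of a DNA string
#'
#' @param x Character scalar over \{A,C,G,T,N\}.
#' @return Character scalar, the reverse complement.
#' @export
#' @examples
#' revcomp("ATGC")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a DNA string in frame 0
#'
#' Stops are rendered as `*`; the sequence length must be a multiple of 3.
#'
#' @param x Character scalar, length a multiple of 3.
#' @return Character scalar amino-acid sequence.
#' @export
translate_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) %% 3L != 0L) {
    stop("sequence length ", nchar(x), " is not a multiple of 3", call. = FALSE)
  }
  # no.init.codon: translate literally, never as an initiator (otherwise
  # CTG/TTG/GTG at position 1 would read as Met)
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "error"))
}

# split a coding sequence into codon triplets
split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) stop("length not a multiple of 3", call. = FALSE)
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

# validate an upper-cased nucleotide string; N allowed, other ambiguity
# codes and lower case rejected before upcasing happens at the caller
assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, x)) {
    bad <- unique(strsplit(gsub(if (allow_n) "[ACGTN]" else "[ACGT]", "", x),
                           "")[[1]])
    stop(what, " contains disallowed characters: ",
         paste(bad, collapse = ", "),
         " (only A, C, G, T", if (allow_n) ", N", " are accepted)",
         call. = FALSE)
  }
  invisible(x)
}

# all start positions (1-based) of fixed pattern in subject
find_all <- function(pattern, subject) {
  if (nchar(pattern) == 0L || nchar(subject) < nchar(pattern)) return(integer())
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

# count of occurrences of fixed pattern on either strand of subject
count_both_strands <- function(pattern, subject) {
  n <- length(find_all(pattern, subject))
  rc <- revcomp(pattern)
  if (rc != pattern) n <- n + length(find_all(rc, subject))
  n
}

# run a block with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# random DNA of length n using the current RNG stream
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
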