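# Independent oracles used throughout the suite. These deliberately avoid
# the package's code paths: character-level loops and exhaustive
# enumeration instead of the production algorithms.

# reverse complement by character table + rev()
oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# does `subject` contain `kmer`? explicit position-by-position scan
oracle_contains <- function(subject, kmer) {
  k <- nchar(kmer); n <- nchar(subject)
  if (k == 0 || k > n) return(FALSE)
  for (i in seq_len(n - k + 1)) {
    if (substr(subject, i, i + k - 1) == kmer) return(TRUE)
  }
  FALSE
}

# longest substring of query present in subject on either strand,
# by brute-force enumeration of query substrings, longest first
oracle_longest_match <- function(query, subject) {
  rc <- oracle_revcomp(subject)
  for (len in rev(seq_len(nchar(query)))) {
    for (i in seq_len(nchar(query) - len + 1)) {
      sub <- substr(query, i, i + len - 1)
      if (oracle_contains(subject, sub) || oracle_contains(rc, sub)) {
        return(len)
      }
    }
  }
  0L
}

# longest perfect hairpin stem with loop >= min_loop by exhaustive O(n^3)
# scan over (i, j) outer pairs, extending inward one pair at a time
oracle_longest_stem <- function(seq, min_loop = 3L) {
  s <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  n <- length(s)
  best <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      k <- 0L
      while (i + k < j - k &&
             !is.na(comp[s[i + k]]) && comp[s[i + k]] == s[j - k]) {
        k <- k + 1L
        loop <- (j - k) - (i + k) + 1L
        if (loop >= min_loop && k > best) best <- k
      }
    }
  }
  best
}

# exhaustive-search maximum number of silent changes inside a protospacer
# window. context: in-frame codon string covering the protospacer;
# off: 0-based offset of the protospacer within context; L: its length.
# Enumerates every synonymous codon combination obeying the usage floor.
oracle_max_silent_changes <- function(context, off, L, usage,
                                      rare_threshold = 0.10) {
  codons <- substring(context, seq(1, nchar(context), 3),
                      seq(3, nchar(context), 3))
  cand_sets <- lapply(seq_along(codons), function(k) {
    orig <- codons[k]
    aa <- as.character(Biostrings::GENETIC_CODE[[orig]])
    if (aa == "*") return(orig)
    fam <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
    # changes only inside the protospacer window
    pos <- (k - 1) * 3 + 1:3          # 1-based positions in context
    inside <- pos > off & pos <= off + L
    o <- strsplit(orig, "")[[1]]
    fam <- fam[vapply(fam, function(cd) {
      x <- strsplit(cd, "")[[1]]
      all(x[!inside] == o[!inside])
    }, logical(1))]
    changes <- vapply(fam, function(cd) {
      sum(strsplit(cd, "")[[1]][inside] != o[inside])
    }, integer(1))
    common <- vapply(fam, function(cd) {
      fr <- usage$fraction[match(cd, usage$codon)]
      cd == orig || (!is.na(fr) && fr >= rare_threshold)
    }, logical(1))
    # rarity floor, with the fallback rule: if every change-producing
    # synonymous codon is rare, the whole family becomes eligible
    if (any(changes > 0) && max(changes[common]) == 0) fam
    else fam[common]
  })
  combos <- expand.grid(cand_sets, stringsAsFactors = FALSE)
  best <- 0L
  orig_chars <- strsplit(context, "")[[1]]
  for (r in seq_len(nrow(combos))) {
    new <- paste(unlist(combos[r, ]), collapse = "")
    new_chars <- strsplit(new, "")[[1]]
    idx <- (off + 1):(off + L)
    ch <- sum(new_chars[idx] != orig_chars[idx])
    if (ch > best) best <- ch
  }
  best
}

# random DNA helper for tests (uses the ambient RNG; tests set seeds)
rnd_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tiny 3-gene GenBank fixture written in code; the middle gene is on the
# minus strand and one CDS is annotated 101..160 to pin the 1-based
# convention
write_toy_genbank <- function(path) {
  set.seed(42)
  seqn <- rnd_dna(400)
  # plant clean ORFs so CDS features translate without internal stops
  orf <- function(n_codons) {
    paste(c("ATG", sample(c("GCT", "CTG", "AAA", "GAT", "TTC", "CGT"),
                          n_codons - 2, replace = TRUE), "TAA"),
          collapse = "")
  }
  g1 <- orf(20); g2 <- orf(15); g3 <- orf(18)
  substr(seqn, 101, 100 + nchar(g1)) <- g1                  # 101..160
  substr(seqn, 201, 200 + nchar(g2)) <- oracle_revcomp(g2)  # minus strand
  substr(seqn, 301, 300 + nchar(g3)) <- g3
  lines <- c(
    "LOCUS       toy3 400 bp    DNA     linear   PHG",
    "DEFINITION  toy3.",
    "FEATURES             Location/Qualifiers",
    "     source          1..400",
    "     CDS             101..160",
    "                     /gene=\"alpha\"",
    "     CDS             complement(201..245)",
    "                     /gene=\"beta\"",
    "     CDS             301..354",
    "                     /gene=\"gamma\"",
    "ORIGIN")
  seql <- tolower(seqn)
  for (s in seq(1, 400, 60)) {
    chunk <- substr(seql, s, min(s + 59, 400))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s, paste(tens, collapse = " ")))
  }
  writeLines(c(lines, "//"), path)
  invisible(path)
}

toy_usage <- cas13design::default_codon_usage()
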