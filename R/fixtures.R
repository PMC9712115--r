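# Deterministic synthetic-genome generator. Every module is testable
# offline: a toy phage genome has annotated CDSs with no internal stops on
# mixed strands, one gene opening with highly degenerate codons (so
# recoding always has room to move) and one ATG/TGG-rich gene (so the
# "no silent change possible" path is reachable); a host decoy is random
# sequence with an optional embedded k-mer for off-target tests. Same seed,
# same bytes.

# codons with 4- or 6-fold degeneracy where every family member is common
# enough to recode through; used for the guaranteed-degenerate gene
degenerate_codons <- c("GCT", "GGT", "CCG", "ACC", "GTT", "CTG", "CGT", "TCT")

#' Generate a deterministic toy phage genome
#'
#' @param seed Integer seed; the same seed always yields the same genome.
#' @param n_genes Number of CDS features (>= 2).
#' @param gene_len_range Range of CDS lengths in bp (rounded to codons),
#'   start and stop codons included.
#' @param intergenic_range Range of intergenic spacer lengths in bp.
#' @param end_flank Plain sequence left at both genome ends (room for
#'   250 bp homology arms).
#' @param usage Codon usage table used to weight codon sampling.
#' @param path Optional output path; if given, the genome is also written
#'   as a GenBank file.
#' @return A `phage_genome`. Gene ids are `gene01`, `gene02`, ...; the
#'   first gene opens with a run of fully degenerate codons and the last
#'   gene's 5' end is built from ATG/TGG only.
#' @export
make_toy_phage <- function(seed = 1L, n_genes = 5L,
                           gene_len_range = c(150L, 300L),
                           intergenic_range = c(60L, 120L),
                           end_flank = 300L,
                           usage = default_codon_usage(),
                           path = NULL) {
  stopifnot(n_genes >= 2L, gene_len_range[1] >= 45L,
            intergenic_range[1] >= 10L, end_flank >= 0L)
  g <- with_seed(seed, {
    # degenerate amino acids only: no stop can arise and every body codon
    # keeps at least one synonymous alternative
    recodable <- usage[!usage$aa %in% c("*", "M", "W"), ]
    sample_codons <- function(k) {
      sample(recodable$codon, k, replace = TRUE, prob = recodable$fraction)
    }
    gene_seq <- function(idx, len_bp) {
      n_codons <- max(15L, len_bp %/% 3L)      # incl. start and stop
      body_n <- n_codons - 2L
      body <- if (idx == 1L) {
        c(sample(degenerate_codons, min(12L, body_n), replace = TRUE),
          sample_codons(max(0L, body_n - 12L)))
      } else if (idx == n_genes) {
        c(sample(c("ATG", "TGG"), min(12L, body_n), replace = TRUE),
          sample_codons(max(0L, body_n - 12L)))
      } else {
        sample_codons(body_n)
      }
      paste(c("ATG", body, "TAA"), collapse = "")
    }
    lens <- sample(seq(gene_len_range[1], gene_len_range[2]), n_genes,
                   replace = TRUE)
    strands <- rep(c("+", "-"), length.out = n_genes)
    pieces <- character(); feats <- list(); pos <- 0L
    add <- function(s) { pieces[[length(pieces) + 1L]] <<- s; pos <<- pos + nchar(s) }
    add(random_dna(end_flank))
    for (i in seq_len(n_genes)) {
      cds <- gene_seq(i, lens[i])
      placed <- if (strands[i] == "+") cds else revcomp(cds)
      feats[[i]] <- data.frame(gene_id = sprintf("gene%02d", i),
                               start = pos, end = pos + nchar(cds),
                               strand = strands[i], kind = "CDS",
                               partial = FALSE, stringsAsFactors = FALSE)
      add(placed)
      if (i < n_genes) {
        add(random_dna(sample(seq(intergenic_range[1], intergenic_range[2]),
                              1L)))
      }
    }
    add(random_dna(end_flank))
    phage_genome(sprintf("toyphage_s%d", seed), paste(pieces, collapse = ""),
                 do.call(rbind, feats))
  })
  if (!is.null(path)) write_genome(g, path, "genbank")
  g
}

#' Generate a host decoy sequence
#'
#' Random DNA, optionally with a chosen k-mer embedded at a known (or
#' random) position, for exercising the off-target screen.
#'
#' @param seed Integer seed.
#' @param length Decoy length in bp.
#' @param embed Optional sequence to embed.
#' @param embed_at Optional 1-based position for the embedded sequence;
#'   random if omitted.
#' @param path Optional FASTA output path.
#' @return A `phage_genome` (no features); attribute `embed_pos` gives the
#'   1-based start of the embedded k-mer, or `NA`.
#' @export
make_host_decoy <- function(seed = 1L, length = 10000L, embed = NULL,
                            embed_at = NULL, path = NULL) {
  stopifnot(length >= 1L)
  res <- with_seed(seed, {
    seq <- random_dna(length)
    pos <- NA_integer_
    if (!is.null(embed)) {
      embed <- toupper(embed)
      if (nchar(embed) > length) stop("embed longer than decoy", call. = FALSE)
      pos <- if (is.null(embed_at)) {
        sample.int(length - nchar(embed) + 1L, 1L)
      } else as.integer(embed_at)
      substr(seq, pos, pos + nchar(embed) - 1L) <- embed
    }
    list(seq = seq, pos = pos)
  })
  g <- phage_genome(sprintf("hostdecoy_s%d", seed), res$seq)
  attr(g, "embed_pos") <- res$pos
  if (!is.null(path)) write_genome(g, path, "fasta")
  g
}
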