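# Cas13 crRNA spacer design. A spacer is the 31-nt guide segment of the
# crRNA, antisense to the target transcript; the protospacer is the
# transcript-sense sequence it base-pairs with. LbuCas13a has no PAM/PFS
# requirement, so design reduces to window placement plus QC screens.

#' The RFP non-targeting control spacer
#'
#' A functional spacer against an RFP transcript absent from phage and host,
#' used as the negative control in every assay.
#' @return Character scalar (31 nt).
#' @export
rfp_control_spacer <- function() "AACTCTTTGATAACGTCTTCGCTACTCGCCA"

new_spacer_design <- function(spacer, protospacer, mode, gene_id = NA_character_,
                              interval = NULL, spacer_len = nchar(spacer)) {
  stopifnot(nchar(spacer) == spacer_len,
            identical(spacer, revcomp(protospacer)))
  structure(list(spacer = spacer, protospacer = protospacer, mode = mode,
                 gene_id = gene_id, interval = interval,
                 offtarget = list(flag = NA, match_len = NA_integer_),
                 hairpin = list(flag = NA, stem_len = NA_integer_)),
            class = "spacer_design")
}

#' @export
print.spacer_design <- function(x, ...) {
  cat(sprintf("<spacer_design> mode=%s gene=%s len=%d\n", x$mode,
              x$gene_id, nchar(x$spacer)))
  cat("  spacer      5'-", x$spacer, "-3'\n", sep = "")
  cat("  protospacer 5'-", x$protospacer, "-3'\n", sep = "")
  if (!is.null(x$interval)) {
    cat(sprintf("  target %d..%d (%s)\n", x$interval$start + 1L,
                x$interval$end, x$interval$strand))
  }
  if (!is.na(x$offtarget$flag))
    cat(sprintf("  off-target: %s (longest host match %d nt)\n",
                x$offtarget$flag, x$offtarget$match_len))
  if (!is.na(x$hairpin$flag))
    cat(sprintf("  hairpin: %s (stem %d bp)\n", x$hairpin$flag,
                x$hairpin$stem_len))
  invisible(x)
}

# shared: build a design from a transcript window [t_start, t_end) of a gene
spacer_from_transcript_window <- function(genome, gene_id, t_start, spacer_len,
                                          mode) {
  ft <- feature_by_id(genome, gene_id)
  cds_len <- ft$end - ft$start
  t_end <- t_start + spacer_len
  upstream <- max(0L, -t_start)
  downstream <- max(0L, t_end - cds_len)
  tx <- transcript_sequence(genome, gene_id, upstream, downstream)
  protospacer <- substr(tx, t_start + upstream + 1L, t_end + upstream)
  if (grepl("N", protospacer, fixed = TRUE)) {
    stop("design window for ", gene_id, " contains N; pick another window",
         call. = FALSE)
  }
  interval <- transcript_window_to_genome(genome, gene_id, t_start, t_end)
  new_spacer_design(revcomp(protospacer), protospacer, mode, gene_id,
                    interval, spacer_len)
}

#' Design a CDS-start spacer
#'
#' Default targeting mode: the protospacer is the first `spacer_len` nt of
#' the mRNA-sense CDS, so the spacer is their reverse complement.
#'
#' @param genome A `phage_genome`.
#' @param gene_id CDS feature id.
#' @param spacer_len Spacer length in nt (default 31).
#' @return A `spacer_design`.
#' @export
design_cds_start_spacer <- function(genome, gene_id, spacer_len = 31L) {
  ft <- feature_by_id(genome, gene_id)
  if (ft$end - ft$start < spacer_len) {
    stop("CDS ", gene_id, " (", ft$end - ft$start,
         " nt) is shorter than the spacer length ", spacer_len, call. = FALSE)
  }
  spacer_from_transcript_window(genome, gene_id, 0L, spacer_len, "CDS_START")
}

#' Design an RBS-overlapping spacer
#'
#' The protospacer window begins at the -4 to -6 position relative to the
#' start codon (position 1 = the A of ATG), covering the ribosome-binding
#' region plus the 5' end of the CDS.
#'
#' @inheritParams design_cds_start_spacer
#' @param offset Integer in \[-6, -4\]: transcript position at which the
#'   protospacer begins.
#' @export
design_rbs_spacer <- function(genome, gene_id, offset, spacer_len = 31L) {
  if (!(offset %in% -6:-4)) {
    stop("RBS offset must be -4, -5 or -6 (got ", offset, ")", call. = FALSE)
  }
  # offset -4 means the window starts 4 nt upstream of the A of ATG
  spacer_from_transcript_window(genome, gene_id, offset, spacer_len, "RBS")
}

#' Design a mid-CDS (custom-offset) spacer
#'
#' @inheritParams design_cds_start_spacer
#' @param t_start 0-based transcript offset of the protospacer start
#'   (0 = first base of the start codon; negative = upstream).
#' @export
design_custom_spacer <- function(genome, gene_id, t_start, spacer_len = 31L) {
  spacer_from_transcript_window(genome, gene_id, as.integer(t_start),
                                spacer_len, "CUSTOM")
}

#' Design a deletion-verification spacer
#'
#' A guide used to verify a deletion: its protospacer covers the deletion's
#' transcript-sense 3' junction, extending `downstream_offset` (0-15) nt
#' past the deleted interval so that the wildtype locus is targeted while
#' the edit destroys the target site.
#'
#' @param genome A `phage_genome`.
#' @param del_start,del_end Deleted interval, 1-based inclusive.
#' @param strand Transcript orientation of the deleted locus (`+`/`-`).
#' @param downstream_offset Integer in \[0, 15\]: how far the protospacer
#'   extends past the deletion's 3' end.
#' @param spacer_len Spacer length in nt.
#' @export
design_deletion_verify_spacer <- function(genome, del_start, del_end,
                                          strand = "+", downstream_offset = 0L,
                                          spacer_len = 31L) {
  if (!(downstream_offset %in% 0:15)) {
    stop("downstream_offset must lie in [0, 15] (got ", downstream_offset,
         ")", call. = FALSE)
  }
  stopifnot(strand %in% c("+", "-"))
  s0 <- del_start - 1L; e0 <- del_end
  if (strand == "+") {
    w_end <- e0 + downstream_offset
    w_start <- w_end - spacer_len
  } else {
    w_start <- s0 - downstream_offset
    w_end <- w_start + spacer_len
  }
  seq <- genome_slice(genome, w_start, w_end)
  protospacer <- if (strand == "+") seq else revcomp(seq)
  if (grepl("N", protospacer, fixed = TRUE)) {
    stop("verification window contains N", call. = FALSE)
  }
  new_spacer_design(revcomp(protospacer), protospacer, "DELETION_VERIFY",
                    NA_character_,
                    list(start = w_start, end = w_end, strand = strand),
                    spacer_len)
}

#' Build a non-targeting control design
#'
#' @param spacer Spacer sequence; defaults to the RFP control spacer.
#' @export
design_nontargeting_spacer <- function(spacer = rfp_control_spacer()) {
  new_spacer_design(spacer, revcomp(spacer), "NON_TARGETING")
}

## ------------------------------------------------------------ QC screens

#' Longest exact match between a protospacer and a host genome
#'
#' Scans both strands of the host for the longest exact substring of the
#' protospacer, the similarity proxy used to avoid guides cross-reactive
#' with host transcripts.
#'
#' @param spacer A `spacer_design`.
#' @param host A `phage_genome` (the host), or a plain sequence string.
#' @param min_flag_match Match length (nt) at or above which the design is
#'   flagged. Default 15 (about half a 31-nt spacer).
#' @return The `spacer_design` with `offtarget` updated.
#' @export
offtarget_screen <- function(spacer, host, min_flag_match = 15L) {
  hseq <- if (inherits(host, "phage_genome")) host$sequence else toupper(host)
  ml <- longest_shared_match(spacer$protospacer, hseq)
  spacer$offtarget <- list(flag = ml >= min_flag_match, match_len = ml)
  spacer
}

# longest substring of `query` occurring in `subject` on either strand
longest_shared_match <- function(query, subject) {
  n <- nchar(query)
  if (!nchar(subject)) return(0L)
  sub_rc <- revcomp(subject)
  for (len in seq.int(min(n, nchar(subject)), 1L)) {
    starts <- seq_len(n - len + 1L)
    kmers <- unique(substring(query, starts, starts + len - 1L))
    for (k in kmers) {
      if (length(find_all(k, subject)) || length(find_all(k, sub_rc))) {
        return(len)
      }
    }
  }
  0L
}

#' Assemble a mature crRNA
#'
#' @param repeat_seq Direct-repeat sequence of the effector (5' of the
#'   spacer). No default is shipped: the repeat is effector-specific
#'   configuration and must be supplied.
#' @param spacer Spacer sequence or a `spacer_design`.
#' @return List with `repeat_seq`, `spacer`, `full` (repeat then spacer).
#' @export
mature_crrna <- function(repeat_seq, spacer) {
  if (inherits(spacer, "spacer_design")) spacer <- spacer$spacer
  repeat_seq <- toupper(repeat_seq); spacer <- toupper(spacer)
  assert_dna(repeat_seq, "direct repeat"); assert_dna(spacer, "spacer")
  structure(list(repeat_seq = repeat_seq, spacer = spacer,
                 full = paste0(repeat_seq, spacer)),
            class = "mature_crrna")
}

#' Screen a crRNA for self-complementary hairpins
#'
#' Finds the longest perfect Watson-Crick stem (no wobble) with a loop of
#' at least `min_loop` nt anywhere in the sequence. Long stems within the
#' mature crRNA are associated with guide misfolding and toxicity, so
#' designs at or above `min_stem` are flagged (advisory only).
#'
#' @param x A `mature_crrna`, `spacer_design` (spacer-only screen) or plain
#'   sequence.
#' @param min_stem Stem length (bp) at or above which to flag. Default 8.
#' @param min_loop Minimum loop length in nt. Default 3.
#' @return List with `flag` and `stem_len`.
#' @export
hairpin_screen <- function(x, min_stem = 8L, min_loop = 3L) {
  seq <- if (inherits(x, "mature_crrna")) x$full
         else if (inherits(x, "spacer_design")) x$spacer
         else toupper(x)
  stem <- longest_hairpin_stem(seq, min_loop)
  list(flag = stem >= min_stem, stem_len = stem)
}

# longest L such that positions i..i+L-1 pair (reverse-complement) with
# j-L+1..j for some i, j with loop j-i+1-2L >= min_loop. O(n^2) DP on the
# pair matrix; n is a crRNA (<100 nt) so this is immediate.
longest_hairpin_stem <- function(seq, min_loop = 3L) {
  n <- nchar(seq)
  if (n < 2L) return(0L)
  s <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", T = "A", C = "G", G = "C", N = "")
  best <- 0L
  # run[i,j]: consecutive pairs (i,j),(i+1,j-1),... counted inward
  run <- matrix(0L, n, n)
  for (span in seq.int(2L, n)) {
    for (i in seq_len(n - span + 1L)) {
      j <- i + span - 1L
      if (identical(comp[[s[i]]], s[j])) {
        inner <- if (j - i >= 2L) run[i + 1L, j - 1L] else 0L
        run[i, j] <- inner + 1L
        usable <- min(run[i, j], (j - i + 1L - min_loop) %/% 2L)
        if (usable > best) best <- usable
      }
    }
  }
  max(best, 0L)
}

## --------------------------------------------------------------- reports

#' Write a spacer report (TSV, FASTA, BED)
#'
#' @param designs List of `spacer_design` objects.
#' @param prefix Output path prefix; writes `<prefix>.tsv`,
#'   `<prefix>.fasta`, `<prefix>.bed`.
#' @param genome_id Record name for the BED file.
#' @return Data frame of the TSV content, invisibly.
#' @export
write_spacer_report <- function(designs, prefix, genome_id = "genome") {
  rows <- lapply(designs, function(d) {
    has_iv <- !is.null(d$interval)
    data.frame(gene = d$gene_id, mode = d$mode,
               start = if (has_iv) d$interval$start + 1L else NA_integer_,
               end = if (has_iv) d$interval$end else NA_integer_,
               strand = if (has_iv) d$interval$strand else NA_character_,
               spacer = d$spacer, protospacer = d$protospacer,
               offtarget_flag = d$offtarget$flag,
               offtarget_match = d$offtarget$match_len,
               hairpin_flag = d$hairpin$flag,
               hairpin_stem = d$hairpin$stem_len,
               stringsAsFactors = FALSE)
  })
  tb <- do.call(rbind, rows)
  utils::write.table(tb, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fa <- Biostrings::DNAStringSet(vapply(designs, `[[`, "", "spacer"))
  names(fa) <- sprintf("%s_%s_spacer", vapply(designs, `[[`, "", "gene_id"),
                       vapply(designs, `[[`, "", "mode"))
  Biostrings::writeXStringSet(fa, paste0(prefix, ".fasta"))
  targeted <- tb[!is.na(tb$start), , drop = FALSE]
  if (nrow(targeted)) {
    write_bed(data.frame(start = targeted$start - 1L, end = targeted$end,
                         name = paste0(targeted$gene, "_protospacer"),
                         strand = targeted$strand),
              genome_id, paste0(prefix, ".bed"))
  }
  invisible(tb)
}
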