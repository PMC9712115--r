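# Silent (synonymous) recoding of protospacers. The edit keeps the encoded
# protein identical while rewriting the nucleotide sequence Cas13a
# recognizes, at one of three scopes: a single codon (C), the seed region
# of the spacer (S), or the full protospacer (F). Codons are maximally
# altered subject to a codon-usage floor that avoids rare codons.

#' Load a codon usage table
#'
#' TSV with columns `codon`, `aa`, `fraction` (relative synonymous usage
#' within each amino-acid family; families must sum to 1 +/- 1e-6).
#'
#' @param path TSV path; default is the E. coli table shipped with the
#'   package (derived from the classical codon-adaptation reference set for
#'   highly expressed E. coli genes).
#' @return Data frame with columns `codon`, `aa`, `fraction`.
#' @export
read_codon_usage <- function(path = system.file("extdata",
                                                "ecoli_codon_usage.tsv",
                                                package = "cas13design")) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("codon", "aa", "fraction")
  if (!all(need %in% names(tb))) {
    stop("codon usage table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tb$codon <- toupper(tb$codon)
  sums <- tapply(tb$fraction, tb$aa, sum)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("codon usage fractions do not sum to 1 within families: ",
         paste(names(sums)[abs(sums - 1) > 1e-6], collapse = ", "),
         call. = FALSE)
  }
  tb
}

#' @rdname read_codon_usage
#' @export
default_codon_usage <- function() read_codon_usage()

codon_aa <- function(codon) as.character(Biostrings::GENETIC_CODE[[codon]])

# synonymous alternatives (including the codon itself), never stops
synonymous_codons <- function(codon) {
  aa <- codon_aa(codon)
  if (aa == "*") return(codon)
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
}

usage_of <- function(codon, usage) {
  i <- match(codon, usage$codon)
  if (is.na(i)) 0 else usage$fraction[i]
}

# choose the replacement for one codon. mutable: integer subset of 1:3 that
# may change. Returns list(codon, n_changes, rare_fallback).
pick_codon <- function(original, mutable, usage, rare_threshold) {
  cands <- synonymous_codons(original)
  splt <- strsplit(cands, "")
  orig <- strsplit(original, "")[[1]]
  ok <- vapply(splt, function(x) all(x[setdiff(1:3, mutable)] ==
                                       orig[setdiff(1:3, mutable)]),
               logical(1))
  cands <- cands[ok]; splt <- splt[ok]
  changes <- vapply(splt, function(x) sum(x[mutable] != orig[mutable]),
                    integer(1))
  fr <- vapply(cands, usage_of, numeric(1), usage = usage)
  common <- fr >= rare_threshold | cands == original
  pick_best <- function(idx) {
    idx <- idx[order(-changes[idx], -fr[idx], cands[idx])]
    idx[1]
  }
  rare_fallback <- FALSE
  idx <- which(common)
  if (max(changes[idx]) == 0L && max(changes) > 0L) {
    # rarity floor would freeze this codon; fall back to the best rare option
    rare_fallback <- TRUE
    idx <- seq_along(cands)
  }
  best <- pick_best(idx)
  list(codon = cands[best], n_changes = changes[best],
       rare_fallback = rare_fallback)
}

# map a seed window given in spacer coordinates (1-based inclusive, 5'->3'
# on the spacer) to 0-based protospacer positions. Spacer position i pairs
# with protospacer position L - i (0-based).
seed_to_protospacer <- function(seed_window, spacer_len) {
  stopifnot(length(seed_window) == 2L, seed_window[1] <= seed_window[2],
            seed_window[1] >= 1L, seed_window[2] <= spacer_len)
  seq.int(spacer_len - seed_window[2], spacer_len - seed_window[1])
}

#' Silently recode a protospacer
#'
#' Rewrites the protospacer with synonymous codon substitutions at one of
#' three scopes: `"C"` (the single codon admitting the most silent changes),
#' `"S"` (the seed region of the spacer) or `"F"` (the full protospacer).
#' Within each in-scope codon the synonymous alternative maximizing the
#' number of nucleotide changes is chosen, excluding codons rarer than
#' `rare_threshold` (ties broken by higher usage, then alphabetically, so
#' output is deterministic). Substitutions are confined to the protospacer:
#' codons that straddle its edges may change only at in-window positions.
#'
#' @param genome A `phage_genome`.
#' @param spacer A `spacer_design` whose protospacer lies fully inside an
#'   annotated CDS.
#' @param mode `"C"`, `"S"` or `"F"`.
#' @param usage Codon usage table (see [read_codon_usage()]).
#' @param rare_threshold Codons with relative usage below this are avoided
#'   (default 0.10) unless that would freeze a codon entirely.
#' @param seed_window Spacer positions (1-based, inclusive) of the seed
#'   region; default `c(5, 12)`.
#' @return A `recode_design` with the change ledger and SNP count.
#' @export
recode <- function(genome, spacer, mode = c("C", "S", "F"),
                   usage = default_codon_usage(), rare_threshold = 0.10,
                   seed_window = c(5L, 12L)) {
  mode <- match.arg(mode)
  stopifnot(inherits(spacer, "spacer_design"))
  if (is.na(spacer$gene_id) || is.null(spacer$interval)) {
    stop("spacer does not target an annotated gene; cannot recode",
         call. = FALSE)
  }
  ft <- feature_by_id(genome, spacer$gene_id)
  if (ft$kind != "CDS") stop("target feature is not a CDS", call. = FALSE)
  L <- nchar(spacer$protospacer)
  t_start <- if (ft$strand == "+") spacer$interval$start - ft$start
             else ft$end - spacer$interval$end
  cds_len <- ft$end - ft$start
  if (t_start < 0L || t_start + L > cds_len) {
    stop("protospacer is not fully contained in CDS ", spacer$gene_id,
         "; recoding requires an in-frame CDS target", call. = FALSE)
  }
  frame_offset <- t_start %% 3L
  c0 <- t_start %/% 3L
  c1 <- (t_start + L - 1L) %/% 3L
  tx <- transcript_sequence(genome, spacer$gene_id)
  context <- substr(tx, c0 * 3L + 1L, (c1 + 1L) * 3L)
  codons <- split_codons(context)

  scope <- switch(mode,
    F = seq.int(0L, L - 1L),
    S = seed_to_protospacer(seed_window, L),
    C = seq.int(0L, L - 1L))  # candidate region; one codon picked below

  plan <- lapply(seq_along(codons), function(k) {
    ci <- c0 + k - 1L
    pos <- ci * 3L + 0:2 - t_start           # protospacer coords of codon
    mutable <- which(pos %in% intersect(scope, seq.int(0L, L - 1L)))
    list(k = k, original = codons[k], mutable = mutable)
  })

  warnings <- character()
  if (mode == "C") {
    best <- lapply(plan, function(p) {
      if (!length(p$mutable)) return(list(n_changes = 0L))
      pick_codon(p$original, p$mutable, usage, rare_threshold)
    })
    nch <- vapply(best, `[[`, integer(1), "n_changes")
    if (max(nch) == 0L) {
      stop("no silent change possible in any protospacer codon of ",
           spacer$gene_id, call. = FALSE)
    }
    chosen <- which(nch == max(nch))[1]   # ties: closest to protospacer 5'
    plan <- lapply(seq_along(plan), function(k) {
      p <- plan[[k]]
      if (k != chosen) p$mutable <- integer()
      p
    })
  }

  new_codons <- codons
  changes <- list()
  for (p in plan) {
    if (!length(p$mutable)) next
    sel <- pick_codon(p$original, p$mutable, usage, rare_threshold)
    if (sel$rare_fallback) {
      warnings <- c(warnings, paste0("codon ", p$k, " (", p$original,
                                     "): only rare synonymous options; ",
                                     "best rare codon used"))
    }
    if (sel$codon != p$original) {
      diffpos <- which(strsplit(sel$codon, "")[[1]] !=
                         strsplit(p$original, "")[[1]])
      changes[[length(changes) + 1L]] <-
        data.frame(codon_index = c0 + p$k - 1L, old = p$original,
                   new = sel$codon,
                   positions = paste(diffpos, collapse = ","),
                   stringsAsFactors = FALSE)
      new_codons[p$k] <- sel$codon
    }
  }
  if (mode != "C" && !length(changes)) {
    warnings <- c(warnings, "no silent change possible in scope")
  }
  recoded_context <- paste(new_codons, collapse = "")
  off <- t_start - c0 * 3L
  recoded <- substr(recoded_context, off + 1L, off + L)
  stopifnot(translate_dna(context) == translate_dna(recoded_context))
  d <- structure(list(
    mode = mode, gene_id = spacer$gene_id, frame_offset = frame_offset,
    protospacer = spacer$protospacer, recoded = recoded,
    context_original = context, context_recoded = recoded_context,
    t_start = t_start, interval = spacer$interval,
    changes = if (length(changes)) do.call(rbind, changes) else
      data.frame(codon_index = integer(), old = character(),
                 new = character(), positions = character()),
    snp_count = hamming(spacer$protospacer, recoded),
    seed_window = seed_window, warnings = warnings),
    class = "recode_design")
  for (w in warnings) warning(w, call. = FALSE)
  d
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' @export
print.recode_design <- function(x, ...) {
  cat(sprintf("<recode_design> %s-%s: %d SNP(s)\n", x$gene_id, x$mode,
              x$snp_count))
  cat("  wt      ", x$protospacer, "\n  recoded ", x$recoded, "\n", sep = "")
  mark <- ifelse(strsplit(x$protospacer, "")[[1]] ==
                   strsplit(x$recoded, "")[[1]], " ", "*")
  cat("          ", paste(mark, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Advisory escape prediction for a recode design
#'
#' Counterselection escape appears to require multiple contiguous mismatches
#' inside the spacer seed region; designs with fewer are predicted to remain
#' Cas13a-sensitive (single-codon and seed recodings of soc went to
#' extinction under enrichment, while designs with >= 3 contiguous seed
#' changes survived).
#'
#' @param design A `recode_design`.
#' @param min_contiguous_seed_changes Minimum run of contiguous substituted
#'   positions inside the seed window for a predicted escape. Default 3.
#' @return `"ESCAPES"` or `"AT_RISK"` (advisory only).
#' @export
predict_escape <- function(design, min_contiguous_seed_changes = 3L) {
  stopifnot(inherits(design, "recode_design"))
  L <- nchar(design$protospacer)
  changed <- strsplit(design$protospacer, "")[[1]] !=
    strsplit(design$recoded, "")[[1]]
  seedpos <- seed_to_protospacer(design$seed_window, L) + 1L
  in_seed <- logical(L)
  in_seed[seedpos] <- TRUE
  runs <- rle(changed & in_seed)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  if (longest >= min_contiguous_seed_changes) "ESCAPES" else "AT_RISK"
}

#' SNP counts for all three recoding scopes of a gene
#'
#' Convenience report: designs a CDS-start spacer on `gene_id` and recodes
#' it in C, S and F mode, returning the per-scope SNP counts. Useful for
#' side-by-side comparison with published recoding designs.
#'
#' @inheritParams recode
#' @param gene_id CDS feature id.
#' @param spacer_len Spacer length (default 31).
#' @return Data frame with columns `gene_id`, `mode`, `snp_count`, `escape`.
#' @export
recode_snp_report <- function(genome, gene_id, usage = default_codon_usage(),
                              rare_threshold = 0.10, seed_window = c(5L, 12L),
                              spacer_len = 31L) {
  sp <- design_cds_start_spacer(genome, gene_id, spacer_len)
  rows <- lapply(c("C", "S", "F"), function(m) {
    d <- suppressWarnings(recode(genome, sp, m, usage, rare_threshold,
                                 seed_window))
    data.frame(gene_id = gene_id, mode = m, snp_count = d$snp_count,
               escape = predict_escape(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
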