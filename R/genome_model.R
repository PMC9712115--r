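# Annotated-genome container and strand/frame-aware coordinate services.
#
# Internal coordinates are 0-based half-open throughout; everything a user
# sees (GenBank features, TSV coordinate tables, reports) is 1-based
# inclusive. `span_length(165257, 168510) == 3254` pins the convention.

#' Construct an annotated phage genome
#'
#' @param id Record identifier.
#' @param sequence Nucleotide string; upper-cased on construction. Only
#'   A/C/G/T/N are accepted; other IUPAC ambiguity codes are rejected.
#' @param features Data frame with columns `gene_id`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`), `kind` (`CDS`/`other`) and
#'   optionally `partial` (logical). May be `NULL` for no annotation.
#' @param topology `"linear"` (default) or `"circular"`.
#' @return An object of class `phage_genome`.
#' @export
phage_genome <- function(id, sequence, features = NULL,
                         topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("genome sequence is empty", call. = FALSE)
  assert_dna(sequence, "genome sequence")
  if (is.null(features)) {
    features <- data.frame(gene_id = character(), start = integer(),
                           end = integer(), strand = character(),
                           kind = character(), partial = logical(),
                           stringsAsFactors = FALSE)
  }
  if (is.null(features$partial)) features$partial <- FALSE
  features <- features[, c("gene_id", "start", "end", "strand", "kind",
                           "partial")]
  g <- structure(list(id = id, sequence = sequence, topology = topology,
                      features = features),
                 class = "phage_genome")
  validate_genome(g)
}

validate_genome <- function(g) {
  f <- g$features
  n <- genome_length(g)
  if (nrow(f)) {
    if (any(!f$strand %in% c("+", "-")))
      stop("feature strand must be '+' or '-'", call. = FALSE)
    bad <- f$start < 0L | f$end > n | f$start >= f$end
    if (any(bad))
      stop("feature out of bounds or empty: ",
           paste(f$gene_id[bad], collapse = ", "), call. = FALSE)
    cds <- f$kind == "CDS" & !f$partial
    notrip <- cds & ((f$end - f$start) %% 3L != 0L)
    if (any(notrip))
      stop("CDS length not a multiple of 3 (and not flagged partial): ",
           paste(f$gene_id[notrip], collapse = ", "), call. = FALSE)
    if (anyDuplicated(f$gene_id[!f$partial]))
      stop("duplicated gene_id in features", call. = FALSE)
  }
  g
}

#' @export
print.phage_genome <- function(x, ...) {
  cat(sprintf("<phage_genome> %s: %s bp, %s, %d feature(s)\n",
              x$id, format(genome_length(x), big.mark = ","), x$topology,
              nrow(x$features)))
  if (nrow(x$features)) {
    f <- x$features
    cat(sprintf("  %s [%s] %s..%s (%s)\n", f$gene_id, f$kind,
                f$start + 1L, f$end, f$strand), sep = "")
  }
  invisible(x)
}

#' Genome length in bp
#' @param genome A `phage_genome`.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

#' Length of a 1-based inclusive span
#'
#' The inclusive-coordinate convention used in all user-facing reports:
#' a span written `start..end` covers `end - start + 1` bases, so the
#' 165,257..168,510 deletion spans 3,254 bp.
#'
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return Integer span length in bp.
#' @export
#' @examples
#' span_length(165257, 168510)  # 3254
span_length <- function(start, end) {
  if (any(start > end)) stop("start > end", call. = FALSE)
  as.integer(end - start + 1)
}

# 1-based inclusive -> 0-based half-open and back
to_internal <- function(start1, end1) c(start = start1 - 1L, end = end1)
to_external <- function(start0, end0) c(start = start0 + 1L, end = end0)

# extract genome[start0, end0) with wrap-around on circular genomes.
# start0 may be negative / end0 may exceed length only when circular.
genome_slice <- function(genome, start0, end0) {
  n <- genome_length(genome)
  if (start0 >= end0) stop("empty slice", call. = FALSE)
  if (start0 >= 0L && end0 <= n) {
    return(substr(genome$sequence, start0 + 1L, end0))
  }
  if (genome$topology != "circular") {
    stop("slice [", start0, ", ", end0, ") out of bounds on linear genome ",
         genome$id, " (length ", n, ")", call. = FALSE)
  }
  if (end0 - start0 > n) stop("slice longer than circular genome", call. = FALSE)
  idx <- ((seq.int(start0, end0 - 1L)) %% n) + 1L
  paste(strsplit(genome$sequence, "")[[1]][idx], collapse = "")
}

feature_by_id <- function(genome, gene_id) {
  f <- genome$features
  hit <- which(f$gene_id == gene_id & !f$partial)
  if (!length(hit)) hit <- which(f$gene_id == gene_id)
  if (!length(hit)) {
    stop("unknown gene id '", gene_id, "' in genome ", genome$id,
         call. = FALSE)
  }
  f[hit[1], ]
}

#' mRNA-sense sequence of an annotated gene
#'
#' Returns the transcript-sense sequence of a gene, optionally extended
#' `upstream` nt before its start codon and `downstream` nt after its stop
#' codon (both in transcript orientation). On minus-strand genes the result
#' is the reverse complement of the corresponding genomic slice.
#'
#' @param genome A `phage_genome`.
#' @param gene_id Feature identifier.
#' @param upstream,downstream Non-negative extension lengths in nt.
#' @return Character scalar, transcript 5'->3'.
#' @export
transcript_sequence <- function(genome, gene_id, upstream = 0L,
                                downstream = 0L) {
  stopifnot(upstream >= 0L, downstream >= 0L)
  ft <- feature_by_id(genome, gene_id)
  if (ft$strand == "+") {
    s <- genome_slice(genome, ft$start - upstream, ft$end + downstream)
    s
  } else {
    s <- genome_slice(genome, ft$start - downstream, ft$end + upstream)
    revcomp(s)
  }
}

# map a transcript-coordinate window (0-based half-open, relative to the
# start codon's first base = 0; negative = upstream) of a gene onto genome
# coordinates. Returns list(start, end, strand) 0-based half-open.
transcript_window_to_genome <- function(genome, gene_id, t_start, t_end) {
  ft <- feature_by_id(genome, gene_id)
  if (ft$strand == "+") {
    list(start = ft$start + t_start, end = ft$start + t_end, strand = "+")
  } else {
    list(start = ft$end - t_end, end = ft$end - t_start, strand = "-")
  }
}

## ---------------------------------------------------------------- I/O ----

#' Read a genome with annotations
#'
#' Reads a GenBank flat file (sequence + CDS features) or a FASTA file.
#' FASTA input carries no annotation, so CDS features must be supplied as a
#' TSV coordinate table with columns `gene_id`, `start`, `end` (1-based
#' inclusive) and `strand`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"genbank"` or `"fasta"`.
#' @param feature_table Optional path to a TSV coordinate table (FASTA input).
#' @return A `phage_genome`.
#' @export
read_genome <- function(path, format = c("auto", "genbank", "fasta"),
                        feature_table = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  if (format == "genbank") {
    read_genbank(path)
  } else {
    set <- Biostrings::readDNAStringSet(path)
    if (!length(set)) stop("no records in FASTA file ", path, call. = FALSE)
    id <- sub("\\s.*$", "", names(set)[1])
    seq <- toupper(as.character(set[[1]]))
    assert_dna(seq, paste0("FASTA record ", id))
    feats <- NULL
    if (!is.null(feature_table)) feats <- read_feature_table(feature_table)
    phage_genome(id, seq, feats)
  }
}

#' Read a TSV gene-coordinate table
#'
#' Columns: `gene_id`, `start` (1-based), `end` (inclusive), `strand`;
#' optional `kind` (default `CDS`).
#'
#' @param path TSV path.
#' @return Feature data frame in internal 0-based half-open coordinates.
#' @export
read_feature_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "start", "end", "strand")
  if (!all(need %in% names(tb))) {
    stop("coordinate table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(tb$start > tb$end))
    stop("coordinate table has start > end", call. = FALSE)
  data.frame(gene_id = tb$gene_id,
             start = as.integer(tb$start) - 1L,
             end = as.integer(tb$end),
             strand = tb$strand,
             kind = tb$kind %||% rep("CDS", nrow(tb)),
             partial = FALSE,
             stringsAsFactors = FALSE)
}

# Minimal GenBank flat-file reader: LOCUS (name, topology), FEATURES with
# CDS/gene entries (simple and complement() locations; join() of two
# segments is split into partial-flagged rows), ORIGIN sequence block.
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1])) {
    stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
  }
  toks <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  id <- if (length(toks) >= 2) toks[2] else "genome"
  topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"

  ofeat <- grep("^ORIGIN", lines)
  if (!length(ofeat)) stop("GenBank file has no ORIGIN block: ", path,
                           call. = FALSE)
  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1L):(ofeat[1] - 1L)]
    cur <- NULL
    flush <- function(cur) {
      if (is.null(cur)) return(NULL)
      parse_gb_feature(cur, path)
    }
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) {              # new feature
        feats <- c(feats, list(flush(cur)))
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        cur <- list(kind = parts[1], loc = paste(parts[-1], collapse = ""),
                    quals = character())
      } else if (!is.null(cur) && grepl("^ {10,}\\S", ln)) {
        txt <- trimws(ln)
        if (startsWith(txt, "/")) cur$quals <- c(cur$quals, txt)
        else cur$loc <- paste0(cur$loc, txt)    # continuation of location
      }
    }
    feats <- c(feats, list(flush(cur)))
    feats <- feats[!vapply(feats, is.null, logical(1))]
  }
  fdf <- if (length(feats)) do.call(rbind, feats) else NULL

  seq_lines <- lines[(ofeat[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))
  assert_dna(seq, paste0("GenBank record ", id))
  phage_genome(id, seq, fdf, topology)
}

parse_gb_feature <- function(cur, path) {
  if (!cur$kind %in% c("CDS", "gene", "misc_feature")) return(NULL)
  if (cur$kind == "gene") return(NULL)  # companion of CDS; skip
  gid <- NA_character_
  for (q in cur$quals) {
    m <- regmatches(q, regexec('^/(gene|locus_tag|label)="?([^"]+)"?$', q))[[1]]
    if (length(m) == 3 && is.na(gid)) gid <- m[3]
  }
  loc <- cur$loc
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  segs <- loc
  joined <- FALSE
  if (grepl("^join\\(", loc)) {
    joined <- TRUE
    segs <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
  }
  rows <- lapply(segs, function(s) {
    m <- regmatches(s, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", s))[[1]]
    if (length(m) != 3) {
      stop("cannot parse feature location '", cur$loc, "' in ", path,
           call. = FALSE)
    }
    partial <- joined || grepl("[<>]", s)
    data.frame(gene_id = if (is.na(gid)) paste0("feat_", m[2]) else gid,
               start = as.integer(m[2]) - 1L, end = as.integer(m[3]),
               strand = strand,
               kind = if (cur$kind == "CDS") "CDS" else "other",
               partial = partial, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a genome to GenBank or FASTA (+ coordinate table)
#'
#' @param genome A `phage_genome`.
#' @param path Output path.
#' @param format `"genbank"` or `"fasta"`.
#' @param feature_table For FASTA output, optional path for the TSV
#'   coordinate table (1-based inclusive).
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, format = c("genbank", "fasta"),
                         feature_table = NULL) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::DNAStringSet(genome$sequence)
    names(set) <- genome$id
    Biostrings::writeXStringSet(set, path)
    if (!is.null(feature_table)) write_feature_table(genome, feature_table)
    return(invisible(path))
  }
  n <- genome_length(genome)
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s   PHG",
                   genome$id, n, genome$topology),
           sprintf("DEFINITION  %s.", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", n))
  f <- genome$features
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
      if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      kind <- if (f$kind[i] == "CDS") "CDS" else "misc_feature"
      out <- c(out,
               sprintf("     %-16s%s", kind, loc),
               sprintf("                     /gene=\"%s\"", f$gene_id[i]))
    }
  }
  out <- c(out, "ORIGIN")
  seq <- tolower(genome$sequence)
  starts <- seq(1L, n, 60L)
  for (s in starts) {
    chunk <- substr(seq, s, min(s + 59L, n))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", s, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_genome
#' @export
write_feature_table <- function(genome, path) {
  f <- genome$features
  tb <- data.frame(gene_id = f$gene_id, start = f$start + 1L, end = f$end,
                   strand = f$strand, kind = f$kind)
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export intervals as BED (0-based half-open)
#'
#' @param intervals Data frame with columns `start`, `end` (0-based
#'   half-open), `name`, `strand`; optional `score`.
#' @param genome_id Chromosome/record name for column 1.
#' @param path Output path.
#' @export
write_bed <- function(intervals, genome_id, path) {
  bed <- data.frame(chrom = genome_id,
                    start = intervals$start,
                    end = intervals$end,
                    name = intervals$name,
                    score = intervals$score %||% rep(0L, nrow(intervals)),
                    strand = intervals$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
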