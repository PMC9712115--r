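# Homologous-recombination donor design and golden-gate chemistry.
#
# Donors carry two homology arms copied verbatim from the wildtype genome
# around the edit: 250 bp arms for gene/span deletions (with a constant
# primer-binding verification cassette between them) and 52 nt arms
# flanking a recoded protospacer. Fragments are emitted with the 4-nt 5'
# overhangs of the BsaI/BbsI type IIS cloning scheme, and edits can be
# applied and verified in silico.

#' The verification-cassette primer-binding site
#'
#' Constant payload inserted between the arms of deletion donors; N- and
#' C-terminal junction PCRs prime on it.
#' @return Character scalar (32 nt).
#' @export
verification_cassette <- function() "GATAAGAGACGGCTCAACGCCCGTCTCACAGC"

#' The BsaI spacer-cloning dropout sequence
#'
#' The crRNA placeholder region of the expression plasmid: two opposing
#' BsaI sites whose outward cuts release the placeholder and expose the
#' destination overhangs for spacer-duplex ligation.
#' @return Character scalar.
#' @export
bsai_dropout <- function() "AAACAGAGACCTCGTTTACCTATCGGTCTCATGCT"

new_donor_design <- function(kind, up_arm, payload, dn_arm, edit, arm_len,
                             gene_id = NA_character_, orientation = "+",
                             extra = list()) {
  structure(c(list(kind = kind, up_arm = up_arm, payload = payload,
                   dn_arm = dn_arm, edit = edit, arm_len = arm_len,
                   gene_id = gene_id, orientation = orientation),
              extra),
            class = "donor_design")
}

#' @export
print.donor_design <- function(x, ...) {
  cat(sprintf("<donor_design> %s%s: arms %d/%d nt, payload %d nt\n",
              x$kind, if (!is.na(x$gene_id)) paste0(" (", x$gene_id, ")")
              else "", nchar(x$up_arm), nchar(x$dn_arm), nchar(x$payload)))
  cat(sprintf("  edit %d..%d (%s)\n", x$edit$start + 1L, x$edit$end,
              x$edit$strand))
  invisible(x)
}

#' Donor sequence (UP arm + payload + DN arm)
#' @param donor A `donor_design`.
#' @export
donor_sequence <- function(donor) {
  paste0(donor$up_arm, donor$payload, donor$dn_arm)
}

#' Design a gene-deletion donor
#'
#' Deletes the CDS interior while leaving the native start and stop codons
#' intact: the UP arm ends with the last base of the start codon, the DN
#' arm begins with the first base of the stop codon, and the verification
#' cassette sits between them. Arms are taken in transcript orientation.
#'
#' @param genome A `phage_genome`.
#' @param gene_id CDS feature id.
#' @param arm_len Homology arm length in bp (default 250).
#' @param cassette Payload between the arms (default the verification
#'   cassette).
#' @return A `donor_design` of kind `GENE_DELETION`.
#' @export
design_gene_deletion_donor <- function(genome, gene_id, arm_len = 250L,
                                       cassette = verification_cassette()) {
  ft <- feature_by_id(genome, gene_id)
  if (ft$kind != "CDS") stop(gene_id, " is not a CDS", call. = FALSE)
  cds_len <- ft$end - ft$start
  if (cds_len < 9L) stop("gene ", gene_id, " too short to delete an interior",
                         call. = FALSE)
  flank <- arm_len - 3L
  ext <- tryCatch(
    transcript_sequence(genome, gene_id, upstream = flank, downstream = flank),
    error = function(e) stop("insufficient flank for ", arm_len,
                             " bp arms around ", gene_id, ": ",
                             conditionMessage(e), call. = FALSE))
  up_arm <- substr(ext, 1L, arm_len)                       # ... + ATG
  dn_arm <- substr(ext, nchar(ext) - arm_len + 1L, nchar(ext))  # stop + ...
  edit <- transcript_window_to_genome(genome, gene_id, 3L, cds_len - 3L)
  new_donor_design("GENE_DELETION", up_arm, cassette, dn_arm, edit, arm_len,
                   gene_id, ft$strand)
}

#' Design a coordinate-span deletion donor
#'
#' Deletes an arbitrary 1-based inclusive genomic span (for example a
#' multi-gene region), reporting which annotated genes are entirely removed
#' and which are truncated at a breakpoint. Arms flank the span on the top
#' strand.
#'
#' @inheritParams design_gene_deletion_donor
#' @param start,end Deleted span, 1-based inclusive.
#' @export
design_span_deletion_donor <- function(genome, start, end, arm_len = 250L,
                                       cassette = verification_cassette()) {
  n <- genome_length(genome)
  if (start < 1L || end > n || start > end) {
    stop("span ", start, "..", end, " out of bounds for genome of ", n,
         " bp", call. = FALSE)
  }
  s0 <- start - 1L; e0 <- end
  up_arm <- tryCatch(genome_slice(genome, s0 - arm_len, s0),
                     error = function(e)
                       stop("insufficient upstream flank for ", arm_len,
                            " bp arm", call. = FALSE))
  dn_arm <- tryCatch(genome_slice(genome, e0, e0 + arm_len),
                     error = function(e)
                       stop("insufficient downstream flank for ", arm_len,
                            " bp arm", call. = FALSE))
  f <- genome$features
  inside <- f$start >= s0 & f$end <= e0
  overlap <- f$start < e0 & f$end > s0
  truncated <- overlap & !inside
  new_donor_design("SPAN_DELETION", up_arm, cassette, dn_arm,
                   list(start = s0, end = e0, strand = "+"), arm_len,
                   extra = list(deletion_bp = span_length(start, end),
                                genes_removed = f$gene_id[inside],
                                genes_truncated = f$gene_id[truncated]))
}

#' Design a recoding donor
#'
#' The payload is the recoded protospacer; the arms are the wildtype
#' flanks of the protospacer (default 52 nt) in transcript orientation.
#'
#' @inheritParams design_gene_deletion_donor
#' @param design A `recode_design`.
#' @param arm_len Homology arm length in nt (default 52).
#' @export
design_recode_donor <- function(genome, design, arm_len = 52L) {
  stopifnot(inherits(design, "recode_design"))
  ft <- feature_by_id(genome, design$gene_id)
  L <- nchar(design$protospacer)
  cds_len <- ft$end - ft$start
  t0 <- design$t_start
  u_need <- max(0L, arm_len - t0)
  d_need <- max(0L, t0 + L + arm_len - cds_len)
  ext <- tryCatch(
    transcript_sequence(genome, design$gene_id, u_need, d_need),
    error = function(e) stop("insufficient flank for ", arm_len,
                             " nt recoding arms: ", conditionMessage(e),
                             call. = FALSE))
  p_start <- u_need + t0                    # 0-based offset in ext
  up_arm <- substr(ext, p_start - arm_len + 1L, p_start)
  dn_arm <- substr(ext, p_start + L + 1L, p_start + L + arm_len)
  stopifnot(substr(ext, p_start + 1L, p_start + L) == design$protospacer)
  new_donor_design("RECODE", up_arm, design$recoded, dn_arm,
                   design$interval, arm_len, design$gene_id, ft$strand,
                   extra = list(snp_count = design$snp_count))
}

## ------------------------------------------------- type IIS chemistry ----

type2s_enzymes <- list(
  BsaI = list(recognition = "GGTCTC", spacer = 1L, overhang = 4L),
  BbsI = list(recognition = "GAAGAC", spacer = 2L, overhang = 4L)
)

#' Locate type IIS recognition sites
#'
#' @param seq Sequence to scan.
#' @param enzyme `"BsaI"` or `"BbsI"`.
#' @return Data frame with 1-based `position` and `orientation` (`+` for
#'   the recognition sequence on the given strand, `-` for its reverse
#'   complement).
#' @export
find_enzyme_sites <- function(seq, enzyme = c("BsaI", "BbsI")) {
  enzyme <- match.arg(enzyme)
  rec <- type2s_enzymes[[enzyme]]$recognition
  seq <- toupper(seq)
  fwd <- find_all(rec, seq)
  rev <- find_all(revcomp(rec), seq)
  out <- rbind(
    if (length(fwd)) data.frame(position = fwd, orientation = "+"),
    if (length(rev)) data.frame(position = rev, orientation = "-"))
  if (is.null(out)) data.frame(position = integer(), orientation = character())
  else out[order(out$position), , drop = FALSE]
}

# cut coordinates for each site: 0-based positions at which the top and
# bottom strands are severed (cut falls before the given index). A forward
# site GGTCTC(N1) cuts top at site+6+spacer, bottom `overhang` further; a
# reverse-orientation site cuts mirror-image upstream.
type2s_cut_positions <- function(seq, enzyme) {
  enz <- type2s_enzymes[[enzyme]]
  sites <- find_enzyme_sites(seq, enzyme)
  if (!nrow(sites)) return(data.frame(top = integer(), bottom = integer()))
  cuts <- lapply(seq_len(nrow(sites)), function(i) {
    p0 <- sites$position[i] - 1L
    if (sites$orientation[i] == "+") {
      top <- p0 + 6L + enz$spacer
      data.frame(top = top, bottom = top + enz$overhang)
    } else {
      bottom <- p0 - enz$spacer
      data.frame(top = bottom - enz$overhang, bottom = bottom)
    }
  })
  out <- do.call(rbind, cuts)
  out[order(out$top), , drop = FALSE]
}

#' Simulate a type IIS digestion
#'
#' Cuts a linear sequence at every recognition site of the enzyme and
#' returns the fragments with their 4-nt 5' overhang annotations:
#' `left_overhang` is the protruding top-strand 5' end, and
#' `right_overhang_bottom` the protruding bottom-strand 5' end (written
#' 5'->3'). Cut positions falling outside the sequence raise an error.
#'
#' @inheritParams find_enzyme_sites
#' @return List of fragments, each a list with `top` (double-stranded core
#'   plus top overhang), `left_overhang`, `right_overhang_bottom`.
#' @export
digest_type2s <- function(seq, enzyme = c("BsaI", "BbsI")) {
  enzyme <- match.arg(enzyme)
  seq <- toupper(seq)
  cuts <- type2s_cut_positions(seq, enzyme)
  n <- nchar(seq)
  if (nrow(cuts) && (min(cuts$top) < 0L || max(cuts$bottom) > n)) {
    stop("a ", enzyme, " cut falls outside the supplied sequence",
         call. = FALSE)
  }
  bounds <- rbind(data.frame(top = 0L, bottom = 0L), cuts,
                  data.frame(top = n, bottom = n))
  frags <- list()
  for (i in seq_len(nrow(bounds) - 1L)) {
    a <- bounds[i, ]; b <- bounds[i + 1L, ]
    top <- substr(seq, a$top + 1L, b$top)
    lo <- if (a$bottom > a$top) substr(seq, a$top + 1L, a$bottom) else ""
    ro <- if (b$bottom > b$top) revcomp(substr(seq, b$top + 1L, b$bottom))
          else ""
    frags[[i]] <- list(top = top, left_overhang = lo,
                       right_overhang_bottom = ro)
  }
  frags
}

#' Destination and insert overhangs of a BsaI spacer dropout
#'
#' Simulates the outward BsaI cuts on the dropout placeholder and derives
#' the 4-nt 5' overhangs: what the digested destination vector presents and
#' what a spacer insert must therefore carry.
#'
#' @param dropout Dropout sequence (default the shipped placeholder).
#' @return List with `insert_top`, `insert_bottom` (the 5' overhangs of the
#'   spacer duplex) and `vector_left`, `vector_right` (the complementary
#'   vector-end overhangs).
#' @export
bsai_dropout_overhangs <- function(dropout = bsai_dropout()) {
  dropout <- toupper(dropout)
  sites <- find_enzyme_sites(dropout, "BsaI")
  if (nrow(sites) != 2L || length(unique(sites$orientation)) != 2L) {
    stop("dropout must contain exactly two BsaI sites in opposing ",
         "orientation (found ", nrow(sites), ")", call. = FALSE)
  }
  mid <- digest_type2s(dropout, "BsaI")[[2]]
  list(insert_top = mid$left_overhang,
       insert_bottom = mid$right_overhang_bottom,
       vector_left = revcomp(mid$left_overhang),
       vector_right = revcomp(mid$right_overhang_bottom))
}

#' Emit the spacer-cloning oligo pair
#'
#' Two complementary oligos that anneal into the spacer duplex with the
#' 4-nt 5' overhangs matching the BsaI-digested destination ends.
#'
#' @param spacer A `spacer_design` or spacer sequence.
#' @param dropout Destination dropout sequence.
#' @return List with `top`, `bottom` oligos and the `overhangs` used.
#' @export
emit_spacer_oligos <- function(spacer, dropout = bsai_dropout()) {
  if (inherits(spacer, "spacer_design")) spacer <- spacer$spacer
  ov <- bsai_dropout_overhangs(dropout)
  list(top = paste0(ov$insert_top, spacer),
       bottom = paste0(ov$insert_bottom, revcomp(spacer)),
       overhangs = ov)
}

#' Simulate golden-gate ligation of a spacer duplex into its vector
#'
#' Joins the insert between the digested vector ends and returns the
#' junction region top strand; a scarless ligation retains no recognition
#' site of the cloning enzyme.
#'
#' @param oligos Result of [emit_spacer_oligos()].
#' @param vector_left,vector_right Vector top-strand context on each side
#'   of the dropout (up to its cut positions).
#' @param dropout Dropout used for the destination overhangs.
#' @return Character scalar, the ligated top strand.
#' @export
ligate_spacer <- function(oligos, vector_left = "", vector_right = "",
                          dropout = bsai_dropout()) {
  ov <- bsai_dropout_overhangs(dropout)
  paste0(vector_left, oligos$top, ov$vector_right, vector_right)
}

#' Emit a donor insert as a BbsI golden-gate fragment
#'
#' The insert carries 5'-TATC and (bottom strand) 5'-TCCT overhangs,
#' complementary to the ATAG/AGGA ends revealed by BbsI digestion of the
#' RFP-dropout destination vector. Internal BsaI/BbsI sites in the donor
#' (which would cut during assembly) are reported as domestication
#' warnings, not errors.
#'
#' @param donor A `donor_design`.
#' @param left_overhang Insert top-strand 5' overhang (default `"TATC"`).
#' @param right_overhang_bottom Insert bottom-strand 5' overhang (default
#'   `"TCCT"`).
#' @return List of class `goldengate_fragment`: `top`, `core`, overhangs,
#'   `destination` overhangs (written 5'->3', so the left one reads GATA,
#'   i.e. 3'-ATAG-5' on the vector), `enzyme`, `domestication` data frame.
#' @export
emit_donor_fragment <- function(donor, left_overhang = "TATC",
                                right_overhang_bottom = "TCCT") {
  core <- donor_sequence(donor)
  dom <- do.call(rbind, lapply(c("BsaI", "BbsI"), function(e) {
    s <- find_enzyme_sites(core, e)
    if (nrow(s)) cbind(enzyme = e, s) else NULL
  }))
  if (is.null(dom)) {
    dom <- data.frame(enzyme = character(), position = integer(),
                      orientation = character())
  }
  if (nrow(dom)) {
    warning("donor contains internal type IIS site(s): ",
            paste(sprintf("%s at %d (%s)", dom$enzyme, dom$position,
                          dom$orientation), collapse = "; "),
            call. = FALSE)
  }
  structure(list(top = paste0(left_overhang, core),
                 core = core,
                 left_overhang = left_overhang,
                 right_overhang_bottom = right_overhang_bottom,
                 destination = c(left = revcomp(left_overhang),
                                 right = revcomp(right_overhang_bottom)),
                 enzyme = "BbsI",
                 domestication = dom),
            class = "goldengate_fragment")
}

#' Simulate golden-gate ligation of a donor fragment
#'
#' @param fragment A `goldengate_fragment`.
#' @param vector_left,vector_right Destination-vector top-strand context.
#' @return Character scalar, the ligated top strand.
#' @export
ligate_donor <- function(fragment, vector_left = "", vector_right = "") {
  paste0(vector_left, fragment$top,
         revcomp(fragment$right_overhang_bottom), vector_right)
}

## -------------------------------------------------- apply and verify ----

#' Apply a donor edit to a genome in silico
#'
#' Locates both homology arms by exact match (each must occur exactly once,
#' in consistent order; the reverse-complement orientation of the whole
#' donor is tried if the arms are not found as emitted) and replaces the
#' sequence between them with the payload. Feature coordinates to the right
#' of the edit are shifted; features overlapping the replaced interval are
#' dropped and recorded, and the edit itself is annotated.
#'
#' @param genome A `phage_genome`.
#' @param donor A `donor_design`.
#' @return The edited `phage_genome`; attribute `edit_info` records the
#'   replaced interval, length change and any dropped features.
#' @export
apply_edit <- function(genome, donor) {
  seq <- genome$sequence
  up <- donor$up_arm; dn <- donor$dn_arm; payload <- donor$payload
  u_hits <- find_all(up, seq); d_hits <- find_all(dn, seq)
  if (!length(u_hits) && !length(d_hits)) {
    up2 <- revcomp(donor$dn_arm); dn2 <- revcomp(donor$up_arm)
    u_hits <- find_all(up2, seq); d_hits <- find_all(dn2, seq)
    if (length(u_hits) || length(d_hits)) {
      up <- up2; dn <- dn2; payload <- revcomp(donor$payload)
    }
  }
  if (length(u_hits) != 1L || length(d_hits) != 1L) {
    if (!length(u_hits) || !length(d_hits)) {
      stop("homology arm not found in genome ", genome$id, call. = FALSE)
    }
    stop("homology arm matches multiple loci (UP: ", length(u_hits),
         ", DN: ", length(d_hits), ")", call. = FALSE)
  }
  u0 <- u_hits[1] - 1L                       # 0-based arm starts
  d0 <- d_hits[1] - 1L
  i0 <- u0 + nchar(up)                       # replaced interval [i0, d0)
  if (d0 < i0) stop("homology arms are inverted at the target locus",
                    call. = FALSE)
  new_seq <- paste0(substr(seq, 1L, i0), payload,
                    substr(seq, d0 + 1L, nchar(seq)))
  delta <- nchar(payload) - (d0 - i0)
  dropped <- character()
  edited <- genome
  edited$sequence <- new_seq
  if (nrow(genome$features) && !(donor$kind == "RECODE" && delta == 0L)) {
    f2 <- genome$features
    overlap <- !(f2$end <= i0 | f2$start >= d0)
    dropped <- f2$gene_id[overlap]
    f2 <- f2[!overlap, , drop = FALSE]
    shift <- f2$start >= d0
    f2$start[shift] <- f2$start[shift] + delta
    f2$end[shift] <- f2$end[shift] + delta
    edited$features <- f2
  }
  edit_feat <- data.frame(gene_id = paste0("edit_", tolower(donor$kind)),
                          start = i0, end = i0 + nchar(payload),
                          strand = "+", kind = "other", partial = FALSE,
                          stringsAsFactors = FALSE)
  if (nchar(payload)) edited$features <- rbind(edited$features, edit_feat)
  edited <- validate_genome(edited)
  attr(edited, "edit_info") <- list(replaced = c(start = i0, end = d0),
                                    delta = delta, dropped = dropped)
  edited
}

#' Check which spacers still find their target after an edit
#'
#' A spacer is `DISRUPTED` when its exact protospacer no longer occurs in
#' the edited genome on either strand, `INTACT` otherwise. An editing plan
#' is considered valid when the enrichment and verification spacers are
#' DISRUPTED while the positive-control spacer remains INTACT.
#'
#' @param edited An edited `phage_genome`.
#' @param spacers Named list of `spacer_design` objects.
#' @return Data frame with `name`, `gene`, `mode`, `status`.
#' @export
verify_escape <- function(edited, spacers) {
  if (inherits(spacers, "spacer_design")) spacers <- list(spacers)
  nm <- names(spacers) %||% paste0("spacer", seq_along(spacers))
  nm[nm == ""] <- paste0("spacer", which(nm == ""))
  rows <- lapply(seq_along(spacers), function(i) {
    sp <- spacers[[i]]
    hit <- count_both_strands(sp$protospacer, edited$sequence)
    data.frame(name = nm[i], gene = sp$gene_id, mode = sp$mode,
               status = if (hit == 0L) "DISRUPTED" else "INTACT",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Validity of an editing plan from verification statuses
#'
#' @param statuses Result of [verify_escape()].
#' @param roles Character vector (same length) among `enrichment`,
#'   `verification`, `positive`, `negative`.
#' @return Logical scalar.
#' @export
editing_plan_valid <- function(statuses, roles) {
  stopifnot(nrow(statuses) == length(roles))
  need_gone <- roles %in% c("enrichment", "verification")
  need_kept <- roles == "positive"
  all(statuses$status[need_gone] == "DISRUPTED") &&
    all(statuses$status[need_kept] == "INTACT")
}
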