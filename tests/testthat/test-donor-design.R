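test_that("gene-deletion donors keep start and stop codons inside 250 bp arms", {
  g <- make_toy_phage(seed = 51)
  for (gene in c("gene01", "gene02")) {      # plus and minus strand
    don <- design_gene_deletion_donor(g, gene)
    expect_equal(nchar(don$up_arm), 250L)
    expect_equal(nchar(don$dn_arm), 250L)
    expect_equal(substr(don$up_arm, 248, 250), "ATG")
    expect_true(substr(don$dn_arm, 1, 3) %in% c("TAA", "TAG", "TGA"))
    expect_identical(don$payload, verification_cassette())
  }
  tiny <- phage_genome("t", paste0(rnd_dna(20), "ATGTAA", rnd_dna(20)),
                       data.frame(gene_id = "g", start = 20L, end = 26L,
                                  strand = "+", kind = "CDS",
                                  partial = FALSE))
  expect_error(design_gene_deletion_donor(tiny, "g"), "too short")
  expect_error(design_gene_deletion_donor(g, "gene01", arm_len = 10000L),
               "insufficient flank")
})

test_that("span-deletion donors report removed and truncated genes", {
  g <- make_toy_phage(seed = 52)
  f <- g$features
  # span covering exactly gene02
  g2 <- f[f$gene_id == "gene02", ]
  d1 <- design_span_deletion_donor(g, g2$start + 1L, g2$end)
  expect_equal(d1$genes_removed, "gene02")
  expect_equal(length(d1$genes_truncated), 0L)
  expect_equal(d1$deletion_bp, g2$end - g2$start)
  # span cutting into gene02 and gene03
  g3 <- f[f$gene_id == "gene03", ]
  d2 <- design_span_deletion_donor(g, g2$end - 9L, g3$start + 10L)
  expect_setequal(d2$genes_truncated, c("gene02", "gene03"))
  expect_equal(length(d2$genes_removed), 0L)
  expect_error(design_span_deletion_donor(g, 5, genome_length(g) + 10),
               "out of bounds")
})

test_that("recode donors are the wildtype locus carrying only the SNPs", {
  g <- make_toy_phage(seed = 53)
  sp <- design_cds_start_spacer(g, "gene01")
  d <- suppressWarnings(recode(g, sp, "F"))
  don <- design_recode_donor(g, d)
  expect_equal(nchar(don$up_arm), 52L)
  expect_equal(nchar(don$dn_arm), 52L)
  expect_equal(nchar(don$payload), nchar(sp$protospacer))
  # donor = wildtype window with exactly snp_count differences
  wt <- transcript_sequence(g, "gene01", upstream = 52, downstream = 0)
  wt_win <- substr(wt, 1, 52 + 31 + 52)
  donor <- donor_sequence(don)
  expect_equal(nchar(donor), nchar(wt_win))
  diffs <- sum(strsplit(donor, "")[[1]] != strsplit(wt_win, "")[[1]])
  expect_equal(diffs, d$snp_count)
})

test_that("the printed BsaI dropout yields the expected overhang geometry", {
  drop <- bsai_dropout()
  sites <- find_enzyme_sites(drop, "BsaI")
  expect_equal(nrow(sites), 2L)
  expect_setequal(sites$orientation, c("+", "-"))
  ov <- bsai_dropout_overhangs(drop)
  # frozen from the enzyme geometry: GGTCTC(1/5) cutting outward exposes
  # the first four bases (AAAC, insert side) and the TGCT of the 3' flank
  expect_identical(ov$insert_top, "AAAC")
  expect_identical(ov$insert_bottom, "AGCA")
  expect_identical(ov$vector_left, "GTTT")
  expect_identical(ov$vector_right, "TGCT")
  # independent check: overhangs are 4 nt and mutually reverse-complementary
  expect_identical(oracle_revcomp(ov$insert_top), ov$vector_left)
  expect_identical(oracle_revcomp(ov$insert_bottom), ov$vector_right)
  expect_error(bsai_dropout_overhangs("AAACGGTCTCTTTT"), "two BsaI sites")
})

test_that("spacer oligos ligate scarlessly into the BsaI destination", {
  g <- make_toy_phage(seed = 54)
  sp <- design_cds_start_spacer(g, "gene03")
  ol <- emit_spacer_oligos(sp)
  expect_identical(ol$top, paste0("AAAC", sp$spacer))
  expect_identical(ol$bottom, paste0("AGCA", oracle_revcomp(sp$spacer)))
  set.seed(1)
  vl <- "CCTATATAAT"; vr <- "ATTATACCTA"   # site-free vector context
  lig <- ligate_spacer(ol, vl, vr)
  expect_false(oracle_contains(lig, "GGTCTC"))
  expect_false(oracle_contains(lig, oracle_revcomp("GGTCTC")))
  expect_true(oracle_contains(lig, sp$spacer))
})

test_that("donor fragments carry the printed TATC/TCCT BbsI overhangs", {
  g <- make_toy_phage(seed = 55)
  don <- design_gene_deletion_donor(g, "gene01")
  frag <- suppressWarnings(emit_donor_fragment(don))
  expect_identical(frag$left_overhang, "TATC")
  expect_identical(frag$right_overhang_bottom, "TCCT")
  # vector ends written 5'->3': GATA is the overhang printed 3'-ATAG-5'
  expect_identical(unname(frag$destination["left"]), "GATA")
  expect_identical(unname(frag$destination["right"]), "AGGA")
  lig <- ligate_donor(frag, "CCTATATAAT", "ATTATACCTA")
  expect_true(oracle_contains(lig, "TATC"))
  expect_true(oracle_contains(lig, "AGGA"))
  # the donor itself is in the ligation product
  expect_true(oracle_contains(lig, donor_sequence(don)))
})

test_that("internal type IIS sites trigger a domestication warning", {
  up <- rnd_dna(52); dn <- rnd_dna(52)
  payload <- paste0("ACGT", "GGTCTC", "TTAA")
  don <- cas13design:::new_donor_design("RECODE", up, payload, dn,
                                        list(start = 0L, end = 1L,
                                             strand = "+"), 52L)
  expect_warning(frag <- emit_donor_fragment(don), "BsaI at")
  pos <- frag$domestication$position[frag$domestication$enzyme == "BsaI"]
  expect_equal(pos, 52L + 5L)                # 1-based within the donor
})

test_that("apply_edit performs recodes in place and deletions with shifts", {
  g <- make_toy_phage(seed = 56)
  # recode: same length, Hamming = snp_count, features untouched
  sp <- design_cds_start_spacer(g, "gene01")
  d <- suppressWarnings(recode(g, sp, "F"))
  don <- design_recode_donor(g, d)
  ed <- apply_edit(g, don)
  expect_equal(genome_length(ed), genome_length(g))
  expect_equal(sum(strsplit(ed$sequence, "")[[1]] !=
                     strsplit(g$sequence, "")[[1]]), d$snp_count)
  # genes untouched, plus one annotation marking the edit
  expect_true(all(g$features$gene_id %in% ed$features$gene_id))
  expect_equal(nrow(ed$features), nrow(g$features) + 1L)
  # gene deletion: length drops by interior - cassette
  deld <- design_gene_deletion_donor(g, "gene02")
  interior <- deld$edit$end - deld$edit$start
  ed2 <- apply_edit(g, deld)
  expect_equal(genome_length(ed2),
               genome_length(g) - interior + nchar(verification_cassette()))
  # downstream features shifted; the deleted gene's record is gone
  expect_false("gene02" %in% ed2$features$gene_id)
  expect_true("gene03" %in% ed2$features$gene_id)
  tx3 <- transcript_sequence(ed2, "gene03")
  expect_equal(tx3, transcript_sequence(g, "gene03"))
  # arms from another genome: no match
  other <- make_toy_phage(seed = 99)
  expect_error(apply_edit(other, deld), "arm not found")
})

test_that("apply_edit rejects ambiguous and inverted arm placements", {
  core <- rnd_dna(400)
  dup <- phage_genome("dup", paste0(core, rnd_dna(50), core))
  don <- cas13design:::new_donor_design(
    "SPAN_DELETION", substr(core, 1, 60), "TTTT", substr(core, 101, 160),
    list(start = 0L, end = 1L, strand = "+"), 60L)
  expect_error(apply_edit(dup, don), "multiple loci")
  inv <- cas13design:::new_donor_design(
    "SPAN_DELETION", substr(core, 301, 360), "TTTT", substr(core, 1, 60),
    list(start = 0L, end = 1L, strand = "+"), 60L)
  single <- phage_genome("single", core)
  expect_error(apply_edit(single, inv), "inverted")
})

test_that("deletions disrupt enrichment and verification spacers only", {
  g <- make_toy_phage(seed = 57)
  don <- design_gene_deletion_donor(g, "gene02")
  enr <- design_cds_start_spacer(g, "gene02")
  ver <- design_deletion_verify_spacer(g, don$edit$start + 1L, don$edit$end,
                                       don$edit$strand, 5L)
  pos <- design_cds_start_spacer(g, "gene04")   # untouched locus
  ed <- apply_edit(g, don)
  st <- verify_escape(ed, list(enrichment = enr, verification = ver,
                               positive = pos))
  expect_equal(st$status, c("DISRUPTED", "DISRUPTED", "INTACT"))
  expect_true(editing_plan_valid(st, c("enrichment", "verification",
                                       "positive")))
})

test_that("a 1-SNP recode escapes exact matching but is flagged at risk", {
  set.seed(58)
  # GAT is the 10th codon (nt 28-30), the only degenerate codon inside
  # the 31-nt protospacer
  codons <- c("ATG", rep(c("TGG", "ATG"), 4), "GAT", rep("TGG", 4), "TAA")
  g <- phage_genome("socC", paste0(rnd_dna(80), paste(codons, collapse = ""),
                                   rnd_dna(80)),
                    data.frame(gene_id = "g1", start = 80L,
                               end = 80L + 3L * length(codons),
                               strand = "+", kind = "CDS", partial = FALSE))
  sp <- design_cds_start_spacer(g, "g1")
  # uniform usage so GAT -> GAC is reachable: a single-SNP (soc-C-like) edit
  uu <- data.frame(codon = c("GAT", "GAC"), aa = "D", fraction = 0.5)
  d <- recode(g, sp, "C", usage = rbind(toy_usage[toy_usage$aa != "D", ], uu))
  expect_equal(d$snp_count, 1L)
  don <- design_recode_donor(g, d)
  ed <- apply_edit(g, don)
  st <- verify_escape(ed, list(enr = sp))
  expect_equal(st$status, "DISRUPTED")       # exact-match criterion
  expect_identical(predict_escape(d), "AT_RISK")  # yet predicted to fail
})
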