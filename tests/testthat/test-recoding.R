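# helper: uniform codon usage (every synonymous codon equally common) so
# tests can reach maximal-change codons the E. coli rarity floor would veto
uniform_usage <- local({
  gc <- Biostrings::GENETIC_CODE
  aa <- as.character(gc)
  keep <- aa != "*"
  df <- data.frame(codon = names(gc)[keep], aa = aa[keep])
  df$fraction <- ave(rep(1, nrow(df)), df$aa, FUN = function(x) x / length(x))
  df
})

# build a genome whose single plus-strand gene has the given codons
codon_genome <- function(codons, flank = 80) {
  cds <- paste(codons, collapse = "")
  phage_genome("codonfix", paste0(rnd_dna(flank), cds, rnd_dna(flank)),
               data.frame(gene_id = "g1", start = flank,
                          end = flank + nchar(cds), strand = "+",
                          kind = "CDS", partial = FALSE))
}

test_that("the shipped E. coli usage table has coherent family fractions", {
  tb <- default_codon_usage()
  sums <- tapply(tb$fraction, tb$aa, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_false("*" %in% tb$aa)
  expect_equal(sort(unique(nchar(tb$codon))), 3L)
})

test_that("single-codon recoding takes the one change the code forces", {
  set.seed(31)
  # only one degenerate codon in the window: GAT (Asp, codon 10 at
  # nt 28-30) -> GAC, 1 SNP
  codons <- c("ATG", rep(c("TGG", "ATG"), 4), "GAT", rep("TGG", 4), "TAA")
  g <- codon_genome(codons)
  sp <- design_cds_start_spacer(g, "g1")
  d <- recode(g, sp, "C", usage = uniform_usage)
  expect_equal(d$snp_count, 1L)
  expect_equal(d$changes$old, "GAT")
  expect_equal(d$changes$new, "GAC")
  expect_identical(translate_dna(d$context_original),
                   translate_dna(d$context_recoded))
})

test_that("recoding errors when no codon in scope is degenerate", {
  set.seed(32)
  codons <- c("ATG", rep(c("TGG", "ATG"), 8), "TAA")
  g <- codon_genome(codons)
  sp <- design_cds_start_spacer(g, "g1")
  expect_error(recode(g, sp, "C", usage = uniform_usage),
               "no silent change possible")
  expect_warning(recode(g, sp, "F", usage = uniform_usage),
                 "no silent change")
})

test_that("recoding refuses spacers outside an annotated CDS frame", {
  g <- make_toy_phage(seed = 33)
  sp <- design_rbs_spacer(g, "gene01", -4)   # 4 nt upstream of the CDS
  expect_error(recode(g, sp, "F"), "not fully contained")
  nt <- design_nontargeting_spacer()
  expect_error(recode(g, nt, "F"), "does not target")
})

test_that("full-protospacer recoding attains the exhaustive-search optimum", {
  set.seed(34)
  for (rep in 1:12) {
    g <- make_toy_phage(seed = 100 + rep)
    gene <- sample(c("gene01", "gene02", "gene03", "gene04"), 1)
    len <- sample(c(12L, 15L), 1)            # <= 6 codons of context
    t0 <- sample(0:20, 1)
    sp <- design_custom_spacer(g, gene, t0, spacer_len = len)
    for (usage in list(toy_usage, uniform_usage)) {
      d <- suppressWarnings(recode(g, sp, "F", usage = usage))
      off <- d$t_start - (d$t_start %/% 3) * 3
      best <- oracle_max_silent_changes(d$context_original, off, len, usage)
      expect_equal(d$snp_count, best,
                   info = sprintf("seed %d gene %s t0 %d", 100 + rep,
                                  gene, t0))
    }
  }
})

test_that("every recoding is silent and confined to its scope window", {
  gc <- Biostrings::GENETIC_CODE
  n_checked <- 0L
  for (seed in 1:28) {
    g <- make_toy_phage(seed = seed)
    for (gene in c("gene01", "gene02", "gene03", "gene04")) {
      sp <- design_cds_start_spacer(g, gene)
      for (mode in c("C", "S", "F")) {
        d <- suppressWarnings(recode(g, sp, mode, usage = toy_usage))
        # silence, checked codon-for-codon with an independent lookup
        co <- substring(d$context_original,
                        seq(1, nchar(d$context_original), 3),
                        seq(3, nchar(d$context_original), 3))
        cr <- substring(d$context_recoded,
                        seq(1, nchar(d$context_recoded), 3),
                        seq(3, nchar(d$context_recoded), 3))
        expect_identical(unname(gc[cr]), unname(gc[co]))
        # substitutions confined to the protospacer (flanks untouched)
        L <- nchar(d$protospacer)
        ctx_o <- strsplit(d$context_original, "")[[1]]
        ctx_r <- strsplit(d$context_recoded, "")[[1]]
        off <- d$t_start %% 3
        inwin <- seq_along(ctx_o) > off & seq_along(ctx_o) <= off + L
        expect_true(all(ctx_o[!inwin] == ctx_r[!inwin]))
        # S mode: changes only inside the seed window
        if (mode == "S") {
          proto_pos <- which(strsplit(d$protospacer, "")[[1]] !=
                               strsplit(d$recoded, "")[[1]])
          seedpos <- (L - d$seed_window[2] + 1):(L - d$seed_window[1] + 1)
          expect_true(all(proto_pos %in% seedpos))
        }
        expect_equal(d$snp_count,
                     sum(strsplit(d$protospacer, "")[[1]] !=
                           strsplit(d$recoded, "")[[1]]))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 300L)
})

test_that("SNP counts nest across scopes on the same protospacer", {
  checked <- 0L
  for (seed in 41:70) {
    g <- make_toy_phage(seed = seed)
    sp <- design_cds_start_spacer(g, "gene01")
    dC <- suppressWarnings(recode(g, sp, "C", usage = toy_usage))
    dS <- suppressWarnings(recode(g, sp, "S", usage = toy_usage))
    dF <- suppressWarnings(recode(g, sp, "F", usage = toy_usage))
    expect_gte(dF$snp_count, dS$snp_count)
    # C <= S only applies when the chosen codon lies inside the seed window
    L <- nchar(sp$protospacer)
    seedpos <- (L - dC$seed_window[2]):(L - dC$seed_window[1]) # 0-based
    c_codon <- dC$changes$codon_index[1]
    c_pos <- c_codon * 3 + 0:2 - dC$t_start
    if (all(c_pos %in% seedpos)) {
      expect_gte(dS$snp_count, dC$snp_count)
      checked <- checked + 1L
    }
    expect_gte(dF$snp_count, dC$snp_count)
  }
})

test_that("escape prediction needs contiguous seed changes", {
  set.seed(36)
  # seed window (spacer 5..12) maps to protospacer positions 20..27
  # (1-based); codon 8 of a frame-0 protospacer sits at 22..24
  codons <- c("ATG", rep("CTG", 6), "TCT", rep("CTG", 6), "TAA")
  g <- codon_genome(codons)
  sp <- design_cds_start_spacer(g, "g1")
  # TCT (Ser) -> AGC under uniform usage: 3 contiguous changes in the seed
  d <- recode(g, sp, "C", usage = uniform_usage)
  expect_equal(d$changes$old, "TCT")
  expect_equal(d$changes$new, "AGC")
  expect_identical(predict_escape(d, min_contiguous_seed_changes = 3),
                   "ESCAPES")
  # a single change in the seed stays at risk
  d1 <- recode(g, sp, "C", usage = toy_usage)
  if (d1$snp_count < 3) {
    expect_identical(predict_escape(d1, min_contiguous_seed_changes = 3),
                     "AT_RISK")
  }
  # zero seed changes: force the C codon outside the seed window
  codons2 <- c("ATG", "GAT", rep("TGG", 12), "TAA")
  g2 <- codon_genome(codons2)
  sp2 <- design_cds_start_spacer(g2, "g1")
  d2 <- recode(g2, sp2, "C", usage = uniform_usage)
  expect_identical(predict_escape(d2), "AT_RISK")
})

test_that("rarity floor falls back with a warning when it would freeze a codon", {
  tb <- default_codon_usage()
  # Leu: CTG dominates the E. coli table; every alternative is rare
  leu <- tb[tb$aa == "L", ]
  expect_equal(sum(leu$fraction >= 0.10), 1L)
  codons <- c("ATG", rep("TGG", 5), "CTG", rep("TGG", 7), "TAA")
  g <- codon_genome(codons)
  sp <- design_cds_start_spacer(g, "g1")
  expect_warning(d <- recode(g, sp, "C", usage = tb), "rare")
  expect_gte(d$snp_count, 1L)
})

test_that("the per-gene SNP report covers all three scopes", {
  g <- make_toy_phage(seed = 37)
  rep <- recode_snp_report(g, "gene01")
  expect_equal(rep$mode, c("C", "S", "F"))
  expect_true(all(rep$snp_count >= 1L))
  expect_true(all(rep$escape %in% c("ESCAPES", "AT_RISK")))
  expect_gte(rep$snp_count[3], rep$snp_count[2])
})
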