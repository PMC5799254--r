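# shared coding fixture: cut inside codon 50 of a 200-codon gene,
# amplicon = CDS bases 1..300
fx <- coding_fixture(200, plant = list(`50` = "GGT"))
amp <- coding_amplicon(fx, codon = 50)

test_that("a perfect read aligns with zero ops", {
  r <- substr(amp$sequence, 1, 120)
  aln <- align_reads(r, NULL, amp)
  expect_equal(length(aln$fragments), 1L)
  expect_equal(aln$fragments[[1]]$ops, list())
  expect_equal(aln$fragments[[1]]$ranges[1, ], c(0, 120))
})

test_that("alignment scores match an independent DP oracle on small fixtures", {
  set.seed(41)
  small <- amplicon_reference(random_dna(60), 0, 30)
  submat <- Biostrings::nucleotideSubstitutionMatrix(2, -3, baseOnly = TRUE)
  for (i in 1:15) {
    ops <- switch(sample(3, 1),
                  list(del_op(sample(10:40, 1), sample(1:4, 1))),
                  list(ins_op(sample(10:40, 1), random_dna(sample(1:3, 1)))),
                  list(sub_op(sample(10:40, 1), sample(BASES, 1))))
    read <- substr(apply_ops_oracle(small$sequence, ops), 5, 55)
    got <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(read), Biostrings::DNAString(small$sequence),
      type = "global-local", substitutionMatrix = submat,
      gapOpening = 8, gapExtension = 1))
    want <- dp_fit_score(read, small$sequence)
    expect_equal(got, want)
  }
})

test_that("a 3-base deletion is recovered as a single length-3 del op", {
  mut <- apply_ops_oracle(amp$sequence, list(del_op(147, 3)))
  aln <- align_reads(substr(mut, 1, 200), NULL, amp)
  ops <- aln$fragments[[1]]$ops
  expect_equal(length(ops), 1L)
  expect_equal(ops[[1]]$type, "del")
  expect_equal(ops[[1]]$len, 3L)
  # left-aligned placement reproduces the same mutant sequence
  expect_equal(apply_ops_oracle(amp$sequence, ops), mut)
})

test_that("mates with conflicting windowed ops discard the pair", {
  mut <- apply_ops_oracle(amp$sequence, list(del_op(147, 3)))
  r1 <- substr(mut, 1, 250)                       # carries the deletion
  r2 <- rc(substring(amp$sequence, 51, 300))       # wild-type mate
  aln <- align_reads(r1, r2, amp)
  expect_equal(aln$discarded_conflict, 1L)
  expect_equal(length(aln$fragments), 0L)
})

test_that("low-identity reads are discarded and tallied", {
  junk <- random_dna(100)
  aln <- align_reads(junk, NULL, amp)
  expect_equal(aln$discarded_identity, 1L)
  expect_warning(align_reads(character(0), NULL, amp), "empty FASTQ")
})

test_that("haplotype extraction windows, merges and normalizes", {
  wt_pair <- mate_pair(amp$sequence, 170)
  aln <- align_reads(rep(wt_pair$r1, 5), rep(wt_pair$r2, 5), amp)
  al <- extract_haplotypes(aln)
  expect_equal(nrow(al), 1L)
  expect_equal(al$allele, "")
  expect_equal(al$frequency, 1)
  # a substitution 80 bp from the cut is outside the 35/35 window
  refbase <- substr(amp$sequence, amp$cut_coord - 80 + 1, amp$cut_coord - 80 + 1)
  far <- apply_ops_oracle(amp$sequence,
                          list(sub_op(amp$cut_coord - 80,
                                      setdiff(BASES, refbase)[1])))
  expect_false(identical(far, amp$sequence))  # fixture sanity
  fp <- mate_pair(far, 170)
  al2 <- extract_haplotypes(align_reads(fp$r1, fp$r2, amp))
  expect_equal(al2$allele, "")
})

test_that("simulated allele mixtures are recovered within binomial bounds", {
  mix <- c(WT = 0.6, del3 = 0.3, ins1 = 0.1)
  muts <- list(WT = amp$sequence,
               del3 = apply_ops_oracle(amp$sequence, list(del_op(147, 3))),
               ins1 = apply_ops_oracle(amp$sequence, list(ins_op(149, "T"))))
  set.seed(47)
  n <- 10000
  draw <- sample(names(mix), n, replace = TRUE, prob = mix)
  pairs <- lapply(muts, mate_pair, read_len = 170)
  aln <- align_reads(vapply(pairs[draw], `[[`, "", "r1"),
                     vapply(pairs[draw], `[[`, "", "r2"), amp)
  al <- extract_haplotypes(aln)
  expect_equal(sum(al$frequency), 1, tolerance = 1e-9)
  truth_keys <- vapply(names(mix), function(k)
    op_key(normalize_ops(switch(k, WT = list(),
                                del3 = list(del_op(147, 3)),
                                ins1 = list(ins_op(149, "T"))), amp)), "")
  for (k in names(mix)) {
    p <- mix[[k]]
    got <- al$frequency[al$allele == truth_keys[[k]]]
    expect_equal(length(got), 1L)
    expect_lt(abs(got - mean(draw == k)), 1e-9)  # exact recovery, error 0
    expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("allele filtering thresholds, orders and reports removed mass", {
  al <- data.frame(allele = c("", "a", "b"),
                   read_count = c(600L, 300L, 4L),
                   frequency = c(0.6, 0.396, 0.004))
  al$ops <- list(list(), list(del_op(1, 3)), list(del_op(2, 3)))
  class(al) <- c("allele_table", "data.frame")
  f0 <- filter_alleles(al, 0)
  expect_equal(nrow(f0), 3L)
  f <- filter_alleles(al, 0.005)
  expect_equal(nrow(f), 2L)
  expect_equal(attr(f, "other"), 0.004)
  expect_equal(f$frequency, sort(f$frequency, decreasing = TRUE))
  # monotone: retained set at 1% is a subset of retained set at 0.5%
  set.seed(53)
  freqs <- prop.table(rexp(30))
  rnd <- data.frame(allele = paste0("x", 1:30), read_count = 1L,
                    frequency = freqs)
  rnd$ops <- replicate(30, list(), simplify = FALSE)
  class(rnd) <- c("allele_table", "data.frame")
  expect_true(all(filter_alleles(rnd, 0.01)$allele %in%
                  filter_alleles(rnd, 0.005)$allele))
})

test_that("classification reproduces the published name forms", {
  # guard codons flank each planted site so prefix/suffix trimming cannot
  # slide the name through an accidental repeat
  fx2 <- coding_fixture(600, plant = list(
    `382` = "GAT", `383` = "GGT", `384` = "GAA",       # G383
    `129` = "TGT", `130` = "GAT", `131` = "GCT",
    `132` = "CTG", `133` = "CAT",                      # D130 A131 L132
    `165` = "GCT", `166` = "GTG", `167` = "AAA", `168` = "GAA",  # V166 K167
    `527` = "GCT", `528` = "TGT", `529` = "GAA",
    `530` = "CAA", `531` = "AAA", `532` = "GGT"))
  ampG <- amplicon_reference(substr(fx2$cds, 1101, 1400), offset = 1100,
                             cut_coord = 383 * 3 - 1, codon_map = fx2$map)
  v <- classify_and_name(list(del_op(382 * 3, 3)), ampG)  # codon 383 = cds 1146..1148
  expect_equal(v$name, "G383del")
  expect_equal(v$klass, "inframe_deletion")

  ampD <- amplicon_reference(substr(fx2$cds, 301, 600), offset = 300,
                             cut_coord = 131 * 3, codon_map = fx2$map)
  v2 <- classify_and_name(list(del_op(129 * 3, 9)), ampD)
  expect_equal(v2$name, "D130_L132del")
  expect_equal(v2$klass, "inframe_deletion")

  ampV <- amplicon_reference(substr(fx2$cds, 401, 700), offset = 400,
                             cut_coord = 166 * 3, codon_map = fx2$map)
  v3 <- classify_and_name(list(ins_op(166 * 3, "CTG")), ampV)  # Leu codon
  expect_equal(v3$name, "V166_K167insL")
  expect_equal(v3$klass, "inframe_insertion")

  # multi-substitution run C528S,E529V,Q530H,K531I
  ampC <- amplicon_reference(substr(fx2$cds, 1501, 1800), offset = 1500,
                             cut_coord = 528 * 3, codon_map = fx2$map)
  subs <- list(sub_op(527 * 3, "A"),       # C528S (TGT -> AGT)
               sub_op(528 * 3 + 1, "T"),   # E529V
               sub_op(529 * 3 + 2, "T"),   # Q530H (CAA->CAT)
               sub_op(530 * 3 + 1, "T"))   # K531I (AAA->ATA)
  v4 <- classify_and_name(subs, ampC)
  expect_equal(v4$name, "C528S,E529V,Q530H,K531I")
  expect_equal(v4$klass, "missense")

  expect_equal(classify_and_name(list(), ampG)$name, "WT")
  v5 <- classify_and_name(list(del_op(382 * 3, 1)), ampG)
  expect_equal(v5$klass, "frameshift")
  expect_equal(v5$net_indel, -1L)
})

test_that("delins, silent, nonsense and noncoding alleles classify correctly", {
  v <- classify_and_name(list(del_op(147, 3), sub_op(151, "T")), amp)
  expect_true(v$klass %in% c("inframe_delins", "missense", "inframe_deletion"))
  # engineered delins: delete codon 50 and change codon 51's first base
  base51 <- substr(fx$cds, 151, 151)
  alt <- setdiff(BASES, base51)[1]
  v1 <- classify_and_name(list(del_op(147, 3), sub_op(150, alt)), amp)
  expect_true(grepl("del", v1$name))
  # silent third-base change
  v2 <- classify_and_name(list(sub_op(149, "A")), amp)  # GGT -> GGA, still Gly
  expect_equal(v2$klass, "silent")
  expect_equal(v2$name, "G50G")
  # nonsense: GGT -> TGA
  v3 <- classify_and_name(list(sub_op(147, "T"), sub_op(149, "A")), amp)
  expect_equal(v3$klass, "nonsense")
  expect_equal(v3$name, "G50*")
  # intronic allele: amplicon without a codon map, nucleotide-level name
  ampn <- amplicon_reference(amp$sequence, 0, 149, codon_map = NULL)
  v4 <- classify_and_name(list(del_op(100, 8)), ampn)
  expect_equal(v4$klass, "noncoding")
  expect_equal(v4$name, "g.101_108del")
  expect_equal(v4$net_indel, -8L)
})

test_that("frameshift class follows the net-indel mod-3 rule", {
  set.seed(59)
  for (i in 1:200) {
    kind <- sample(3, 1)
    ops <- switch(kind,
                  list(del_op(sample(100:250, 1), sample(1:9, 1))),
                  list(ins_op(sample(100:250, 1), random_dna(sample(1:6, 1)))),
                  list(sub_op(sample(100:250, 1), sample(BASES, 1))))
    v <- classify_and_name(ops, amp)
    expect_equal(v$klass == "frameshift", v$net_indel %% 3 != 0)
  }
})

test_that("naming round-trips: re-applying a named variant's ops renames it", {
  set.seed(61)
  for (i in 1:60) {
    # ops drawn inside the 35/35 window around the cut (149), so the
    # haplotype caller keeps them
    ops <- switch(sample(3, 1),
                  list(del_op(sample(120:170, 1), sample(c(3, 6, 9), 1))),
                  list(ins_op(sample(40:58, 1) * 3L, random_dna(3))),
                  list(sub_op(sample(120:180, 1), sample(BASES, 1))))
    v <- classify_and_name(ops, amp)
    if (!v$klass %in% c("inframe_deletion", "inframe_insertion", "missense"))
      next
    # rebuild the mutant amplicon, re-align, re-extract, re-name
    mut <- apply_ops_oracle(amp$sequence, ops)
    mp <- mate_pair(mut, 170)
    aln <- align_reads(mp$r1, mp$r2, amp)
    # pairs whose indel sits at a read end can be discarded as discordant;
    # the warning ("no reads span") is the expected signal for that case
    al <- classify_alleles(suppressWarnings(extract_haplotypes(aln)))
    if (!nrow(al)) next
    expect_equal(al$name[1], v$name)
  }
})

test_that("mutation-type rollup conserves retained mass", {
  al <- data.frame(allele = c("", "a", "b", "c"),
                   read_count = c(50L, 30L, 15L, 5L),
                   frequency = c(0.5, 0.3, 0.15, 0.05),
                   klass = c("wild_type", "inframe_deletion", "frameshift",
                             "noncoding"))
  s <- mutation_type_summary(al)
  expect_equal(unname(s["wild_type"]), 0.5)
  expect_equal(unname(s["in_frame"]), 0.3)
  expect_equal(unname(s["frameshift"]), 0.15)
  expect_equal(unname(s["noncoding"]), 0.05)
  expect_equal(sum(s), sum(al$frequency))
  all_wt <- data.frame(allele = "", read_count = 10L, frequency = 1,
                       klass = "wild_type")
  expect_equal(unname(mutation_type_summary(all_wt)["wild_type"]), 1)
})

test_that("SNV spectrum localizes and rows sum to one", {
  # 30% of reads carry a deletion at [cut-3, cut)
  mut <- apply_ops_oracle(amp$sequence, list(del_op(amp$cut_coord - 3, 3)))
  mpw <- mate_pair(amp$sequence, 170); mpm <- mate_pair(mut, 170)
  aln <- align_reads(c(rep(mpw$r1, 7), rep(mpm$r1, 3)),
                     c(rep(mpw$r2, 7), rep(mpm$r2, 3)), amp)
  sp <- snv_spectrum(aln)
  # the aligner may left-shift the deletion through repeats: same mutant
  key <- vapply(aln$fragments, function(f) op_key(f$ops), "")
  delpos <- which(sp$freq[, "del"] > 0)
  expect_equal(length(delpos), 3L)
  expect_equal(unname(sp$freq[delpos, "del"]), rep(0.3, 3))
  covered <- which(sp$coverage > 0)
  expect_equal(unname(rowSums(sp$freq[covered, , drop = FALSE])),
               rep(1, length(covered)))
  # error-free wild-type reads give zero variant frequency everywhere
  alnw <- align_reads(mpw$r1, mpw$r2, amp)
  spw <- snv_spectrum(alnw)
  expect_true(all(spw$variant_freq[spw$coverage > 0] == 0))
})
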