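sp <- nuclease_profile("SpCas9")
cpf <- nuclease_profile("AsCpf1")

test_that("enumeration matches a constructed two-strand fixture", {
  # 40-bp fixture with exactly 2 forward N21GG matches and 1 reverse match
  set.seed(123)
  repeat {
    seq <- random_dna(40)
    o <- brute_force_sites(seq, sp)
    if (sum(o$strand == "+") == 2 && sum(o$strand == "-") == 1) break
  }
  g <- enumerate_guides(seq, data.frame(start = 0, end = 40), sp)
  expect_equal(nrow(g), 3L)
  expect_equal(sort(paste(g$site_start, g$strand)),
               sort(paste(o$site_start, o$strand)))
})

test_that("poly-A yields no SpCas9 guides; TTTN24 yields one AsCpf1 guide", {
  expect_equal(nrow(enumerate_guides(strrep("A", 100),
                                     data.frame(start = 0, end = 100), sp)),
               0L)
  set.seed(5)
  seq <- paste0("TTTC", paste(sample(c("A", "C", "G"), 24, replace = TRUE),
                              collapse = ""))
  g <- enumerate_guides(seq, data.frame(start = 0, end = 28), cpf)
  gf <- g[g$strand == "+", ]
  expect_equal(nrow(gf), 1L)
  expect_equal(gf$pam, "TTTC")
  expect_equal(nchar(gf$protospacer), 24L)
})

test_that("enumeration equals the brute-force oracle on random fixtures", {
  set.seed(31)
  for (i in 1:40) {
    prof <- if (i %% 2) sp else cpf
    seq <- random_dna(sample(60:300, 1))
    got <- enumerate_guides(seq, data.frame(start = 0, end = nchar(seq)), prof)
    want <- brute_force_sites(seq, prof)
    expect_equal(sort(paste(got$site_start, got$strand, got$protospacer)),
                 sort(paste(want$site_start, want$strand, want$protospacer)))
    # strand-read sites carry the PAM where the profile says
    if (nrow(got)) {
      if (prof$name == "SpCas9") expect_true(all(grepl("GG$", got$pam)))
      else expect_true(all(grepl("^TTT", got$pam)))
    }
  }
})

test_that("sites containing N are skipped", {
  seq <- paste0(strrep("A", 10), "N", strrep("A", 10), "GG", strrep("A", 5))
  expect_equal(nrow(enumerate_guides(seq, data.frame(start = 0, end = nchar(seq)), sp)),
               0L)
})

test_that("dedup merges isoforms per gene and drops TTTTT guides", {
  g <- data.frame(
    gene = c("A", "A", "A", "B"),
    isoforms = c("A.1", "A.2", "A.1", "B.1"),
    gene_strand = "+",
    protospacer = c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT",
                    "ACGTTTTTACGTACGTACGT", "ACGTACGTACGTACGTACGT"),
    pam = "AGG", strand = c("+", "+", "+", "+"),
    site_start = c(10, 10, 50, 10), site_end = c(33, 33, 73, 33),
    cut_coord = c(27, 27, 67, 27))
  out <- dedup_and_filter(g)
  a <- out[out$gene == "A", ]
  expect_equal(nrow(a), 1L)                       # dup merged, TTTTT removed
  expect_setequal(strsplit(a$isoforms, ";")[[1]], c("A.1", "A.2"))
  expect_equal(nrow(out[out$gene == "B", ]), 1L)  # same sequence kept in B
  # all-distinct set passes through unchanged
  g2 <- data.frame(gene = "A", isoforms = "A.1", gene_strand = "+",
                   protospacer = c("AAAACCCCGGGGTTTTAAAC",
                                   "CCCCGGGGAAAATTTTCCCA"),
                   site_start = c(1, 30), site_end = c(24, 53),
                   strand = "+")
  expect_equal(dedup_and_filter(g2)$protospacer, g2$protospacer)
})

test_that("dedup keeps the 5'-most representative in gene orientation", {
  g <- data.frame(gene = "A", isoforms = c("A.1", "A.2"), gene_strand = "-",
                  protospacer = "ACGTACGTACGTACGTACGT",
                  strand = c("+", "-"),
                  site_start = c(10, 80), site_end = c(33, 103))
  out <- dedup_and_filter(g)
  expect_equal(out$site_start, 80)  # largest coordinate = 5'-most on minus gene
})

test_that("oligo assembly honours the published total lengths", {
  gsp <- data.frame(protospacer = strrep("A", 20))
  expect_equal(assemble_oligo(gsp, sp)$oligo_len, 60L)
  gcpf <- data.frame(protospacer = strrep("C", 24))
  ocpf <- assemble_oligo(gcpf, cpf)
  expect_equal(ocpf$oligo_len, 79L)
  # direct repeat sits immediately 5' of the protospacer
  expect_true(grepl(paste0("TAATTTCTACTCTTGTAGA", strrep("C", 24)),
                    ocpf$oligo, fixed = TRUE))
  # identity configuration
  o <- assemble_oligo(gsp, nuclease_profile("SpCas9", oligo_len = 20,
                                            adapters = c(left = "", right = "")))
  expect_equal(o$oligo, gsp$protospacer)
  # inconsistent adapters are a configuration error
  expect_error(assemble_oligo(gsp, sp, adapters = c(left = "A", right = "C")),
               "oligo length")
})

test_that("controls are non-matching, deterministic and optional", {
  set.seed(17)
  ref <- setNames(random_dna(400), "chr")
  m <- gene_model("G", "G.1", "+", data.frame(start = 50, end = 350), "chr", 400)
  lib <- design_library(list(m), ref, sp)
  expect_identical(add_controls(lib, 0, ref, sp), lib)
  c1 <- add_controls(lib, 20, ref, sp, seed = 42)
  c2 <- add_controls(lib, 20, ref, sp, seed = 42)
  expect_identical(c1, c2)
  ctrl <- c1$protospacer[c1$gene == "CONTROL"]
  expect_equal(length(ctrl), 20L)
  hay <- c(ref, rc(unname(ref)))
  for (p in ctrl) {
    expect_false(any(grepl(p, hay, fixed = TRUE)))
    expect_false(grepl("TTTTT", p, fixed = TRUE))
  }
})

test_that("sub-pools are contiguous alphabetical gene blocks", {
  g <- data.frame(gene = rep(c("ABL1", "HDAC9", "IFNAR1", "VEGFB"),
                             c(5, 5, 5, 5)),
                  protospacer = replicate(20, random_dna(20)))
  out <- split_sublibraries(g, 2)
  expect_setequal(unique(out$gene[out$subpool == "A"]), c("ABL1", "HDAC9"))
  expect_setequal(unique(out$gene[out$subpool == "B"]), c("IFNAR1", "VEGFB"))
  expect_equal(unique(split_sublibraries(g, 1)$subpool), "A")
  expect_error(split_sublibraries(g, 5), "exceeds")
  # 10 equal genes, 2 pools -> 5 + 5 (oracle: enumerate contiguous splits)
  g10 <- data.frame(gene = rep(LETTERS[1:10], each = 3),
                    protospacer = replicate(30, random_dna(20)))
  out10 <- split_sublibraries(g10, 2)
  expect_equal(as.integer(table(out10$subpool)), c(15L, 15L))
  best <- min(vapply(1:9, function(b) max(b, 10 - b) * 3, 1))
  expect_equal(as.numeric(max(table(out10$subpool))), best)
})

test_that("library TSV + FASTA round-trip and are byte-stable", {
  set.seed(23)
  ref <- setNames(random_dna(500), "chr")
  m <- gene_model("G", "G.1", "+", data.frame(start = 60, end = 420), "chr", 500)
  lib <- design_library(list(m), ref, sp, n_controls = 4, n_pools = 1, seed = 3)
  tsv <- tempfile(fileext = ".tsv")
  write_library(lib, tsv)
  back <- read_library(tsv)
  expect_equal(nrow(back), nrow(lib))
  expect_setequal(back$protospacer, lib$protospacer)
  fa <- Biostrings::readDNAStringSet(paste0(tsv, ".fa"))
  expect_setequal(names(fa), lib$guide_id)
  expect_setequal(as.character(fa), lib$protospacer)
  # determinism: identical inputs + seed give byte-identical files
  tsv2 <- tempfile(fileext = ".tsv")
  write_library(design_library(list(m), ref, sp, n_controls = 4,
                               n_pools = 1, seed = 3), tsv2)
  expect_identical(readLines(tsv), readLines(tsv2))
})

test_that("designed guide sets satisfy the library invariants", {
  set.seed(29)
  ref <- setNames(random_dna(700), "chr")
  ms <- list(gene_model("AAA", "AAA.1", "+", data.frame(start = 50, end = 320),
                        "chr", 700),
             gene_model("BBB", "BBB.1", "-", data.frame(start = 400, end = 640),
                        "chr", 700))
  for (prof in list(sp, cpf)) {
    lib <- design_library(ms, ref, prof, n_controls = 3, n_pools = 2, seed = 1)
    expect_true(all(nchar(lib$oligo) == prof$oligo_len))
    per_gene <- split(lib$protospacer, lib$gene)
    expect_true(all(vapply(per_gene, anyDuplicated, 1L) == 0))
    expect_false(any(grepl("TTTTT", lib$protospacer, fixed = TRUE)))
    genes_per_pool <- tapply(lib$gene[lib$gene != "CONTROL"],
                             lib$subpool[lib$gene != "CONTROL"], unique)
    expect_equal(sum(lengths(genes_per_pool)), 2L)  # genes stay whole
    if (prof$name == "AsCpf1") {
      hits <- gregexpr(prof$direct_repeat, lib$oligo, fixed = TRUE)
      expect_true(all(lengths(hits) == 1L & vapply(hits, `[`, 0L, 1) == 19L))
    }
  }
})
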