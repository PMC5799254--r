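# Shared fixtures and independent oracles. Oracles are deliberately naive
# re-implementations (substring loops, dynamic programming) kept independent
# of the package code paths they check.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rc <- function(x) vapply(x, function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
  "", USE.NAMES = FALSE)

# brute-force two-strand site scan: checks every window with substring ops
brute_force_sites <- function(seq, profile) {
  n <- nchar(seq); L <- profile$site_len
  rows <- list()
  if (n >= L) for (s in 0:(n - L)) {
    win <- substr(seq, s + 1L, s + L)
    if (grepl("[^ACGT]", win)) next
    for (strand in c("+", "-")) {
      oriented <- if (strand == "+") win else rc(win)
      ok <- if (profile$name == "SpCas9") substr(oriented, 22, 23) == "GG"
            else substr(oriented, 1, 3) == "TTT"
      if (!ok) next
      proto <- if (profile$name == "SpCas9") substr(oriented, 1, 20)
               else substr(oriented, 5, 28)
      rows[[length(rows) + 1L]] <-
        data.frame(site_start = s, strand = strand, protospacer = proto)
    }
  }
  if (!length(rows))
    return(data.frame(site_start = integer(), strand = character(),
                      protospacer = character()))
  do.call(rbind, rows)
}

# affine-gap semi-global DP (pattern global, subject local), score only;
# Biostrings convention: a gap of length k costs open + k * extend
dp_fit_score <- function(pattern, subject, match = 2, mismatch = -3,
                         open = 8, extend = 1) {
  p <- strsplit(pattern, "")[[1]]; s <- strsplit(subject, "")[[1]]
  n <- length(p); m <- length(s)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # last col consumed both
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in subject (consumes pattern)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in pattern (consumes subject)
  M[1, ] <- 0                      # free leading subject
  for (i in 1:n) {
    Ix[i + 1, 1] <- -(open + extend * i)
    for (j in 0:m) {
      if (j >= 1) {
        sc <- if (p[i] == s[j]) match else mismatch
        M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + sc
        Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                                Iy[i + 1, j] - extend)
      }
      Ix[i + 1, j + 1] <- max(Ix[i + 1, j + 1],
                              M[i, j + 1] - open - extend,
                              Ix[i, j + 1] - extend)
    }
  }
  max(M[n + 1, ], Ix[n + 1, ], Iy[n + 1, ])  # free trailing subject
}

# planted-codon coding fixture: a single-exon gene of `n_codons` codons on a
# reference that IS the CDS; selected codons can be fixed for naming tests
coding_fixture <- function(n_codons = 200, plant = list(), seed = 99) {
  set.seed(seed)
  pool <- c("GCT", "GAA", "CTG", "AAA", "TGT", "GGT", "GAT", "GTG", "CCT",
            "TAC", "TCT", "CAT", "ATT", "CAA")
  codons <- c("ATG", sample(pool, n_codons - 2, replace = TRUE), "TAA")
  for (pos in names(plant)) codons[as.integer(pos)] <- plant[[pos]]
  cds <- paste(codons, collapse = "")
  model <- gene_model("GENE", "GENE.1", "+",
                      data.frame(start = 0, end = nchar(cds)), "chr",
                      nchar(cds))
  map <- codon_map(model, cds)
  list(cds = cds, model = model, map = map)
}

# amplicon centred on a cut inside codon `codon` of a coding fixture
coding_amplicon <- function(fx, codon = 50, span = c(1, 300)) {
  cut <- codon * 3L - 1L
  amplicon_reference(substr(fx$cds, span[1], span[2]), offset = span[1] - 1L,
                     cut_coord = cut, codon_map = fx$map)
}

# exact mate pair (no errors) for a mutant amplicon sequence
mate_pair <- function(mutseq, read_len) {
  list(r1 = substr(mutseq, 1, read_len),
       r2 = rc(substring(mutseq, nchar(mutseq) - read_len + 1L,
                         nchar(mutseq))))
}

# reference mutation by ops, independent of the package's apply_ops
apply_ops_oracle <- function(seq, ops, offset = 0L) {
  ops <- ops[order(vapply(ops, `[[`, 1L, "start"), decreasing = TRUE)]
  for (o in ops) {
    loc <- o$start - offset  # 0-based local
    if (o$type == "del")
      seq <- paste0(substr(seq, 1, loc), substring(seq, loc + o$len + 1L))
    else if (o$type == "ins")
      seq <- paste0(substr(seq, 1, loc), o$seq, substring(seq, loc + 1L))
    else
      seq <- paste0(substr(seq, 1, loc), o$base, substring(seq, loc + 2L))
  }
  seq
}

del_op <- function(start, len) list(type = "del", start = as.integer(start),
                                    len = as.integer(len))
ins_op <- function(start, seq) list(type = "ins", start = as.integer(start),
                                    seq = seq)
sub_op <- function(pos, base) list(type = "sub", start = as.integer(pos),
                                   base = base)
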