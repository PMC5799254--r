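# Targeted amplicon analysis: semi-global read alignment, cut-site-window
# haplotype extraction, allele frequency filtering, protein-level
# classification with HGVS-like names, and per-position SNV spectra.
#
# Alleles are represented as op lists: del(start, len), ins(start, seq;
# inserted before reference coordinate `start`), sub(pos, base). All op
# coordinates are 0-based reference coordinates.

#' Cut-site haplotype window
#'
#' The haplotype window spans `[cut - upstream, cut + downstream)`. Each arm
#' is restricted to 15--70 bases so the total span stays in the supported
#' 35--140 bp range; the default 35/35 is the midpoint.
#'
#' @param upstream,downstream Bases up-/downstream of the cut (15--70 each).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(upstream = 35L, downstream = 35L) {
  if (upstream < 15 || upstream > 70 || downstream < 15 || downstream > 70)
    stop("window arms must each be within 15-70 bases")
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream)),
            class = "window_spec")
}

#' Amplicon reference descriptor
#'
#' @param sequence Amplicon DNA sequence (uppercase ACGT).
#' @param offset Reference coordinate of the amplicon's first base (0-based).
#' @param cut_coord Canonical cut coordinate (the cut falls between
#'   `cut_coord - 1` and `cut_coord`); must lie within the amplicon.
#' @param guide_id Guide responsible for the cut (annotation only).
#' @param codon_map Optional [codon_map()] for protein-level classification;
#'   amplicon positions outside the map are treated as non-coding (intronic).
#' @return An object of class `amplicon_reference`.
#' @export
amplicon_reference <- function(sequence, offset = 0L, cut_coord,
                               guide_id = "", codon_map = NULL) {
  sequence <- toupper(as.character(sequence))
  offset <- as.integer(offset)
  cut_coord <- as.integer(cut_coord)
  if (cut_coord < offset || cut_coord >= offset + nchar(sequence))
    stop("cut_coord outside amplicon span")
  structure(list(sequence = sequence, offset = offset, cut_coord = cut_coord,
                 guide_id = guide_id, codon_map = codon_map,
                 length = nchar(sequence)),
            class = "amplicon_reference")
}

#' Alignment parameters for amplicon reads
#'
#' Semi-global alignment (reads global, amplicon local) with affine gap
#' penalties. Defaults: match +2, mismatch -3, gap open -8, gap extend -1,
#' and a 70% identity filter over aligned columns -- permissive enough for
#' the <= 17-bp indels this assay produces while rejecting junk reads.
#'
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (penalties
#'   given as the magnitudes subtracted).
#' @param min_identity Minimum fraction of matching columns.
#' @return List of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -3, gap_open = 8,
                         gap_extend = 1, min_identity = 0.70) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity = min_identity),
            class = "align_params")
}

op_del <- function(start, len) list(type = "del", start = as.integer(start),
                                    len = as.integer(len))
op_ins <- function(start, seq) list(type = "ins", start = as.integer(start),
                                    seq = seq)
op_sub <- function(pos, base) list(type = "sub", start = as.integer(pos),
                                   base = base)

#' Canonical string key of an op list
#' @param ops List of ops (`op_del`/`op_ins`/`op_sub`); empty = wild type.
#' @return Single string, `""` for wild type.
#' @export
op_key <- function(ops) {
  if (!length(ops)) return("")
  s <- vapply(ops, function(o) switch(o$type,
    del = sprintf("del:%d:%d", o$start, o$len),
    ins = sprintf("ins:%d:%s", o$start, o$seq),
    sub = sprintf("sub:%d:%s", o$start, o$base)), "")
  paste(s[order(vapply(ops, `[[`, 1L, "start"),
                vapply(ops, `[[`, "", "type"))], collapse = "|")
}

#' Parse an op key back into an op list
#' @param key String from [op_key()].
#' @export
parse_op_key <- function(key) {
  if (!nzchar(key)) return(list())
  lapply(strsplit(key, "|", fixed = TRUE)[[1]], function(s) {
    f <- strsplit(s, ":", fixed = TRUE)[[1]]
    switch(f[1],
           del = op_del(as.integer(f[2]), as.integer(f[3])),
           ins = op_ins(as.integer(f[2]), f[3]),
           sub = op_sub(as.integer(f[2]), f[3]))
  })
}

#' Normalize an allele to its left-aligned canonical form
#'
#' Indels in repeats have several equivalent placements; the pipeline (like
#' standard variant normalization) left-aligns them. This helper applies the
#' same normalization to externally constructed or simulated op lists so
#' their keys are comparable with pipeline output.
#'
#' @param ops Op list or canonical key string.
#' @param amplicon The [amplicon_reference] the coordinates live on.
#' @return Left-aligned op list.
#' @export
normalize_ops <- function(ops, amplicon) {
  if (is.character(ops)) ops <- parse_op_key(ops)
  left_align_ops(ops, amplicon$sequence, amplicon$offset)
}

# shift indels left through repeats so equivalent gap placements get one
# canonical (left-aligned) representation; `refseq`/`offset` describe the
# amplicon the coordinates live on
left_align_ops <- function(ops, refseq, offset) {
  ref <- strsplit(refseq, "")[[1]]
  at <- function(coord) ref[coord - offset + 1L]
  lapply(ops, function(o) {
    if (o$type == "del") {
      while (o$start > offset && at(o$start - 1L) == at(o$start + o$len - 1L))
        o$start <- o$start - 1L
    } else if (o$type == "ins") {
      seq <- strsplit(o$seq, "")[[1]]
      while (o$start > offset && at(o$start - 1L) == seq[length(seq)]) {
        seq <- c(seq[length(seq)], seq[-length(seq)])
        o$start <- o$start - 1L
      }
      o$seq <- paste(seq, collapse = "")
    }
    o
  })
}

# batch semi-global alignment of unique read sequences against the amplicon;
# returns per-sequence list(ops, identity, cov_start, cov_end) or NULL when
# unalignable / below identity. Sequences are deduplicated and reads that are
# exact substrings of the amplicon bypass the aligner entirely.
align_batch <- function(seqs, amplicon, params, try_revcomp = FALSE) {
  if (!length(seqs)) return(list())
  uq <- unique(seqs)
  back <- match(seqs, uq)
  res <- vector("list", length(uq))
  exact <- vapply(uq, function(s)
    regexpr(s, amplicon$sequence, fixed = TRUE)[1], 1L, USE.NAMES = FALSE)
  ex <- which(exact > 0L)
  for (i in ex) {
    st <- amplicon$offset + exact[i] - 1L
    res[[i]] <- list(ops = list(), identity = 1,
                     cov_start = st, cov_end = st + nchar(uq[i]))
  }
  todo <- which(exact <= 0L)
  if (length(todo))
    res[todo] <- align_batch_core(uq[todo], amplicon, params, try_revcomp)
  res[back]
}

# Op extraction uses the vectorized PairwiseAlignments accessors
# (deletion/insertion ranges are relative to the aligned subject start;
# mismatchTable coordinates are absolute subject positions) -- the gapped
# string accessors are prohibitively slow at scale.
align_batch_core <- function(seqs, amplicon, params, try_revcomp = FALSE) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = TRUE)
  do_aln <- function(x) Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(x),
    subject = Biostrings::DNAString(amplicon$sequence),
    type = "global-local", substitutionMatrix = submat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  aln <- do_aln(seqs)
  reads <- seqs
  if (try_revcomp) {
    rc <- revcomp(seqs)
    aln_rc <- do_aln(rc)
    use_rc <- Biostrings::score(aln_rc) > Biostrings::score(aln)
    if (any(use_rc)) {
      aln <- c(aln[!use_rc], aln_rc[use_rc])
      reads <- c(seqs[!use_rc], rc[use_rc])
      perm <- order(c(which(!use_rc), which(use_rc)))
    } else perm <- seq_along(seqs)
  } else perm <- seq_along(seqs)

  s0 <- Biostrings::start(Biostrings::subject(aln))
  se <- Biostrings::end(Biostrings::subject(aln))
  dels <- Biostrings::deletion(aln)
  inss <- Biostrings::insertion(aln)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  mt <- Biostrings::mismatchTable(aln)
  mt_by <- split(mt[, c("SubjectStart", "PatternSubstring")], mt$PatternId)
  off <- amplicon$offset
  out <- lapply(seq_along(reads), function(i) {
    d <- dels[[i]]; ins <- inss[[i]]
    dw <- sum(IRanges::width(d)); iw <- sum(IRanges::width(ins))
    identity <- nm[i] / (nm[i] + nmm[i] + dw + iw)
    if (identity < params$min_identity) return(NULL)
    ops <- list()
    for (k in seq_along(d))
      ops[[length(ops) + 1L]] <-
        op_del(off + s0[i] - 2L + IRanges::start(d)[k], IRanges::width(d)[k])
    if (length(ins)) {
      ist <- IRanges::start(ins); iwd <- IRanges::width(ins)
      o <- order(ist)
      ins_before <- 0L
      for (k in o) {
        # read bases consumed before this insertion, in read coordinates
        del_before <- sum(IRanges::width(d)[IRanges::start(d) < ist[k]])
        pc <- (ist[k] - 1L) - del_before + ins_before
        ops[[length(ops) + 1L]] <-
          op_ins(off + s0[i] + ist[k] - 2L,
                 substr(reads[i], pc + 1L, pc + iwd[k]))
        ins_before <- ins_before + iwd[k]
      }
    }
    m <- mt_by[[as.character(i)]]
    if (!is.null(m)) for (k in seq_len(nrow(m)))
      ops[[length(ops) + 1L]] <-
        op_sub(off + m$SubjectStart[k] - 1L,
               as.character(m$PatternSubstring[k]))
    list(ops = left_align_ops(ops, amplicon$sequence, amplicon$offset),
         identity = identity,
         cov_start = off + s0[i] - 1L, cov_end = off + se[i])
  })
  out[perm]
}

#' Align amplicon reads and reconcile mate pairs
#'
#' Reads are aligned semi-globally to the amplicon (affine gaps; see
#' [align_params()]); alignments below the identity floor are discarded.
#' Mate 2 is reverse-complemented before alignment. When both mates of a pair
#' span the haplotype window their windowed op lists must agree -- otherwise
#' the pair is discarded and counted; op lists of concordant mates are merged
#' (identical ops deduplicated, any same-position disagreement discards the
#' pair).
#'
#' @param fastq1 FASTQ path or character vector of read sequences (mate 1 /
#'   single-end).
#' @param fastq2 Optional mate-2 FASTQ path or character vector.
#' @param amplicon An [amplicon_reference].
#' @param params [align_params()].
#' @param window [window_spec()] used for mate reconciliation and kept as the
#'   default for downstream calls.
#' @return Object of class `amplicon_alignments`: `fragments` is a
#'   `data.frame` with `key`, `n` (read/pair count), `cov_start`, `cov_end`
#'   and a list column `ops`; plus discard tallies.
#' @export
align_reads <- function(fastq1, fastq2 = NULL, amplicon,
                        params = align_params(), window = window_spec()) {
  get_seqs <- function(x) {
    if (is.null(x)) return(NULL)
    if (length(x) == 1 && file.exists(x))
      toupper(as.character(Biostrings::readDNAStringSet(x, format = "fastq")))
    else toupper(as.character(x))
  }
  r1 <- get_seqs(fastq1)
  r2 <- get_seqs(fastq2)
  paired <- !is.null(r2)
  if (paired && length(r1) != length(r2))
    stop("mate FASTQ files have different read counts")
  if (!length(r1)) {
    warning("empty FASTQ: no alignments")
    return(empty_alignments(amplicon, window))
  }
  pkey <- if (paired) paste(r1, r2, sep = "\r") else r1
  tab <- table(pkey)
  uniq <- names(tab)
  w <- as.integer(tab)
  u1 <- if (paired) vapply(strsplit(uniq, "\r", fixed = TRUE), `[`, "", 1L) else uniq
  u2 <- if (paired) vapply(strsplit(uniq, "\r", fixed = TRUE), `[`, "", 2L) else NULL

  a1 <- align_batch(u1, amplicon, params, try_revcomp = !paired)
  a2 <- if (paired) align_batch(revcomp(u2), amplicon, params) else NULL

  ws <- amplicon$cut_coord - window$upstream
  we <- amplicon$cut_coord + window$downstream
  frag <- list(); fw <- integer(0)
  disc_identity <- 0L; disc_conflict <- 0L
  for (i in seq_along(uniq)) {
    f1 <- a1[[i]]; f2 <- if (paired) a2[[i]] else NULL
    if (is.null(f1) && is.null(f2)) { disc_identity <- disc_identity + w[i]; next }
    if (paired && !is.null(f1) && !is.null(f2)) {
      # mates must tell the same story wherever they both have coverage
      # (this covers the both-span-the-window case); inconsistent pairs --
      # e.g. an indel at one mate's edge scored as substitutions -- are
      # discarded and tallied
      os <- max(f1$cov_start, f2$cov_start)
      oe <- min(f1$cov_end, f2$cov_end)
      if (os < oe &&
          op_key(window_ops(f1$ops, os, oe)) != op_key(window_ops(f2$ops, os, oe))) {
        disc_conflict <- disc_conflict + w[i]; next
      }
      merged <- merge_mate_ops(f1$ops, f2$ops)
      if (is.null(merged)) { disc_conflict <- disc_conflict + w[i]; next }
      fr <- list(ops = merged,
                 ranges = rbind(c(f1$cov_start, f1$cov_end),
                                c(f2$cov_start, f2$cov_end)))
    } else {
      f <- if (!is.null(f1)) f1 else f2
      fr <- list(ops = f$ops, ranges = rbind(c(f$cov_start, f$cov_end)))
    }
    frag[[length(frag) + 1L]] <- fr
    fw <- c(fw, w[i])
  }
  structure(list(fragments = frag, weights = fw, amplicon = amplicon,
                 window = window, n_reads = length(r1),
                 discarded_identity = disc_identity,
                 discarded_conflict = disc_conflict),
            class = "amplicon_alignments")
}

empty_alignments <- function(amplicon, window) {
  structure(list(fragments = list(), weights = integer(0),
                 amplicon = amplicon, window = window, n_reads = 0L,
                 discarded_identity = 0L, discarded_conflict = 0L),
            class = "amplicon_alignments")
}

#' @export
print.amplicon_alignments <- function(x, ...) {
  cat(sprintf("<amplicon_alignments> %d reads -> %d distinct fragments (%d kept), %d low-identity, %d mate-conflict\n",
              x$n_reads, length(x$fragments), sum(x$weights),
              x$discarded_identity, x$discarded_conflict))
  invisible(x)
}

# ops overlapping the window [ws, we); indels straddling an edge are kept
window_ops <- function(ops, ws, we) {
  keep <- vapply(ops, function(o) switch(o$type,
    del = o$start < we && (o$start + o$len) > ws,
    ins = o$start >= ws && o$start <= we,
    sub = o$start >= ws && o$start < we), TRUE)
  ops[keep]
}

# union of two mates' ops; NULL (discard the pair) when non-identical ops
# overlap -- e.g. one mate representing an indel near its end as
# substitutions while the other holds the gap
merge_mate_ops <- function(ops1, ops2) {
  all_ops <- c(ops1, ops2)
  keys <- vapply(all_ops, op_key_one, "")
  merged <- all_ops[!duplicated(keys)]
  if (length(merged) > 1) {
    # doubled coordinates so zero-width insertions can collide with bases
    lo <- vapply(merged, function(o)
      if (o$type == "ins") 2L * o$start - 1L else 2L * o$start, 1L)
    hi <- vapply(merged, function(o) switch(o$type,
      del = 2L * (o$start + o$len), ins = 2L * o$start + 1L,
      sub = 2L * o$start + 2L), 1L)
    o <- order(lo)
    if (any(lo[o][-1] < hi[o][-length(o)])) return(NULL)
  }
  merged[order(vapply(merged, `[[`, 1L, "start"))]
}

op_key_one <- function(o) op_key(list(o))

#' Extract cut-site-window haplotypes
#'
#' Only reads (fragments) fully spanning the window contribute. An allele is
#' the exact op list restricted to the window: ops fully outside are ignored;
#' an indel straddling a window edge keeps the read and extends that allele's
#' footprint. Identical op lists are merged and counted; frequencies are
#' relative to the spanning-read total, so they sum to 1 before filtering.
#'
#' @param alignments An `amplicon_alignments` object.
#' @param window [window_spec()]; defaults to the one stored at alignment.
#' @return `data.frame` of class `allele_table`: `allele` (canonical key,
#'   `""` = wild type), list column `ops`, `read_count`, `frequency`, sorted
#'   by descending frequency. Attribute `spanning` holds the denominator.
#' @export
extract_haplotypes <- function(alignments, window = NULL) {
  if (is.null(window)) window <- alignments$window
  amp <- alignments$amplicon
  ws <- amp$cut_coord - window$upstream
  we <- amp$cut_coord + window$downstream
  keys <- character(0); wts <- integer(0); opslist <- list()
  for (i in seq_along(alignments$fragments)) {
    fr <- alignments$fragments[[i]]
    if (!spans(fr$ranges, ws, we)) next
    wo <- window_ops(fr$ops, ws, we)
    k <- op_key(wo)
    j <- match(k, keys)
    if (is.na(j)) {
      keys <- c(keys, k); wts <- c(wts, alignments$weights[i])
      opslist[[length(opslist) + 1L]] <- wo
    } else wts[j] <- wts[j] + alignments$weights[i]
  }
  if (!length(keys)) {
    warning("no reads span the haplotype window")
    out <- data.frame(allele = character(), read_count = integer(),
                      frequency = numeric())
    out$ops <- list()
  } else {
    o <- order(wts, decreasing = TRUE)
    out <- data.frame(allele = keys[o], read_count = wts[o],
                      frequency = wts[o] / sum(wts))
    out$ops <- opslist[o]
  }
  attr(out, "spanning") <- sum(wts)
  attr(out, "window") <- window
  attr(out, "amplicon") <- amp
  class(out) <- c("allele_table", "data.frame")
  out
}

# does the (possibly two-range) coverage fully contain [ws, we)?
spans <- function(ranges, ws, we) {
  r <- IRanges::reduce(IRanges::IRanges(start = ranges[, 1] + 1L,
                                        end = ranges[, 2]))
  any(IRanges::start(r) <= ws + 1L & IRanges::end(r) >= we)
}

#' Filter alleles by minimum frequency
#'
#' Retains alleles with `frequency >= min_freq` (default 0.5%; some displays
#' use 1%), ordered by descending frequency. The removed mass is reported in
#' the `"other"` attribute.
#'
#' @param alleles An `allele_table`.
#' @param min_freq Frequency threshold in `[0, 1]`.
#' @return Filtered `allele_table` with attribute `other`.
#' @export
filter_alleles <- function(alleles, min_freq = 0.005) {
  stopifnot(min_freq >= 0, min_freq <= 1)
  keep <- alleles$frequency >= min_freq
  out <- alleles[keep, , drop = FALSE]
  out <- out[order(out$frequency, decreasing = TRUE), , drop = FALSE]
  for (a in c("spanning", "window", "amplicon"))
    attr(out, a) <- attr(alleles, a)
  attr(out, "other") <- sum(alleles$frequency[!keep])
  class(out) <- class(alleles)
  out
}

#' Classify one allele and name it at the protein level
#'
#' Classification follows the reading frame: (1) alleles touching no coding
#' base are `noncoding` and described at the nucleotide level (e.g. an
#' intronic deletion `g.101_108del`); (2) a net coding indel not divisible by
#' 3 is a `frameshift`, named `<AA><pos>fs` at the first affected codon;
#' (3) otherwise the mutant CDS is spliced and translated -- a premature stop
#' is `nonsense` (`<AA><pos>*`), an unchanged protein is `silent` (or
#' `wild_type` for an empty op list, named `"WT"`), and protein differences
#' are named HGVS-like by comparing reference and mutant proteins after
#' trimming their common prefix/suffix: `G383del`, `D130_L132del`,
#' `V166_K167insL`, substitution runs listed per residue
#' (`C528S,E529V,Q530H,K531I`), and combined changes as `delins`.
#'
#' @param ops Op list (or canonical key string) of the allele.
#' @param amplicon An [amplicon_reference] carrying a `codon_map`.
#' @return Object of class `protein_variant`: list with `name`, `klass`,
#'   `net_indel` and `affected_codons`.
#' @export
classify_and_name <- function(ops, amplicon) {
  if (is.character(ops)) ops <- parse_op_key(ops)
  cm <- amplicon$codon_map
  pv <- function(name, klass, net, aff = integer(0))
    structure(list(name = name, klass = klass, net_indel = as.integer(net),
                   affected_codons = as.integer(aff)),
              class = "protein_variant")
  if (!length(ops)) return(pv("WT", "wild_type", 0L))
  coding <- if (is.null(cm)) integer(0) else cm$ref_coord
  cds_of <- function(r) match(r, coding)       # 1-based CDS index or NA
  touches <- vapply(ops, function(o) switch(o$type,
    del = any((o$start:(o$start + o$len - 1L)) %in% coding),
    ins = (o$start - 1L) %in% coding && o$start %in% coding,
    sub = o$start %in% coding), TRUE)
  if (!any(touches)) {
    nm <- paste(vapply(ops, noncoding_name, ""), collapse = ";")
    net <- sum(vapply(ops, function(o) switch(o$type,
      del = -o$len, ins = nchar(o$seq), sub = 0L), 0L))
    return(pv(nm, "noncoding", net))
  }
  if (is.null(cm)) stop("coding classification requires a codon_map")
  net <- 0L
  touched_idx <- integer(0)
  for (o in ops) {
    if (o$type == "del") {
      idx <- cds_of(o$start:(o$start + o$len - 1L))
      idx <- idx[!is.na(idx)]
      net <- net - length(idx)
      touched_idx <- c(touched_idx, idx)
    } else if (o$type == "ins") {
      idx <- cds_of(c(o$start - 1L, o$start))
      if (!anyNA(idx)) {
        net <- net + nchar(o$seq)
        touched_idx <- c(touched_idx, min(idx) + 1L)
      }
    } else {
      idx <- cds_of(o$start)
      if (!is.na(idx)) touched_idx <- c(touched_idx, idx)
    }
  }
  prot <- cm$protein
  first_codon <- codon_number(min(touched_idx) - 1L)
  if (net %% 3L != 0L) {
    aa <- substr(prot, first_codon, first_codon)
    return(pv(sprintf("%s%dfs", aa, first_codon), "frameshift", net,
              first_codon:nchar(prot)))
  }
  mut <- mutant_protein(ops, cm)
  if (mut == prot) {
    if (first_codon <= nchar(prot)) {
      aa <- substr(prot, first_codon, first_codon)
      return(pv(sprintf("%s%d%s", aa, first_codon, aa), "silent", net,
                first_codon))
    }
    return(pv("silent", "silent", net))
  }
  mstop <- regexpr("*", mut, fixed = TRUE)
  if (mstop > 0 && mstop < nchar(mut)) {   # stop internal to the mutant
    aa <- if (mstop <= nchar(prot)) substr(prot, mstop, mstop) else "?"
    return(pv(sprintf("%s%d*", aa, mstop), "nonsense", net, mstop))
  }
  diff_name(prot, mut, net, pv)
}

noncoding_name <- function(o) {
  switch(o$type,
    del = if (o$len == 1L) sprintf("g.%ddel", o$start + 1L)
          else sprintf("g.%d_%ddel", o$start + 1L, o$start + o$len),
    ins = sprintf("g.%d_%dins%s", o$start, o$start + 1L, o$seq),
    sub = sprintf("g.%d>%s", o$start + 1L, o$base))
}

# mutant CDS built by applying ops through the codon map (strand-aware), then
# translated
mutant_protein <- function(ops, cm) {
  L <- nchar(cm$cds)
  ref <- strsplit(cm$cds, "")[[1]]
  keep <- rep(TRUE, L)
  repl <- ref
  ins_after <- vector("list", L + 1L)   # [[i+1]]: inserted after CDS index i
  cds_of <- function(r) match(r, cm$ref_coord)
  for (o in ops) {
    if (o$type == "del") {
      idx <- cds_of(o$start:(o$start + o$len - 1L))
      keep[idx[!is.na(idx)]] <- FALSE
    } else if (o$type == "sub") {
      idx <- cds_of(o$start)
      if (!is.na(idx))
        repl[idx] <- if (cm$strand == "-") chartr("ACGT", "TGCA", o$base) else o$base
    } else {
      idx <- cds_of(c(o$start - 1L, o$start))
      if (!anyNA(idx)) {
        after <- min(idx)
        seq <- if (cm$strand == "-") revcomp(o$seq) else o$seq
        ins_after[[after + 1L]] <- c(ins_after[[after + 1L]], seq)
      }
    }
  }
  pieces <- character(0)
  for (i in 0:L) {
    if (!is.null(ins_after[[i + 1L]]))
      pieces <- c(pieces, ins_after[[i + 1L]])
    if (i < L && keep[i + 1L]) pieces <- c(pieces, repl[i + 1L])
  }
  mut <- paste(pieces, collapse = "")
  stopifnot(nchar(mut) %% 3L == 0L)
  as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                     if.fuzzy.codon = "solve"))
}

# HGVS-like name from the reference/mutant protein pair (in-frame,
# non-nonsense case): trim the common prefix and suffix and name the middle
diff_name <- function(ref, mut, net, pv) {
  rc <- strsplit(ref, "")[[1]]; mc <- strsplit(mut, "")[[1]]
  nR <- length(rc); nM <- length(mc)
  p <- 0L
  while (p < min(nR, nM) && rc[p + 1L] == mc[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < min(nR, nM) - p && rc[nR - s] == mc[nM - s]) s <- s + 1L
  rmid <- if (p + s < nR) rc[(p + 1L):(nR - s)] else character(0)
  mmid <- if (p + s < nM) mc[(p + 1L):(nM - s)] else character(0)
  rng <- function(i) sprintf("%s%d", rc[i], i)
  if (!length(mmid)) {                  # pure deletion of codons p+1 .. nR-s
    a <- p + 1L; b <- nR - s
    nm <- if (a == b) sprintf("%s%ddel", rc[a], a)
          else sprintf("%s%d_%s%ddel", rc[a], a, rc[b], b)
    return(pv(nm, "inframe_deletion", net, a:b))
  }
  if (!length(rmid)) {                  # pure insertion between p and p+1
    a <- max(1L, p); b <- min(nR, p + 1L)
    nm <- sprintf("%s_%sins%s", rng(a), rng(b), paste(mmid, collapse = ""))
    return(pv(nm, "inframe_insertion", net, c(a, b)))
  }
  if (length(rmid) == length(mmid)) {   # substitution run
    d <- which(rmid != mmid)
    nm <- paste(sprintf("%s%d%s", rmid[d], p + d, mmid[d]), collapse = ",")
    return(pv(nm, "missense", net, p + d))
  }
  a <- p + 1L; b <- nR - s
  nm <- if (a == b) sprintf("%s%ddelins%s", rc[a], a, paste(mmid, collapse = ""))
        else sprintf("%s%d_%s%ddelins%s", rc[a], a, rc[b], b,
                     paste(mmid, collapse = ""))
  pv(nm, "inframe_delins", net, a:b)
}

#' @export
print.protein_variant <- function(x, ...) {
  cat(sprintf("<protein_variant> %s [%s, net %+d nt]\n",
              x$name, x$klass, x$net_indel))
  invisible(x)
}

#' Classify every allele of an allele table
#'
#' @param alleles An `allele_table`.
#' @param amplicon An [amplicon_reference]; defaults to the one stored on the
#'   table.
#' @return `alleles` with `name`, `klass`, `net_indel` columns added.
#' @export
classify_alleles <- function(alleles, amplicon = attr(alleles, "amplicon")) {
  vars <- lapply(alleles$ops, classify_and_name, amplicon = amplicon)
  alleles$name <- vapply(vars, `[[`, "", "name")
  alleles$klass <- vapply(vars, `[[`, "", "klass")
  alleles$net_indel <- vapply(vars, `[[`, 0L, "net_indel")
  alleles
}

#' Roll allele frequencies up into mutation-type categories
#'
#' Aggregates classified allele frequencies into the four display categories
#' -- wild-type, in-frame (deletion / insertion / delins / missense /
#' silent), frameshift and nonsense -- with non-coding alleles reported
#' separately. Category masses sum to the total retained allele mass.
#'
#' @param alleles A classified `allele_table` (see [classify_alleles()]).
#' @return Named numeric vector over
#'   `c("wild_type", "in_frame", "frameshift", "nonsense", "noncoding")`.
#' @export
mutation_type_summary <- function(alleles) {
  if (is.null(alleles$klass))
    stop("alleles must be classified first (classify_alleles)")
  rollup <- c(wild_type = "wild_type",
              inframe_deletion = "in_frame", inframe_insertion = "in_frame",
              inframe_delins = "in_frame", missense = "in_frame",
              silent = "in_frame", frameshift = "frameshift",
              nonsense = "nonsense", noncoding = "noncoding")
  cat4 <- factor(unname(rollup[alleles$klass]),
                 levels = c("wild_type", "in_frame", "frameshift",
                            "nonsense", "noncoding"))
  vapply(split(alleles$frequency, cat4), sum, 0)
}

#' Per-position SNV and deletion spectrum
#'
#' For every amplicon position, the frequency of A/C/G/T and deletion among
#' the fragments covering it. The variant frequency of a position is
#' `1 - frequency(reference base)`.
#'
#' @param alignments An `amplicon_alignments` object.
#' @return List with `freq` (positions x A,C,G,T,del row-normalized matrix),
#'   `counts`, `coverage` and `variant_freq`. Rows with zero coverage are
#'   `NA`.
#' @export
snv_spectrum <- function(alignments) {
  amp <- alignments$amplicon
  L <- amp$length
  bases <- c("A", "C", "G", "T", "del")
  counts <- matrix(0, nrow = L, ncol = 5L, dimnames = list(NULL, bases))
  refc <- strsplit(amp$sequence, "")[[1]]
  for (i in seq_along(alignments$fragments)) {
    fr <- alignments$fragments[[i]]
    w <- alignments$weights[i]
    covered <- unique(unlist(apply(fr$ranges, 1, function(r)
      seq.int(r[1], r[2] - 1L), simplify = FALSE)))
    covered <- covered[covered >= amp$offset & covered < amp$offset + L]
    loc <- covered - amp$offset + 1L
    base_idx <- match(refc[loc], bases)
    names(base_idx) <- loc
    for (o in fr$ops) {
      if (o$type == "sub") {
        l <- o$start - amp$offset + 1L
        if (as.character(l) %in% names(base_idx))
          base_idx[as.character(l)] <- match(o$base, bases)
      } else if (o$type == "del") {
        l <- (o$start:(o$start + o$len - 1L)) - amp$offset + 1L
        l <- l[l >= 1L & l <= L]
        base_idx[as.character(l)] <- 5L
      }
    }
    ij <- cbind(as.integer(names(base_idx)), unname(base_idx))
    ij <- ij[!is.na(ij[, 2]), , drop = FALSE]
    for (k in seq_len(nrow(ij)))
      counts[ij[k, 1], ij[k, 2]] <- counts[ij[k, 1], ij[k, 2]] + w
  }
  cov <- rowSums(counts)
  freq <- counts / ifelse(cov > 0, cov, NA_real_)
  ref_idx <- match(refc, bases)
  vf <- 1 - freq[cbind(seq_len(L), ref_idx)]
  list(freq = freq, counts = counts, coverage = cov, variant_freq = vf)
}

#' Write allele, spectrum and rollup tables as TSV
#'
#' @param alleles Classified `allele_table`.
#' @param path Output TSV for the alleles; the SNV spectrum and rollup are
#'   written alongside as `<path>.spectrum.tsv` / `<path>.rollup.tsv` when
#'   `alignments` is supplied.
#' @param alignments Optional `amplicon_alignments` for the spectrum table.
#' @export
write_alleles <- function(alleles, path, alignments = NULL) {
  df <- data.frame(allele = alleles$allele, read_count = alleles$read_count,
                   frequency = alleles$frequency)
  if (!is.null(alleles$name)) {
    df$name <- alleles$name
    df$klass <- alleles$klass
    df$net_indel <- alleles$net_indel
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(alleles$klass)) {
    ro <- mutation_type_summary(alleles)
    write.table(data.frame(category = names(ro), frequency = unname(ro)),
                paste0(path, ".rollup.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(alignments)) {
    sp <- snv_spectrum(alignments)
    out <- data.frame(pos = seq_len(nrow(sp$freq)) +
                        alignments$amplicon$offset - 1L,
                      coverage = sp$coverage, sp$freq,
                      variant_freq = sp$variant_freq)
    write.table(out, paste0(path, ".spectrum.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
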