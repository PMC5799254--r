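# Built-in oligo adapters. The published totals are 60 nt (SpCas9:
# 20 + 20-nt protospacer + 20) and 79 nt (AsCpf1: 18 + 19-nt direct repeat +
# 24-nt protospacer + 18); the adapter sequences themselves were not
# published, so fixed defaults are supplied and user-overridable.
.SPCAS9_ADAPTERS <- c(left = "TATCTTGTGGAAAGGACGAA", right = "GTTTTAGAGCTAGAAATAGC")
.ASCPF1_ADAPTERS <- c(left = "AGGCACTTGCTCGTACGA", right = "CGTACGCTAAGGCTTAGC")
.ASCPF1_DIRECT_REPEAT <- "TAATTTCTACTCTTGTAGA"

#' Nuclease profile for guide enumeration
#'
#' Bundles the PAM motif and side, protospacer length, exon-extension lengths,
#' cut-site convention, direct repeat and oligo layout of a supported
#' endonuclease.
#'
#' * **SpCas9**: NGG PAM 3' of a 20-nt protospacer (sites are N21GG, 23 nt);
#'   exons extended 20 bp 5' / 9 bp 3' on each searched strand; blunt cut
#'   between protospacer positions 17 and 18 (3 bp 5' of the PAM); oligos
#'   20 + 20 + 20 = 60 nt.
#' * **AsCpf1**: TTTN PAM 5' of a 24-nt protospacer (sites are TTTN24, 28 nt);
#'   25-bp extension at intron-exon boundaries only; staggered cut, canonical
#'   coordinate after protospacer position 18 (4-nt 5' overhang recorded as
#'   metadata); crRNA oligos carry the direct repeat
#'   `TAATTTCTACTCTTGTAGA` immediately 5' of the protospacer,
#'   18 + 19 + 24 + 18 = 79 nt.
#'
#' @param name `"SpCas9"` or `"AsCpf1"`.
#' @param adapters Named character vector `c(left=, right=)` overriding the
#'   built-in PCR adapters.
#' @param oligo_len Expected total oligo length; defaults to 60 / 79.
#' @return An object of class `nuclease_profile`.
#' @export
nuclease_profile <- function(name = c("SpCas9", "AsCpf1"), adapters = NULL,
                             oligo_len = NULL) {
  name <- match.arg(name)
  p <- if (name == "SpCas9") {
    list(name = "SpCas9", pam_pattern = "NGG", pam_side = "3p", pam_len = 3L,
         protospacer_len = 20L, site_len = 23L, ext5 = 20L, ext3 = 9L,
         boundary_only = FALSE, cut_offset = 17L, overhang = 0L,
         direct_repeat = "", oligo_len = 60L,
         adapters = .SPCAS9_ADAPTERS)
  } else {
    list(name = "AsCpf1", pam_pattern = "TTTN", pam_side = "5p", pam_len = 4L,
         protospacer_len = 24L, site_len = 28L, ext5 = 25L, ext3 = 25L,
         boundary_only = TRUE, cut_offset = 18L, overhang = 4L,
         direct_repeat = .ASCPF1_DIRECT_REPEAT, oligo_len = 79L,
         adapters = .ASCPF1_ADAPTERS)
  }
  if (!is.null(adapters)) {
    stopifnot(all(c("left", "right") %in% names(adapters)))
    p$adapters <- adapters[c("left", "right")]
  }
  if (!is.null(oligo_len)) p$oligo_len <- as.integer(oligo_len)
  stopifnot(p$site_len == p$protospacer_len + p$pam_len)
  structure(p, class = "nuclease_profile")
}

#' @export
print.nuclease_profile <- function(x, ...) {
  cat(sprintf("<nuclease_profile> %s: %s PAM (%s), %d-nt protospacer, ext %d/%d%s, oligo %d nt\n",
              x$name, x$pam_pattern, if (x$pam_side == "3p") "3'" else "5'",
              x$protospacer_len, x$ext5, x$ext3,
              if (x$boundary_only) " (intron boundaries only)" else "",
              x$oligo_len))
  invisible(x)
}

#' Enumerate all PAM-proximal guide sites in search intervals
#'
#' Scans both strands of the given reference intervals for every position
#' matching the profile's full-site pattern (N21GG for SpCas9; TTTN24 for
#' AsCpf1) and emits one record per site. Protospacer and PAM are reported in
#' guide (strand) orientation; sites containing `N` are skipped. The canonical
#' cut coordinate is stored such that the cut falls between `cut_coord - 1`
#' and `cut_coord` on the reference.
#'
#' @param reference Reference sequence (single character string) or named
#'   vector from [read_reference()] together with `seqid`.
#' @param intervals `data.frame` of 0-based half-open `start`, `end`; an
#'   optional `strand` column restricts scanning of that interval to one
#'   strand (`"+"`, `"-"`, default both).
#' @param profile A [nuclease_profile].
#' @param seqid Sequence to scan when `reference` is a multi-sequence vector.
#' @return `data.frame` with columns `protospacer`, `pam`, `strand`,
#'   `site_start`, `site_end`, `cut_coord`, sorted by position.
#' @export
enumerate_guides <- function(reference, intervals, profile, seqid = NULL) {
  if (length(reference) > 1 || !is.null(names(reference))) {
    if (is.null(seqid)) seqid <- names(reference)[1]
    reference <- reference[[seqid]]
  }
  n <- nchar(reference)
  intervals <- as.data.frame(intervals)
  if (is.null(intervals$strand)) intervals$strand <- "*"
  if (any(intervals$start < 0) || any(intervals$end > n))
    stop("search interval outside reference bounds")
  out <- vector("list", 2L * nrow(intervals))
  k <- 0L
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    subseq <- substr(reference, s + 1L, e)
    for (str in c("+", "-")) {
      if (!intervals$strand[i] %in% c("*", str)) next
      k <- k + 1L
      out[[k]] <- scan_sites(subseq, s, str, profile)
    }
  }
  g <- do.call(rbind, out[seq_len(k)])
  if (is.null(g) || !nrow(g)) {
    return(data.frame(protospacer = character(), pam = character(),
                      strand = character(), site_start = integer(),
                      site_end = integer(), cut_coord = integer()))
  }
  g <- unique(g)  # merged intervals should not overlap, but be safe
  g[order(g$site_start, g$strand), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

# scan one interval substring for sites of `profile` on one strand; offset is
# the 0-based reference coordinate of the substring's first base
scan_sites <- function(subseq, offset, strand, profile) {
  L <- profile$site_len; P <- profile$protospacer_len
  pat <- if (profile$name == "SpCas9") {
    if (strand == "+") "(?=[ACGT]{21}GG)" else "(?=CC[ACGT]{21})"
  } else {
    if (strand == "+") "(?=TTT[ACGT]{25})" else "(?=[ACGT]{25}AAA)"
  }
  m <- gregexpr(pat, subseq, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(protospacer = character(), pam = character(),
                      strand = character(), site_start = integer(),
                      site_end = integer(), cut_coord = integer()))
  site_start <- offset + as.integer(m) - 1L
  site_end <- site_start + L
  site <- substring(subseq, as.integer(m), as.integer(m) + L - 1L)
  oriented <- if (strand == "+") site else revcomp(site)
  if (profile$pam_side == "3p") {
    protospacer <- substr(oriented, 1L, P)
    pam <- substr(oriented, P + 1L, L)
    cut <- if (strand == "+") site_start + profile$cut_offset
           else site_end - profile$cut_offset
  } else {
    pam <- substr(oriented, 1L, profile$pam_len)
    protospacer <- substr(oriented, profile$pam_len + 1L, L)
    cut <- if (strand == "+") site_start + profile$pam_len + profile$cut_offset
           else site_end - profile$pam_len - profile$cut_offset
  }
  data.frame(protospacer = protospacer, pam = pam, strand = strand,
             site_start = site_start, site_end = site_end,
             cut_coord = as.integer(cut))
}

#' Deduplicate guides per gene and drop poly-T protospacers
#'
#' Within each gene, one record is kept per distinct protospacer sequence
#' (isoform annotations are merged); the representative is the 5'-most site in
#' gene orientation, ties broken by `+` strand first. Guides whose protospacer
#' contains `TTTTT` (a Pol III terminator) are removed. Identical protospacers
#' in *different* genes are retained in each.
#'
#' @param guides `data.frame` with at least `gene`, `protospacer`; optional
#'   `isoforms` (";"-separated), `gene_strand`, `site_start`, `site_end`,
#'   `strand`.
#' @return Filtered `data.frame`, original relative order of representatives.
#' @export
dedup_and_filter <- function(guides) {
  g <- as.data.frame(guides)
  if (is.null(g$isoforms)) g$isoforms <- ""
  if (is.null(g$gene_strand)) g$gene_strand <- "+"
  keep <- !grepl("TTTTT", g$protospacer, fixed = TRUE)
  g <- g[keep, , drop = FALSE]
  if (!nrow(g)) return(g)
  parts <- split(g, g$gene)
  res <- lapply(parts, function(d) {
    # 5'-most in gene orientation: smallest site_start for + genes, largest
    # site_end for - genes; tie broken by + strand first
    pos <- if (!is.null(d$site_start)) d$site_start else seq_len(nrow(d))
    endp <- if (!is.null(d$site_end)) d$site_end else seq_len(nrow(d))
    ordkey <- if (d$gene_strand[1] == "-") -endp else pos
    o <- order(ordkey, d$strand != "+")
    d <- d[o, , drop = FALSE]
    first <- !duplicated(d$protospacer)
    iso <- vapply(split(d$isoforms, d$protospacer), function(v) {
      u <- unique(unlist(strsplit(v, ";", fixed = TRUE)))
      paste(u[nzchar(u)], collapse = ";")
    }, "")
    d <- d[first, , drop = FALSE]
    d$isoforms <- unname(iso[d$protospacer])
    d
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assemble synthesizable oligos for a guide set
#'
#' `oligo = left_adapter [+ direct_repeat] + protospacer + right_adapter`.
#' For AsCpf1 the direct repeat sits immediately 5' of the protospacer. The
#' resulting length must equal the profile's `oligo_len`.
#'
#' @param guides Guide `data.frame` (column `protospacer`).
#' @param profile A [nuclease_profile].
#' @param adapters Optional `c(left=, right=)` override.
#' @return `guides` with `oligo` and `oligo_len` columns added.
#' @export
assemble_oligo <- function(guides, profile, adapters = NULL) {
  if (is.null(adapters)) adapters <- profile$adapters
  oligo <- paste0(adapters[["left"]], profile$direct_repeat,
                  guides$protospacer, adapters[["right"]])
  lens <- nchar(oligo)
  if (length(lens) && any(lens != profile$oligo_len))
    stop(sprintf("oligo length %d != configured %d; check adapter lengths",
                 lens[which(lens != profile$oligo_len)[1]], profile$oligo_len))
  guides$oligo <- oligo
  guides$oligo_len <- lens
  guides
}

#' Add scrambled non-targeting control guides
#'
#' Controls are generated by shuffling the bases of randomly chosen library
#' protospacers until the shuffle has no exact occurrence anywhere in the
#' reference (either strand) and no `TTTTT` run. Deterministic for a given
#' seed.
#'
#' @param library Guide `data.frame`.
#' @param n Number of controls (the published libraries used 100 sgRNA / 30
#'   crRNA controls).
#' @param reference Reference sequence(s) the controls must not match.
#' @param profile A [nuclease_profile].
#' @param seed Integer RNG seed.
#' @param max_tries Retry bound per control before failing.
#' @return `library` with `n` appended rows, `gene == "CONTROL"`.
#' @export
add_controls <- function(library, n, reference, profile, seed = 1L,
                         max_tries = 1000L) {
  stopifnot(n >= 0)
  if (n == 0) return(library)
  if (!nrow(library)) stop("cannot scramble controls from an empty library")
  set.seed(seed)
  haystack <- paste(c(reference, revcomp(unname(reference))), collapse = "|")
  existing <- character(0)
  ctrl <- character(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      src <- library$protospacer[sample.int(nrow(library), 1L)]
      cand <- paste(sample(strsplit(src, "")[[1]]), collapse = "")
      if (!grepl(cand, haystack, fixed = TRUE) &&
          !grepl("TTTTT", cand, fixed = TRUE) && !(cand %in% existing)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not generate a non-matching scrambled control after ",
                  max_tries, " tries")
    ctrl[i] <- cand
    existing <- c(existing, cand)
  }
  ctrl_df <- data.frame(gene = "CONTROL", isoforms = "", gene_strand = "+",
                        protospacer = ctrl, pam = NA_character_,
                        strand = NA_character_, site_start = NA_integer_,
                        site_end = NA_integer_, cut_coord = NA_integer_)
  cols <- union(names(library), names(ctrl_df))
  for (cn in setdiff(cols, names(library))) library[[cn]] <- NA
  for (cn in setdiff(cols, names(ctrl_df))) ctrl_df[[cn]] <- NA
  out <- rbind(library[cols], ctrl_df[cols])
  rownames(out) <- NULL
  out
}

#' Split a library into contiguous alphabetical sub-pools
#'
#' Genes are sorted alphabetically by symbol and partitioned into `n_pools`
#' contiguous blocks that minimize the largest pool's guide count (all guides
#' of one gene stay together, mirroring the published A/B split *ABL1--HDAC9*
#' / *IFNAR1--VEGFB*). Controls are distributed round-robin across pools.
#'
#' @param library Guide `data.frame` (columns `gene`, `protospacer`).
#' @param n_pools Number of sub-pools (>= 1).
#' @return `library` with a `subpool` column (`"A"`, `"B"`, ...).
#' @export
split_sublibraries <- function(library, n_pools) {
  stopifnot(n_pools >= 1)
  is_ctrl <- library$gene == "CONTROL"
  genes <- sort(unique(library$gene[!is_ctrl]))
  if (n_pools > length(genes))
    stop(sprintf("n_pools (%d) exceeds number of genes (%d)",
                 n_pools, length(genes)))
  sizes <- as.integer(table(factor(library$gene[!is_ctrl], levels = genes)))
  breaks <- partition_contiguous(sizes, n_pools)
  pool_of_gene <- setNames(rep(LETTERS[seq_len(n_pools)], times = breaks), genes)
  library$subpool <- NA_character_
  library$subpool[!is_ctrl] <- unname(pool_of_gene[library$gene[!is_ctrl]])
  if (any(is_ctrl))
    library$subpool[is_ctrl] <-
      LETTERS[((seq_len(sum(is_ctrl)) - 1L) %% n_pools) + 1L]
  library
}

# linear-partition DP: split `sizes` into k contiguous blocks minimizing the
# maximum block sum; returns the block lengths
partition_contiguous <- function(sizes, k) {
  n <- length(sizes)
  cs <- c(0, cumsum(sizes))
  cost <- matrix(Inf, n + 1L, k)        # cost[i+1, j]: first i genes in j blocks
  cut <- matrix(0L, n + 1L, k)
  cost[seq(2, n + 1L), 1L] <- cs[seq(2, n + 1L)]
  if (k > 1) for (j in 2:k) for (i in j:n) {
    for (m in (j - 1):(i - 1)) {
      v <- max(cost[m + 1L, j - 1L], cs[i + 1L] - cs[m + 1L])
      if (v < cost[i + 1L, j]) { cost[i + 1L, j] <- v; cut[i + 1L, j] <- m }
    }
  }
  ends <- integer(k); i <- n
  for (j in k:1) { ends[j] <- i; i <- cut[i + 1L, j] }
  starts <- c(0L, ends[-k])
  ends - starts
}

#' Design a complete tiling guide library
#'
#' Runs the full designer for one nuclease over a set of gene models:
#' expanded search intervals per strand, exhaustive PAM-site enumeration,
#' gene-level deduplication and poly-T filtering, oligo assembly, scrambled
#' controls and sub-pool splitting. Guide ids are `"<gene>_<k>"` in 5'->3'
#' gene order; the whole procedure is deterministic for a given seed.
#'
#' @param models List of [gene_model] objects (e.g. from
#'   [read_gene_models()]).
#' @param reference Named reference vector from [read_reference()].
#' @param profile A [nuclease_profile].
#' @param n_controls Number of scrambled controls to append.
#' @param n_pools Number of sub-pools.
#' @param seed RNG seed for control generation.
#' @param adapters Optional adapter override for [assemble_oligo()].
#' @return Guide library `data.frame` with columns `guide_id`, `gene`,
#'   `isoforms`, `protospacer`, `pam`, `strand`, `site_start`, `site_end`,
#'   `cut_coord`, `subpool`, `oligo`.
#' @export
design_library <- function(models, reference, profile, n_controls = 0L,
                           n_pools = 1L, seed = 1L, adapters = NULL) {
  per_iso <- lapply(models, function(m) {
    ref <- reference[[m$reference_id]]
    hits <- lapply(c("+", "-"), function(str) {
      iv <- expanded_search_intervals(m, profile, strand = str,
                                      reference_length = nchar(ref))
      iv$strand <- str
      enumerate_guides(ref, iv, profile)
    })
    g <- do.call(rbind, hits)
    if (!nrow(g)) return(NULL)
    g$gene <- m$gene_symbol
    g$isoforms <- m$isoform_id
    g$gene_strand <- m$strand
    g$reference_id <- m$reference_id
    g
  })
  g <- do.call(rbind, per_iso[!vapply(per_iso, is.null, TRUE)])
  if (is.null(g)) g <- data.frame(gene = character(), isoforms = character(),
                                  gene_strand = character(),
                                  protospacer = character(), pam = character(),
                                  strand = character(), site_start = integer(),
                                  site_end = integer(), cut_coord = integer())
  g <- dedup_and_filter(g)
  if (nrow(g)) {
    g <- g[order(g$gene), , drop = FALSE]  # per-gene 5' order kept from dedup
    g$guide_id <- unlist(lapply(split(seq_len(nrow(g)), g$gene)[unique(g$gene)],
                                function(ix) paste0(g$gene[ix[1]], "_",
                                                    seq_along(ix))))
  } else g$guide_id <- character(0)
  if (n_controls > 0)
    g <- add_controls(g, n_controls, reference, profile, seed = seed)
  g$guide_id[g$gene == "CONTROL"] <-
    paste0("CONTROL_", seq_len(sum(g$gene == "CONTROL")))
  g <- split_sublibraries(g, n_pools)
  g <- assemble_oligo(g, profile, adapters = adapters)
  cols <- c("guide_id", "gene", "isoforms", "protospacer", "pam", "strand",
            "site_start", "site_end", "cut_coord", "subpool", "oligo")
  out <- g[, c(cols, setdiff(names(g), cols)), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a guide library
#'
#' The library is written as a TSV with the full record columns plus a FASTA
#' of protospacers whose headers are the guide ids. Rows are written in a
#' stable (gene, guide_id) order so identical inputs give byte-identical
#' files.
#'
#' @param library Guide library `data.frame`.
#' @param path Output TSV path.
#' @param fasta_path Protospacer FASTA path; default `<path>.fa`.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path, fasta_path = paste0(path, ".fa")) {
  lib <- library[order(library$gene != "CONTROL", library$gene,
                       library$guide_id, method = "radix",
                       decreasing = c(TRUE, FALSE, FALSE)), , drop = FALSE]
  write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  writeLines(paste0(">", lib$guide_id, "\n", lib$protospacer), fasta_path)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(guide_id = "character", gene = "character",
                            protospacer = "character"))
}
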