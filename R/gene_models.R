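#' @import methods
#' @importFrom stats rbinom rgeom runif rpois setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Internal convention: all coordinates are 0-based half-open [start, end).
# 1-based coordinates appear only in GFF3/GenBank I/O and human-facing
# variant names.

#' Construct a strand-aware CDS gene model
#'
#' A gene model is the ordered set of CDS exon intervals of one isoform on a
#' reference sequence. Exons are stored 0-based half-open and ranked in
#' transcription (5'->3' on the gene strand) order: rank 1 of a minus-strand
#' model is the exon with the largest coordinates.
#'
#' @param gene_symbol Gene symbol, e.g. `"XPO1"`.
#' @param isoform_id Isoform/transcript identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with columns `start`, `end` (0-based half-open);
#'   an optional `rank` column is recomputed from the strand.
#' @param reference_id Name of the reference sequence the coordinates refer to.
#' @param reference_length Optional length of that sequence, used for bounds
#'   checks and search-interval clipping.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_symbol, isoform_id, strand, exons, reference_id,
                       reference_length = NA_integer_) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start < 0L) || any(exons$end <= exons$start))
    stop("invalid exon interval: need 0 <= start < end")
  if (!is.na(reference_length) && any(exons$end > reference_length))
    stop(sprintf("CDS of %s/%s exceeds bounds of reference '%s'",
                 gene_symbol, isoform_id, reference_id))
  o <- order(exons$start)
  if (strand == "-") o <- rev(o)
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1) {
    s <- exons[order(exons$start), ]
    if (any(s$start[-1] < s$end[-nrow(s)]))
      stop("exons of one model must be non-overlapping")
  }
  exons$rank <- seq_len(nrow(exons))
  rownames(exons) <- NULL
  len <- sum(exons$end - exons$start)
  structure(
    list(gene_symbol = gene_symbol, isoform_id = isoform_id, strand = strand,
         exons = exons, reference_id = reference_id,
         reference_length = as.integer(reference_length),
         cds_length = as.integer(len), complete = (len %% 3L == 0L)),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s / %s (%s) on %s: %d exon(s), CDS %d bp%s\n",
              x$gene_symbol, x$isoform_id, x$strand, x$reference_id,
              nrow(x$exons), x$cds_length,
              if (x$complete) "" else " [incomplete: length not divisible by 3]"))
  invisible(x)
}

#' Read a reference FASTA into a named character vector
#'
#' @param fasta_file Path to a (possibly gzipped) FASTA file.
#' @return Named uppercase character vector, one element per sequence; names
#'   are truncated at the first whitespace.
#' @export
read_reference <- function(fasta_file) {
  x <- Biostrings::readDNAStringSet(fasta_file)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("reference contains characters outside {A,C,G,T,N}: ",
         paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Read gene models from GFF3 or GenBank annotation
#'
#' Builds one [gene_model] per (gene, isoform) from the CDS features of the
#' annotation. Coordinates are converted to 0-based half-open regardless of
#' the source dialect. GFF3 files are read with rtracklayer; a minimal
#' single-record GenBank reader handles `CDS` features with `join()` /
#' `complement()` locations and `/gene` qualifiers.
#'
#' @param annotation_file GFF3 (`.gff`, `.gff3`) or GenBank (`.gb`, `.gbk`,
#'   `.genbank`) file.
#' @param fasta_file Reference FASTA. May be `NULL` for GenBank files carrying
#'   an `ORIGIN` block.
#' @param format `"auto"` (by extension), `"gff3"` or `"genbank"`.
#' @return A list with elements `models` (list of `gene_model`) and
#'   `reference` (named character vector of sequences).
#' @export
read_gene_models <- function(annotation_file, fasta_file = NULL,
                             format = c("auto", "gff3", "genbank")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|genbank)$", annotation_file,
                        ignore.case = TRUE)) "genbank" else "gff3"
  }
  if (format == "genbank") {
    gb <- parse_genbank(annotation_file)
    reference <- if (!is.null(fasta_file)) read_reference(fasta_file) else gb$reference
    feats <- gb$features
  } else {
    reference <- read_reference(fasta_file)
    feats <- parse_gff3_cds(annotation_file)
  }
  missing <- setdiff(unique(feats$seqid), names(reference))
  if (length(missing))
    stop("annotation references sequence(s) absent from FASTA: ",
         paste(missing, collapse = ", "))
  key <- paste(feats$gene, feats$isoform, sep = "\r")
  models <- lapply(split(feats, key), function(d) {
    gene_model(d$gene[1], d$isoform[1], d$strand[1],
               d[, c("start", "end")], d$seqid[1],
               reference_length = nchar(reference[[d$seqid[1]]]))
  })
  names(models) <- vapply(models, function(m)
    paste(m$gene_symbol, m$isoform_id, sep = "/"), "")
  models <- models[order(names(models))]
  list(models = models, reference = reference)
}

parse_gff3_cds <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "CDS"]
  if (!length(gr)) stop("no CDS features in ", path)
  mc <- S4Vectors::mcols(gr)
  pick <- function(cols) {
    for (cn in cols) if (cn %in% colnames(mc)) {
      v <- mc[[cn]]
      if (is(v, "List") || is.list(v))
        v <- vapply(v, function(e) if (length(e)) as.character(e[1]) else NA_character_, "")
      v <- as.character(v)
      if (!all(is.na(v))) return(v)
    }
    rep(NA_character_, length(gr))
  }
  gene <- pick(c("gene_id", "gene_name", "gene", "Name"))
  iso <- pick(c("transcript_id", "Parent", "ID"))
  gene[is.na(gene)] <- iso[is.na(gene)]
  if (anyNA(gene)) stop("CDS features lack gene/transcript attributes")
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,  # 1-based incl -> 0-based
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             gene = gene, isoform = iso, stringsAsFactors = FALSE)
}

# Minimal GenBank flat-file reader: LOCUS name, CDS features with
# join()/complement() locations, /gene and /locus_tag qualifiers, ORIGIN
# sequence. Enough for single-record annotation fixtures.
parse_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank file (no LOCUS line): ", path)
  seqid <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]

  origin <- grep("^ORIGIN", lines)
  seq <- ""
  if (length(origin)) {
    body <- lines[(origin[1] + 1L):length(lines)]
    body <- body[!grepl("^//", body)]
    seq <- toupper(gsub("[^acgtnACGTN]", "", paste(body, collapse = "")))
  }

  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) stop("GenBank file has no FEATURES table: ", path)
  fend <- if (length(origin)) origin[1] - 1L else length(lines)
  flines <- lines[(fstart[1] + 1L):fend]

  # a feature line has a key in columns 6-20; continuation lines are blank there
  is_key <- grepl("^ {5}\\S", flines)
  idx <- cumsum(is_key)
  feats <- list()
  for (i in unique(idx[idx > 0])) {
    block <- flines[idx == i]
    key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
    if (key != "CDS") next
    qual_start <- grep("^\\s+/", block)
    loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(block)
    loc <- gsub("\\s+", "", paste(
      sub("^\\s*CDS\\s*", "", block[1]),
      paste(trimws(block[seq_len(loc_end)][-1]), collapse = ""), sep = ""))
    quals <- paste(block[-seq_len(loc_end)], collapse = " ")
    getq <- function(q) {
      m <- regmatches(quals, regexpr(sprintf('/%s="[^"]*"', q), quals))
      if (length(m)) sub(sprintf('/%s="([^"]*)"', q), "\\1", m) else NA_character_
    }
    p <- parse_gb_location(loc)
    feats[[length(feats) + 1L]] <- data.frame(
      seqid = seqid, start = p$start, end = p$end, strand = p$strand,
      gene = getq("gene"), isoform = getq("locus_tag"),
      stringsAsFactors = FALSE)
  }
  if (!length(feats)) stop("GenBank file has no CDS features: ", path)
  f <- do.call(rbind, feats)
  f$gene[is.na(f$gene)] <- seqid
  f$isoform[is.na(f$isoform)] <- paste0(f$gene[is.na(f$isoform)], ".1")
  reference <- setNames(seq, seqid)
  if (!nzchar(seq)) reference <- character()
  list(reference = reference, features = f)
}

parse_gb_location <- function(loc) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  m <- regmatches(parts, regexec("^<?(\\d+)\\.\\.>?(\\d+)$|^(\\d+)$", parts))
  starts <- integer(0); ends <- integer(0)
  for (mm in m) {
    if (!length(mm)) stop("unsupported GenBank location: ", loc)
    if (nzchar(mm[2])) { a <- as.integer(mm[2]); b <- as.integer(mm[3]) }
    else { a <- b <- as.integer(mm[4]) }
    starts <- c(starts, a - 1L)   # 1-based inclusive -> 0-based half-open
    ends <- c(ends, b)
  }
  list(start = starts, end = ends, strand = strand)
}

#' Write gene models as GFF3
#'
#' One CDS feature per exon, with `gene_id` and `transcript_id` attributes, so
#' that [read_gene_models()] round-trips the models exactly.
#'
#' @param models List of [gene_model] objects.
#' @param path Output GFF3 path.
#' @export
write_gene_models_gff3 <- function(models, path) {
  rows <- unlist(lapply(models, function(m) {
    sprintf("%s\ttilescan\tCDS\t%d\t%d\t.\t%s\t.\tID=cds-%s-%d;gene_id=%s;transcript_id=%s",
            m$reference_id, m$exons$start + 1L, m$exons$end, m$strand,
            m$isoform_id, m$exons$rank, m$gene_symbol, m$isoform_id)
  }))
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Expanded guide-search intervals for a gene model
#'
#' Expands each CDS exon by the nuclease profile's extension lengths so that
#' guides straddling exon-intron boundaries are found. For SpCas9, 20 bp are
#' added on the 5' side and 9 bp on the 3' side of every exon *on the strand
#' being searched*, so the plus- and minus-strand search spaces differ. For
#' AsCpf1 the extension is 25 bp on each side but only at intron-exon
#' boundaries, not at the CDS start/stop termini. Intervals are clipped to the
#' reference and overlapping intervals merged.
#'
#' @param model A [gene_model].
#' @param profile A [nuclease_profile].
#' @param strand Strand being searched: `"+"` or `"-"`.
#' @param reference_length Length of the reference sequence (defaults to the
#'   length stored in the model).
#' @return `data.frame` with 0-based half-open `start`, `end` columns, sorted
#'   and non-overlapping.
#' @export
expanded_search_intervals <- function(model, profile, strand = "+",
                                      reference_length = model$reference_length) {
  stopifnot(strand %in% c("+", "-"))
  if (is.na(reference_length)) reference_length <- Inf
  ex <- model$exons[order(model$exons$start), , drop = FALSE]
  # extension on the genomic-left/right edge of each exon, for this search strand
  if (strand == "+") { left <- profile$ext5; right <- profile$ext3 }
  else               { left <- profile$ext3; right <- profile$ext5 }
  lext <- rep(left, nrow(ex)); rext <- rep(right, nrow(ex))
  if (isTRUE(profile$boundary_only)) {
    lext[which.min(ex$start)] <- 0L     # CDS terminus, not an intron boundary
    rext[which.max(ex$end)] <- 0L
  }
  s <- pmax(0L, ex$start - lext)
  e <- pmin(reference_length, ex$end + rext)
  r <- IRanges::reduce(IRanges::IRanges(start = s + 1L, end = e))
  data.frame(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

#' CDS-to-reference codon map and protein sequence
#'
#' Splices the CDS of a gene model strand-correctly, translates it with the
#' standard genetic code, and returns an invertible map from 0-based CDS
#' position to reference coordinate. Codon numbers are 1-based protein
#' numbering from the initiator Met: `codon_number(p) = floor(p/3) + 1`.
#'
#' @param model A complete [gene_model].
#' @param reference Reference sequence (character) of the model's chromosome,
#'   or the named vector from [read_reference()].
#' @return An object of class `codon_map`: list with `ref_coord` (integer
#'   vector indexed by CDS position + 1), `strand`, `cds`, `protein`,
#'   `premature_stop`, and the originating `model`. A premature internal stop
#'   triggers a warning and sets the flag; the map is kept.
#' @export
codon_map <- function(model, reference) {
  if (!is.null(names(reference)) && model$reference_id %in% names(reference))
    reference <- reference[[model$reference_id]]
  reference <- as.character(reference)
  if (model$cds_length %% 3L != 0L)
    stop("CDS length not divisible by 3; model is incomplete")
  ex <- model$exons  # already in rank (transcription) order
  coords <- unlist(lapply(seq_len(nrow(ex)), function(i) {
    if (model$strand == "+") ex$start[i]:(ex$end[i] - 1L)
    else (ex$end[i] - 1L):ex$start[i]
  }))
  bases <- strsplit(reference, "")[[1]][coords + 1L]
  if (model$strand == "-") bases <- chartr("ACGTN", "TGCAN", bases)
  cds <- paste(bases, collapse = "")
  protein <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "solve"))
  stops <- which(strsplit(protein, "")[[1]] == "*")
  premature <- length(stops) > 0 && any(stops < nchar(protein))
  if (premature)
    warning(sprintf("internal stop codon at protein position %d of %s/%s",
                    stops[1], model$gene_symbol, model$isoform_id))
  structure(list(ref_coord = as.integer(coords), strand = model$strand,
                 cds = cds, protein = protein, premature_stop = premature,
                 model = model),
            class = "codon_map")
}

#' @export
print.codon_map <- function(x, ...) {
  cat(sprintf("<codon_map> %s/%s: CDS %d bp, protein %d aa%s\n",
              x$model$gene_symbol, x$model$isoform_id, nchar(x$cds),
              nchar(x$protein),
              if (x$premature_stop) " [premature stop]" else ""))
  invisible(x)
}

#' Protein codon number of a CDS position
#' @param cds_pos 0-based CDS position(s).
#' @return 1-based codon (protein) number(s).
#' @export
codon_number <- function(cds_pos) cds_pos %/% 3L + 1L

#' Map reference coordinates to CDS positions
#'
#' @param map A [codon_map].
#' @param ref_coord 0-based reference coordinate(s).
#' @return 0-based CDS position(s); `NA` for non-coding coordinates.
#' @export
cds_position <- function(map, ref_coord) {
  match(ref_coord, map$ref_coord) - 1L
}

revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = ""),
    "", USE.NAMES = FALSE)
}
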