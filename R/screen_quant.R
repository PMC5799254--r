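# Pooled-screen guide quantification and the adjusted log2 fold-change
# enrichment statistic: log2((1 + RPM_after) / (1 + RPM_before)).

#' Count guide cassettes in pooled-screen reads
#'
#' For each read, the constant 5' flank of the guide cassette is located by
#' exact match (first occurrence); the following `protospacer_len` bases are
#' extracted and counted on exact match to the library. Reads without the
#' flank anchor or without an exact library match are tallied as unassigned.
#' Matching is exact by design: no mismatch rescue, so counts are fully
#' reproducible.
#'
#' @param fastq FASTQ path (gz-aware), or a character vector of read
#'   sequences.
#' @param library Guide library `data.frame` (`guide_id`, `protospacer`);
#'   protospacers must be unique across the library.
#' @param flank5 Constant cassette sequence immediately 5' of the
#'   protospacer.
#' @param flank3 Constant 3' cassette sequence (kept for provenance; the
#'   extraction is anchored on `flank5` alone).
#' @param sample_id Label stored in the table.
#' @return An object of class `count_table`: list with `sample_id`, `counts`
#'   (named integer over all library guides), `assigned_total`, `unassigned`,
#'   `reads_processed`.
#' @export
trim_and_count <- function(fastq, library, flank5, flank3 = NULL,
                           sample_id = "sample") {
  if (anyDuplicated(library$protospacer))
    stop("duplicate protospacers in library: assignment would be ambiguous")
  reads <- if (length(fastq) == 1 && file.exists(fastq))
    as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  else as.character(fastq)
  plen <- unique(nchar(library$protospacer))
  if (length(plen) != 1)
    stop("library protospacers must have uniform length")
  pos <- regexpr(flank5, reads, fixed = TRUE)
  ext <- rep(NA_character_, length(reads))
  hit <- pos > 0L
  ext[hit] <- substr(reads[hit], pos[hit] + nchar(flank5),
                     pos[hit] + nchar(flank5) + plen - 1L)
  idx <- match(ext, library$protospacer)
  assigned <- !is.na(idx)
  counts <- tabulate(idx[assigned], nbins = nrow(library))
  counts <- setNames(as.integer(counts), library$guide_id)
  structure(list(sample_id = sample_id, counts = counts,
                 assigned_total = sum(counts),
                 unassigned = length(reads) - sum(counts),
                 reads_processed = length(reads)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %s: %d guides, %d assigned / %d reads (%.1f%%)\n",
              x$sample_id, length(x$counts), x$assigned_total,
              x$reads_processed,
              100 * x$assigned_total / max(1, x$reads_processed)))
  invisible(x)
}

#' Reads per million assigned reads
#'
#' `rpm(g) = counts(g) * 1e6 / assigned_total`. The denominator is the number
#' of library-assigned reads, so the normalization is invariant to junk-read
#' contamination.
#'
#' @param table A `count_table`.
#' @return Named numeric vector summing to 1e6.
#' @export
rpm <- function(table) {
  if (table$assigned_total == 0) stop("no assigned reads: RPM undefined")
  table$counts * 1e6 / table$assigned_total
}

#' Per-guide fraction of assigned reads
#' @param table A `count_table`.
#' @return Named numeric vector summing to 1.
#' @export
read_fraction <- function(table) {
  if (table$assigned_total == 0) stop("no assigned reads: fraction undefined")
  table$counts / table$assigned_total
}

#' Adjusted log2 fold-change enrichment
#'
#' The screen's enrichment statistic per guide is
#' \deqn{\log_2\frac{1 + \mathrm{RPM}_{after}}{1 + \mathrm{RPM}_{before}}}
#' with RPM the reads per million assigned reads in the post-treatment and
#' post-puromycin (pre-treatment) pools. The +1 pseudocount is placed on the
#' RPM values by default; `pseudocount_on = "count"` instead adds 1 to each
#' raw read count before normalization (the alternative convention used in
#' some of the screen's dot plots). Guides absent from a sample count as 0.
#'
#' @param before,after `count_table`s over the same library.
#' @param pseudocount_on `"rpm"` (default) or `"count"`.
#' @return `data.frame` of class `enrichment_table` with columns `guide_id`,
#'   `rpm_before`, `rpm_after`, `log2_fc`, `read_fraction_after`, `hit`
#'   (`NA` until [call_hits()]).
#' @export
enrichment <- function(before, after, pseudocount_on = c("rpm", "count")) {
  pseudocount_on <- match.arg(pseudocount_on)
  if (!identical(sort(names(before$counts)), sort(names(after$counts))))
    stop("count tables are over different libraries")
  ids <- names(before$counts)
  cb <- before$counts[ids]
  ca <- after$counts[ids]
  rb <- cb * 1e6 / before$assigned_total
  ra <- ca * 1e6 / after$assigned_total
  lfc <- if (pseudocount_on == "rpm") {
    log2((1 + ra) / (1 + rb))
  } else {
    log2(((ca + 1) / after$assigned_total) / ((cb + 1) / before$assigned_total))
  }
  out <- data.frame(guide_id = ids, rpm_before = unname(rb),
                    rpm_after = unname(ra), log2_fc = unname(lfc),
                    read_fraction_after = unname(ca / after$assigned_total),
                    hit = NA)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Flag guides enriched above a fold-change threshold
#'
#' A guide is a hit when its adjusted fold change
#' `(1 + RPM_after) / (1 + RPM_before)` exceeds `fold_threshold`, i.e.
#' `log2_fc > log2(fold_threshold)`. The screens used a >100-fold rule.
#'
#' @param records An `enrichment_table` from [enrichment()].
#' @param fold_threshold Fold-change threshold (> 1).
#' @return `records` with the `hit` column set.
#' @export
call_hits <- function(records, fold_threshold = 100) {
  stopifnot(fold_threshold > 1)
  records$hit <- records$log2_fc > log2(fold_threshold)
  records
}

#' Intersect hit lists of replicate screens
#'
#' @param hitsA,hitsB `enrichment_table`s with hits called, or character
#'   vectors of guide ids.
#' @param library Optional library `data.frame` mapping `guide_id` to `gene`
#'   for the gene-level rollup.
#' @return List with `guides` (shared hit guide ids) and `genes` (per-gene
#'   hit counts among the shared set, if a library was given).
#' @export
replicate_intersection <- function(hitsA, hitsB, library = NULL) {
  ids <- function(h) {
    if (is.character(h)) h
    else h$guide_id[!is.na(h$hit) & h$hit]
  }
  shared <- intersect(ids(hitsA), ids(hitsB))
  genes <- NULL
  if (!is.null(library)) {
    gg <- library$gene[match(shared, library$guide_id)]
    genes <- sort(table(gg), decreasing = TRUE)
  }
  list(guides = shared, genes = genes)
}

#' Write / read a count table TSV
#' @param table A `count_table`.
#' @param path TSV path.
#' @export
write_counts <- function(table, path) {
  df <- data.frame(guide_id = names(table$counts),
                   count = unname(table$counts))
  hdr <- sprintf("# sample_id=%s assigned=%d unassigned=%d",
                 table$sample_id, table$assigned_total, table$unassigned)
  writeLines(c(hdr, paste(colnames(df), collapse = "\t"),
               paste(df$guide_id, df$count, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  kv <- do.call(rbind, strsplit(meta, "="))
  df <- read.delim(text = paste(lines[-1], collapse = "\n"),
                   stringsAsFactors = FALSE)
  counts <- setNames(as.integer(df$count), df$guide_id)
  structure(list(sample_id = kv[kv[, 1] == "sample_id", 2],
                 counts = counts, assigned_total = sum(counts),
                 unassigned = as.integer(kv[kv[, 1] == "unassigned", 2]),
                 reads_processed = sum(counts) +
                   as.integer(kv[kv[, 1] == "unassigned", 2])),
            class = "count_table")
}
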